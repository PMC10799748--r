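# helper: well-separated 2-feature toy problem
toy_tabular <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(c("positive", "negative"), n / 2)
  X <- cbind(f1 = rnorm(n, ifelse(y == "positive", 3, -3), 0.3),
             f2 = rnorm(n, ifelse(y == "positive", -3, 3), 0.3))
  list(X = X, y = y)
}

test_that("every family separates a linearly separable toy set", {
  toy <- toy_tabular(40)
  for (fam in c("rf", "svm", "knn", "gboost")) {
    m <- train_model(fam, toy$X, toy$y, seed = 3, validation = "none",
                     hyper = if (fam == "rf") list(num_trees = 100)
                             else if (fam == "gboost")
                               list(n_estimators = 50) else list())
    p <- predict_proba(m, toy$X)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(mean((p > 0.5) == (toy$y == "positive")), 1,
                 info = fam)
  }
  mdnn <- train_model("dnn", toy$X, toy$y, seed = 3, validation = "none",
                      hyper = list(units = c(16L, 8L),
                                   dropout = c(NA, NA), epochs = 30L))
  expect_gte(mean((predict_proba(mdnn, toy$X) > 0.5) ==
                    (toy$y == "positive")), 0.97)
  frs <- ifelse(toy$y == "positive", "DEDKDED", "WAWKWAW")
  mlstm <- train_model("lstm", labels = toy$y, fragments = frs,
                       seed = 3, validation = "none",
                       hyper = list(emb_dim = 8L, hidden = 8L,
                                    epochs = 20L))
  expect_equal(mean((predict_proba(mlstm, fragments = frs) > 0.5) ==
                      (toy$y == "positive")), 1)
})

test_that("deterministic families reproduce predictions given seed", {
  toy <- toy_tabular(30, seed = 4)
  Xnew <- toy_tabular(30, seed = 5)$X
  for (fam in c("rf", "svm", "knn", "gboost")) {
    hp <- if (fam == "rf") list(num_trees = 100)
          else if (fam == "gboost") list(n_estimators = 50) else list()
    m1 <- train_model(fam, toy$X, toy$y, hyper = hp, seed = 11,
                      validation = "none")
    m2 <- train_model(fam, toy$X, toy$y, hyper = hp, seed = 11,
                      validation = "none")
    expect_identical(predict_proba(m1, Xnew), predict_proba(m2, Xnew),
                     info = fam)
  }
})

test_that("training rejects single-class labels and non-finite features", {
  toy <- toy_tabular(20)
  expect_error(train_model("rf", toy$X, rep("positive", 20)),
               "single class")
  Xbad <- toy$X
  Xbad[3, 2] <- NaN
  expect_error(train_model("rf", Xbad, toy$y), "f2")
})

test_that("the scaler is fitted on the training partition alone", {
  toy <- toy_tabular(40, seed = 6)
  m <- train_model("svm", toy$X, toy$y, seed = 1, validation = "none")
  expect_equal(m$scaler$center, colMeans(toy$X))
  expect_equal(m$scaler$scale, apply(toy$X, 2, sd))

  # a deliberately leaky variant (test+train scaled together, then fed
  # pre-scaled) must change test predictions: the restriction is active
  test <- toy_tabular(40, seed = 7)
  all_scaled <- scale(rbind(toy$X, test$X))
  leaky <- train_model("svm", all_scaled[1:40, ], toy$y, seed = 1,
                       scale = FALSE, validation = "none")
  p_clean <- predict_proba(m, test$X)
  p_leaky <- predict_proba(leaky, all_scaled[41:80, ])
  expect_false(identical(p_clean, p_leaky))
})

test_that("grid search returns the single point of a one-point grid", {
  toy <- toy_tabular(24, seed = 8)
  out <- grid_search("rf", toy$X, toy$y, cv_folds = 3,
                     grid = data.frame(num_trees = 100L), seed = 2)
  expect_equal(out$hyper$num_trees, 100L)
  expect_length(out$grid_accuracy, 1L)
})

test_that("grid search recovers a planted optimal K for KNN", {
  # two tight clusters with 4 label-flipped points placed as nearest
  # neighbors of clean points: K = 1 copies the noise, K = 5 outvotes it,
  # K = 49 exceeds the cluster size and degenerates to the majority class
  set.seed(9)
  x_pos <- seq(0, 2.8, length.out = 15)
  x_neg <- seq(10, 12.8, length.out = 15)
  X <- cbind(x = c(x_pos, x_neg), z = 0)
  y <- rep(c("positive", "negative"), each = 15)
  y[c(3, 8)] <- "negative"   # flipped inside the positive cluster
  y[c(18, 23)] <- "positive" # flipped inside the negative cluster
  out <- suppressWarnings(  # class::knn caps k = 49 above the fold size
    grid_search("knn", X, y, cv_folds = 3,
                grid = data.frame(k = c(1L, 5L, 49L)), seed = 3))
  expect_equal(out$hyper$k, 5L)
})

test_that("grid order breaks ties deterministically", {
  toy <- toy_tabular(24, seed = 10)
  grid <- data.frame(num_trees = c(200L, 400L))
  out <- grid_search("rf", toy$X, toy$y, cv_folds = 3, grid = grid,
                     seed = 4)
  if (out$grid_accuracy[1] == out$grid_accuracy[2])
    expect_equal(out$hyper$num_trees, 200L)
  expect_length(out$grid_accuracy, 2L)
})

test_that("the average vote reproduces hand-set member probabilities", {
  v <- hybrid_vote(matrix(c(0.8, 0.6, 0.7, 0.9), 1), rep(0.8, 4))
  expect_equal(v$probability, 0.75)
  expect_equal(v$label, "positive")
  # all members agreeing on p returns p
  same <- hybrid_vote(matrix(0.3, 1, 4), rep(0.8, 4))
  expect_equal(same$probability, 0.3)
  expect_equal(same$label, "negative")
})

test_that("an exact 0.5 tie defers to the best-validated member", {
  probs <- matrix(c(0.9, 0.1, 0.7, 0.3), 1)
  expect_equal(rowMeans(probs), 0.5)
  v1 <- hybrid_vote(probs, c(0.9, 0.6, 0.6, 0.6))  # best member says 0.9
  expect_equal(v1$label, "positive")
  v2 <- hybrid_vote(probs, c(0.6, 0.9, 0.6, 0.6))  # best member says 0.1
  expect_equal(v2$label, "negative")
})

test_that("the vote is bounded by member extremes and order-invariant", {
  set.seed(12)
  for (i in 1:50) {
    p <- matrix(runif(4), 1)
    v <- hybrid_vote(p, runif(4))
    expect_gte(v$probability, min(p))
    expect_lte(v$probability, max(p))
    perm <- sample(4)
    expect_equal(hybrid_vote(p[, perm, drop = FALSE],
                             rep(0.5, 4))$probability, v$probability)
  }
})

test_that("hybrid training, prediction and member bookkeeping fit together", {
  cfg <- synthetic_config(n_proteins = 40L, length_range = c(80L, 120L),
                          n_positive_sites = 80L, motif_strength = 0.9,
                          seed = 21)
  fx <- end_to_end_fixture(cfg, half_width = 7L)
  X <- assemble_features(fx$train, c("eaac", "egaac"))
  Xt <- assemble_features(fx$test, c("eaac", "egaac"))
  hy <- train_hybrid(X, fx$train, fx$train$label, seed = 22,
                     hyper = list(rf = list(num_trees = 200),
                                  gboost = list(n_estimators = 100),
                                  lstm = list(epochs = 5L)))
  expect_named(hy$members, c("rf", "svm", "gboost", "lstm"))
  va <- vapply(hy$members, function(m) m$validation_accuracy, numeric(1))
  expect_true(all(va >= 0 & va <= 1))
  pr <- hybrid_predict(hy, Xt, fx$test)
  expect_equal(pr$probability,
               rowMeans(pr[, c("p_rf", "p_svm", "p_gboost", "p_lstm")]))
  broken <- hy
  broken$members$lstm <- NULL
  expect_error(hybrid_predict(broken, Xt, fx$test), "missing")
})

test_that("base learners and the hybrid separate a strongly planted motif", {
  cfg <- synthetic_config(n_proteins = 60L, length_range = c(80L, 120L),
                          n_positive_sites = 120L, motif_strength = 0.9,
                          seed = 23)
  fx <- suppressWarnings(end_to_end_fixture(cfg, half_width = 7L))
  X <- assemble_features(fx$train, c("eaac", "egaac", "blosum62"))
  Xt <- assemble_features(fx$test, c("eaac", "egaac", "blosum62"))
  aucs <- c()
  for (fam in c("rf", "svm", "knn", "gboost", "dnn")) {
    hp <- switch(fam, rf = list(num_trees = 300),
                 gboost = list(n_estimators = 150),
                 dnn = list(epochs = 40L), list())
    m <- train_model(fam, X, fx$train$label, hyper = hp, seed = 24,
                     validation = "none")
    aucs[fam] <- roc_auc(predict_proba(m, Xt), fx$test$label)$auc
  }
  mlstm <- train_model("lstm", labels = fx$train$label,
                       fragments = fx$train$residues, seed = 24,
                       validation = "none")
  aucs["lstm"] <- roc_auc(predict_proba(mlstm,
                                        fragments = fx$test$residues),
                          fx$test$label)$auc
  hy <- train_hybrid(X, fx$train, fx$train$label, seed = 25,
                     hyper = list(rf = list(num_trees = 300),
                                  gboost = list(n_estimators = 150)))
  aucs["hybrid"] <- roc_auc(hybrid_predict(hy, Xt, fx$test)$probability,
                            fx$test$label)$auc
  expect_true(all(aucs >= 0.9), info = paste(names(aucs), round(aucs, 3),
                                             collapse = " "))
})
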