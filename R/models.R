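## Uniform train/predict-probability contracts for the base learners (random
## forest, RBF-SVM, KNN, gradient boosting, dense net, LSTM), grid search over
## their declared hyperparameter domains, and the equal-weight soft-voting
## hybrid of four members.

MODEL_FAMILIES <- c("rf", "svm", "knn", "gboost", "dnn", "lstm")

norm_labels <- function(labels) {
  if (is.numeric(labels)) labels <- ifelse(labels > 0, "positive", "negative")
  labels <- as.character(labels)
  if (!all(labels %in% c("positive", "negative")))
    stop("labels must be 'positive'/'negative' (or 0/1)")
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class")
  list(y = as.integer(labels == "positive"),
       fac = factor(labels, levels = c("negative", "positive")))
}

fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(scaler, X) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, `/`)
}

check_features <- function(X) {
  bad <- which(apply(X, 2, function(v) any(!is.finite(v))))
  if (length(bad) > 0L)
    stop("non-finite feature column(s): ",
         paste(utils::head(colnames(X)[bad], 10), collapse = ", "))
}

default_hyper <- function(family) {
  switch(family,
    rf = list(num_trees = 1000L),
    svm = list(cost = 10, gamma = 0.001),
    knn = list(k = 5L),
    gboost = list(n_estimators = 1000L, max_depth = 6L),
    dnn = list(units = c(512L, 256L, 128L, 128L, 64L, 128L, 256L),
               dropout = c(0.5, 0.4, 0.4, 0.4, 0.4, NA, 0.5),
               lr = 0.001, epochs = 50L, batch_size = 32L),
    lstm = list(emb_dim = 64L, hidden = 64L, lr = 0.001, epochs = 10L,
                batch_size = 32L))
}

fit_family <- function(family, X, y, fac, seqs, hp, seed) {
  switch(family,
    rf = ranger::ranger(x = X, y = fac, num.trees = hp$num_trees,
                        mtry = floor(sqrt(ncol(X))), probability = TRUE,
                        seed = seed, num.threads = 1L),
    svm = with_seed(seed,
      e1071::svm(x = X, y = fac, kernel = "radial", cost = hp$cost,
                 gamma = hp$gamma, probability = TRUE, scale = FALSE)),
    knn = list(train = X, fac = fac, k = hp$k),
    gboost = with_seed(seed,
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth, nthread = 1L,
                      seed = seed),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
        nrounds = hp$n_estimators, verbose = 0)),
    dnn = train_dense_net(X, y, units = hp$units, dropout = hp$dropout,
                          lr = hp$lr, epochs = hp$epochs,
                          batch_size = hp$batch_size, seed = seed),
    lstm = train_lstm(seqs, y, emb_dim = hp$emb_dim, hidden = hp$hidden,
                      lr = hp$lr, epochs = hp$epochs,
                      batch_size = hp$batch_size, seed = seed))
}

predict_family <- function(family, fit, X, seqs, seed = 1L) {
  switch(family,
    rf = stats::predict(fit, data = X, num.threads = 1L)$
      predictions[, "positive"],
    svm = {
      pr <- attr(stats::predict(fit, X, probability = TRUE), "probabilities")
      pr[, "positive"]
    },
    knn = {
      pred <- with_seed(seed, class::knn(fit$train, X, fit$fac, k = fit$k,
                                         prob = TRUE))
      p_win <- attr(pred, "prob")
      ifelse(pred == "positive", p_win, 1 - p_win)
    },
    gboost = stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1L)),
    dnn = predict_dense_net(fit, X),
    lstm = predict_lstm(fit, seqs))
}

#' Train a base classifier with a leak-free scaler
#'
#' Tabular families (`rf`, `svm`, `knn`, `gboost`, `dnn`) consume a feature
#' matrix and standardize it with per-feature statistics computed from the
#' training rows only; the fitted scaler is stored and re-applied at predict
#' time.  The `lstm` family consumes the raw fragment residue strings
#' (integer-mapped internally).  Defaults: random forest with 1000 trees and
#' sqrt(p) features per split; RBF-SVM with cost 10 and gamma 0.001; KNN with
#' K = 5; gradient boosting with 1000 estimators of depth 6; the dense net
#' and LSTM as documented in [train_dense_net()] and [train_lstm()].
#'
#' Validation accuracy (used by the hybrid tie-break) is estimated on a
#' seeded stratified 20% internal hold-out before the final fit on the full
#' training partition; `validation = "none"` skips it.
#'
#' @param family One of `r paste(MODEL_FAMILIES, collapse = ", ")`.
#' @param features Numeric feature matrix (tabular families).
#' @param labels `"positive"`/`"negative"` (or 0/1) labels.
#' @param fragments Character vector of residue strings (`lstm`).
#' @param hyper Named list of hyperparameter overrides.
#' @param seed Integer seed.
#' @param scale Standardize features (default TRUE).  Disabling it is only
#'   meant for inputs scaled by other leak-free means.
#' @param validation `"holdout"` or `"none"`.
#' @return A `trained_model` with elements `family`, `hyper`, `fit`,
#'   `scaler`, `validation_accuracy`, `seed`.
#' @export
train_model <- function(family, features = NULL, labels, fragments = NULL,
                        hyper = list(), seed = 1L, scale = TRUE,
                        validation = c("holdout", "none")) {
  family <- match.arg(family, MODEL_FAMILIES)
  validation <- match.arg(validation)
  lab <- norm_labels(labels)
  hp <- utils::modifyList(default_hyper(family), hyper)
  seqs <- NULL; X <- NULL; scaler <- NULL
  if (family == "lstm") {
    if (is.null(fragments)) stop("lstm needs fragment residue strings")
    seqs <- fragments_to_int(fragments)
  } else {
    if (is.null(features)) stop(family, " needs a feature matrix")
    X <- as.matrix(features)
    check_features(X)
    if (scale) {
      scaler <- fit_scaler(X)
      X <- apply_scaler(scaler, X)
    }
  }
  val_acc <- NA_real_
  if (validation == "holdout") {
    n <- length(lab$y)
    hold <- with_seed(seed + 104729L, {
      idx_pos <- which(lab$y == 1L); idx_neg <- which(lab$y == 0L)
      c(sample(idx_pos, max(1L, round(0.2 * length(idx_pos)))),
        sample(idx_neg, max(1L, round(0.2 * length(idx_neg)))))
    })
    if (length(unique(lab$y[-hold])) == 2L) {
      fit0 <- fit_family(family, X[-hold, , drop = FALSE], lab$y[-hold],
                         lab$fac[-hold],
                         if (!is.null(seqs)) seqs[-hold, , drop = FALSE],
                         hp, seed)
      p0 <- predict_family(family, fit0, X[hold, , drop = FALSE],
                           if (!is.null(seqs)) seqs[hold, , drop = FALSE],
                           seed)
      val_acc <- mean((p0 > 0.5) == (lab$y[hold] == 1L))
    }
  }
  fit <- fit_family(family, X, lab$y, lab$fac, seqs, hp, seed)
  structure(list(family = family, hyper = hp, fit = fit, scaler = scaler,
                 validation_accuracy = val_acc, seed = as.integer(seed)),
            class = "trained_model")
}

#' Predict positive-class probabilities
#'
#' @param model A `trained_model`.
#' @param features Feature matrix (tabular families).
#' @param fragments Residue strings (`lstm`).
#' @return Numeric probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, features = NULL, fragments = NULL) {
  stopifnot(inherits(model, "trained_model"))
  if (model$family == "lstm") {
    if (is.null(fragments)) stop("lstm needs fragment residue strings")
    return(predict_family("lstm", model$fit, NULL,
                          fragments_to_int(fragments), model$seed))
  }
  if (is.null(features)) stop(model$family, " needs a feature matrix")
  X <- apply_scaler(model$scaler, as.matrix(features))
  predict_family(model$family, model$fit, X, NULL, model$seed)
}

#' Default hyperparameter grids
#'
#' rf: trees 100..1000 by 100; svm: cost decades 1e-4..1e4, gamma decades
#' 1e-4..1; knn: odd K in 1..99; gboost: estimators 100..1000 by 100, depth
#' 3..8.
#'
#' @param family Model family.
#' @return data.frame, one row per grid point, in grid order.
#' @export
default_grid <- function(family) {
  switch(family,
    rf = data.frame(num_trees = seq(100L, 1000L, 100L)),
    svm = expand.grid(gamma = 10^(-4:0), cost = 10^(-4:4))[, c("cost",
                                                               "gamma")],
    knn = data.frame(k = seq(1L, 99L, 2L)),
    gboost = expand.grid(max_depth = 3:8,
                         n_estimators = seq(100L, 1000L, 100L))[,
                           c("n_estimators", "max_depth")],
    stop("no default grid for family '", family, "'"))
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Grid search by stratified cross-validated accuracy
#'
#' Evaluates each grid point with k-fold stratified CV (scaler refit per
#' fold) and returns the point maximizing mean CV accuracy; ties go to the
#' first point in grid order.
#'
#' @param family Model family (`rf`, `svm`, `knn`, `gboost`).
#' @param features Feature matrix.
#' @param labels Labels.
#' @param cv_folds Number of folds (default 5).
#' @param grid Optional data.frame of grid points (defaults to
#'   [default_grid()]); values must lie within the default domains.
#' @param seed Integer seed.
#' @return List with `family`, `hyper` (best point), `accuracy`, and the
#'   per-point mean accuracies.
#' @export
grid_search <- function(family, features, labels, cv_folds = 5L, grid = NULL,
                        seed = 1L) {
  family <- match.arg(family, c("rf", "svm", "knn", "gboost"))
  if (is.null(grid)) grid <- default_grid(family)
  lab <- norm_labels(labels)
  X <- as.matrix(features)
  fold <- stratified_folds(lab$y, cv_folds, seed)
  if (any(tapply(lab$y, fold, function(v) length(unique(v))) < 2L))
    stop("stratification error: a fold contains a single class")
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    hp <- as.list(grid[gi, , drop = FALSE])
    correct <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      scaler <- fit_scaler(X[tr, , drop = FALSE])
      Xtr <- apply_scaler(scaler, X[tr, , drop = FALSE])
      Xte <- apply_scaler(scaler, X[!tr, , drop = FALSE])
      fit <- fit_family(family, Xtr, lab$y[tr], lab$fac[tr], NULL,
                        utils::modifyList(default_hyper(family), hp), seed)
      p <- predict_family(family, fit, Xte, NULL, seed)
      correct <- correct + sum((p > 0.5) == (lab$y[!tr] == 1L))
    }
    acc[gi] <- correct / length(lab$y)
  }
  best <- which.max(acc)  # which.max takes the first maximum: grid order
  list(family = family, hyper = as.list(grid[best, , drop = FALSE]),
       accuracy = acc[best], grid_accuracy = acc)
}

#' Train the four-member soft-voting hybrid
#'
#' Trains the tabular random forest, RBF-SVM and gradient-boosting members
#' on the feature matrix and the LSTM member on the raw fragment residues,
#' each with its defaults (overridable per member through `hyper`), and
#' stores each member's internal validation accuracy for the tie-break rule.
#'
#' @param features Feature matrix aligned to `fragments`.
#' @param fragments Fragment data.frame (`id`, `residues`) or character
#'   vector of residue strings.
#' @param labels Labels.
#' @param hyper Named list of per-member hyperparameter overrides, e.g.
#'   `list(rf = list(num_trees = 500))`.
#' @param seed Integer seed (fanned out per member by fixed offsets).
#' @return A `hybrid_model` with `members` (rf, svm, gboost, lstm).
#' @export
train_hybrid <- function(features, fragments, labels, hyper = list(),
                         seed = 1L) {
  res <- if (is.data.frame(fragments)) fragments$residues else fragments
  fams <- c("rf", "svm", "gboost", "lstm")
  members <- list()
  for (i in seq_along(fams)) {
    fam <- fams[i]
    members[[fam]] <- train_model(
      fam,
      features = if (fam == "lstm") NULL else features,
      labels = labels,
      fragments = if (fam == "lstm") res else NULL,
      hyper = if (is.null(hyper[[fam]])) list() else hyper[[fam]],
      seed = seed + i)
  }
  structure(list(members = members), class = "hybrid_model")
}

#' Equal-weight average vote over member probabilities
#'
#' y = mean of the member probabilities; label positive iff y > 0.5; at
#' exactly 0.5 the label is copied from the member with the highest
#' validation accuracy.
#'
#' @param probs Matrix of member probabilities (rows = fragments, one column
#'   per member).
#' @param validation_accuracy Numeric vector aligned to columns, used only
#'   to break exact ties.
#' @return data.frame with `probability` and `label`.
#' @export
hybrid_vote <- function(probs, validation_accuracy) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == length(validation_accuracy))
  y <- rowMeans(probs)
  label <- ifelse(y > 0.5, "positive", "negative")
  ties <- which(y == 0.5)
  if (length(ties) > 0L) {
    best <- which.max(validation_accuracy)
    label[ties] <- ifelse(probs[ties, best] > 0.5, "positive", "negative")
  }
  data.frame(probability = y, label = label, stringsAsFactors = FALSE)
}

#' Equal-weight soft-voting prediction
#'
#' The hybrid probability is the arithmetic mean of the four member
#' probabilities; the label is positive iff it exceeds 0.5.  When it equals
#' 0.5 exactly, the label is copied from the member with the highest
#' validation accuracy.
#'
#' @param hybrid A `hybrid_model`.
#' @param features Feature matrix for the tabular members.
#' @param fragments Fragment data.frame or residue strings for the LSTM
#'   member.
#' @return data.frame with `probability`, `label` and one probability column
#'   per member.
#' @export
hybrid_predict <- function(hybrid, features, fragments) {
  stopifnot(inherits(hybrid, "hybrid_model"))
  need <- c("rf", "svm", "gboost", "lstm")
  if (!all(need %in% names(hybrid$members)))
    stop("hybrid member(s) missing: ",
         paste(setdiff(need, names(hybrid$members)), collapse = ", "))
  res <- if (is.data.frame(fragments)) fragments$residues else fragments
  probs <- sapply(need, function(fam)
    predict_proba(hybrid$members[[fam]],
                  features = if (fam == "lstm") NULL else features,
                  fragments = if (fam == "lstm") res else NULL))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, need))
  va <- vapply(hybrid$members[need], function(m) m$validation_accuracy,
               numeric(1))
  out <- hybrid_vote(probs, va)
  out[paste0("p_", need)] <- as.data.frame(probs)
  out
}
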