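## Confusion-matrix metrics, ROC/PR curves with trapezoid AUC, and the
## leak-free stratified cross-validation harness.  Metrics are stored as
## fractions throughout; multiply by 100 only for display.

#' Build confusion counts from labels and predictions
#'
#' @param truth `"positive"`/`"negative"` (or 0/1) true labels.
#' @param predicted Predicted labels in the same coding.
#' @return List with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  t01 <- if (is.numeric(truth)) truth > 0 else truth == "positive"
  p01 <- if (is.numeric(predicted)) predicted > 0 else predicted == "positive"
  list(TP = sum(t01 & p01), TN = sum(!t01 & !p01),
       FP = sum(!t01 & p01), FN = sum(t01 & !p01))
}

safe_ratio <- function(num, den) if (den == 0) NaN else num / den

#' Threshold classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision, F1, Matthews
#' correlation coefficient and Cohen's kappa
#' (2(TP*TN - FN*FP) / ((TP+FP)(FP+TN) + (TP+FN)(FN+TN))), all as fractions.
#' Ratios with a zero denominator are reported as `NaN` and flagged in
#' `undefined`, never silently zeroed.
#'
#' @param counts List with non-negative `TP`, `TN`, `FP`, `FN`
#'   (see [confusion_counts()]).
#' @return A `metrics_report` list.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, TN, FP, FN) < 0)) stop("negative confusion counts")
    n <- TP + TN + FP + FN
    if (n == 0) stop("empty confusion matrix")
    mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
    kap_den <- (TP + FP) * (FP + TN) + (TP + FN) * (FN + TN)
    prec <- safe_ratio(TP, TP + FP)
    sens <- safe_ratio(TP, TP + FN)
    rep <- list(
      accuracy = (TP + TN) / n,
      sensitivity = sens,
      specificity = safe_ratio(TN, TN + FP),
      precision = prec,
      f1 = if (is.nan(prec) || is.nan(sens) || prec + sens == 0) NaN
           else 2 * prec * sens / (prec + sens),
      mcc = if (mcc_den == 0) NaN else (TP * TN - FN * FP) / mcc_den,
      kappa = if (kap_den == 0) NaN
              else 2 * (TP * TN - FN * FP) / kap_den,
      counts = counts)
    rep$undefined <- names(which(vapply(
      rep[c("sensitivity", "specificity", "precision", "f1", "mcc",
            "kappa")], is.nan, logical(1))))
    class(rep) <- "metrics_report"
    rep
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Classification metrics (x100):\n")
  for (m in c("accuracy", "sensitivity", "specificity", "precision", "f1",
              "mcc", "kappa"))
    cat(sprintf("  %-12s %6.2f\n", m, 100 * x[[m]]))
  if (!is.null(x$auc_roc)) cat(sprintf("  %-12s %6.2f\n", "auc_roc",
                                       100 * x$auc_roc))
  if (!is.null(x$auc_pr)) cat(sprintf("  %-12s %6.2f\n", "auc_pr",
                                      100 * x$auc_pr))
  invisible(x)
}

roc_points <- function(scores, labels) {
  y <- if (is.numeric(labels)) labels > 0 else labels == "positive"
  if (length(unique(y)) < 2L) stop("ROC/PR need both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(y); nn <- sum(!y)
  tp <- vapply(thr, function(t) sum(scores >= t & y), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !y), numeric(1))
  data.frame(threshold = thr, tpr = tp / np, fpr = fp / nn,
             precision = ifelse(tp + fp == 0, 1, tp / (tp + fp)),
             recall = tp / np)
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                             utils::tail(y, -1)) / 2)

#' ROC curve and trapezoid AUC
#'
#' The curve sweeps all distinct score thresholds; the trapezoid AUC equals
#' the Mann-Whitney statistic with tied score pairs counted one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels True labels.
#' @return List with `auc` and `curve` (threshold, tpr, fpr points).
#' @export
roc_auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  fpr <- c(0, pts$fpr, 1)
  tpr <- c(0, pts$tpr, 1)
  list(auc = trapezoid(fpr, tpr),
       curve = pts[, c("threshold", "tpr", "fpr")])
}

#' Precision-recall curve and trapezoid AUC
#'
#' Trapezoid over recall; the curve starts at recall 0 with the precision of
#' the strictest threshold.
#'
#' @inheritParams roc_auc
#' @return List with `auc` and `curve` (threshold, precision, recall).
#' @export
pr_auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  rec <- c(0, pts$recall)
  prec <- c(pts$precision[1], pts$precision)
  list(auc = trapezoid(rec, prec),
       curve = pts[, c("threshold", "precision", "recall")])
}

#' Full evaluation of probabilistic predictions
#'
#' Threshold metrics at `threshold` plus ROC and PR AUC with their curves.
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels True labels.
#' @param threshold Decision threshold (default 0.5).
#' @return A `metrics_report` with `auc_roc`, `auc_pr` and `curves`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  pred <- ifelse(scores > threshold, "positive", "negative")
  rep <- compute_metrics(confusion_counts(labels, pred))
  roc <- roc_auc(scores, labels)
  pr <- pr_auc(scores, labels)
  rep$auc_roc <- roc$auc
  rep$auc_pr <- pr$auc
  rep$curves <- merge(roc$curve, pr$curve, by = "threshold")
  rep
}

#' Leak-free stratified k-fold cross-validation
#'
#' Folds are stratified by fragment label.  Within every fold the
#' corpus-fitted encoder states (BPB, PWM, KNN-feature, TF-IDF, TF-CRF) and
#' the feature scaler are fitted on the training folds only and then applied
#' to the held-out fold; the KNN-feature encoder additionally excludes each
#' training fragment from its own neighbor pool.
#'
#' @param fragments Fragment data.frame with `id`, `protein_id`,
#'   `center_pos`, `residues`, `label`.
#' @param schemes Encoder scheme list for [assemble_features()].
#' @param family Model family or `"hybrid"`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param profiles,aaindex Passed to [assemble_features()].
#' @param hyper Hyperparameter overrides.
#' @param threshold Decision threshold.
#' @return List with `folds` (per-fold `metrics_report`s), `pooled` (report
#'   over all out-of-fold predictions), `mean`, `sd` (per-metric across
#'   folds), and `predictions` (id, fold, probability, label, truth).
#' @export
cross_validate <- function(fragments, schemes, family = "hybrid", k = 5L,
                           seed = 1L, profiles = NULL, aaindex = NULL,
                           hyper = list(), threshold = 0.5) {
  if (k < 2L) stop("k must be >= 2")
  y <- fragments$label
  fold <- stratified_folds(as.integer(y == "positive"), k, seed)
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2L))
    stop("stratification error: a fold contains a single class")
  preds <- data.frame(id = fragments$id, fold = fold,
                      probability = NA_real_, truth = y,
                      stringsAsFactors = FALSE)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fragments[fold != f, , drop = FALSE]
    te <- fragments[fold == f, , drop = FALSE]
    states <- fit_encoder_states(schemes, tr)
    Xtr <- assemble_features(tr, schemes, states, profiles, aaindex,
                             loo_knn = TRUE)
    Xte <- assemble_features(te, schemes, states, profiles, aaindex)
    if (family == "hybrid") {
      mod <- train_hybrid(Xtr, tr, tr$label, hyper = hyper, seed = seed + f)
      p <- hybrid_predict(mod, Xte, te)$probability
    } else {
      mod <- train_model(family,
                         features = if (family == "lstm") NULL else Xtr,
                         labels = tr$label,
                         fragments = if (family == "lstm") tr$residues,
                         hyper = hyper, seed = seed + f,
                         validation = "none")
      p <- predict_proba(mod,
                         features = if (family == "lstm") NULL else Xte,
                         fragments = if (family == "lstm") te$residues)
    }
    preds$probability[fold == f] <- p
    reports[[f]] <- evaluate_predictions(p, te$label, threshold)
  }
  pooled <- evaluate_predictions(preds$probability, preds$truth, threshold)
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    "f1", "mcc", "kappa", "auc_roc", "auc_pr")
  permetric <- sapply(metric_names, function(m)
    vapply(reports, function(r) r[[m]], numeric(1)))
  list(folds = reports, pooled = pooled,
       mean = colMeans(permetric), sd = apply(permetric, 2, stats::sd),
       predictions = preds)
}
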