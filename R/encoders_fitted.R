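## Corpus-fitted encoders.  Each `fit_*` returns an `encoder_state` (a plain,
## serializable list) fitted exclusively on training-fold fragments; the
## matching `encode_*` maps a fragment to features using only that state, so
## held-out labels can never leak into the encoding.

new_encoder_state <- function(scheme, ...) {
  structure(c(list(scheme = scheme), list(...)), class = "encoder_state")
}

check_state <- function(state, scheme) {
  if (!inherits(state, "encoder_state") || !identical(state$scheme, scheme))
    stop("encode_", scheme, ": fit_", scheme, "() state required (got ",
         if (inherits(state, "encoder_state")) state$scheme else class(state)[1],
         ")")
}

# positional 21 x L count matrix of a fragment set
positional_counts <- function(fragments) {
  L <- nchar(fragments[1])
  cnt <- matrix(0L, 21L, L, dimnames = list(AA21, NULL))
  for (f in fragments) {
    idx <- residue_index(split_residues(f))
    cnt[cbind(idx, seq_len(L))] <- cnt[cbind(idx, seq_len(L))] + 1L
  }
  cnt
}

#' Bi-profile Bayes (BPB) encoder
#'
#' `fit_bpb()` tabulates positional residue counts separately over the
#' positive and negative training fragments.  `encode_bpb()` emits the 2L
#' vector of positional posteriors: x_i = (count of the query's residue at
#' position i among positives + alpha) / (N+ + 21*alpha) for i = 1..L, and
#' the analogous negative-class posteriors for i = L+1..2L.
#'
#' @param fragments Character vector of training fragment residue strings.
#' @param labels Character vector, `"positive"`/`"negative"`.
#' @param alpha Pseudocount over the 21 symbols (default 1; 0 reproduces raw
#'   frequencies).
#' @return `fit_bpb`: an `encoder_state`; `encode_bpb`: numeric vector of 2L
#'   features.
#' @export
fit_bpb <- function(fragments, labels, alpha = 1) {
  if (!all(c("positive", "negative") %in% labels))
    stop("fit_bpb needs both classes in the training set")
  new_encoder_state("bpb",
    pos = positional_counts(fragments[labels == "positive"]),
    neg = positional_counts(fragments[labels == "negative"]),
    n_pos = sum(labels == "positive"), n_neg = sum(labels == "negative"),
    alpha = alpha)
}

#' @rdname fit_bpb
#' @param state A fitted `encoder_state`.
#' @param fragment Residue string to encode.
#' @export
encode_bpb <- function(state, fragment) {
  check_state(state, "bpb")
  idx <- residue_index(split_residues(fragment))
  L <- length(idx)
  if (L != ncol(state$pos))
    stop("fragment length ", L, " does not match fitted length ",
         ncol(state$pos))
  a <- state$alpha
  xp <- (state$pos[cbind(idx, seq_len(L))] + a) / (state$n_pos + 21 * a)
  xn <- (state$neg[cbind(idx, seq_len(L))] + a) / (state$n_neg + 21 * a)
  out <- c(xp, xn)
  names(out) <- c(paste0("BPB.pos.p", pad2(seq_len(L))),
                  paste0("BPB.neg.p", pad2(seq_len(L))))
  out
}

#' Position weight matrix (PWM) encoder
#'
#' `fit_pwm()` builds a positional frequency matrix from the positive
#' training fragments with pseudocount `alpha` over the 21 symbols;
#' `encode_pwm()` emits, per position, the fitted frequency of the query's
#' residue there (L features).
#'
#' @param positives Character vector of positive training fragments.
#' @param alpha Pseudocount (default 1).
#' @export
fit_pwm <- function(positives, alpha = 1) {
  if (length(positives) == 0L) stop("fit_pwm needs at least one positive")
  cnt <- positional_counts(positives)
  new_encoder_state("pwm",
    freq = (cnt + alpha) / (length(positives) + 21 * alpha))
}

#' @rdname fit_pwm
#' @param state A fitted `encoder_state`.
#' @param fragment Residue string to encode.
#' @export
encode_pwm <- function(state, fragment) {
  check_state(state, "pwm")
  idx <- residue_index(split_residues(fragment))
  L <- length(idx)
  if (L != ncol(state$freq))
    stop("fragment length ", L, " does not match fitted length ",
         ncol(state$freq))
  out <- state$freq[cbind(idx, seq_len(L))]
  names(out) <- paste0("PWM.p", pad2(seq_len(L)))
  out
}

# 21x21 similarity matrix: min-max normalized BLOSUM62; pairs involving the
# dummy symbol score 0
knn_sim_matrix <- function() {
  b <- blosum62_matrix()
  s <- (b - min(b)) / (max(b) - min(b))
  out <- matrix(0, 21, 21, dimnames = list(AA21, AA21))
  out[AA20, AA20] <- s
  out
}

#' KNN similarity-profile encoder
#'
#' `fit_knn_feature()` stores the training fragments and labels.  For a
#' query, Dist(S1,S2) = 1 - mean positional similarity, with similarity the
#' min-max-normalized BLOSUM62 score (so Dist(W-run, W-run) = 0); per
#' neighbor fraction k the feature is the fraction of positives among the
#' `ceiling(k*N)` nearest training fragments (distance ties broken by
#' training-set order).  When the query is itself a training fragment
#' (matched by id), it is excluded from its own neighbor pool.
#'
#' @param fragments Character vector of training fragment residue strings.
#' @param labels `"positive"`/`"negative"` labels.
#' @param ids Optional fragment ids enabling self-exclusion at encode time.
#' @export
fit_knn_feature <- function(fragments, labels, ids = NULL) {
  if (length(fragments) == 0L) stop("fit_knn_feature: empty training set")
  L <- nchar(fragments[1])
  mat <- t(vapply(fragments,
                  function(f) residue_index(split_residues(f)),
                  integer(L)))
  rownames(mat) <- NULL
  new_encoder_state("knn", train = mat,
                    is_pos = labels == "positive",
                    ids = ids, sim = knn_sim_matrix())
}

#' @rdname fit_knn_feature
#' @param state A fitted `encoder_state`.
#' @param fragment Residue string to encode.
#' @param k_fracs Neighbor fractions (default 1, 2, 5, 10 percent).
#' @param id Optional id of the query fragment for self-exclusion.
#' @export
encode_knn <- function(state, fragment, k_fracs = c(0.01, 0.02, 0.05, 0.10),
                       id = NULL) {
  check_state(state, "knn")
  q <- residue_index(split_residues(fragment))
  L <- length(q)
  if (L != ncol(state$train))
    stop("fragment length ", L, " does not match fitted length ",
         ncol(state$train))
  n <- nrow(state$train)
  simsum <- rowSums(matrix(state$sim[cbind(rep(q, each = n),
                                           as.vector(state$train))],
                           nrow = n))
  d <- 1 - simsum / L
  keep <- rep(TRUE, n)
  if (!is.null(id) && !is.null(state$ids)) keep <- state$ids != id
  ord <- which(keep)[order(d[keep])]
  n_eff <- length(ord)
  out <- vapply(k_fracs, function(k) {
    kk <- max(1L, ceiling(k * n_eff))
    mean(state$is_pos[ord[seq_len(kk)]])
  }, numeric(1))
  names(out) <- paste0("KNN.k", sub("^0\\.", "", format(k_fracs)))
  out
}

#' TF-IDF residue encoder
#'
#' `fit_tfidf()` records document frequencies of the 20 standard residues
#' over the training corpus.  `encode_tfidf()` emits TF(t,d) * IDF(t) with
#' TF = count/L and IDF = log10(|D| / DF(t)) (0 when DF = 0).
#'
#' @param fragments Character vector of training fragment residue strings.
#' @export
fit_tfidf <- function(fragments) {
  if (length(fragments) == 0L) stop("fit_tfidf: empty corpus")
  df <- vapply(AA20, function(a)
    sum(vapply(fragments, function(f) grepl(a, f, fixed = TRUE),
               logical(1))), numeric(1))
  new_encoder_state("tfidf", df = df, n_docs = length(fragments))
}

#' @rdname fit_tfidf
#' @param state A fitted `encoder_state`.
#' @param fragment Residue string to encode.
#' @export
encode_tfidf <- function(state, fragment) {
  check_state(state, "tfidf")
  res <- split_residues(fragment)
  L <- length(res)
  tf <- as.numeric(table(factor(res, levels = AA20))) / L
  idf <- ifelse(state$df > 0, log10(state$n_docs / state$df), 0)
  out <- tf * idf
  names(out) <- paste0("TFIDF.", AA20)
  out
}

#' TF-CRF residue encoder
#'
#' Term frequency weighted by the category relevancy factor.  For category c
#' and term t: PositiveRF(t,c) is the fraction of class-c training fragments
#' containing t, NegativeRF(t,c) the same fraction over the opposite class,
#' and crfValue = PositiveRF / (NegativeRF + eps).  The weight of t in a
#' query d is log(1 + count(t in d)) * crfValue(t,c).  To stay label-free at
#' encode time the weight is emitted w.r.t. both categories (2 x 20
#' features).
#'
#' @param fragments Character vector of training fragment residue strings.
#' @param labels `"positive"`/`"negative"` labels.
#' @param eps Denominator stabilizer (default 1e-6).
#' @export
fit_tfcrf <- function(fragments, labels, eps = 1e-6) {
  if (!all(c("positive", "negative") %in% labels))
    stop("fit_tfcrf needs both classes in the training set")
  has_term <- function(cls) vapply(AA20, function(a)
    sum(vapply(fragments[labels == cls],
               function(f) grepl(a, f, fixed = TRUE), logical(1))),
    numeric(1))
  new_encoder_state("tfcrf",
    n_pos = sum(labels == "positive"), n_neg = sum(labels == "negative"),
    t_pos = has_term("positive"), t_neg = has_term("negative"), eps = eps)
}

#' @rdname fit_tfcrf
#' @param state A fitted `encoder_state`.
#' @param fragment Residue string to encode.
#' @export
encode_tfcrf <- function(state, fragment) {
  check_state(state, "tfcrf")
  res <- split_residues(fragment)
  cnt <- as.numeric(table(factor(res, levels = AA20)))
  logtf <- log(1 + cnt)
  rf_pos <- state$t_pos / state$n_pos   # P(t | positive)
  rf_neg <- state$t_neg / state$n_neg   # P(t | negative)
  crf_pos <- rf_pos / (rf_neg + state$eps)  # w.r.t. positive category
  crf_neg <- rf_neg / (rf_pos + state$eps)  # w.r.t. negative category
  out <- c(logtf * crf_pos, logtf * crf_neg)
  names(out) <- c(paste0("TFCRF.pos.", AA20), paste0("TFCRF.neg.", AA20))
  out
}

#' Save / load an encoder state
#'
#' States are plain lists; serialization round-trips give bit-identical
#' encodings.
#'
#' @param state An `encoder_state` or named list of states.
#' @param path File path.
#' @export
write_encoder_state <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname write_encoder_state
#' @export
read_encoder_state <- function(path) readRDS(path)
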