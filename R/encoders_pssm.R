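## PSSM-derived encoders: the per-fragment evolutionary window and the
## per-protein S-FPSSM summary.  Profiles are read from PSI-BLAST ASCII files
## (see read_pssm_ascii); this package never runs PSI-BLAST itself.

#' PSSM window encoding
#'
#' Concatenates the 20-score log-odds rows of the profile at the fragment's
#' positions (center_pos - n .. center_pos + n).  Positions outside the
#' protein (padded fragment edges) give zero rows.
#'
#' @param profile A `pssm_profile` for the fragment's protein.
#' @param center_pos 1-based position of the central lysine.
#' @param half_width Flank width n.
#' @return Named numeric vector of `20 * (2n + 1)` features.
#' @export
encode_pssm_window <- function(profile, center_pos, half_width) {
  if (is.null(profile)) stop("missing PSSM profile")
  stopifnot(inherits(profile, "pssm_profile"))
  Lp <- nrow(profile$scores)
  if (center_pos < 1L || center_pos > Lp)
    stop("center position ", center_pos, " outside profile of length ", Lp,
         " for '", profile$protein_id, "'")
  n <- as.integer(half_width)
  L <- 2L * n + 1L
  idx <- (center_pos - n):(center_pos + n)
  out <- numeric(20L * L)
  names(out) <- as.vector(vapply(seq_len(L), function(i)
    paste0("PSSM.p", pad2(i), ".", AA20), character(20)))
  inside <- idx >= 1L & idx <= Lp
  if (any(inside)) {
    rows <- profile$scores[idx[inside], , drop = FALSE]
    pos_in_frag <- which(inside)
    for (r in seq_along(pos_in_frag)) {
      i <- pos_in_frag[r]
      out[((i - 1L) * 20L + 1L):(i * 20L)] <- rows[r, ]
    }
  }
  out
}

#' S-FPSSM per-protein descriptor
#'
#' The profile is clipped to `[0, delta]` (negatives to zero, entries above
#' delta to delta), then for each residue identity i and each column j the
#' clipped scores of rows whose residue is i are summed, giving the 20x20
#' vector flattened row-major (i-major).  Rows carrying a dummy residue
#' contribute to no group.
#'
#' @param profile A `pssm_profile`.
#' @param delta Clipping ceiling (default 7).
#' @return Named numeric vector of 400 features.
#' @export
encode_sfpssm <- function(profile, delta = 7) {
  stopifnot(inherits(profile, "pssm_profile"))
  f <- pmin(pmax(profile$scores, 0), delta)
  res <- split_residues(canonicalize_sequence(profile$row_residues))
  out <- numeric(400)
  names(out) <- as.vector(vapply(AA20, function(i)
    paste0("SFPSSM.", i, ".", AA20), character(20)))
  for (ii in seq_along(AA20)) {
    rows <- which(res == AA20[ii])
    if (length(rows) > 0L)
      out[((ii - 1L) * 20L + 1L):(ii * 20L)] <- colSums(f[rows, , drop = FALSE])
  }
  out
}

SCHEME_REGISTRY <- c("aac", "dpc", "dde", "eaac", "egaac", "bina", "num",
                     "blosum62", "cksaap", "ebgw", "pwaa", "profile", "ebpr",
                     "zscales", "side_chain", "reduced_alphabet", "aaindex",
                     "bpb", "pwm", "knn", "tfidf", "tfcrf", "pssm", "sfpssm")
FITTED_SCHEMES <- c("bpb", "pwm", "knn", "tfidf", "tfcrf")

#' Fit all corpus-fitted encoder states needed by a scheme list
#'
#' @param schemes Character vector of scheme names.
#' @param fragments Training fragment data.frame (`id`, `residues`, `label`).
#' @return Named list of `encoder_state` objects (possibly empty).
#' @export
fit_encoder_states <- function(schemes, fragments) {
  states <- list()
  if ("bpb" %in% schemes)
    states$bpb <- fit_bpb(fragments$residues, fragments$label)
  if ("pwm" %in% schemes)
    states$pwm <- fit_pwm(fragments$residues[fragments$label == "positive"])
  if ("knn" %in% schemes)
    states$knn <- fit_knn_feature(fragments$residues, fragments$label,
                                  ids = fragments$id)
  if ("tfidf" %in% schemes)
    states$tfidf <- fit_tfidf(fragments$residues)
  if ("tfcrf" %in% schemes)
    states$tfcrf <- fit_tfcrf(fragments$residues, fragments$label)
  states
}

encode_one <- function(scheme, frag_row, states, profiles, aaindex,
                       loo_knn = FALSE) {
  r <- frag_row$residues
  switch(scheme,
    aac = encode_aac(r), dpc = encode_dpc(r), dde = encode_dde(r),
    eaac = encode_eaac(r), egaac = encode_egaac(r), bina = encode_bina(r),
    num = encode_num(r), blosum62 = encode_blosum62(r),
    cksaap = encode_cksaap(r), ebgw = encode_ebgw(r), pwaa = encode_pwaa(r),
    profile = encode_profile(r), ebpr = encode_ebpr(r),
    zscales = encode_physchem(r, "zscales"),
    side_chain = encode_physchem(r, "side_chain"),
    reduced_alphabet = encode_physchem(r, "reduced_alphabet"),
    aaindex = {
      if (is.null(aaindex)) stop("scheme 'aaindex' requires an index table")
      encode_aaindex(r, aaindex)
    },
    bpb = encode_bpb(states$bpb, r),
    pwm = encode_pwm(states$pwm, r),
    knn = encode_knn(states$knn, r,
                     id = if (loo_knn) frag_row$id else NULL),
    tfidf = encode_tfidf(states$tfidf, r),
    tfcrf = encode_tfcrf(states$tfcrf, r),
    pssm = {
      p <- profiles[[frag_row$protein_id]]
      if (is.null(p)) stop("missing PSSM profile for accession '",
                           frag_row$protein_id, "'")
      encode_pssm_window(p, frag_row$center_pos,
                         (nchar(r) - 1L) %/% 2L)
    },
    sfpssm = {
      p <- profiles[[frag_row$protein_id]]
      if (is.null(p)) stop("missing PSSM profile for accession '",
                           frag_row$protein_id, "'")
      encode_sfpssm(p)
    },
    stop("unknown scheme '", scheme, "'")
  )
}

#' Assemble a feature matrix from encoder blocks
#'
#' Encodes every fragment under every requested scheme and concatenates the
#' blocks horizontally in the given order.  Corpus-fitted schemes require a
#' fitted state (see [fit_encoder_states()]); PSSM schemes require profiles
#' keyed by accession.  Encoder errors are re-raised with the offending
#' fragment id attached.
#'
#' @param fragments Fragment data.frame (`id`, `protein_id`, `center_pos`,
#'   `residues`).
#' @param schemes Ordered character vector of scheme names.
#' @param states Named list of fitted `encoder_state`s.
#' @param profiles Named list of `pssm_profile`s keyed by accession.
#' @param aaindex Optional AAindex table for the `aaindex` scheme.
#' @param loo_knn Exclude each training fragment from its own KNN neighbor
#'   pool (used when encoding the training partition itself).
#' @return Numeric matrix, rownames = fragment ids, colnames = globally
#'   unique scheme-prefixed feature names; `attr(,"schemes")` records the
#'   block order.
#' @export
assemble_features <- function(fragments, schemes, states = list(),
                              profiles = NULL, aaindex = NULL,
                              loo_knn = FALSE) {
  schemes <- match.arg(schemes, SCHEME_REGISTRY, several.ok = TRUE)
  for (s in intersect(schemes, FITTED_SCHEMES))
    if (is.null(states[[s]]))
      stop("scheme '", s, "' needs a fitted state; see fit_encoder_states()")
  blocks <- lapply(schemes, function(s) {
    rows <- lapply(seq_len(nrow(fragments)), function(i) {
      row <- fragments[i, ]
      tryCatch(encode_one(s, row, states, profiles, aaindex, loo_knn),
               error = function(e) stop("fragment '", row$id, "': ",
                                        conditionMessage(e), call. = FALSE))
    })
    do.call(rbind, rows)
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- fragments$id
  if (anyDuplicated(colnames(out)))
    stop("internal error: duplicated feature names")
  stopifnot(all(is.finite(out)))
  attr(out, "schemes") <- schemes
  out
}
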