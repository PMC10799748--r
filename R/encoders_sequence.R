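## Stateless per-fragment encoders.  Every encoder takes the residue string of
## one lysine-centered fragment (over the canonical 21-letter alphabet) and
## returns a named numeric vector; [assemble_features()] stacks them into a
## feature matrix.  Feature names are scheme-prefixed, e.g. "EAAC.w03.A".

pad2 <- function(i) formatC(i, width = 2, flag = "0")

#' Amino acid composition (AAC)
#'
#' Per standard residue, its count divided by the number of non-dummy
#' residues in the fragment.  Dummy residues are excluded from both numerator
#' and denominator; an all-dummy fragment yields a zero vector with a
#' warning.
#'
#' @param fragment Residue string over the 21-letter alphabet.
#' @return Named numeric vector of 20 features.
#' @export
encode_aac <- function(fragment) {
  res <- split_residues(fragment)
  res <- res[res != "O"]
  out <- numeric(20)
  names(out) <- paste0("AAC.", AA20)
  if (length(res) == 0L) {
    warning("all-dummy fragment: AAC is a zero vector")
    return(out)
  }
  tab <- table(factor(res, levels = AA20))
  out[] <- as.numeric(tab) / length(res)
  out
}

#' Dipeptide composition (DPC)
#'
#' For each ordered pair of standard residues, the count of adjacent
#' occurrences divided by L-1.  Pairs touching a dummy are skipped in the
#' numerator; the denominator stays L-1.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of 400 features.
#' @export
encode_dpc <- function(fragment) {
  res <- split_residues(fragment)
  L <- length(res)
  if (L < 2L) stop("DPC needs fragment length >= 2")
  nm <- as.vector(t(outer(AA20, AA20, paste, sep = ".")))
  out <- numeric(400)
  names(out) <- paste0("DPC.", nm)
  a <- res[-L]; b <- res[-1]
  ok <- a != "O" & b != "O"
  if (any(ok)) {
    tab <- table(factor(paste0("DPC.", a[ok], ".", b[ok]), levels = names(out)))
    out[] <- as.numeric(tab) / (L - 1)
  }
  out
}

#' Dipeptide deviation from expected mean (DDE)
#'
#' DDE(m,n) = (DC - TM) / sqrt(TV), where DC is the observed dipeptide
#' fraction (adjacent-pair count over L-1), TM = (C_m/61)(C_n/61) with C_m
#' the standard genetic-code codon multiplicities, and
#' TV = TM(1-TM)/(L-1).
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of 400 features.
#' @export
encode_dde <- function(fragment) {
  res <- split_residues(fragment)
  L <- length(res)
  if (L < 2L) stop("DDE needs fragment length >= 2")
  dc <- encode_dpc(fragment)
  tm <- as.vector(t(outer(CODON_COUNTS / CODON_TOTAL,
                          CODON_COUNTS / CODON_TOTAL)))
  tv <- tm * (1 - tm) / (L - 1)
  stopifnot(all(tv > 0))
  out <- (as.numeric(dc) - tm) / sqrt(tv)
  names(out) <- sub("^DPC", "DDE", names(dc))
  out
}

#' Enhanced amino acid composition (EAAC)
#'
#' A length-`subwindow` window slides with stride 1 fully inside the
#' fragment; per window the 20 standard-residue counts are divided by the
#' window length (dummies contribute zero to every feature).
#'
#' @inheritParams encode_aac
#' @param subwindow Sliding sub-window length (default 5).
#' @return Named numeric vector of `20 * (L - subwindow + 1)` features.
#' @export
encode_eaac <- function(fragment, subwindow = 5L) {
  res <- split_residues(fragment)
  L <- length(res)
  w <- as.integer(subwindow)
  if (L < w) stop("fragment shorter than sub-window (", w,
                  "); consider padded extraction")
  nwin <- L - w + 1L
  out <- numeric(20L * nwin)
  names(out) <- as.vector(vapply(seq_len(nwin), function(i)
    paste0("EAAC.w", pad2(i), ".", AA20), character(20)))
  for (i in seq_len(nwin)) {
    tab <- table(factor(res[i:(i + w - 1L)], levels = AA20))
    out[((i - 1L) * 20L + 1L):(i * 20L)] <- as.numeric(tab) / w
  }
  out
}

#' Enhanced grouped amino acid composition (EGAAC)
#'
#' As [encode_eaac()] but over the five physicochemical categories
#' (aliphatic GAVLMI, aromatic FYW, positively charged KRH, negatively
#' charged DE, uncharged STCPNQ).
#'
#' @inheritParams encode_eaac
#' @return Named numeric vector of `5 * (L - subwindow + 1)` features.
#' @export
encode_egaac <- function(fragment, subwindow = 5L) {
  res <- split_residues(fragment)
  L <- length(res)
  w <- as.integer(subwindow)
  if (L < w) stop("fragment shorter than sub-window (", w,
                  "); consider padded extraction")
  grp <- names(EGAAC_GROUPS)
  gmap <- rep(NA_character_, 21)
  names(gmap) <- AA21
  for (g in grp) gmap[EGAAC_GROUPS[[g]]] <- g
  gseq <- gmap[res]
  nwin <- L - w + 1L
  out <- numeric(5L * nwin)
  names(out) <- as.vector(vapply(seq_len(nwin), function(i)
    paste0("EGAAC.w", pad2(i), ".", grp), character(5)))
  for (i in seq_len(nwin)) {
    tab <- table(factor(gseq[i:(i + w - 1L)], levels = grp))
    out[((i - 1L) * 5L + 1L):(i * 5L)] <- as.numeric(tab) / w
  }
  out
}

#' Binary one-hot encoding (BINA)
#'
#' Per position, a 21-dimensional one-hot vector over the canonical alphabet
#' (the dummy 'O' is the 21st symbol).
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of `21 * L` features.
#' @export
encode_bina <- function(fragment) {
  res <- split_residues(fragment)
  L <- length(res)
  out <- numeric(21L * L)
  names(out) <- as.vector(vapply(seq_len(L), function(i)
    paste0("BINA.p", pad2(i), ".", AA21), character(21)))
  out[(seq_len(L) - 1L) * 21L + residue_index(res)] <- 1
  out
}

#' Numerical residue mapping (NUM)
#'
#' Alphabetical rank per residue (A=1 ... Y=20, dummy=21) with the fixed
#' central lysine omitted, giving L-1 features.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of `L - 1` features.
#' @export
encode_num <- function(fragment) {
  res <- split_residues(fragment)
  L <- length(res)
  if (L %% 2L == 0L) stop("NUM expects an odd-length, lysine-centered fragment")
  ctr <- (L + 1L) %/% 2L
  if (res[ctr] != "K") stop("NUM expects lysine at the fragment center")
  out <- as.numeric(residue_index(res)[-ctr])
  names(out) <- paste0("NUM.p", pad2(seq_len(L)[-ctr]))
  out
}

#' BLOSUM62 row encoding
#'
#' Per position, the 20-valued BLOSUM62 substitution row of that residue
#' (bundled standard matrix); dummy positions give a zero row.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of `20 * L` features.
#' @export
encode_blosum62 <- function(fragment) {
  res <- split_residues(fragment)
  L <- length(res)
  b62 <- blosum62_matrix()
  out <- numeric(20L * L)
  names(out) <- as.vector(vapply(seq_len(L), function(i)
    paste0("BLOSUM62.p", pad2(i), ".", AA20), character(20)))
  for (i in seq_len(L)) {
    if (res[i] != "O")
      out[((i - 1L) * 20L + 1L):(i * 20L)] <- b62[res[i], ]
  }
  out
}

#' Composition of k-spaced amino acid pairs (CKSAAP)
#'
#' Per gap k, the count of every ordered 21x21 residue pair separated by
#' exactly k residues, divided by N_total = L - k - 1.
#'
#' @inheritParams encode_aac
#' @param gaps Integer vector of gaps (default 0:4, giving 5 x 441 = 2205
#'   features).
#' @return Named numeric vector of `441 * length(gaps)` features.
#' @export
encode_cksaap <- function(fragment, gaps = 0:4) {
  res <- split_residues(fragment)
  L <- length(res)
  if (L < max(gaps) + 2L)
    stop("fragment length ", L, " too short for gap ", max(gaps))
  pair_nm <- as.vector(t(outer(AA21, AA21, paste, sep = ".")))
  out <- numeric(0)
  for (k in gaps) {
    n_tot <- L - k - 1L
    a <- res[seq_len(n_tot)]
    b <- res[seq_len(n_tot) + k + 1L]
    tab <- table(factor(paste(a, b, sep = "."), levels = pair_nm))
    blk <- as.numeric(tab) / n_tot
    names(blk) <- paste0("CKSAAP.k", k, ".", pair_nm)
    out <- c(out, blk)
  }
  out
}

#' Encoding based on grouped weight (EBGW)
#'
#' Three binary dichotomy sequences are built from the four-class grouping
#' (hydrophobic C1, polar C2, acidic C3, basic C4): H1 = C1 or C2, H2 = C1 or
#' C3, H3 = C1 or C4.  The j-th of J nested prefixes has length
#' `int(j*L/J)`; each feature is the fraction of ones in that prefix.
#'
#' @inheritParams encode_aac
#' @param J Number of nested prefixes (default 5).
#' @return Named numeric vector of `3 * J` features in `[0, 1]`.
#' @export
encode_ebgw <- function(fragment, J = 5L) {
  res <- split_residues(fragment)
  L <- length(res)
  J <- as.integer(J)
  if (J > L) stop("J must not exceed the fragment length")
  inC <- function(g) res %in% EBAG_GROUPS[[g]]
  H <- list(H1 = inC("C1.hydrophobic") | inC("C2.polar"),
            H2 = inC("C1.hydrophobic") | inC("C3.acidic"),
            H3 = inC("C1.hydrophobic") | inC("C4.basic"))
  out <- numeric(3L * J)
  nm <- character(3L * J)
  idx <- 1L
  for (h in names(H)) {
    cs <- cumsum(H[[h]])
    for (j in seq_len(J)) {
      len <- as.integer(floor(j * L / J))
      out[idx] <- if (len > 0L) cs[len] / len else 0
      nm[idx] <- paste0("EBGW.", h, ".j", j)
      idx <- idx + 1L
    }
  }
  names(out) <- nm
  out
}

#' Position-weighted amino acid composition (PWAA)
#'
#' For each of the 21 symbols i, G_i = (1/(m(m+1))) * sum_j v_ij *
#' (j + |j|/m) over flank offsets j = -m..m around the central lysine
#' (the center contributes weight zero).
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of 21 features.
#' @export
encode_pwaa <- function(fragment) {
  res <- split_residues(fragment)
  L <- length(res)
  if (L %% 2L == 0L) stop("PWAA expects an odd-length fragment")
  m <- (L - 1L) %/% 2L
  if (m == 0L) stop("PWAA needs at least one flanking residue")
  j <- seq(-m, m)
  wt <- j + abs(j) / m
  out <- numeric(21)
  names(out) <- paste0("PWAA.", AA21)
  for (i in seq_len(L)) out[paste0("PWAA.", res[i])] <-
      out[paste0("PWAA.", res[i])] + wt[i]
  out / (m * (m + 1))
}

#' Profile encoding
#'
#' Position i holds the within-fragment frequency of the residue type found
#' at position i (count of that type divided by L).
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of L features.
#' @export
encode_profile <- function(fragment) {
  res <- split_residues(fragment)
  L <- length(res)
  cnt <- table(res)
  out <- as.numeric(cnt[res]) / L
  names(out) <- paste0("PROFILE.p", pad2(seq_len(L)))
  out
}

#' EBPR: profile encoding over the EBAG reduced alphabet
#'
#' Residues are mapped to the four EBAG classes (dummy to "X"), then the
#' profile encoding is applied to the class sequence.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of L features.
#' @export
encode_ebpr <- function(fragment) {
  res <- split_residues(fragment)
  gmap <- rep("X", 21)
  names(gmap) <- AA21
  for (g in names(EBAG_GROUPS)) gmap[EBAG_GROUPS[[g]]] <- g
  gseq <- gmap[res]
  L <- length(gseq)
  cnt <- table(gseq)
  out <- as.numeric(cnt[gseq]) / L
  names(out) <- paste0("EBPR.p", pad2(seq_len(L)))
  out
}

#' Physicochemical position-wise encodings
#'
#' `zscales`: the five Sandberg descriptor variables per position (5L
#' features); `side_chain`: one-hot over six R-group categories (6L);
#' `reduced_alphabet`: one-hot over the eight-letter reduced alphabet (8L).
#' Dummy positions give a zero block in every scheme.
#'
#' @inheritParams encode_aac
#' @param scheme One of `"zscales"`, `"side_chain"`, `"reduced_alphabet"`.
#' @param table Optional replacement 20x5 matrix for the zscales scheme.
#' @return Named numeric vector.
#' @export
encode_physchem <- function(fragment,
                            scheme = c("zscales", "side_chain",
                                       "reduced_alphabet"),
                            table = NULL) {
  scheme <- match.arg(scheme)
  res <- split_residues(fragment)
  L <- length(res)
  if (scheme == "zscales") {
    tab <- if (is.null(table)) ZSCALES else table
    if (!is.matrix(tab) || ncol(tab) != 5L || !all(AA20 %in% rownames(tab)))
      stop("zscales requires a 20x5 table with residue rownames")
    out <- numeric(5L * L)
    names(out) <- as.vector(vapply(seq_len(L), function(i)
      paste0("ZSCALES.p", pad2(i), ".z", 1:5), character(5)))
    for (i in seq_len(L))
      if (res[i] != "O") out[((i - 1L) * 5L + 1L):(i * 5L)] <- tab[res[i], ]
    return(out)
  }
  groups <- if (scheme == "side_chain") SIDECHAIN_GROUPS else REDUCED8_GROUPS
  G <- length(groups)
  gmap <- rep(NA_character_, 21)
  names(gmap) <- AA21
  for (g in names(groups)) gmap[groups[[g]]] <- g
  prefix <- if (scheme == "side_chain") "SIDECHAIN" else "REDUCED8"
  out <- numeric(G * L)
  names(out) <- as.vector(vapply(seq_len(L), function(i)
    paste0(prefix, ".p", pad2(i), ".", names(groups)), character(G)))
  for (i in seq_len(L)) {
    g <- gmap[res[i]]
    if (!is.na(g))
      out[(i - 1L) * G + match(g, names(groups))] <- 1
  }
  out
}

#' AAindex value encoding
#'
#' Per position and per selected index, the index value of the residue at
#' that position; dummies give 0.
#'
#' @inheritParams encode_aac
#' @param table Named list of 20-value vectors as from [read_aaindex()].
#' @param indices Names of the indices to use (default: all in `table`).
#' @return Named numeric vector of `length(indices) * L` features.
#' @export
encode_aaindex <- function(fragment, table, indices = names(table)) {
  missing_idx <- setdiff(indices, names(table))
  if (length(missing_idx) > 0L)
    stop("unknown AAindex name(s): ", paste(missing_idx, collapse = ", "),
         "; available: ", paste(names(table), collapse = ", "))
  res <- split_residues(fragment)
  L <- length(res)
  out <- numeric(0)
  for (ix in indices) {
    v <- ifelse(res %in% AA20, table[[ix]][res], 0)
    v[is.na(v)] <- 0
    names(v) <- paste0("AAINDEX.", ix, ".p", pad2(seq_len(L)))
    out <- c(out, v)
  }
  out
}
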