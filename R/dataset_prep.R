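## Benchmark-dataset construction: exhaustive lysine-site labeling, fixed-width
## fragment extraction, homology reduction, class balancing and the
## protein-level independent split.

#' Enumerate all lysine sites of a protein
#'
#' Every K position of the (canonicalized) sequence appears exactly once,
#' labeled positive when it carries an annotation, negative otherwise.
#' Annotated positions whose residue is not K are dropped with a warning;
#' annotations beyond the sequence end are errors.
#'
#' @param protein One-row data.frame (or list) with `id` and `sequence`.
#' @param positives data.frame of site annotations (`protein_id`, `position`)
#'   for this protein; may be empty.
#' @return data.frame with `protein_id`, `position`, `label`.
#' @export
enumerate_sites <- function(protein, positives = NULL) {
  seq <- canonicalize_sequence(protein$sequence)
  res <- split_residues(seq)
  pos_set <- integer(0)
  if (!is.null(positives) && nrow(positives) > 0L) {
    positives <- positives[positives$protein_id == protein$id, , drop = FALSE]
    if (any(positives$position > length(res)))
      stop("annotation beyond sequence end for protein '", protein$id, "'")
    is_k <- res[positives$position] == "K"
    if (any(!is_k))
      warning(sum(!is_k), " annotated position(s) on protein '", protein$id,
              "' are not lysine and were dropped")
    pos_set <- unique(positives$position[is_k])
  }
  k_pos <- which(res == "K")
  if (length(k_pos) == 0L)
    return(data.frame(protein_id = character(0), position = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  data.frame(protein_id = protein$id, position = k_pos,
             label = ifelse(k_pos %in% pos_set, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Extract fixed-width lysine-centered fragments
#'
#' One (2n+1)-mer per site with n full residues on each flank.  Sites closer
#' than n to either terminus are omitted by default (the trimmed-sequence
#' rule) or padded with the dummy symbol `"O"` when `pad = TRUE`.
#'
#' @param protein One-row data.frame/list with `id` and `sequence`.
#' @param sites data.frame from [enumerate_sites()].
#' @param half_width Flank width n (window 2n+1).  The scanned range is
#'   3..17; larger values are allowed with a warning.
#' @param pad Pad truncated flanks with `"O"` instead of omitting the site.
#' @return data.frame with `id`, `protein_id`, `center_pos`, `residues`,
#'   `label`.
#' @export
extract_fragments <- function(protein, sites, half_width = 17L, pad = FALSE) {
  n <- as.integer(half_width)
  if (n < 1L) stop("half_width must be >= 1")
  if (n < 3L || n > 17L)
    warning("half_width ", n, " is outside the scanned 3..17 range")
  seq <- canonicalize_sequence(protein$sequence)
  res <- split_residues(seq)
  L <- length(res)
  sites <- sites[sites$protein_id == protein$id, , drop = FALSE]
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    lo <- p - n; hi <- p + n
    if (!pad && (lo < 1L || hi > L)) next
    idx <- lo:hi
    frag <- ifelse(idx >= 1L & idx <= L, res[pmax(pmin(idx, L), 1L)], "O")
    out[[i]] <- data.frame(
      id = paste0(protein$id, "_", p),
      protein_id = protein$id, center_pos = p,
      residues = paste0(frag, collapse = ""),
      label = sites$label[i], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(id = character(0), protein_id = character(0),
                      center_pos = integer(0), residues = character(0),
                      label = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# approximate pairwise identity: best ungapped k-mer-anchored diagonal,
# matches / shorter length
kmer_identity <- function(a, b, k = 3L) {
  ra <- split_residues(a); rb <- split_residues(b)
  if (length(ra) > length(rb)) { tmp <- ra; ra <- rb; rb <- tmp }
  la <- length(ra); lb <- length(rb)
  if (la < k) return(as.numeric(paste0(ra, collapse = "") %in%
                                  paste0(rb, collapse = "")))
  ka <- vapply(seq_len(la - k + 1L),
               function(i) paste0(ra[i:(i + k - 1L)], collapse = ""),
               character(1))
  kb <- vapply(seq_len(lb - k + 1L),
               function(i) paste0(rb[i:(i + k - 1L)], collapse = ""),
               character(1))
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) return(0)
  # candidate diagonal offsets (position in b minus position in a)
  offs <- unique(unlist(lapply(shared, function(s)
    outer(which(kb == s), which(ka == s), `-`))))
  best <- 0L
  for (d in offs) {
    ia <- seq_len(la)
    ib <- ia + d
    ok <- ib >= 1L & ib <= lb
    m <- sum(ra[ia[ok]] == rb[ib[ok]])
    if (m > best) best <- m
  }
  best / la
}

#' Remove homologous sequences
#'
#' Greedy longest-first clustering in the CD-HIT spirit: proteins are visited
#' in decreasing length order and a protein is discarded when its identity to
#' any already-retained protein is at or above `threshold`.  The built-in
#' identity estimate is the best ungapped k-mer-anchored diagonal alignment
#' (matches divided by the shorter length) and is approximate; alternatively
#' an external CD-HIT executable can be delegated to, parsing its `.clstr`
#' output.
#'
#' @param proteins data.frame with `id`, `sequence`.
#' @param threshold Identity threshold in (0, 1]; default 0.40.
#' @param external_cdhit Optional path to a CD-HIT executable.
#' @return The retained subset of `proteins`.
#' @export
reduce_homology <- function(proteins, threshold = 0.40,
                            external_cdhit = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!is.null(external_cdhit)) {
    if (!file.exists(external_cdhit) && Sys.which(external_cdhit) == "")
      stop("external CD-HIT executable not found ('", external_cdhit,
           "'); omit external_cdhit to use the built-in reducer")
    td <- tempfile("cdhit"); dir.create(td)
    fin <- file.path(td, "in.fasta"); fout <- file.path(td, "out.fasta")
    write_fasta(proteins, fin)
    status <- system2(external_cdhit,
                      c("-i", fin, "-o", fout, "-c", threshold, "-n", "2"),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L || !file.exists(fout))
      stop("external CD-HIT run failed (exit ", status, ")")
    kept <- read_fasta(fout)$id
    return(proteins[proteins$id %in% kept, , drop = FALSE])
  }
  ord <- order(-nchar(proteins$sequence))
  seqs <- canonicalize_sequence(proteins$sequence)
  kept <- integer(0)
  for (i in ord) {
    redundant <- FALSE
    for (j in kept) {
      if (kmer_identity(seqs[i], seqs[j]) >= threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  proteins[sort(kept), , drop = FALSE]
}

#' Balance classes by undersampling negatives
#'
#' All positives are kept; negatives are sampled uniformly without
#' replacement down to the positive count.  Deterministic for a given seed.
#'
#' @param fragments Fragment data.frame with a `label` column.
#' @param seed Integer seed.
#' @return The balanced fragment data.frame (row order: original order).
#' @export
balance_undersample <- function(fragments, seed = 1L) {
  pos <- which(fragments$label == "positive")
  neg <- which(fragments$label == "negative")
  if (length(pos) == 0L) stop("balance_undersample: no positive fragments")
  if (length(neg) < length(pos)) {
    warning("fewer negatives (", length(neg), ") than positives (",
            length(pos), "); keeping all negatives")
    keep <- c(pos, neg)
  } else {
    keep <- c(pos, with_seed(seed, sample(neg, length(pos))))
  }
  out <- fragments[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein-level train/test split
#'
#' Proteins (not fragments) are randomly partitioned so that about
#' `test_fraction` of proteins form the independent test set; every fragment
#' of one protein lands on exactly one side, preventing near-duplicate
#' leakage across the split.
#'
#' @param fragments Fragment data.frame with a `protein_id` column.
#' @param test_fraction Fraction of proteins held out (default 0.10).
#' @param seed Integer seed.
#' @return List with `train`, `test` (fragment data.frames) and `seed`.
#' @export
split_by_protein <- function(fragments, test_fraction = 0.10, seed = 1L) {
  prot <- unique(fragments$protein_id)
  if (length(prot) < 2L) stop("need at least 2 proteins to split")
  n_test <- max(1L, round(test_fraction * length(prot)))
  test_prot <- with_seed(seed, sample(prot, n_test))
  list(train = fragments[!(fragments$protein_id %in% test_prot), ,
                         drop = FALSE],
       test = fragments[fragments$protein_id %in% test_prot, , drop = FALSE],
       seed = as.integer(seed))
}
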