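## Seeded synthetic proteome generator with a planted, tunable positive-site
## motif: proteins drawn from background residue frequencies, a random subset
## of lysines marked positive, and the upstream flanks of positive sites
## re-drawn with an enrichment boost for acidic residues.  Purely a
## controllable statistical structure for testing — no biological claim.

#' Synthetic-data configuration
#'
#' @param n_proteins Number of proteins.
#' @param length_range Min/max protein length (uniform).
#' @param n_positive_sites Number of lysines marked positive.
#' @param motif_strength Probability s in `[0, 1]` that an enriched-flank
#'   position is drawn from `enriched_residues` instead of the background;
#'   0 plants no signal.
#' @param enriched_residues Residues enriched upstream of positive sites.
#' @param flank_width How many upstream positions are re-drawn.
#' @param background Named length-20 residue frequency vector (normalized
#'   internally); default uniform.
#' @param seed Integer seed; the single source of all randomness.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 60L, length_range = c(200L, 400L),
                             n_positive_sites = 400L, motif_strength = 0.8,
                             enriched_residues = c("D", "E"),
                             flank_width = 5L, background = NULL,
                             seed = 1L) {
  if (is.null(background)) background <- stats::setNames(rep(1, 20), AA20)
  if (!all(names(background) %in% AA20) || length(background) != 20L)
    stop("background must be a named frequency vector over the 20 residues")
  if (motif_strength < 0 || motif_strength > 1)
    stop("motif_strength must be in [0, 1]")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_positive_sites = as.integer(n_positive_sites),
                 motif_strength = motif_strength,
                 enriched_residues = enriched_residues,
                 flank_width = as.integer(flank_width),
                 background = background / sum(background),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic proteome with planted positive sites
#'
#' Sequences are drawn from the background frequencies (with at least one
#' lysine guaranteed per protein); `n_positive_sites` lysines are sampled as
#' positives and, for each, the `flank_width` upstream positions are re-drawn
#' so that with probability `motif_strength` the residue comes uniformly from
#' `enriched_residues` (otherwise from the background).  Deterministic per
#' seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `proteins` (data.frame `id`, `sequence`) and `sites`
#'   (data.frame `protein_id`, `position`, `label = "positive"`).
#' @export
generate_proteins <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    lens <- sample(config$length_range[1]:config$length_range[2],
                   config$n_proteins, replace = TRUE)
    seqs <- lapply(lens, function(L) {
      s <- sample(AA20, L, replace = TRUE, prob = config$background)
      if (!("K" %in% s)) s[sample.int(L, 1L)] <- "K"
      s
    })
    k_sites <- do.call(rbind, lapply(seq_along(seqs), function(i)
      data.frame(protein = i, position = which(seqs[[i]] == "K"))))
    if (nrow(k_sites) < config$n_positive_sites)
      stop("only ", nrow(k_sites), " lysines available for ",
           config$n_positive_sites, " requested positive sites")
    pos_idx <- sample.int(nrow(k_sites), config$n_positive_sites)
    pos_sites <- k_sites[pos_idx, , drop = FALSE]
    pos_key <- paste(pos_sites$protein, pos_sites$position)
    for (r in seq_len(nrow(pos_sites))) {
      i <- pos_sites$protein[r]; p <- pos_sites$position[r]
      for (off in seq_len(config$flank_width)) {
        q <- p - off
        if (q < 1L) next
        if (paste(i, q) %in% pos_key) next  # never overwrite a positive K
        seqs[[i]][q] <- if (stats::runif(1) < config$motif_strength)
          sample(config$enriched_residues, 1L)
        else
          sample(AA20, 1L, prob = config$background)
      }
    }
    ids <- sprintf("SYN%04d", seq_along(seqs))
    list(proteins = data.frame(
           id = ids,
           sequence = vapply(seqs, paste0, character(1), collapse = ""),
           stringsAsFactors = FALSE),
         sites = data.frame(protein_id = ids[pos_sites$protein],
                            position = pos_sites$position,
                            label = "positive", stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic PSSM profile for a protein
#'
#' Integer log-odds-like scores: a positive bonus on each residue's own
#' column plus noise elsewhere, clipped to `[-10, 12]` to mimic PSI-BLAST
#' output.
#'
#' @param protein One-row data.frame/list with `id`, `sequence`.
#' @param seed Integer seed.
#' @param match_bonus Mean own-column score boost.
#' @return A `pssm_profile`.
#' @export
generate_pssm <- function(protein, seed = 1L, match_bonus = 5) {
  seqc <- canonicalize_sequence(protein$sequence)
  res <- split_residues(seqc)
  L <- length(res)
  with_seed(seed, {
    sc <- matrix(round(stats::rnorm(L * 20L, mean = -1, sd = 2)), L, 20L,
                 dimnames = list(NULL, AA20))
    for (i in seq_len(L))
      if (res[i] != "O")
        sc[i, res[i]] <- sc[i, res[i]] + match_bonus
    sc <- pmin(pmax(sc, -10), 12)
    structure(list(protein_id = protein$id, scores = sc,
                   row_residues = seqc),
              class = "pssm_profile")
  })
}

#' Generate PSSM profiles for a whole protein set
#'
#' @param proteins data.frame with `id`, `sequence`.
#' @param seed Base seed; each protein uses `seed + row index`.
#' @return Named list of `pssm_profile`s keyed by accession.
#' @export
generate_pssm_set <- function(proteins, seed = 1L) {
  out <- lapply(seq_len(nrow(proteins)), function(i)
    generate_pssm(proteins[i, ], seed = seed + i))
  names(out) <- proteins$id
  out
}

#' Build a complete ready-to-train fixture
#'
#' Runs the dataset-construction chain on a generated proteome: exhaustive
#' lysine-site enumeration, fragment extraction, a protein-level independent
#' split, and class balancing within each side (so train and test are both
#' balanced), plus matched PSSM profiles.
#'
#' @param config A [synthetic_config()].
#' @param half_width Fragment flank width n (default 17, window 35).
#' @param test_fraction Protein fraction held out (default 0.10).
#' @param pad Pad edge fragments instead of omitting them.
#' @return List with `train`, `test` (balanced fragment data.frames),
#'   `profiles`, `proteins`, `sites`, `config`.
#' @export
end_to_end_fixture <- function(config = synthetic_config(),
                               half_width = 17L, test_fraction = 0.10,
                               pad = FALSE) {
  gen <- generate_proteins(config)
  frags <- do.call(rbind, lapply(seq_len(nrow(gen$proteins)), function(i) {
    prot <- gen$proteins[i, ]
    sites <- enumerate_sites(prot, gen$sites)
    extract_fragments(prot, sites, half_width = half_width, pad = pad)
  }))
  split <- split_by_protein(frags, test_fraction, seed = config$seed + 1L)
  list(train = balance_undersample(split$train, seed = config$seed + 2L),
       test = balance_undersample(split$test, seed = config$seed + 3L),
       profiles = generate_pssm_set(gen$proteins, seed = config$seed + 10L),
       proteins = gen$proteins, sites = gen$sites, config = config)
}
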