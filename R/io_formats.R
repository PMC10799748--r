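## Readers and writers for the plain-text formats the pipeline consumes:
## FASTA, PSI-BLAST ASCII PSSM profiles, dbPTM-style site tables, AAindex-style
## tables, feature-matrix CSV and metrics JSON.  Positions are 1-based in all
## files and annotations; conversion to 0-based offsets (where needed) happens
## at the point of use, never here.

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] adding the error
#' contract the pipeline needs: empty files, sequence data before the first
#' header and zero-length records are reported as parse errors with line
#' numbers.  Sequences are uppercased; whitespace and CR are stripped.
#' Non-standard letters are left untouched here — canonicalization to the
#' 21-letter alphabet is a separate, explicit step.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (first token of the header) and
#'   `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) stop("FASTA parse error: empty file: ", path)
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("FASTA parse error at line ", nonblank[1],
         ": sequence data before first '>' header")
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1]
    hdr <- which(startsWith(lines, ">"))[bad]
    stop("FASTA parse error at line ", hdr, ": zero-length sequence for record '",
         ids[bad], "'")
  }
  if (anyDuplicated(ids))
    stop("FASTA parse error: duplicated record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins data.frame with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the layout produced by `psiblast -out_ascii_pssm` (and consumed by
#' POSSUM): header lines, then one row per residue carrying the position, the
#' residue letter and 40 numeric columns of which the FIRST 20 (the log-odds
#' block) are kept.  Rows with fewer than 20 parseable scores or a
#' non-monotone position column are parse errors, never silently dropped.
#'
#' @param path Path to the ASCII PSSM file.
#' @param protein_id Accession to attach; defaults to the file base name.
#' @return A `pssm_profile`: list with `protein_id`, `scores` (L x 20 matrix,
#'   columns in canonical [AA20] order) and `row_residues` (length-L string).
#' @export
read_pssm_ascii <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(protein_id))
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  # data rows: first token integer position, second a single letter
  is_row <- vapply(toks, function(tk) {
    length(tk) >= 2L && grepl("^[0-9]+$", tk[1]) &&
      grepl("^[A-Za-z]$", tk[2])
  }, logical(1))
  rows <- which(is_row)
  if (length(rows) == 0L)
    stop("PSSM parse error: no residue rows found in ", path)
  # locate the column order from the header line of AA letters, if present
  col_order <- AA20
  hdr <- which(vapply(toks, function(tk)
    length(tk) >= 20L && all(tk[1:20] %in% c(LETTERS)), logical(1)))
  hdr <- hdr[hdr < rows[1]]
  if (length(hdr) > 0L) col_order <- toks[[hdr[length(hdr)]]][1:20]
  pos <- integer(length(rows))
  res <- character(length(rows))
  sc <- matrix(NA_real_, length(rows), 20L)
  for (i in seq_along(rows)) {
    tk <- toks[[rows[i]]]
    nums <- suppressWarnings(as.numeric(tk[-(1:2)]))
    nums <- nums[!is.na(nums)]
    if (length(nums) < 20L)
      stop("PSSM parse error at line ", rows[i], " of ", path,
           ": expected 20 log-odds scores, found ", length(nums))
    pos[i] <- as.integer(tk[1])
    res[i] <- toupper(tk[2])
    sc[i, ] <- nums[1:20]
  }
  if (any(diff(pos) <= 0L))
    stop("PSSM parse error in ", path, ": non-monotone position column")
  colnames(sc) <- col_order
  sc <- sc[, AA20, drop = FALSE]
  structure(list(protein_id = protein_id, scores = sc,
                 row_residues = paste0(res, collapse = "")),
            class = "pssm_profile")
}

#' Write a PSSM profile in PSI-BLAST ASCII layout
#'
#' Emits only what [read_pssm_ascii()] consumes: two header lines (including
#' the 20-letter column header) and one row per residue with position, residue
#' letter and the 20 log-odds columns duplicated into the percentage block so
#' the file shape matches real `-out_ascii_pssm` output.
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  sc <- profile$scores
  res <- split_residues(profile$row_residues)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("            ", paste(AA20, collapse = "   "))), con)
  for (i in seq_len(nrow(sc))) {
    writeLines(sprintf("%5d %s %s", i, res[i],
                       paste(sprintf("%4d", as.integer(round(sc[i, ]))),
                             collapse = "")), con)
  }
  invisible(path)
}

#' Read a dbPTM-style site table
#'
#' Expects a tab-separated file with header columns `accession`, `position`
#' and `ptm_type`.  Only rows whose modification type matches `modification`
#' (case-insensitively) are kept; duplicate (accession, position) pairs are
#' collapsed.  Rows with a non-integer position are collected and reported as
#' a warning without discarding the remaining rows.
#'
#' @param path Path to the TSV file.
#' @param modification Modification type to keep, e.g. `"Malonylation"`.
#' @return data.frame with columns `protein_id`, `position` (1-based integer)
#'   and `label` (all `"positive"`).
#' @export
read_site_table <- function(path, modification) {
  if (!file.exists(path)) stop("site table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "position", "ptm_type")
  if (!all(need %in% names(tab)))
    stop("site table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  tab <- tab[tolower(tab$ptm_type) == tolower(modification), , drop = FALSE]
  pos <- suppressWarnings(as.integer(tab$position))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad) > 0L) {
    warning(length(bad), " malformed site record(s) skipped (non-integer ",
            "position): ", paste(utils::head(tab$accession[bad], 5),
                                 collapse = ", "))
    tab <- tab[-bad, , drop = FALSE]
    pos <- pos[-bad]
  }
  if (nrow(tab) == 0L)
    stop("site table ", path, ": no valid rows for modification '",
         modification, "'")
  keep <- !duplicated(paste(tab$accession, pos))
  data.frame(protein_id = tab$accession[keep], position = pos[keep],
             label = "positive", stringsAsFactors = FALSE)
}

#' Write a site table in the dbPTM-style TSV schema
#'
#' @param sites data.frame with `protein_id` and `position`.
#' @param path Output path.
#' @param modification Modification type written to every row.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path, modification = "Malonylation") {
  utils::write.table(
    data.frame(accession = sites$protein_id, position = sites$position,
               ptm_type = modification),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an AAindex-style table
#'
#' One index per line: `name<TAB>v_A<TAB>...<TAB>v_Y`, 20 values in canonical
#' [AA20] order.  Entries with missing or non-finite values are errors.
#'
#' @param path Path to the table.
#' @return Named list of numeric 20-vectors (named by residue).
#' @export
read_aaindex <- function(path) {
  if (!file.exists(path)) stop("AAindex table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    tk <- strsplit(lines[i], "\t")[[1]]
    if (length(tk) != 21L)
      stop("AAindex parse error at entry ", i, ": expected name + 20 values")
    v <- suppressWarnings(as.numeric(tk[-1]))
    if (any(!is.finite(v)))
      stop("AAindex parse error: non-finite value in entry '", tk[1], "'")
    names(v) <- AA20
    out[[tk[1]]] <- v
  }
  out
}

#' Write a feature matrix to CSV
#'
#' Layout: `id`, `label`, then one column per feature name.
#'
#' @param fm Numeric matrix with rownames = fragment ids and colnames =
#'   feature names (as produced by [assemble_features()]).
#' @param labels Character vector of labels aligned to rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, labels, path) {
  dt <- data.table::data.table(id = rownames(fm), label = labels)
  dt <- cbind(dt, data.table::as.data.table(fm))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return List with `values` (matrix, rownames = ids), `labels`.
#' @export
read_feature_csv <- function(path) {
  dt <- data.table::fread(path, data.table = TRUE)
  vals <- as.matrix(dt[, -(1:2)])
  rownames(vals) <- dt$id
  list(values = vals, labels = dt$label)
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report` (see [compute_metrics()]) or any list of
#'   scalars/vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
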