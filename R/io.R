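#' Construct a protein record
#'
#' A protein record bundles an accession, its amino-acid sequence and the
#' set of 1-based residue positions annotated as FAD-binding.
#'
#' @param accession Single accession string.
#' @param sequence Amino-acid sequence (string over the 20 canonical
#'   residues plus `X`); lower case is accepted and upper-cased.
#' @param sites Integer vector of 1-based binding positions (duplicates
#'   collapsed).
#' @return An object of class `protein_record` with elements `accession`,
#'   `sequence` and `sites` (sorted unique integer vector).
#' @export
protein_record <- function(accession, sequence, sites = integer()) {
  stopifnot(is.character(accession), length(accession) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L)
    .stop_fmt("record '%s': empty sequence", accession)
  bad <- setdiff(unique(strsplit(sequence, "")[[1L]]), .SEQ_ALPHABET)
  if (length(bad))
    .stop_fmt("record '%s': illegal sequence character(s): %s",
              accession, paste(bad, collapse = ", "))
  sites <- sort(unique(as.integer(sites)))
  if (length(sites) && (min(sites) < 1L || max(sites) > nchar(sequence)))
    .stop_fmt("record '%s': binding positions must lie in [1, %d]",
              accession, nchar(sequence))
  structure(list(accession = accession, sequence = sequence, sites = sites),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa, %d annotated binding site(s)\n",
              x$accession, nchar(x$sequence), length(x$sites)))
  invisible(x)
}

#' Construct a PSSM profile
#'
#' @param accession Accession the profile belongs to.
#' @param scores L x 20 matrix of integer log-odds, columns in
#'   [AMINO_ACIDS] order.
#' @param residues Optional character vector of length L with the residue
#'   letters of the profiled sequence (used for cross-checks).
#' @return An object of class `pssm_profile`.
#' @export
pssm_profile <- function(accession, scores, residues = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    .stop_fmt("profile '%s': expected 20 score columns, got %d",
              accession, ncol(scores))
  if (!is.null(residues) && length(residues) != nrow(scores))
    .stop_fmt("profile '%s': %d residue letters for %d rows",
              accession, length(residues), nrow(scores))
  colnames(scores) <- AMINO_ACIDS
  structure(list(accession = accession, scores = scores,
                 residues = residues),
            class = "pssm_profile")
}

#' Read protein sequences from a FASTA file
#'
#' The accession is the header token before the first whitespace; sequences
#' are upper-cased. Binding-site sets are left empty (see
#' [read_site_annotations()]).
#'
#' @param path Path to a FASTA file.
#' @return Named list of [protein_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stop_fmt("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .stop_fmt("malformed FASTA '%s': %s",
                                                path, conditionMessage(e)))
  if (length(set) == 0L) .stop_fmt("FASTA file '%s' contains no entries", path)
  acc <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  if (anyDuplicated(acc))
    .stop_fmt("duplicate accession(s) in '%s': %s", path,
              paste(unique(acc[duplicated(acc)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  recs <- vector("list", length(acc))
  for (i in seq_along(acc)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1L]]), .SEQ_ALPHABET)
    if (length(bad)) {
      # locate the first offending line for a useful message
      lines <- readLines(path)
      hit <- grep(paste0("[", paste(bad, collapse = ""), "]"),
                  lines[!startsWith(lines, ">")], fixed = FALSE)[1L]
      .stop_fmt("FASTA '%s', entry '%s': illegal character(s) %s (sequence line %d)",
                path, acc[i], paste(bad, collapse = ","),
                if (is.na(hit)) -1L else hit)
    }
    recs[[i]] <- protein_record(acc[i], seqs[[i]])
  }
  stats::setNames(recs, acc)
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "accession")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read residue-level binding-site annotations
#'
#' Tab-separated file with two columns: accession and a comma-separated
#' list of 1-based binding positions. Duplicate positions collapse.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping accession to a sorted integer vector of
#'   positions.
#' @export
read_site_annotations <- function(path) {
  if (!file.exists(path)) .stop_fmt("annotation file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 1L || !nzchar(fields[1L]))
      .stop_fmt("'%s' line %d: missing accession", path, i)
    acc <- fields[1L]
    pos <- integer()
    if (length(fields) >= 2L && nzchar(trimws(fields[2L]))) {
      pos <- suppressWarnings(as.integer(strsplit(fields[2L], ",")[[1L]]))
      if (anyNA(pos))
        .stop_fmt("'%s' line %d: non-integer position", path, i)
      if (any(pos < 1L))
        .stop_fmt("'%s' line %d: positions are 1-based; got %d",
                  path, i, min(pos))
    }
    out[[acc]] <- sort(unique(c(out[[acc]], pos)))
  }
  out
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: free-text header, then one row per
#' residue starting with the 1-based position and the residue letter,
#' followed by (at least) 20 integer log-odds columns. Only the first 20
#' score columns (the log-odds block) are retained; the weighted-percentage
#' block and trailing statistics are ignored.
#'
#' @param path Path to the PSSM file.
#' @param accession Accession to attach; defaults to the file base name.
#' @return A [pssm_profile()].
#' @export
read_pssm <- function(path, accession = NULL) {
  if (!file.exists(path)) .stop_fmt("PSSM file not found: %s", path)
  if (is.null(accession))
    accession <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  rows <- list(); residues <- character(); expect <- 1L
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
    if (length(tok) < 2L) next
    pos <- suppressWarnings(as.integer(tok[1L]))
    if (is.na(pos) || !grepl("^[A-Za-z]$", tok[2L])) next
    if (pos != expect)
      .stop_fmt("PSSM '%s': expected row %d, found position %s (line %d)",
                path, expect, tok[1L], i)
    vals <- suppressWarnings(as.integer(tok[-(1:2)]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 20L)
      .stop_fmt("PSSM '%s': row %d has %d parsable score columns (need 20)",
                path, pos, length(vals))
    rows[[pos]] <- vals[1:20]
    residues[pos] <- toupper(tok[2L])
    expect <- expect + 1L
  }
  if (!length(rows)) .stop_fmt("PSSM '%s': no score rows found", path)
  pssm_profile(accession, do.call(rbind, rows), residues)
}

#' Write a PSSM profile in the PSI-BLAST ASCII dialect
#'
#' Emits the standard three header lines, position/residue columns, the 20
#' log-odds columns and nothing else; [read_pssm()] round-trips the file.
#'
#' @param profile A [pssm_profile()] with `residues` set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"), !is.null(profile$residues))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("            ", paste(sprintf("%3s", AMINO_ACIDS),
                                            collapse = " "))), con)
  for (i in seq_len(nrow(profile$scores)))
    writeLines(sprintf("%5d %s  %s", i, profile$residues[i],
                       paste(sprintf("%3d", profile$scores[i, ]),
                             collapse = " ")), con)
  invisible(path)
}

#' Assemble a labelled dataset from records, annotations and profiles
#'
#' @param records Named list of [protein_record()] (as from [read_fasta()]).
#' @param sites Optional named list accession -> positions (as from
#'   [read_site_annotations()]); accessions absent from `records` are
#'   dropped with a warning.
#' @param profiles Optional named list of [pssm_profile()]; each profile
#'   must match its record's length, and residue letters are cross-checked
#'   when present.
#' @return An object of class `fad_dataset` with elements `records` and
#'   `profiles`.
#' @export
assemble_dataset <- function(records, sites = NULL, profiles = NULL) {
  acc <- vapply(records, `[[`, "", "accession")
  names(records) <- acc
  if (anyDuplicated(acc))
    .stop_fmt("duplicate accessions in dataset: %s",
              paste(unique(acc[duplicated(acc)]), collapse = ", "))
  if (!is.null(sites)) {
    unknown <- setdiff(names(sites), acc)
    if (length(unknown))
      warning(sprintf("site annotations for unknown accession(s) ignored: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
    for (a in intersect(names(sites), acc))
      records[[a]] <- protein_record(a, records[[a]]$sequence, sites[[a]])
  }
  if (!is.null(profiles)) {
    names(profiles) <- vapply(profiles, `[[`, "", "accession")
    unknown <- setdiff(names(profiles), acc)
    if (length(unknown))
      .stop_fmt("profile(s) without matching record: %s",
                paste(unknown, collapse = ", "))
    for (a in names(profiles)) {
      L <- nchar(records[[a]]$sequence)
      if (nrow(profiles[[a]]$scores) != L)
        .stop_fmt("profile '%s' has %d rows but sequence has %d residues",
                  a, nrow(profiles[[a]]$scores), L)
      res <- profiles[[a]]$residues
      if (!is.null(res)) {
        seqchr <- strsplit(records[[a]]$sequence, "")[[1L]]
        if (any(res != seqchr & res != "X" & seqchr != "X"))
          .stop_fmt("profile '%s': residue letters disagree with sequence", a)
      }
    }
  }
  structure(list(records = records, profiles = profiles %||% list()),
            class = "fad_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fad_dataset <- function(x, ...) {
  npos <- sum(vapply(x$records, function(r) length(r$sites), 0L))
  nres <- sum(vapply(x$records, function(r) nchar(r$sequence), 0L))
  cat(sprintf("<fad_dataset> %d protein(s), %d residues, %d binding sites, %d PSSM profile(s)\n",
              length(x$records), nres, npos, length(x$profiles)))
  invisible(x)
}

#' Write residue-level predictions to TSV
#'
#' @param predictions Data frame with columns `accession`, `position`
#'   (1-based), `residue`, `score` (decision value) and `label`
#'   (`"binding"`/`"non-binding"`), sorted by accession then position.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("accession", "position", "residue", "score", "label")
  miss <- setdiff(need, names(predictions))
  if (length(miss)) .stop_fmt("predictions missing column(s): %s",
                              paste(miss, collapse = ", "))
  key <- paste(predictions$accession, predictions$position)
  if (anyDuplicated(key))
    .stop_fmt("duplicate (accession, position) row(s) in predictions")
  o <- order(predictions$accession, predictions$position)
  if (!identical(o, seq_len(nrow(predictions))))
    .stop_fmt("predictions must be sorted by accession then position")
  out <- predictions[, need]
  out$score <- sprintf("%.10g", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#' @param path Path to the TSV file.
#' @return Data frame with the five prediction columns.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$position <- as.integer(df$position)
  df$score <- as.numeric(df$score)
  df
}
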