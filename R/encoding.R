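#' Extract residue-centred windows from a protein record
#'
#' One window per residue: a stretch of `w` residues centred on the
#' classified position, with positions beyond the termini filled with the
#' pad symbol `-`. The label is `TRUE` when the centre residue is an
#' annotated binding site.
#'
#' @param record A [protein_record()].
#' @param w Odd window width >= 3 (default 17).
#' @return Data frame with columns `accession`, `center` (1-based),
#'   `residues` (string of length `w`) and `label` (logical).
#' @export
extract_windows <- function(record, w = 17L) {
  w <- as.integer(w)
  if (w < 3L || w %% 2L == 0L)
    .stop_fmt("window width must be odd and >= 3, got %d", w)
  seqchr <- strsplit(record$sequence, "")[[1L]]
  L <- length(seqchr)
  half <- (w - 1L) %/% 2L
  padded <- c(rep(PAD_SYMBOL, half), seqchr, rep(PAD_SYMBOL, half))
  idx <- outer(seq_len(L) - 1L, seq_len(w), `+`)  # rows: start..start+w-1
  win <- apply(matrix(padded[idx], nrow = L), 1L, paste, collapse = "")
  data.frame(accession = record$accession,
             center = seq_len(L),
             residues = win,
             label = seq_len(L) %in% record$sites,
             stringsAsFactors = FALSE)
}

#' Extract windows for every record in a dataset
#'
#' @param dataset A `fad_dataset`.
#' @inheritParams extract_windows
#' @return Row-bound window data frame over all proteins.
#' @export
dataset_windows <- function(dataset, w = 17L) {
  do.call(rbind, lapply(dataset$records, extract_windows, w = w))
}

# windows as an n x w character matrix
.window_chars <- function(windows) {
  w <- nchar(windows$residues[1L])
  matrix(unlist(strsplit(windows$residues, ""), use.names = FALSE),
         ncol = w, byrow = TRUE)
}

#' Logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, used to squash integer PSSM log-odds into (0, 1).
#' Saturates cleanly for large `|x|` (no overflow: the negative branch is
#' computed as `exp(x) / (1 + exp(x))`).
#'
#' @param x Numeric vector.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' One-hot (binary) window encoding
#'
#' Each window position contributes a 20-slot block with a single 1 at the
#' slot of its residue; pad symbols and `X` contribute all-zero blocks.
#' Vector length is `20 * w` (340 for the default window of 17).
#'
#' @param windows Window data frame from [extract_windows()].
#' @return Numeric matrix, one row per window.
#' @export
encode_binary <- function(windows) {
  chars <- .window_chars(windows)
  n <- nrow(chars); w <- ncol(chars)
  X <- matrix(0, n, 20L * w)
  aa_idx <- match(chars, AMINO_ACIDS)            # NA for pad / X
  pos <- which(!is.na(aa_idx))
  col <- (((pos - 1L) %/% n)) * 20L + aa_idx[pos]  # block by window position
  X[cbind(((pos - 1L) %% n) + 1L, col)] <- 1
  colnames(X) <- paste0("p", rep(seq_len(w), each = 20L), ".", AMINO_ACIDS)
  X
}

#' Return the 20 x 20 substitution matrix used by [encode_substitution()]
#'
#' The NCBI-standard integer PAM250 / BLOSUM62 tables (via Biostrings),
#' restricted to the 20 canonical residues in [AMINO_ACIDS] order.
#'
#' @param matrix_name `"PAM250"` or `"BLOSUM62"` (case-insensitive).
#' @return Integer matrix with residue dimnames.
#' @export
substitution_matrix <- function(matrix_name) {
  nm <- toupper(matrix_name)
  if (!nm %in% c("PAM250", "BLOSUM62"))
    .stop_fmt("unknown substitution matrix '%s' (PAM250 or BLOSUM62)",
              matrix_name)
  env <- new.env()
  utils::data(list = nm, package = "Biostrings", envir = env)
  m <- get(nm, envir = env)[AMINO_ACIDS, AMINO_ACIDS]
  storage.mode(m) <- "integer"
  m
}

#' Substitution-matrix window encoding
#'
#' Each window position contributes the 20-entry substitution row of its
#' residue from the chosen matrix; pads and `X` contribute zero blocks.
#'
#' @inheritParams encode_binary
#' @param matrix_name `"PAM250"` or `"BLOSUM62"`.
#' @return Numeric matrix, one row per window, `20 * w` columns.
#' @export
encode_substitution <- function(windows, matrix_name = "BLOSUM62") {
  sub <- substitution_matrix(matrix_name)
  chars <- .window_chars(windows)
  n <- nrow(chars); w <- ncol(chars)
  X <- matrix(0, n, 20L * w)
  aa_idx <- match(chars, AMINO_ACIDS)
  dim(aa_idx) <- dim(chars)
  for (j in seq_len(w)) {
    ok <- !is.na(aa_idx[, j])
    if (any(ok))
      X[ok, ((j - 1L) * 20L + 1L):(j * 20L)] <- sub[aa_idx[ok, j], ]
  }
  colnames(X) <- paste0("p", rep(seq_len(w), each = 20L), ".", AMINO_ACIDS)
  X
}

#' PSSM window encoding
#'
#' Each in-sequence window position contributes the element-wise sigmoid of
#' its 20 PSSM log-odds scores; pad positions contribute zero blocks (zero
#' marks "no information", distinct from `sigmoid(0) = 0.5`). Length is
#' `20 * w` (17 * 20 = 340 at the default window).
#'
#' @inheritParams encode_binary
#' @param profiles Named list of [pssm_profile()] keyed by accession,
#'   covering every accession present in `windows`.
#' @return Numeric matrix with entries in \[0, 1).
#' @export
encode_pssm <- function(windows, profiles) {
  w <- nchar(windows$residues[1L])
  half <- (w - 1L) %/% 2L
  n <- nrow(windows)
  X <- matrix(0, n, 20L * w)
  for (acc in unique(windows$accession)) {
    prof <- profiles[[acc]]
    if (is.null(prof))
      .stop_fmt("no PSSM profile for accession '%s'", acc)
    L <- nrow(prof$scores)
    rows <- which(windows$accession == acc)
    if (max(windows$center[rows]) > L)
      .stop_fmt("profile '%s' shorter than its sequence windows", acc)
    S <- sigmoid(prof$scores)               # L x 20, recycled per window
    dim(S) <- dim(prof$scores)
    for (j in seq_len(w)) {
      src <- windows$center[rows] + (j - half - 1L)
      ok <- src >= 1L & src <= L
      if (any(ok))
        X[rows[ok], ((j - 1L) * 20L + 1L):(j * 20L)] <- S[src[ok], ]
    }
  }
  colnames(X) <- paste0("p", rep(seq_len(w), each = 20L), ".", AMINO_ACIDS)
  X
}
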