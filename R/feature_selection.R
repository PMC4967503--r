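#' F-score of a single feature
#'
#' Ratio of the squared deviations of the class means from the grand mean
#' to the sum of the two within-class sample variances:
#' \deqn{F = \frac{(\bar x^{(+)}-\bar x)^2 + (\bar x^{(-)}-\bar x)^2}
#'             {\frac{1}{n_+-1}\sum_k (x^{(+)}_k-\bar x^{(+)})^2 +
#'              \frac{1}{n_--1}\sum_k (x^{(-)}_k-\bar x^{(-)})^2}}
#' A larger value indicates stronger class separation for the feature.
#' When both within-class variances are zero the score is defined as
#' `Inf` if the numerator is positive and `0` otherwise.
#'
#' @param values_pos Feature values of the positive class (length >= 2).
#' @param values_neg Feature values of the negative class (length >= 2).
#' @return Non-negative scalar (possibly `Inf`).
#' @export
f_score <- function(values_pos, values_neg) {
  if (length(values_pos) < 2L || length(values_neg) < 2L)
    .stop_fmt("each class needs >= 2 instances for the F-score")
  xall <- mean(c(values_pos, values_neg))
  xp <- mean(values_pos); xn <- mean(values_neg)
  num <- (xp - xall)^2 + (xn - xall)^2
  den <- stats::var(values_pos) + stats::var(values_neg)
  if (den == 0) return(if (num > 0) Inf else 0)
  num / den
}

#' Rank feature columns by F-score
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Binary labels (logical or 0/1), positive = binding.
#' @return Data frame with columns `feature_index` and `score`, sorted by
#'   descending score; ties broken by lower feature index (stable).
#' @export
rank_features <- function(X, y) {
  y <- as.logical(y)
  if (length(unique(y)) < 2L)
    .stop_fmt("rank_features needs both classes present")
  if (nrow(X) != length(y)) .stop_fmt("X and y sizes disagree")
  scores <- vapply(seq_len(ncol(X)),
                   function(j) f_score(X[y, j], X[!y, j]), 0)
  o <- order(-scores, seq_along(scores))
  data.frame(feature_index = o, score = scores[o])
}

#' Append the top-k F-score features to a PSSM feature matrix
#'
#' @param pssm_X Base feature matrix (e.g. the 340-column PSSM encoding).
#' @param candidate_X Candidate matrix the F-score ranking is drawn from
#'   (by default the binary encoding matrix in the pipeline).
#' @param y Binary labels aligned with both matrices.
#' @param k Number of top-ranked candidate columns to append (default 30).
#' @param ranking Optional precomputed [rank_features()] result (used to
#'   apply a ranking learned on training data to held-out rows).
#' @return Matrix of width `ncol(pssm_X) + k`.
#' @export
augment_with_fscore <- function(pssm_X, candidate_X, y, k = 30L,
                                ranking = NULL) {
  if (nrow(pssm_X) != nrow(candidate_X))
    .stop_fmt("row counts of pssm_X and candidate_X disagree")
  k <- as.integer(k)
  if (k > ncol(candidate_X))
    .stop_fmt("k = %d exceeds the %d candidate columns", k, ncol(candidate_X))
  if (k == 0L) return(pssm_X)
  if (is.null(ranking)) ranking <- rank_features(candidate_X, y)
  sel <- ranking$feature_index[seq_len(k)]
  out <- cbind(pssm_X, candidate_X[, sel, drop = FALSE])
  base_names <- colnames(pssm_X) %||%
    paste0("base", seq_len(ncol(pssm_X)))
  colnames(out) <- c(base_names, paste0("fscore", seq_len(k)))
  out
}

#' Ordered amino-acid pairs occurring in a window
#'
#' Contiguous ordered dipeptides (positions i, i+1+gap) within the window;
#' any pair touching a pad symbol or an `X` is excluded. Presence is per
#' window (a set), matching the sequence-counting enrichment statistic.
#'
#' @param residues Window string (or vector of strings).
#' @param gap Number of skipped positions between the two residues
#'   (default 0 = contiguous).
#' @return For a single window, a character vector of unique pairs; for a
#'   vector input, a list of such vectors.
#' @export
pairs_in_window <- function(residues, gap = 0L) {
  one <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    w <- length(ch)
    if (w < 2L + gap) return(character())
    a <- ch[seq_len(w - 1L - gap)]
    b <- ch[seq_len(w - 1L - gap) + 1L + gap]
    ok <- a %in% AMINO_ACIDS & b %in% AMINO_ACIDS
    unique(paste0(a[ok], b[ok]))
  }
  if (length(residues) == 1L) one(residues) else lapply(residues, one)
}

#' Hypergeometric enrichment p-value for an amino-acid pair
#'
#' Point probability of observing exactly `x` positive windows among the
#' `n` windows that contain the pair, when `M` of the `N` windows are
#' positive: `choose(M, x) * choose(N - M, n - x) / choose(N, n)`.
#' Computed in log space via [stats::dhyper()]. With `tail = TRUE` the
#' upper tail `P(X >= x)` is returned instead.
#'
#' @param N Total number of windows.
#' @param M Number of positive (binding-site) windows.
#' @param n Number of windows containing the pair.
#' @param x Number of positive windows containing the pair.
#' @param tail Return the upper-tail sum instead of the point mass.
#' @return Probability in \[0, 1\].
#' @export
saap_pvalue <- function(N, M, n, x, tail = FALSE) {
  if (M < 0 || M > N || n < 0 || n > N || x < 0 || x > n ||
      x > M || (n - x) > (N - M))
    .stop_fmt("invalid hypergeometric parameters N=%d M=%d n=%d x=%d",
              N, M, n, x)
  if (tail)
    stats::phyper(x - 1, M, N - M, n, lower.tail = FALSE)
  else
    stats::dhyper(x, M, N - M, n)
}

#' Discover significant amino-acid pairs (SAAPs)
#'
#' For each of the 400 ordered dipeptides, counts the windows containing it
#' in the whole set (`n`) and among positive windows (`x`), with
#' `N` = total windows and `M` = positive windows, and computes the
#' hypergeometric enrichment statistic of [saap_pvalue()]. Pairs with
#' p-value below `alpha` that are over-represented in positive windows
#' (`x / n > M / N`) are kept, ranked by ascending p-value (ties broken
#' lexicographically on the pair), and truncated to `max_k`.
#'
#' @param windows Window data frame with `residues` and `label` columns.
#' @param alpha Significance threshold (default 0.13; strict `<`).
#' @param max_k Maximum number of returned patterns (default 38).
#' @param gap Passed to [pairs_in_window()].
#' @param tail Use the upper-tail p-value instead of the point mass.
#' @return Data frame with columns `pair`, `x`, `n`, `M`, `N`, `p_value`,
#'   `rank` (possibly zero rows).
#' @export
discover_saaps <- function(windows, alpha = 0.13, max_k = 38L, gap = 0L,
                           tail = FALSE) {
  lab <- as.logical(windows$label)
  if (length(unique(lab)) < 2L)
    .stop_fmt("discover_saaps needs both classes present")
  all_pairs <- as.vector(outer(AMINO_ACIDS, AMINO_ACIDS, paste0))
  plist <- pairs_in_window(windows$residues, gap = gap)
  if (!is.list(plist)) plist <- list(plist)
  N <- length(plist); M <- sum(lab)
  n_all <- table(factor(unlist(plist), levels = all_pairs))
  n_pos <- table(factor(unlist(plist[lab]), levels = all_pairs))
  n <- as.integer(n_all); x <- as.integer(n_pos)
  p <- stats::dhyper(x, M, N - M, n)
  if (tail) p <- stats::phyper(x - 1, M, N - M, n, lower.tail = FALSE)
  enriched <- n > 0L & (x / n) > (M / N)
  keep <- which(p < alpha & enriched)
  out <- data.frame(pair = all_pairs[keep], x = x[keep], n = n[keep],
                    M = rep(M, length(keep)), N = rep(N, length(keep)),
                    p_value = p[keep], stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$pair), , drop = FALSE]
  if (nrow(out) > max_k) out <- out[seq_len(max_k), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Binary SAAP indicator features for windows
#'
#' One indicator column per discovered pattern, in rank order: 1 when the
#' window contains the ordered pair. Appended to the PSSM encoding this
#' yields 340 + 38 = 378 columns at the default configuration.
#'
#' @param windows Window data frame.
#' @param patterns [discover_saaps()] result (rank-ordered).
#' @param gap Passed to [pairs_in_window()].
#' @return Numeric 0/1 matrix, `nrow(windows)` x `nrow(patterns)`.
#' @export
encode_saap_features <- function(windows, patterns, gap = 0L) {
  plist <- pairs_in_window(windows$residues, gap = gap)
  if (!is.list(plist)) plist <- list(plist)
  X <- matrix(0, length(plist), nrow(patterns))
  for (j in seq_len(nrow(patterns)))
    X[, j] <- vapply(plist, function(p) patterns$pair[j] %in% p, TRUE)
  colnames(X) <- if (nrow(patterns)) paste0("saap.", patterns$pair)
  X
}
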