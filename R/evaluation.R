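#' Confusion counts for binary residue predictions
#'
#' Positive class = binding.
#'
#' @param y_true,y_pred Logical (or 0/1) vectors of equal length.
#' @return Object of class `confusion_counts`: a named list with integer
#'   elements `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.logical(y_true); y_pred <- as.logical(y_pred)
  if (length(y_true) != length(y_pred))
    .stop_fmt("y_true and y_pred lengths disagree")
  structure(list(TP = sum(y_true & y_pred), FP = sum(!y_true & y_pred),
                 TN = sum(!y_true & !y_pred), FN = sum(y_true & !y_pred)),
            class = "confusion_counts")
}

#' Build confusion counts directly from the four cell counts
#' @param TP,FP,TN,FN Non-negative integers.
#' @return A `confusion_counts` object.
#' @export
confusion_from_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Sensitivity, specificity and accuracy (percent)
#'
#' `sensitivity = 100 * TP / (TP + FN)` — the percentage of binding sites
#' recovered; `specificity = 100 * TN / (TN + FP)`;
#' `accuracy = 100 * (TP + TN) / (TP + FP + TN + FN)`. A zero denominator
#' yields `NA` (an undefined-metric marker), never an error.
#'
#' @param counts A `confusion_counts` object.
#' @return Percentage in \[0, 100\], or `NA` when undefined.
#' @export
sensitivity <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) NA_real_ else 100 * counts$TP / d
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  d <- counts$TN + counts$FP
  if (d == 0) NA_real_ else 100 * counts$TN / d
}

#' @rdname sensitivity
#' @export
accuracy <- function(counts) {
  d <- counts$TP + counts$FP + counts$TN + counts$FN
  if (d == 0) NA_real_ else 100 * (counts$TP + counts$TN) / d
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any
#' factor under the root is zero the coefficient is defined as 0 (the
#' standard convention for degenerate margins).
#'
#' @param counts A `confusion_counts` object.
#' @return Value in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Summarise confusion counts as the four standard metrics
#'
#' @param counts A `confusion_counts` object.
#' @param auc Optional AUC to carry along.
#' @param digits Rounding for display (default 2, matching common
#'   reporting practice); the unrounded values are kept.
#' @return Object of class `metric_report`: list with `counts`,
#'   `sensitivity`, `specificity`, `accuracy`, `mcc`, `auc`.
#' @export
metric_report <- function(counts, auc = NA_real_, digits = 2L) {
  structure(list(counts = counts,
                 sensitivity = sensitivity(counts),
                 specificity = specificity(counts),
                 accuracy = accuracy(counts),
                 mcc = mcc(counts),
                 auc = auc, digits = digits),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  d <- x$digits
  cat(sprintf("Sens %s%%  Spec %s%%  Acc %s%%  MCC %s%s\n",
              round(x$sensitivity, d), round(x$specificity, d),
              round(x$accuracy, d), round(x$mcc, d),
              if (is.na(x$auc)) "" else sprintf("  AUC %.4f", x$auc)))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores; the AUC is the trapezoidal
#' area, which with rank-averaged tie handling equals the Mann-Whitney
#' statistic `(concordant + ties/2) / (n_pos * n_neg)`.
#'
#' @param scores Real-valued decision scores (larger = more binding-like).
#' @param y_true Binary labels.
#' @return List with `curve` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  y <- as.logical(y_true)
  if (length(scores) != length(y)) .stop_fmt("scores and labels disagree")
  np <- sum(y); nn <- sum(!y)
  if (np == 0L || nn == 0L)
    .stop_fmt("ROC needs both classes present")
  # curve: descending thresholds at unique score values
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  cum_tp <- cumsum(ys); cum_fp <- cumsum(!ys)
  last <- !duplicated(ss, fromLast = TRUE)   # last index of each threshold
  curve <- data.frame(threshold = c(Inf, ss[last]),
                      fpr = c(0, cum_fp[last] / nn),
                      tpr = c(0, cum_tp[last] / np))
  auc_trap <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                       utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc_trap)
}

#' Stratified k-fold cross-validation of the RBFN classifier
#'
#' Splits windows into `k` stratified folds from a seeded shuffle, retrains
#' the network on each training split and pools the held-out predictions
#' before computing metrics (so the report reflects one pooled confusion
#' matrix, not a mean of per-fold metrics).
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @param bandwidth,ridge Passed to [rbfn_train()].
#' @return List with `report` (a [metric_report()] including pooled AUC),
#'   `counts`, `scores`, `predicted`, `fold` (fold id per row).
#' @export
kfold_cv <- function(X, y, k = 5L, seed = 1L, bandwidth = 5, ridge = 1e-8) {
  y <- as.logical(y)
  k <- as.integer(k)
  if (k < 2L) .stop_fmt("k must be >= 2")
  if (min(sum(y), sum(!y)) < k)
    .stop_fmt("need at least k = %d samples in each class", k)
  fold <- make_folds(y, k, seed)
  scores <- numeric(length(y)); pred <- logical(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- rbfn_train(X[tr, , drop = FALSE], y[tr],
                        bandwidth = bandwidth, ridge = ridge)
    p <- rbfn_predict(model, X[!tr, , drop = FALSE])
    scores[!tr] <- p$score; pred[!tr] <- p$label
  }
  counts <- confusion_counts(y, pred)
  list(report = metric_report(counts, auc = roc_auc(scores, y)$auc),
       counts = counts, scores = scores, predicted = pred, fold = fold)
}

#' Stratified fold assignment
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold ids in `1..k`; within each class, fold
#'   sizes differ by at most 1.
#' @export
make_folds <- function(y, k, seed = 1L) {
  y <- as.logical(y)
  fold <- integer(length(y))
  set.seed(as.integer(seed))
  offset <- 0L   # rotate the second class so overall sizes differ by <= 1
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Leave-one-protein-out evaluation
#'
#' For each protein, trains on all other proteins' windows and tests on the
#' held-out protein, so no window of the evaluated protein ever enters its
#' own training set. Feature selection (SAAP discovery, F-score ranking)
#' is refit inside each training split.
#'
#' @param dataset A `fad_dataset` with >= 2 proteins (profiles required for
#'   PSSM-based schemes).
#' @param scheme Encoding scheme; see [build_features()].
#' @param w Window width.
#' @param bandwidth,ridge RBFN hyper-parameters.
#' @param ... Further arguments to [build_features()].
#' @return List with `per_protein` (data frame of per-protein counts and
#'   metrics), `mean` (unweighted arithmetic means of the four metrics
#'   across proteins) and `reports` (named list of [metric_report()]).
#' @export
leave_one_protein_out <- function(dataset, scheme = "pssm+saap", w = 17L,
                                  bandwidth = 5, ridge = 1e-8, ...) {
  accs <- names(dataset$records)
  if (length(accs) < 2L) .stop_fmt("need >= 2 proteins for LOPO")
  windows <- dataset_windows(dataset, w)
  reports <- list()
  rows <- list()
  for (acc in accs) {
    tr_w <- windows[windows$accession != acc, , drop = FALSE]
    te_w <- windows[windows$accession == acc, , drop = FALSE]
    fs <- fit_feature_space(tr_w, scheme, dataset$profiles, ...)
    model <- rbfn_train(fs$X, tr_w$label, bandwidth = bandwidth,
                        ridge = ridge)
    Xte <- apply_feature_space(fs, te_w, dataset$profiles)
    p <- rbfn_predict(model, Xte)
    counts <- confusion_counts(te_w$label, p$label)
    auc <- if (length(unique(te_w$label)) == 2L)
      roc_auc(p$score, te_w$label)$auc else NA_real_
    rep <- metric_report(counts, auc = auc)
    reports[[acc]] <- rep
    rows[[acc]] <- data.frame(accession = acc, TP = counts$TP,
                              FP = counts$FP, TN = counts$TN,
                              FN = counts$FN,
                              sensitivity = rep$sensitivity,
                              specificity = rep$specificity,
                              accuracy = rep$accuracy, mcc = rep$mcc,
                              auc = auc, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows); rownames(per) <- NULL
  means <- colMeans(per[, c("sensitivity", "specificity", "accuracy",
                            "mcc")], na.rm = TRUE)
  list(per_protein = per, mean = means, reports = reports)
}

#' Amino-acid composition of binding vs non-binding residues
#'
#' Occurrence frequency of each of the 20 amino acids among annotated
#' binding residues and among the remaining residues, plus the
#' binding-minus-non-binding difference.
#'
#' @param dataset A `fad_dataset`.
#' @return Data frame with columns `aa`, `binding`, `non_binding`,
#'   `difference`; each frequency column sums to 1 (or is all `NA` when
#'   the class is empty).
#' @export
composition_analysis <- function(dataset) {
  bind <- character(); non <- character()
  for (r in dataset$records) {
    ch <- strsplit(r$sequence, "")[[1L]]
    is_site <- seq_along(ch) %in% r$sites
    bind <- c(bind, ch[is_site]); non <- c(non, ch[!is_site])
  }
  freq <- function(x) {
    x <- x[x %in% AMINO_ACIDS]
    if (!length(x)) return(rep(NA_real_, 20L))
    as.numeric(table(factor(x, levels = AMINO_ACIDS))) / length(x)
  }
  fb <- freq(bind); fn <- freq(non)
  data.frame(aa = AMINO_ACIDS, binding = fb, non_binding = fn,
             difference = fb - fn, stringsAsFactors = FALSE)
}
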