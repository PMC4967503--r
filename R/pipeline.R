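#' Default run configuration
#'
#' The defaults reproduce the published configuration of the method:
#' window 17, Gaussian bandwidth 5, SAAP significance threshold 0.13 with
#' at most 38 patterns, and 30 F-score-selected features appended to the
#' PSSM encoding.
#'
#' @param window Odd window width.
#' @param scheme Encoding scheme (`"binary"`, `"pam250"`, `"blosum62"`,
#'   `"pssm"`, `"pssm+fscore"`, `"pssm+saap"`).
#' @param bandwidth RBFN kernel bandwidth.
#' @param ridge RBFN regularisation.
#' @param alpha SAAP significance threshold.
#' @param max_saaps Maximum number of SAAP patterns.
#' @param fscore_k Number of F-score features appended.
#' @param seed Seed for all randomised steps.
#' @return A named list of class `fad_config`.
#' @export
fad_config <- function(window = 17L, scheme = "pssm+saap", bandwidth = 5,
                       ridge = 1e-8, alpha = 0.13, max_saaps = 38L,
                       fscore_k = 30L, seed = 1L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    .stop_fmt("window must be odd and >= 3, got %d", window)
  if (!scheme %in% c("binary", "pam250", "blosum62", "pssm",
                     "pssm+fscore", "pssm+saap"))
    .stop_fmt("unknown scheme '%s'", scheme)
  structure(list(window = window, scheme = scheme, bandwidth = bandwidth,
                 ridge = ridge, alpha = alpha,
                 max_saaps = as.integer(max_saaps),
                 fscore_k = as.integer(fscore_k),
                 seed = as.integer(seed)),
            class = "fad_config")
}

#' Fit a feature space on (training) windows
#'
#' Computes the base encoding and, for the augmented schemes, learns the
#' data-dependent parts — the SAAP pattern list or the F-score ranking —
#' from these windows only, so held-out data can be transformed without
#' leakage via [apply_feature_space()].
#'
#' @param windows Window data frame (training split).
#' @param scheme Encoding scheme (see [fad_config()]).
#' @param profiles Named list of PSSM profiles (PSSM-based schemes).
#' @param alpha,max_saaps SAAP discovery parameters.
#' @param fscore_k Number of appended F-score features; the candidate pool
#'   is the one-hot encoding of the same windows.
#' @param gap SAAP gap parameter.
#' @return List of class `feature_space` with the fitted parameters and
#'   `X`, the encoded training matrix.
#' @export
fit_feature_space <- function(windows, scheme = "pssm+saap",
                              profiles = NULL, alpha = 0.13,
                              max_saaps = 38L, fscore_k = 30L, gap = 0L) {
  base <- function(wdf) switch(scheme,
    binary = encode_binary(wdf),
    pam250 = encode_substitution(wdf, "PAM250"),
    blosum62 = encode_substitution(wdf, "BLOSUM62"),
    `pssm` = ,
    `pssm+fscore` = ,
    `pssm+saap` = encode_pssm(wdf, profiles),
    .stop_fmt("unknown scheme '%s'", scheme))
  X <- base(windows)
  patterns <- NULL; ranking <- NULL
  if (scheme == "pssm+saap") {
    patterns <- discover_saaps(windows, alpha = alpha, max_k = max_saaps,
                               gap = gap)
    if (nrow(patterns))
      X <- cbind(X, encode_saap_features(windows, patterns, gap = gap))
  } else if (scheme == "pssm+fscore") {
    cand <- encode_binary(windows)
    ranking <- rank_features(cand, windows$label)
    X <- augment_with_fscore(X, cand, windows$label, k = fscore_k,
                             ranking = ranking)
  }
  structure(list(scheme = scheme, patterns = patterns, ranking = ranking,
                 fscore_k = fscore_k, gap = gap, X = X),
            class = "feature_space")
}

#' Transform windows under a fitted feature space
#'
#' @param fs A `feature_space` from [fit_feature_space()].
#' @param windows Window data frame to transform.
#' @param profiles PSSM profiles covering these windows (PSSM schemes).
#' @return Encoded feature matrix with the training feature width.
#' @export
apply_feature_space <- function(fs, windows, profiles = NULL) {
  X <- switch(fs$scheme,
    binary = encode_binary(windows),
    pam250 = encode_substitution(windows, "PAM250"),
    blosum62 = encode_substitution(windows, "BLOSUM62"),
    `pssm` = ,
    `pssm+fscore` = ,
    `pssm+saap` = encode_pssm(windows, profiles))
  if (fs$scheme == "pssm+saap" && !is.null(fs$patterns) &&
      nrow(fs$patterns))
    X <- cbind(X, encode_saap_features(windows, fs$patterns, gap = fs$gap))
  if (fs$scheme == "pssm+fscore") {
    cand <- encode_binary(windows)
    sel <- fs$ranking$feature_index[seq_len(fs$fscore_k)]
    ext <- cand[, sel, drop = FALSE]
    colnames(ext) <- paste0("fscore", seq_len(fs$fscore_k))
    X <- cbind(X, ext)
  }
  X
}

#' One-shot feature matrix for a set of windows
#'
#' Convenience wrapper that fits the feature space and encodes the same
#' windows (appropriate when no held-out evaluation is involved).
#'
#' @inheritParams fit_feature_space
#' @return Encoded feature matrix.
#' @export
build_features <- function(windows, scheme = "pssm+saap", profiles = NULL,
                           ...) {
  fit_feature_space(windows, scheme, profiles, ...)$X
}

#' Cross-validated evaluation of the full prediction pipeline
#'
#' Stratified window-level k-fold cross-validation in which the
#' data-dependent feature-space parts (SAAP discovery, F-score ranking)
#' are refit inside each training split before the RBFN is trained, and
#' held-out predictions are pooled for the final metrics.
#'
#' @param dataset A `fad_dataset`.
#' @param config A [fad_config()].
#' @param k Number of folds.
#' @return As [kfold_cv()], plus `windows`.
#' @export
pipeline_cv <- function(dataset, config = fad_config(), k = 5L) {
  windows <- dataset_windows(dataset, config$window)
  y <- windows$label
  fold <- make_folds(y, k, config$seed)
  scores <- numeric(length(y)); pred <- logical(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    fs <- fit_feature_space(windows[tr, , drop = FALSE], config$scheme,
                            dataset$profiles, alpha = config$alpha,
                            max_saaps = config$max_saaps,
                            fscore_k = config$fscore_k)
    model <- rbfn_train(fs$X, y[tr], bandwidth = config$bandwidth,
                        ridge = config$ridge)
    Xte <- apply_feature_space(fs, windows[!tr, , drop = FALSE],
                               dataset$profiles)
    p <- rbfn_predict(model, Xte)
    scores[!tr] <- p$score; pred[!tr] <- p$label
  }
  counts <- confusion_counts(y, pred)
  list(report = metric_report(counts, auc = roc_auc(scores, y)$auc),
       counts = counts, scores = scores, predicted = pred, fold = fold,
       windows = windows)
}

#' Train on one dataset and predict residues of another
#'
#' Fits the feature space and RBFN on all windows of `train` and returns
#' residue-level predictions for `test` (the independent-set protocol).
#'
#' @param train,test `fad_dataset` objects.
#' @param config A [fad_config()].
#' @return List with `predictions` (data frame: accession, position,
#'   residue, score, label), `report` and `scores`.
#' @export
train_and_predict <- function(train, test, config = fad_config()) {
  tr_w <- dataset_windows(train, config$window)
  te_w <- dataset_windows(test, config$window)
  fs <- fit_feature_space(tr_w, config$scheme, train$profiles,
                          alpha = config$alpha,
                          max_saaps = config$max_saaps,
                          fscore_k = config$fscore_k)
  model <- rbfn_train(fs$X, tr_w$label, bandwidth = config$bandwidth,
                      ridge = config$ridge)
  Xte <- apply_feature_space(fs, te_w, test$profiles)
  p <- rbfn_predict(model, Xte)
  half <- (config$window - 1L) %/% 2L
  res <- substr(te_w$residues, half + 1L, half + 1L)
  preds <- data.frame(accession = te_w$accession, position = te_w$center,
                      residue = res, score = p$score,
                      label = ifelse(p$label, "binding", "non-binding"),
                      stringsAsFactors = FALSE)
  preds <- preds[order(preds$accession, preds$position), , drop = FALSE]
  counts <- confusion_counts(te_w$label, p$label)
  auc <- if (length(unique(te_w$label)) == 2L)
    roc_auc(p$score, te_w$label)$auc else NA_real_
  list(predictions = preds, report = metric_report(counts, auc = auc),
       scores = p$score, truth = te_w$label, model = model,
       feature_space = fs)
}
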