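# O(n^2) rank-free AUC oracle: concordant pairs plus half-ties
auc_oracle <- function(scores, y) {
  pos <- scores[as.logical(y)]; neg <- scores[!as.logical(y)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

test_that("confusion counts tally the four cells", {
  y <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  p <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  cc <- confusion_counts(y, p)
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               list(TP = 3L, FP = 2L, TN = 4L, FN = 1L))  # manual tally
  ident <- confusion_counts(y, y)
  expect_equal(ident$FP + ident$FN, 0L)
  compl <- confusion_counts(y, !y)
  expect_equal(compl$TP + compl$TN, 0L)
  expect_error(confusion_counts(y, p[-1]), "disagree")
})

test_that("metrics recompute every published worked-example row", {
  rows <- published_rows()
  for (i in seq_len(nrow(rows))) {
    cc <- confusion_from_counts(rows$TP[i], rows$FP[i], rows$TN[i],
                                rows$FN[i])
    expect_lt(abs(sensitivity(cc) - rows$sens[i]), printed_tol(rows$sens[i]),
              label = sprintf("sens %s/%s", rows$group[i], rows$id[i]))
    expect_lt(abs(specificity(cc) - rows$spec[i]), printed_tol(rows$spec[i]),
              label = sprintf("spec %s/%s", rows$group[i], rows$id[i]))
    expect_lt(abs(accuracy(cc) - rows$acc[i]), printed_tol(rows$acc[i]),
              label = sprintf("acc %s/%s", rows$group[i], rows$id[i]))
    expect_lt(abs(mcc(cc) - rows$mcc[i]), printed_tol(rows$mcc[i]),
              label = sprintf("mcc %s/%s", rows$group[i], rows$id[i]))
  }
})

test_that("undefined metrics yield NA markers, MCC degenerates to 0", {
  cc <- confusion_from_counts(0, 3, 5, 0)
  expect_true(is.na(sensitivity(cc)))
  expect_equal(mcc(cc), 0)
  expect_equal(mcc(confusion_from_counts(0, 0, 0, 0)), 0)
  expect_true(is.na(accuracy(confusion_from_counts(0, 0, 0, 0))))
  expect_equal(mcc(confusion_from_counts(10, 0, 12, 0)), 1)   # perfect
})

test_that("AUC equals the pairwise concordance oracle, ties included", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  set.seed(64)
  for (rep in 1:100) {
    n <- sample(4:200, 1)
    y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    scores <- sample(seq_len(max(2L, n %/% 3L)), n, TRUE) +
      ifelse(runif(n) < 0.5, 0, 0.5)   # plenty of exact ties
    expect_equal(roc_auc(scores, y)$auc, auc_oracle(scores, y))
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  y <- sample(c(TRUE, FALSE), 80, TRUE)
  s <- rnorm(80)
  base <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, base)
  expect_equal(roc_auc(5 * s - 3, y)$auc, base)
  expect_equal(roc_auc(atan(s), y)$auc, base)
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(31)
  y <- sample(c(TRUE, FALSE), 150, TRUE)
  s <- round(rnorm(150), 1)    # coarse scores force ties
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y)$auc, ref)
})

test_that("ROC curve starts at (0,0), ends at (1,1) and is monotone", {
  set.seed(2)
  y <- sample(c(TRUE, FALSE), 40, TRUE)
  r <- roc_auc(rnorm(40), y)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(utils::tail(r$curve$fpr, 1), 1)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
  expect_true(!is.unsorted(r$curve$fpr) && !is.unsorted(r$curve$tpr))
})

test_that("stratified folds are balanced, seeded and exhaustive", {
  y <- rep(c(TRUE, FALSE), c(23, 77))
  f1 <- make_folds(y, 5, seed = 3)
  f2 <- make_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_folds(y, 5, seed = 4)))
  sizes <- table(f1)
  expect_lte(diff(range(sizes)), 1L)
  pos_sizes <- table(f1[y])
  expect_lte(diff(range(pos_sizes)), 1L)
  expect_setequal(unique(f1), 1:5)
})

test_that("cross-validation pools counts over all samples deterministically", {
  set.seed(90)
  n <- 120
  y <- rep_len(c(TRUE, FALSE, FALSE), n)
  X <- matrix(rnorm(n * 6), n, 6) + 2 * as.numeric(y)
  cv1 <- kfold_cv(X, y, k = 5, seed = 17)
  cv2 <- kfold_cv(X, y, k = 5, seed = 17)
  expect_equal(cv1$report$accuracy, cv2$report$accuracy)
  expect_identical(cv1$scores, cv2$scores)
  cc <- cv1$counts
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, n)   # conservation
  expect_gt(cv1$report$auc, 0.9)                   # separable toy problem
  expect_error(kfold_cv(X, y, k = 1, seed = 1), ">= 2")
})

test_that("a constant feature space predicts the majority class throughout", {
  n <- 60
  y <- rep(c(TRUE, FALSE), c(20, 40))
  X <- matrix(1, n, 3)
  cv <- kfold_cv(X, y, k = 5, seed = 2, ridge = 1)
  expect_equal(cv$report$accuracy, 100 * mean(!y))
  expect_equal(cv$counts$TP, 0L)
})

test_that("leave-one-protein-out never trains on the held-out protein", {
  ds <- toy_dataset(2L, seed = 19L)
  res <- leave_one_protein_out(ds, scheme = "pssm", w = 9L)
  expect_equal(nrow(res$per_protein), 2L)
  site_counts <- vapply(ds$records, function(r) length(r$sites), 0L)
  expect_equal(res$per_protein$TP + res$per_protein$FN,
               unname(site_counts[res$per_protein$accession]))
  total_windows <- sum(vapply(ds$records,
                              function(r) nchar(r$sequence), 0L))
  expect_equal(sum(res$per_protein$TP + res$per_protein$FP +
                     res$per_protein$TN + res$per_protein$FN),
               total_windows)
  expect_error(leave_one_protein_out(
    assemble_dataset(list(protein_record("A", "ACDEF", 2L)))), ">= 2")
})

test_that("LOPO recovers strong planted signal across proteins", {
  ds <- generate_dataset(synthetic_spec(n_proteins = 6L,
                                        length_range = c(100L, 140L),
                                        pssm_signal = 8L, seed = 23L))
  res <- leave_one_protein_out(ds, scheme = "pssm+saap", w = 17L)
  expect_gt(mean(res$per_protein$accuracy), 90)
  expect_equal(unname(res$mean["accuracy"]),
               mean(res$per_protein$accuracy))
})

test_that("composition analysis returns normalised per-class frequencies", {
  ds <- assemble_dataset(list(protein_record("G1", "GGG", sites = 2L)))
  comp <- composition_analysis(ds)
  expect_equal(comp$binding[comp$aa == "G"], 1)
  expect_equal(sum(comp$binding), 1)
  expect_equal(sum(comp$non_binding), 1)

  big <- generate_dataset(synthetic_spec(n_proteins = 10L,
                                         length_range = c(150L, 200L),
                                         site_rate = 0.05,
                                         motif_bias = 0.9, seed = 3L))
  comp2 <- composition_analysis(big)
  expect_equal(sum(comp2$binding), 1, tolerance = 1e-12)
  expect_equal(sum(comp2$non_binding), 1, tolerance = 1e-12)
  expect_equal(comp2$difference, comp2$binding - comp2$non_binding)
  # generator plants G/S/A/T enrichment at binding sites
  gsat <- comp2$aa %in% c("G", "S", "A", "T")
  expect_true(all(sort(comp2$difference[gsat], decreasing = TRUE)[1:4] >=
                    max(comp2$difference[!gsat])))
})

test_that("empty class yields NA frequency markers", {
  ds <- assemble_dataset(list(protein_record("P1", "ACDEF")))
  comp <- composition_analysis(ds)
  expect_true(all(is.na(comp$binding)))
  expect_equal(sum(comp$non_binding), 1)
})
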