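# independent transcription of the F-score formula, kept deliberately
# naive (explicit sums) so it cannot share code with the implementation
f_score_oracle <- function(xp, xn) {
  xbar <- mean(c(xp, xn)); xbp <- mean(xp); xbn <- mean(xn)
  num <- (xbp - xbar)^2 + (xbn - xbar)^2
  den <- sum((xp - xbp)^2) / (length(xp) - 1) +
    sum((xn - xbn)^2) / (length(xn) - 1)
  if (den == 0) { if (num > 0) Inf else 0 } else num / den
}

test_that("f_score matches an independent transcription of the formula", {
  expect_equal(f_score(c(1, 2, 3), c(4, 5, 6)),
               f_score_oracle(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(f_score(c(1, 2, 3), c(4, 5, 6)), 2.25)  # hand-computed
  set.seed(101)
  for (rep in 1:50) {
    xp <- rnorm(sample(2:20, 1)); xn <- rnorm(sample(2:20, 1))
    expect_equal(f_score(xp, xn), f_score_oracle(xp, xn))
  }
})

test_that("f_score edge conventions and invariances hold", {
  expect_equal(f_score(rep(2, 5), rep(2, 4)), 0)        # zero numerator
  expect_identical(f_score(rep(1, 3), rep(2, 3)), Inf)  # zero variance, split means
  expect_error(f_score(1, c(1, 2)), ">= 2")

  set.seed(7)
  xp <- rnorm(9); xn <- rnorm(12)
  base <- f_score(xp, xn)
  expect_equal(f_score(3.7 * xp - 2, 3.7 * xn - 2), base)   # affine
  expect_equal(f_score(-xp, -xn), base)
  expect_equal(f_score(xn, xp), base)                       # class swap
})

test_that("rank_features is a stable descending sort with index tie-breaks", {
  set.seed(21)
  n <- 60
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(noise1 = rnorm(n), signal = as.numeric(y) + rnorm(n, sd = 0.1),
             noise2 = rnorm(n), dup = 0)
  X[, "dup"] <- X[, "signal"]
  r <- rank_features(X, y)
  # brute force: the label-aligned column scores highest
  scores <- apply(X, 2, function(col) f_score_oracle(col[y], col[!y]))
  expect_equal(r$feature_index[1], unname(which.max(scores)))
  expect_equal(r$score, sort(scores, decreasing = TRUE), ignore_attr = TRUE)
  # duplicated column: adjacent ranks, index-ordered
  dup_pos <- which(r$feature_index %in% c(2L, 4L))
  expect_equal(diff(dup_pos), 1L)
  expect_equal(r$feature_index[dup_pos], c(2L, 4L))
  # joint row permutation leaves the ranking unchanged
  p <- sample(n)
  expect_equal(rank_features(X[p, ], y[p]), r)
  expect_error(rank_features(X, rep(TRUE, n)), "both classes")
})

test_that("augment_with_fscore appends exactly the top-k candidates", {
  set.seed(5)
  n <- 40
  y <- rep(c(TRUE, FALSE), each = n / 2)
  pssm_X <- matrix(runif(n * 340), n, 340)
  cand <- matrix(rnorm(n * 50), n, 50)
  out <- augment_with_fscore(pssm_X, cand, y, k = 30)
  expect_equal(ncol(out), 370L)
  top <- rank_features(cand, y)$feature_index[1:30]
  expect_equal(unname(out[, 341:370]), unname(cand[, top]))
  expect_identical(augment_with_fscore(pssm_X, cand, y, k = 0), pssm_X)
  expect_error(augment_with_fscore(pssm_X, cand, y, k = 51), "exceeds")
  expect_error(augment_with_fscore(pssm_X[-1, ], cand, y), "disagree")
})

test_that("pairs_in_window collects ordered contiguous pairs, skipping pads", {
  expect_setequal(pairs_in_window("GAG"), c("GA", "AG"))
  expect_equal(pairs_in_window("-AC"), "AC")
  expect_equal(pairs_in_window("---"), character())
  expect_equal(pairs_in_window("AXC"), character())   # X never forms a pair
  expect_setequal(pairs_in_window("GAGA"), c("GA", "AG"))  # presence, not count
  # optional gap: pairs (i, i+1+gap)
  expect_setequal(pairs_in_window("GACD", gap = 1L), c("GC", "AD"))
})

test_that("saap_pvalue equals the printed hypergeometric point mass", {
  # enumeration oracle: all C(10,3) subsets, count those with exactly 2
  # of the 4 positives
  subsets <- utils::combn(10, 3)
  frac <- mean(colSums(subsets <= 4) == 2)
  expect_equal(frac, 0.3)
  expect_equal(saap_pvalue(10, 4, 3, 2), 0.3)
  expect_equal(saap_pvalue(8, 8, 5, 5), 1)        # all-positive degenerate
  # distribution normalisation over the support
  set.seed(9)
  for (rep in 1:25) {
    N <- sample(2:60, 1); M <- sample(0:N, 1); n <- sample(0:N, 1)
    xs <- max(0, n - (N - M)):min(n, M)
    expect_equal(sum(vapply(xs, function(x) saap_pvalue(N, M, n, x), 0)), 1)
  }
  expect_error(saap_pvalue(10, 11, 3, 2), "invalid")
  expect_error(saap_pvalue(10, 4, 3, 4), "invalid")
  # upper-tail variant dominates the point mass
  expect_gte(saap_pvalue(20, 10, 8, 6, tail = TRUE),
             saap_pvalue(20, 10, 8, 6))
})

test_that("discover_saaps finds planted pairs and orders them deterministically", {
  set.seed(33)
  # balanced toy set: plant 'WC' in every positive window, never in negatives
  rand_win <- function() paste(sample(setdiff(AMINO_ACIDS, c("W", "C")), 9,
                                      TRUE), collapse = "")
  pos <- vapply(1:30, function(i) {
    s <- rand_win(); substr(s, 4, 5) <- "WC"; s
  }, "")
  neg <- vapply(1:30, function(i) rand_win(), "")
  w <- manual_windows(c(pos, neg), label = rep(c(TRUE, FALSE), each = 30))
  saaps <- discover_saaps(w, alpha = 0.13, max_k = 38)
  expect_equal(saaps$pair[1], "WC")
  expect_equal(saaps$x[1], 30L)
  expect_equal(saaps$n[1], 30L)
  # brute-force p-values over all 400 ordered pairs agree
  plist <- pairs_in_window(w$residues)
  for (i in seq_len(nrow(saaps))) {
    n_i <- sum(vapply(plist, function(p) saaps$pair[i] %in% p, TRUE))
    x_i <- sum(vapply(plist[w$label], function(p) saaps$pair[i] %in% p, TRUE))
    expect_equal(saaps$n[i], n_i)
    expect_equal(saaps$x[i], x_i)
    expect_equal(saaps$p_value[i], saap_pvalue(60, 30, n_i, x_i))
  }
  expect_equal(saaps$rank, seq_len(nrow(saaps)))
  expect_true(!is.unsorted(saaps$p_value))
  # enriched-in-positives filter: x/n must exceed M/N for every kept pair
  expect_true(all(saaps$x / saaps$n > saaps$M / saaps$N))
  expect_equal(nrow(discover_saaps(w, alpha = 0)), 0L)   # strict inequality
  expect_identical(discover_saaps(w), discover_saaps(w)) # deterministic
  expect_error(discover_saaps(manual_windows("AAA", TRUE)), "both classes")
})

test_that("label shuffling kills significance at stringent alpha", {
  # permutation oracle: with labels detached from content, practically no
  # pair reaches p < 0.001 on 200 windows
  set.seed(55)
  hits <- 0L
  for (rep in 1:5) {
    wins <- vapply(1:200, function(i)
      paste(sample(AMINO_ACIDS, 9, TRUE), collapse = ""), "")
    lab <- sample(rep(c(TRUE, FALSE), each = 100))
    hits <- hits + nrow(discover_saaps(manual_windows(wins, lab),
                                       alpha = 0.001, max_k = 400))
  }
  expect_lt(hits / 5, 1)
})

test_that("SAAP indicator features line up with pattern ranks", {
  w <- manual_windows(c("GACWF", "QQQQQ", "-WCGA"),
                      label = c(TRUE, FALSE, TRUE))
  pats <- data.frame(pair = c("WC", "GA"), x = c(2, 2), n = c(2, 2),
                     M = 2, N = 3, p_value = c(0.01, 0.02), rank = 1:2)
  X <- encode_saap_features(w, pats)
  expect_equal(dim(X), c(3L, 2L))
  expect_equal(X[, 1], c(0, 0, 1))   # WC occurs only in window 3
  expect_equal(X[, 2], c(1, 0, 1))
  expect_equal(unname(X[2, ]), c(0, 0))
})
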