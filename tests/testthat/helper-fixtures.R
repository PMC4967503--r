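# Shared in-code fixtures for the test suite.

# small deterministic dataset with planted signal
toy_dataset <- function(n_proteins = 4L, seed = 11L, ...) {
  generate_dataset(synthetic_spec(n_proteins = n_proteins,
                                  length_range = c(60L, 80L),
                                  site_rate = 0.05, seed = seed, ...))
}

# a window data frame built by hand from explicit strings
manual_windows <- function(residues, label = rep(FALSE, length(residues)),
                           accession = "T1") {
  data.frame(accession = accession,
             center = seq_along(residues),
             residues = residues, label = label,
             stringsAsFactors = FALSE)
}

# published worked-example confusion matrices with their printed metrics
# (percentages / MCC exactly as reported; `digits` = printed decimals).
# Groups: "ws" = window-size comparison (5-fold and independent-set blocks),
# "features" = independent-set feature-set comparison, "lopo" =
# per-protein leave-one-out rows, "fadpred" = the external baseline row
# on a newly discovered protein.
published_rows <- function() {
  rows <- rbind(
    data.frame(group = "ws5fold", id = c("WS13", "WS15", "WS17", "WS19"),
               TP = c(139, 139, 139, 138), FP = c(973, 990, 966, 1004),
               TN = c(3909, 3893, 3917, 3879), FN = c(33, 33, 33, 35),
               sens = c(80.8, 80.8, 80.8, 79.8),
               spec = c(80.1, 79.7, 80.2, 79.4),
               acc = c(80.1, 79.8, 80.2, 79.5),
               mcc = c(0.27, 0.26, 0.27, 0.26)),
    data.frame(group = "wsindep", id = c("WS13", "WS15", "WS17", "WS19"),
               TP = c(50, 50, 51, 51), FP = c(1444, 1223, 1169, 1225),
               TN = c(1586, 1807, 1861, 1805), FN = c(13, 13, 12, 12),
               sens = c(79.4, 79.4, 81, 81),
               spec = c(52.3, 59.6, 61.4, 59.6),
               acc = c(52.9, 60, 61.8, 60),
               mcc = c(0.09, 0.11, 0.12, 0.12)),
    data.frame(group = "features",
               id = c("BINARY", "BLOSUM62", "PAM250", "PSSM",
                      "PSSM+F-score", "PSSM+SAAPs"),
               TP = c(45, 41, 42, 51, 51, 54),
               FP = c(972, 977, 996, 1169, 1142, 1074),
               TN = c(2058, 2053, 2032, 1861, 1888, 1955),
               FN = c(18, 22, 21, 12, 12, 9),
               sens = c(71.43, 65.08, 66.67, 80.95, 80.95, 85.71),
               spec = c(67.92, 67.76, 67.11, 61.42, 62.31, 64.54),
               acc = c(67.99, 67.7, 67.1, 61.82, 62.69, 64.97),
               mcc = c(0.12, 0.1, 0.1, 0.12, 0.13, 0.15)),
    data.frame(group = "lopo",
               id = c("Q9YHT1", "P00455", "Q03103", "Q96HE7", "A3KEZ1",
                      "P55931"),
               TP = c(17, 9, 6, 6, 6, 6), FP = c(223, 111, 1, 68, 5, 0),
               TN = c(417, 247, 557, 394, 400, 612),
               FN = c(9, 3, 0, 1, 0, 0),
               sens = c(65.38, 75, 100, 85.71, 100, 100),
               spec = c(65.16, 68.99, 99.82, 85.28, 98.77, 100),
               acc = c(65.17, 69.19, 99.82, 85.29, 98.78, 100),
               mcc = c(0.12, 0.17, 0.92, 0.24, 0.73, 1)),
    data.frame(group = "fadpred", id = "Q96HE7",
               TP = 7, FP = 282, TN = 179, FN = 0,
               sens = 100, spec = 38.83, acc = 39.74, mcc = 0.1))
  rows
}

# tolerance implied by a printed value: half a unit in its last place
printed_tol <- function(x) {
  dec <- vapply(as.character(x), function(s) {
    dot <- regexpr(".", s, fixed = TRUE)
    if (dot < 0) 0L else nchar(s) - dot
  }, 0L)
  0.5 * 10^(-dec) + 1e-9
}
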