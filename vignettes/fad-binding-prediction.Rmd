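---
title: "Predicting FAD-binding residues from PSSM profiles and significant amino acid pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting FAD-binding residues from PSSM profiles and significant amino acid pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadsite)
```

## The problem

Flavin adenine dinucleotide (FAD) carries electrons through the
respiratory chain: it is the redox cofactor of succinate dehydrogenase
(Complex II) and of many other flavoproteins. Knowing *which residues* of
a flavoprotein contact FAD helps interpret mutations, annotate newly
sequenced electron transport proteins, and prioritise wet-lab work. This
package treats the task as residue-level binary classification: every
residue of a query protein is labelled *binding* or *non-binding*.

Each residue is represented by a sequence window of width $w$ (default
17) centred on it, so a protein of length $L$ yields $L$ overlapping
windows. Windows that run past a terminus are padded with a dedicated
symbol, and padded positions contribute all-zero feature blocks — zero
marks "no information", which is deliberately distinct from the value
$\sigma(0) = 0.5$ that a real but uninformative profile cell would
produce. The published description of the method is silent on terminus
handling; zero-padding is this package's choice and is flagged here.

## Feature encodings

Four base encodings map a window to a fixed-length vector of width
$20w$ (340 at $w = 17$):

* **binary** — one-hot: each non-pad, non-`X` position sets a single 1 in
  its 20-slot block;
* **pam250** / **blosum62** — each position contributes the 20-entry
  substitution row of its residue from the NCBI-standard integer tables
  (shipped via Biostrings; they are not re-derived from mutation
  probabilities);
* **pssm** — each position contributes the element-wise logistic sigmoid
  $\sigma(x) = 1/(1+e^{-x})$ of its 20 position-specific scoring matrix
  (PSSM) log-odds, squashing integer scores into $(0,1)$.

`X` (unknown residue) gives a zero block in the binary and substitution
encodings; in the PSSM encoding the profile row is used as-is, since the
profile carries information even where the sequence letter does not.

Two augmented schemes extend the PSSM vector:

* **pssm+fscore** appends the $k = 30$ top-ranked candidate features by
  F-score,
  $$F(i) = \frac{(\bar x_i^{(+)} - \bar x_i)^2 + (\bar x_i^{(-)} - \bar x_i)^2}
  {\frac{1}{n_+-1}\sum_k (x_{k,i}^{(+)} - \bar x_i^{(+)})^2 +
   \frac{1}{n_--1}\sum_k (x_{k,i}^{(-)} - \bar x_i^{(-)})^2},$$
  giving 370 features at the defaults. The published description does not
  state which candidate pool the 30 features are drawn from; this package
  uses the one-hot encoding of the same windows as the default pool,
  configurable by the caller, and documents that as an interpretation.
  (The second denominator term is printed in the source literature with a
  positive-class mean; that is treated as a typographical slip for the
  negative-class mean, which restores the standard between/within
  variance ratio.)
* **pssm+saap** appends one indicator per *significant amino acid pair*
  (SAAP), giving $340 + 38 = 378$ features when the full 38-pattern list
  is found.

## SAAP enrichment

A SAAP is an ordered contiguous dipeptide over-represented in windows
around binding sites. For each of the 400 ordered pairs we count windows
containing it ($n$ overall, $x$ among the $M$ positive windows out of
$N$ total) and score it with the hypergeometric point probability
$$p = \binom{M}{x}\binom{N-M}{n-x}\Big/\binom{N}{n},$$
computed in log space. Pairs with $p < 0.13$ (strict, no multiple-testing
correction — the published threshold is used as printed) that are also
over-represented in positives ($x/n > M/N$) are kept, ranked by ascending
$p$ with lexicographic tie-breaks, and truncated to 38.

Three interpretation choices are worth making explicit:

* "Sequences" in the counting formula is read as *windows*, not whole
  proteins: with only six positive proteins, protein-level counting
  cannot produce 38 patterns below 0.13 under any reading we could
  construct.
* The printed statistic is the point mass, not a tail sum; it is
  implemented exactly as printed, with an upper-tail variant available
  behind `tail = TRUE` for users who prefer a conventional enrichment
  p-value.
* Presence is per window (a set), matching a statistic that counts
  "sequences including" a pair; pair multiplicity within a window is
  ignored. Gapped pairs are available behind `gap > 0` (default 0) for
  exploration.

## The classifier

The radial basis function network uses every training vector as a kernel
centre with a constant Gaussian bandwidth $\sigma = 5$:
$$g_j(x) = \sum_{i=1}^{k} w_{ji}\, \varphi(\lVert x - \mu_i \rVert; \sigma),
\qquad \varphi(d; \sigma) = e^{-d^2 / 2\sigma^2}.$$
The source literature does not name the kernel's functional form or the
solver; the Gaussian is the canonical choice of the RBFN software it
cites, and the output weights here solve the ridge-regularised
least-squares problem $(\Phi^\top\Phi + \lambda I)W = \Phi^\top T$ with
one-hot 0/1 targets on two output nodes (non-binding, binding) and
$\lambda = 10^{-8}$ by default. At $\lambda = 0$ the square system
$\Phi W = T$ is solved directly and interpolates the targets exactly for
distinct points — the property the unit tests check against a dense
solver. Prediction takes the larger output node, with exact ties resolved
to non-binding; the score $g_{\text{bind}} - g_{\text{non}}$ orders
residues for ROC analysis. There is no class rebalancing or threshold
tuning (none is described for the original method); a `threshold`
argument exists for users.

The design matrix is $n \times n$, so training is $O(n^2)$ in time and
memory; the trainer accumulates the normal equations over row blocks
(2048 rows by default) so the full kernel matrix and its cross-product
never coexist.

## Evaluation harness

`confusion_counts()` and the metric functions implement sensitivity,
specificity and accuracy (as percentages) and Matthews correlation
coefficient, with two conventions stated explicitly: a zero denominator
yields an `NA` marker (never a silent 0), except MCC where a zero factor
under the root gives 0, the standard degenerate-margin convention.
Metrics are displayed at two decimals, matching how such results are
conventionally reported; comparisons in the test-suite use the printed
precision of each reference value.

`roc_auc()` sweeps thresholds at unique scores and integrates
trapezoidally; with rank-averaged tie handling this equals the
Mann–Whitney statistic, which the tests verify against an $O(n^2)$
concordant-pair oracle. `kfold_cv()` uses stratified *window-level* folds
from a seeded shuffle and pools held-out predictions before computing
metrics. Whether cross-validation folds should respect protein boundaries
is not specified in the source description; window-level folds are the
default interpretation and `leave_one_protein_out()` provides the
protein-level protocol, in which feature selection (SAAP discovery,
F-score ranking) is refit inside every training split to avoid leakage.
The per-protein "average" is the unweighted arithmetic mean across
proteins.

Two inconsistencies in the published tables are documented rather than
resolved: the overall counts of binding/non-binding residues are stated
differently in the data-set table and the accompanying text
(940/26475 vs 863/24408), and the printed per-protein averages of the
leave-one-out table (e.g. 97.37 % sensitivity) do not equal the
arithmetic mean of its printed rows under any parsing we attempted. The
harness always reports means it computed itself. One external-baseline
row is also arithmetically inconsistent (its printed accuracy cannot be
produced by any confusion matrix consistent with its other columns) and
is excluded from the worked-example fixtures.

## The synthetic benchmark

Because the original training data (UniProt-derived sequences and
PSSMs computed against a historical non-redundant database) cannot be
reconstructed, the package ships a seeded generator so the entire
pipeline is testable end to end. It emulates three signals:

* **composition bias** — residues inside positive windows are redrawn
  from {G, S, A, T} with probability `motif_bias` (default 0.5),
  mirroring the glycine-rich composition observed at real FAD contact
  sites;
* **planted dipeptides** — each planted pair (defaults `GS`, `AT`) is
  inserted into a site's window with probability 0.8 and into a random
  5 % of non-site windows, giving the SAAP screen a known recovery
  target;
* **profile conservation** — PSSM rows within `signal_radius` (default
  2) of a site have the true-residue column raised by `pssm_signal`
  (default 4) and the other 19 columns lowered by it. This is the shape
  real conserved PSSM rows take (the observed residue scores high, the
  rest are depressed). The footprint is kept deliberately narrow: if the
  conservation mark were smeared across the whole 17-residue window,
  windows centred one residue away from a site would be statistically
  indistinguishable from the site window itself, capping attainable
  discrimination for *any* classifier — an instructive property of
  residue-level labels with window features, but the wrong regime for a
  learnability benchmark.

Background residues are uniform over the 20 amino acids so the enrichment
arithmetic stays transparent (natural frequencies behind
`background = "natural"`); PSSM noise is uniform integer scores in
$[-3, 3]$, the scale of real log-odds. A single global seed feeds
independent per-protein streams, so extending a dataset never perturbs
existing proteins. Other defaults: 3 % of residues are sites (the
independent-set prevalence of the real data is about 2 %), sequence
lengths 120–250.

What passing the synthetic tests does **not** show: the generator has no
evolutionary correlation structure between neighbouring profile rows, no
realistic domain architecture, and its planted signal is cleaner than
biological conservation. Synthetic results demonstrate that the
statistics and the pipeline are implemented correctly and can recover
known signal — not that the model attains any particular accuracy on
real flavoproteins.

## Problem sizes and numerical choices

The test-suite and the acceptance script use about 2 000 windows
(10 proteins of ~200 residues) for pipeline-level runs and 5-fold
cross-validation — large enough for stable AUC estimates with ~60
positive windows, small enough that a full run of suite plus script
completes in well under a minute. Determinism is enforced everywhere: a
fixed seed reproduces byte-identical generated files and identical
cross-validation reports. The sigmoid is computed branch-wise to avoid
overflow at $|x| > 700$; hypergeometric probabilities go through
`dhyper` in log space; kernel distances clamp tiny negative values
arising from floating-point cancellation.

## Known limitations

* Exact reproduction of the published confusion matrices from raw data
  is out of reach (it requires the original PSSMs and the internals of
  the original RBFN software); the package instead reproduces every
  metric those tables print *from* their printed counts, and proves the
  pipeline's statistical behaviour on synthetic data.
* Training with all centres is quadratic in windows; tens of thousands
  of windows are feasible, hundreds of thousands are not.
* The SAAP screen tests 400 hypotheses with no multiplicity correction,
  faithfully to the published procedure; users applying it to new data
  may prefer `tail = TRUE` and their own correction.
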