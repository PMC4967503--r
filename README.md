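# fadsite

Residue-level prediction of FAD-binding sites in proteins, with an
emphasis on electron transport chain flavoproteins.

Flavin adenine dinucleotide (FAD) is the electron carrier of succinate
dehydrogenase (Complex II) and many other respiratory flavoproteins.
Identifying which residues of a protein contact FAD from sequence alone
helps annotate newly discovered electron transport proteins. `fadsite`
implements a classical machine-learning approach to this task:

* every residue is represented by a **sequence window** of width *w*
  (default 17) encoded as one-hot, PAM250, BLOSUM62, or
  sigmoid-normalised **PSSM** features (17 × 20 = 340 values);
* features are optionally augmented with the 30 top **F-score** columns
  — F(i) = ((x̄ᵢ⁺ − x̄ᵢ)² + (x̄ᵢ⁻ − x̄ᵢ)²) / (s²₊ + s²₋) — or with
  indicators for **significant amino acid pairs (SAAPs)**: ordered
  dipeptides enriched near binding sites under the hypergeometric
  statistic p = C(M,x)·C(N−M,n−x)/C(N,n), kept at p < 0.13 and capped
  at 38 patterns (340 + 38 = 378 features);
* classification uses a **radial basis function network**
  gⱼ(x) = Σᵢ wⱼᵢ·exp(−‖x−μᵢ‖²/2σ²) with all training windows as
  centres, σ = 5, and least-squares output weights;
* the evaluation harness provides sensitivity/specificity/accuracy/MCC,
  ROC/AUC with Mann–Whitney tie handling, stratified 5-fold
  cross-validation, leave-one-protein-out, and an amino-acid composition
  analysis.

A seeded synthetic-data generator with planted signal (composition bias,
planted dipeptides, profile conservation) makes the entire pipeline
testable without any downloads. See the methods vignette
(`vignettes/fad-binding-prediction.Rmd`) for the model, its assumptions
and the design decisions.

## Worked example

Train on one synthetic protein set, predict an independent one:

```r
library(fadsite)
train <- generate_dataset(synthetic_spec(n_proteins = 8, seed = 101))
test  <- generate_dataset(synthetic_spec(n_proteins = 2, seed = 202))

res <- train_and_predict(train, test, fad_config())   # PSSM+SAAP, w=17
res$report
#> Sens 69.23%  Spec 100%  Acc 98.79%  MCC 0.83  AUC 1.0000

head(res$predictions[res$predictions$label == "binding", ], 4)
#>     accession position residue      score   label
#> 11     SYN001       11       T 0.01333576 binding
#> 93     SYN001       93       A 0.11915142 binding
#> 105    SYN001      105       S 0.23220530 binding
#> 131    SYN001      131       S 0.26739158 binding
```

The report reads: 69 % of the held-out binding residues were recovered
(sensitivity), every non-binding residue was called correctly
(specificity 100 %), and the score ordering separates the classes
perfectly (AUC 1.0) — the argmax decision rule is conservative under
the ~3 % class prevalence, which is exactly how the method behaves on
real data. The SAAP screen on the training windows recovers the planted
and composition-driven dipeptides:

```r
head(discover_saaps(dataset_windows(train, 17)), 3)
#>   pair  x   n  M    N      p_value rank
#> 1   TG 24 332 46 1286 6.416314e-05    1
#> 2   SG 27 407 46 1286 7.480696e-05    2
#> 3   GS 41 832 46 1286 1.074457e-04    3
```

A command-line interface covers the same pipeline
(`exec/fadsite {simulate,encode,discover-saaps,train,predict,evaluate}`).

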