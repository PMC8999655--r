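# ybrca1

Validation and majority-voting integration of yeast-based functional assays
for BRCA1 missense variants.

## The problem

Most BRCA1 missense variants found in hereditary breast/ovarian cancer
screening are variants of uncertain significance (VUS): too rare for
co-segregation or case–control genetics to classify. Yeast-based functional
assays offer a readout of BRCA1 activity that does not depend on variant
frequency: expressing a pathogenic BRCA1 variant in *Saccharomyces
cerevisiae* raises the frequency of intra- and inter-chromosomal homologous
recombination (HR) and of gene reversion (GR), and relieves the growth
inhibition that wild-type BRCA1 imposes (the small colony phenotype, SCP).
Each assay is informative but imperfect, and the variants each assay gets
wrong differ — which is exactly the situation where combining classifiers
helps.

This package is for analysts validating such assay panels and applying them
to VUS. It implements:

- **per-assay calibration** — replicate readouts are summarized per variant
  as medians (fold of the wild-type control median for HR/GR; raw
  cells-per-colony for SCP), a ROC curve is swept over the medians of a
  benchmark panel of known pathogenic and benign variants, and the best
  cut-off `c*` maximizes the Youden index
  `J(c) = sensitivity(c) + specificity(c) − 1`
  over midpoints between consecutive distinct medians;
- **per-variant scoring** — a functional-impact call
  `FI = pathogenic ⇔ median > c*`, plus a bootstrap prediction score
  `PS = P̂(median* > c*)` from B = 4000 resamples of the replicates,
  clamped to [1/B, 1 − 1/B];
- **majority-voting integration** — with `PV` pathogenic calls among
  `k` assays, the pathogenic prediction score is `PPS = PV/k` and the final
  label is pathogenic iff `PPS > 0.5` (a 2-of-4 tie is benign);
- **combined performance** — accuracy with exact (Clopper–Pearson) binomial
  95% CI, sensitivity, specificity, Matthews correlation coefficient and
  Cohen's kappa, plus the AUROC of PPS as a ranking score;
- **a synthetic-data generator** — log-normal replicate noise around
  per-assay control locations with median fold-shifts for pathogenic
  variants, including a planted panel that reproduces the benchmark's exact
  per-assay confusion structure, so the whole pipeline is testable without
  wet-lab data.

## Worked example

The analysis is organized as numbered drivers under `analysis/`, each a thin
script over the package functions:

```sh
Rscript analysis/01_build_panel.R        # synthetic 56-variant panel -> results/panel.tsv
Rscript analysis/02_validate_assays.R    # per-assay calibration
Rscript analysis/03_classify_variants.R  # scoring + majority-vote integration
Rscript analysis/04_parameter_recovery.R # 50-seed recovery study
```

`02_validate_assays.R` prints the per-assay validation table:

```
     assay sensitivity specificity accuracy auroc youden_index best_cutoff
1 intra_hr       0.957       0.783    0.870 0.749        0.739       1.926
2 inter_hr       0.870       0.913    0.891 0.794        0.783       1.973
3       gr       0.913       0.870    0.891 0.794        0.783       1.965
4      scp       1.000       0.913    0.957 0.913        0.913      23.801
```

Each row is one assay calibrated on the 46 classified variants: SCP is the
strongest single assay (sensitivity 1.0, accuracy 0.957); the HR and GR
assays each misclassify a handful of variants — and different ones.
`03_classify_variants.R` then integrates the four calls per variant:

```
Integrated accuracy: 0.9565 (95% CI 0.8516-0.9947)
Sensitivity 0.9565, specificity 0.9565, MCC 0.9130, kappa 0.9130
Concordant in all four assays: 35 of 46
Misclassified by the integrated vote: p.I1275V, p.R71K
VUS calls: 6 pathogenic, 4 benign
```

Only 35/46 classified variants are called correctly by *every* assay, but
the majority vote fixes all discordances except the two variants that are
wrong in three or more assays (p.R71K, a pathogenic variant that only SCP
detects, and p.I1275V, a benign variant elevated in all four readouts):
44/46 correct, better than the best single assay. Of the ten VUS, six reach
three or four pathogenic votes (PPS ≥ 0.75) and are called pathogenic; the
four with at most two votes (PPS ≤ 0.5) are called benign.

The same phases are available directly as functions:

```r
library(ybrca1)
panel <- generate_benchmark_panel(seed = 1)
val   <- run_validate(panel)                      # cut-offs + ROC per assay
cls   <- run_classify(panel, val$calibrations,    # PS/FI per assay, PV/PPS/label
                      B = 4000, seed = 1)
```

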