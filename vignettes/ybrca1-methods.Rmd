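---
title: "Calibrating and integrating yeast-based BRCA1 functional assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating and integrating yeast-based BRCA1 functional assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ybrca1)
```

## The measurement model

Four yeast readouts report on BRCA1 function, each in its own units:
intra-chromosomal homologous recombination (HIS3 colonies per 10^4 plated
cells), inter-chromosomal homologous recombination (ADE2 colonies per 10^5
cells), gene reversion (ILV1 revertant colonies per 10^6 cells), and the
small colony phenotype (cells per colony). In all four, loss of BRCA1
function pushes the readout *up*: pathogenic variants raise recombination
and reversion frequencies and restore growth under wild-type-BRCA1
suppression. The pipeline therefore fixes the orientation "higher readout
implies pathogenic" everywhere and never auto-detects it.

Every variant is measured in at least five independent experiments
(replicates), alongside wild-type BRCA1 controls grown under the same
conditions. All downstream statistics are median-based: the per-variant
summary is the replicate median with its interquartile range (quartiles by
linear interpolation between order statistics, `stats::quantile` type 7 —
the choice affects only the exported boxes, never a call).

**Normalization.** The three frequency assays are summarized as fold of the
control median, which makes panels comparable across batches and puts the
cut-off on a unitless scale; SCP stays in raw cells-per-colony. Both modes
are exposed per assay (`default_normalization()`), because nothing in the
calibration mathematics depends on the choice — only the scale of the
cut-off does. A control median of zero makes fold normalization degenerate
and is a hard error rather than a silent fallback.

## Per-assay calibration

Calibration uses only variants with a known prior label (pathogenic or
benign); VUS never enter. The ROC curve is swept over the distinct
per-variant medians with the strict rule "median > threshold ⇒ pathogenic",
so tied medians cross the curve atomically; the AUROC is the trapezoidal
area, which equals the Mann–Whitney probability that a random pathogenic
variant outranks a random benign one, with half credit for ties. The test
suite holds this equality against a brute-force pairwise oracle on hundreds
of random instances.

The best cut-off maximizes the Youden index J = sensitivity + specificity −
1 over candidate thresholds placed at midpoints between consecutive
distinct sorted medians — published cut-offs for assays of this kind fall
between variant values, not on them, and midpoints avoid the instability of
thresholding exactly on an observed value. Ties in J are broken toward the
higher-specificity candidate, then toward the smaller threshold; a call
exactly at the cut-off is benign. Single-class input and all-identical
medians are explicit errors (`ybrca1_undefined_roc_error`), not NaNs.

## Per-variant scoring

Each variant × assay gets two quantities:

- **FI (functional impact)** — the binary call, median versus cut-off. FI
  drives the votes.
- **PS (prediction score)** — the bootstrap probability that the median
  exceeds the cut-off: replicates are resampled with replacement B times
  and the exceedance fraction is clamped to [1/B, 1 − 1/B]. The default
  B = 4000 gives scores on a 1/4000 grid with extremes 0.00025 and
  0.99975, matching the granularity such scores are reported at. One seed
  governs all bootstrap draws of a run and is written to the run log.

PS is deliberately *not* used for voting by default: a variant whose median
sits just above the cut-off can have FI = pathogenic with PS < 0.5, and the
published VUS integration counts exactly such calls as pathogenic votes.
The PS > 0.5 voting rule is nevertheless available (`vote_mode = "ps"`) for
sensitivity analyses. For small replicate counts the bootstrap distribution
of the median is exactly enumerable (all n^n resamples; for odd n it
reduces to a binomial tail in the fraction of replicates above the
cut-off), and the tests pin the Monte-Carlo scores to those exact values.
Note a subtlety of the strict exceedance rule: replicates placed
symmetrically around the cut-off do *not* score 0.5, because resamples
whose median lands exactly on the cut-off count as non-exceeding.

## Majority-voting integration

With PV pathogenic votes among k equal-weight assays, PPS = PV/k and the
final label is pathogenic iff PPS > 0.5. The tie (PV = k/2) is benign: the
integration is asymmetric by design, requiring a strict majority of
pathogenic evidence. k is configurable (≥ 2); the validated instance is
k = 4. Combined performance is reported as accuracy with an exact
Clopper–Pearson 95% interval (`stats::binom.test`), sensitivity,
specificity, the Matthews correlation coefficient, Cohen's kappa, and the
AUROC of PPS as a ranking score. With four assays PPS takes only the five
values {0, 0.25, 0.5, 0.75, 1}, so this AUROC is a coarse summary; it is
reported for completeness, not optimized for.

On the benchmark call matrix — 23 pathogenic and 23 benign variants, with
each assay's observed false-positive and false-negative lists
(`benchmark_assay_errors()`) — the integration yields 44/46 correct
(accuracy 0.9565, CI 0.8516–0.9947), sensitivity = specificity = 0.9565,
and MCC = kappa = 0.913. The MCC/kappa values follow directly from the
TP = TN = 22, FP = FN = 1 confusion matrix; they are what the defining
formulas give, computed at full precision and rounded only for display.

## The synthetic generator

Replicate readouts are log-normal around `control_location × fold`:
colony-count-derived frequencies are strictly positive and right-skewed,
and parameterizing the noise by the natural-scale coefficient of variation
(CV) keeps the spread interpretable. The fold shift applies to the
*median* of the distribution, matching the median-based summaries
downstream. SCP is generated by the same machinery in cells-per-colony
units (pathogenic ⇒ larger colonies). Controls are pooled per assay — the
generator attaches one control vector to every measurement of an assay —
while the data model allows per-measurement controls, since batch-matched
controls are the more general design.

Defaults define the study conditions: 23 + 23 + 10 variants, 5 replicates,
pathogenic fold 3, benign fold 1, CV 0.3, and per-assay control locations
of 2.5 (intra-HR), 2.0 (inter-HR), 1.5 (GR) and 12 (SCP) in native units.
The fold and CV are modeling choices — published panels of this kind report
roughly threefold median elevations against replicate scatter of tens of
percent, and no dispersion estimates are available to fit — as are the
control locations, which set scale only and cancel under fold
normalization. VUS behave pathogenic in each assay independently with
probability 0.5 by default; the drawn truth is recorded in a `vus_truth`
attribute so recovery studies can score VUS calls.

**The planted benchmark panel.** `generate_benchmark_panel()` plants each
classified variant on the side of the cut-off that the benchmark
discordance lists dictate, and each VUS according to its published
per-assay labels. Discordant variants carry an extra fold margin (FP benign
at fold 3 × 1.3, FN pathogenic at fold 1/1.3) placing them strictly
interior to the "wrong" cluster. The margin matters: without it, a planted
false positive that happens to land at the boundary of the elevated
cluster can be traded against a true positive at equal Youden index, and
the higher-specificity tie-break would then pull the cut-off inside the
cluster, changing the confusion lists. With the margin and tight noise
(CV 0.05) the between-cluster midpoint is the strict optimum, so the
planted lists are recovered exactly at any seed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: plating/colony Poisson sampling, survival
fractions, induction kinetics, batch effects between experiment days,
inter-assay correlation of a variant's residual noise, and any relation
between protein expression level and readout. Synthetic recovery results
demonstrate the pipeline's correctness, not the assays' biological
validity.

## Numerical and design choices

- Rounding to 3 decimals happens only in written reports; all comparisons
  and stored values keep full precision.
- Classification is a two-phase design: `run_validate()` fits cut-offs on
  a classified panel and `run_classify()` requires that calibration
  artifact, so cut-offs are never silently refit on VUS-containing data.
- Variant identifiers are opaque strings in HGVS protein style; the
  pipeline never parses residue positions.
- The interchange format is long/tidy with an `is_control` flag, one row
  per replicate; the reader is row-order agnostic and the writer's output
  round-trips exactly.
- Problem sizes in the test suite and acceptance script: 200 random ROC
  instances (n ≤ 50) for the oracle equalities, exact bootstrap
  enumeration up to n = 5 plus the odd-n closed form at n = 7, and 50
  generator seeds for the recovery study — sizes at which every oracle is
  exact or its Monte-Carlo error is far below the asserted tolerances.

## Known limitations

- Per-assay AUROC and cut-off magnitudes on the planted panel are
  generator artifacts (the margin places discordant variants at cluster
  edges, which *lowers* the ranking AUROC below what the confusion counts
  suggest); only the confusion structure, not those magnitudes, is
  reproduced.
- The bootstrap PS treats replicates as exchangeable; day/batch structure
  within replicates is not modeled.
- The benchmark's concordant classified variants are synthetic placeholder
  ids (`p.PATH*`, `p.BEN*`): their identities play no role in any
  computation, but reports on the planted panel should not be read as
  statements about real variants beyond the named discordant ones.
- With k = 4 assays the vote is coarse (five PPS levels); confidence in a
  final label is better judged from the per-assay PS values in the
  classification table than from PPS alone.
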