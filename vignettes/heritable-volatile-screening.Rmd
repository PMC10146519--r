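---
title: "Screening insect gland volatile profiles for heritable line variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening insect gland volatile profiles for heritable line variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandvolatiles)
```

## The problem

Isofemale lines — each founded from a single wild-mated female and kept in a
common laboratory environment — trap a sample of field genetic variation.
When replicate cages of a line, assayed across several generations, differ
consistently from other lines in some trait, that repeatability indicates
inherited variation. This package implements that screen for gas-chromatography
profiles of rectal-gland volatile extracts in tephritid fruit flies: peak-area
tables from GC-FID runs of male and female flies (virgin and mixed-sex
cohorts) across two dozen lines from several source localities, with a
long-domesticated line included as a reference.

The pipeline has five stages, each usable on its own:

1. **Table handling** — reading deposited-style CSVs, validation, and batch
   normalisation.
2. **Classification** — inclusion filtering and per-peak abundance, sex-bias
   and elution-range classification, with a ratio enrichment test.
3. **Kovats calibration** — a piecewise retention-time (Rt) to Kovats-index
   (KI) model for imputing indices for unidentified GC-FID peaks.
4. **Cross-platform matching** — pairing FID peaks (imputed KI) with GC-MS
   peaks (observed KI) by tolerance and adjacency, rated for sex/mating
   abundance compatibility.
5. **Statistics** — the per-peak line-variation screen (rank-normal
   transform, one-way F, FDR, marginal means, compact letters), Spearman
   correlation structure, and multivariate PERMANOVA / LDA locality
   analyses.

A synthetic-study generator with known ground truth makes every stage
testable without any external download.

## The statistical model

### Per-peak screen

Peak areas are non-negative, heavy-tailed and zero-inflated (zero encodes
"not detected"). Each retained peak is transformed by an *ordered-quantile*
(rank-normal) map: ranks of the training values (average ranks for ties,
zeros included as smallest-rank ties) are mapped to standard-normal
quantiles at plotting positions $p = (r - 0.5)/n$. Training scores then
have mean zero exactly (for distinct values) and variance near one. The
inverse map — monotone interpolation of the fitted (value, score) nodes,
clamped at the extremes — is used only for display back-transformation.

The line effect is tested by the one-way fixed-effects decomposition

$$F = \frac{\mathrm{SS}_{\text{between lines}}/(k-1)}
           {\mathrm{SS}_{\text{within lines}}/(n-k)},$$

where replicate cages within and across generations supply the residual.
Generation and cage deliberately stay in the residual: repeatability across
generations is the evidence of inheritance, so absorbing generation into
the model would remove part of the signal the design relies on (a
sensitivity option to include it is trivial to add via `lm` but is not the
default). p values are Benjamini–Hochberg adjusted **within each dataset**
(each sex/mating category is its own family, matching how results are
reported per dataset); marginal means, 95% confidence limits and
Tukey-adjusted pairwise contrasts (via `emmeans`) are computed for
FDR-significant peaks, and summarised by an insert-and-absorb compact
letter display: lines share a letter exactly when their contrast is not
significant.

### Classification rules

* **Inclusion**: a peak is analysed if detected in at least 50% of samples
  in at least one line × sex/mating-category cell (`>=`, configurable; one
  source describes the same rule as "> 50%", and we follow the methods
  wording).
* **Abundance**: share of the peak in the summed total area of its best
  category; ≥ 1% major, 0.1–0.99% intermediate, < 0.1% minor. Shares use
  summed areas over all samples of the category, not per-sample mean
  shares.
* **Sex bias**: detected in one sex only → *specific*; detected in both
  with more than a log10 difference in mean area → *selective* (a tie at
  exactly 10-fold classifies as no bias: the rule is strict). Means include
  zeros, which are true non-detections in this data model (configurable).
* **Elution ranges**: short/mid/long at Rt 4.60–10.39 / 10.40–13.59 /
  13.60–21 min, equivalently KI 840–1095 / 1096–1240 / 1241–2175.
* **Enrichment test**: observed category counts of significant peaks vs the
  proportions of all peaks tested, as a χ² goodness of fit with
  `df = k − 1`. A 2 × k contingency formulation (observed vs remaining) is
  also exposed; the two answer slightly different questions and give
  slightly different statistics, and for one published abundance-ratio
  comparison neither reproduces the printed value, so both are reported and
  neither is forced.

### Kovats calibration

On a temperature-programmed run the Rt–KI relation is linear early and
late and curved in between. The model interpolates linearly between
calibrator peaks for Rt ≤ 13.59 and Rt ≥ 17.37 min (defaults; both
configurable and best placed at actual calibrators) and fits a
least-squares polynomial, degree 3 by default, over the mid region using
the mid calibrators plus the innermost calibrator of each linear region.
Degree 3 is the lowest degree that reproduces the visible curvature;
boundary agreement is enforced softly (the polynomial must pass within 1 KI
unit of the boundary calibrators) and the whole map must be monotone,
checked on a fine grid — violations are errors, not silent repairs. Imputed
KIs are rounded to integers, as indices are conventionally printed.
Extrapolation beyond the calibrator span (± 1 min grace) is off by default.

### Cross-platform matching

A FID peak and an MS peak are paired when they are mutually nearest, no
more than 4 KI units apart, and each strictly closer to the other than to
any alternative on either side — an equidistant tie rejects the pair. The
strict mutual-nearest reading of "clearly more similar than the adjacent
peaks" is conservative and makes the pair set symmetric in the two
platforms (one-directional adjacency would not be). Accepted pairs are then
rated: **YY** when per-sample-type, per-sex detection states agree (with
"all samples" and "some samples" collapsed, and "not assayed" compatible
with anything); **Y** when the only disagreements are presences that are
partial (*some*) in a peak of at most minor abundance, or presences keeping
a greater-than-10-fold mean bias toward the sex in question; **N**
otherwise. The fold-bias *flag* uses ≥ 10 while the Y *rule* uses > 10 —
each follows its own defining sentence — and a fold bias is defined only
when both sexes have nonzero means: a sex-specific presence is a
presence/absence pattern, not a bias.

KI proximity cannot, even in principle, reject a platform-specific peak
that happens to fall within tolerance of an unrelated peak on the other
side; only the abundance-compatibility rating can. The matching
calibration therefore quantifies two things separately: recovery of truly
shared peaks with the correct partner, and the mis-assignment rate among
shared peaks (wrong neighbour). Platform-specific intruders are left to the
rating stage, which is exactly the role the harsh compatibility filter
plays in the original analysis.

### Multivariate analyses

Per elution range, Bray–Curtis dissimilarities (the standard choice for
non-negative abundance profiles with many zeros; Euclidean and a `log1p`
option are provided — the original metric is unstated) feed two
PERMANOVAs with sequential sums of squares and free row permutation:
**Analysis I**, differences across all lines; **Analysis II**, excluding
the domesticated line, locality of origin plus lines within localities
(line identities are unique to their locality, so the sequential line term
is the nested term). Permutation p values use the +1 correction and are
reproducible given a seed. Locality differences are visualised by linear
discriminant analysis on centred PCA scores, keeping fewer components than
the smallest locality's sample size; the package reports per-locality
centroids ± standard errors (within-group SD / √n) per axis and each
axis's share of the between-group variance.

## The synthetic study generator

`sim_config()` / `simulate_study()` emulate the design: 23 isofemale lines
over 7 localities plus one domesticated line (`DOM`), four sex/mating
categories, four screened generations with 1–4 replicate cages per
line × generation (sampled with weights favouring single cages, mimicking
the sparse replication of recently established lines), and ~150 peaks.

Areas are log-normal: `log10(area)` is the sum of a peak baseline
(N(3.2, 1)), a sex shift (half applied to each sex; a configurable
fraction of peaks is structurally sex-specific, two-thirds of them
male-specific), a line effect (on a configurable fraction of peaks, SD = 2
residual SDs by default; the domesticated line draws a positive effect
scaled by a multiplier, emulating higher abundances after domestication),
a line × generation jitter (SD 0.1), a per-batch log scale factor (SD
0.05; batches are the screened generations, so batch corrections are
"minor" as in the real data), and residual noise (SD 0.3 log10 units).
Values below the detection threshold (100 area units) are recorded as 0,
reproducing the presence/absence structure the classification rules need.

Peaks are placed near-regularly on the KI scale (20% jitter) and mapped to
Rt through the true piecewise calibration — real aligned peak lists are
dense in Rt late in the run but roughly even in KI, and upstream alignment
merges anything closer than its Rt tolerance, so purely random placement
would create unresolvable 1–2-KI neighbours that no aligned list contains.
The MS side re-observes a configurable fraction of peaks with Gaussian KI
noise (SD 1.5) plus platform-specific extras.

What the generator does *not* emulate: correlated line effects across
peaks (effects are drawn independently per peak, except that the
domesticated line is shifted on all affected peaks — so correlation
structure in real profiles is only partly mirrored), systematic
(non-Gaussian) imputation error shared by neighbouring peaks, co-eluting
compounds, and any compound-identity structure. Passing tests therefore
demonstrate the statistical machinery under a faithful *design*, not the
chemistry of real extracts.

## Numerical choices and degenerate inputs

* Batch normalisation rescales each batch to the grand mean of batch
  totals (the target is not stated in the original methods; the grand mean
  is symmetric in the batches and preserves overall scale). It is
  idempotent to 1e-9 and leaves the zero pattern untouched. A batch with
  zero total is an error.
* Missing CSV cells are read as 0 with a logged message; negative areas,
  duplicate sample ids and non-numeric peak headers are hard errors naming
  the offender.
* A constant peak cannot be rank-normalised and is skipped with a log
  message; a design without replication (residual df 0) is an error; a
  perfect fit (zero within-line mean square, detected at relative
  tolerance 1e-12) is flagged degenerate with `F = Inf` rather than tested.
* Spearman correlations with a constant vector are reported as missing, not
  dropped silently.
* The exact emmeans contrast adjustment behind the published letter
  displays is unstated; Tukey is the default here and `"none"`/`"BH"` are
  accepted. Whether the rank-normal map was fitted per peak per dataset or
  globally is likewise unstated; this package fits per peak per dataset.

## Problem sizes used in the tests

The test-suite simulations use 40–150 peaks, 4–24 lines and up to ~170
samples per table; the statistical calibrations run 1000 null F tests,
3 × 60-peak power screens at 5 replicates/line, 50 matching simulations at
the default density, and 500 null PERMANOVAs at 199 permutations. These
sizes give Monte-Carlo error comfortably inside the asserted bands while
keeping a full run in the order of a minute; all of them are the package's
own choices and can be scaled up freely by editing the scripts.

## Known limitations

* The one-way screen estimates no heritability; it only flags repeatable
  line differences. Mixed-model or h² extensions are out of scope.
* Published multivariate F tables for the real data are not reproducible
  here because the distance metric and pre-transformations behind them are
  unstated and part of the underlying raw data is deposited with an
  earlier companion study; the package instead guarantees the structural
  and statistical properties of its own implementations.
* Chromatogram processing (baseline subtraction, integration, retention
  alignment) is upstream and out of scope; inputs are assumed aligned.
  Alignment parameters can be recorded in configs for provenance only.
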