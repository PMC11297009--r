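---
title: "Spatial immune signatures from multiplex immunofluorescence: methods and design"
author: "spatialSIS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial immune signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialSIS)
```

# The scientific problem

Regulatory T cells (Tregs) shape anti-tumor immunity not only through their
abundance but through *where they sit* relative to tumor cells and other
T cells. In multiplex-immunofluorescence (mIF) tissue-microarray (TMA)
studies of operable non-small cell lung cancer, each patient contributes two
roughly 1 mm cores — one at the invasive margin (IM), one in the tumor
center (TC) — and phenotyping software emits a table of segmented cells with
coordinates and marker positivity (panel 1: CK, CD4, CD8, FOXP3; panel 2:
CK, FOXP3, PD-1, PD-L1). `spatialSIS` turns those tables into per-patient
spatial interaction features, selects prognostic features by a
three-algorithm consensus, and combines them into a linear Spatial Immune
Signature (SIS) for recurrence-free survival (RFS).

# Phenotype gating

Marker positivity arrives as booleans; intensity thresholding is upstream
and out of scope. Gates are hierarchical and mutually exclusive where
lineages are concerned:

* **Tumor** — any CK+ cell. CK positivity dominates: a CK+CD4+ cell is
  called tumor and never enters a T-cell gate.
* **CD4 / CD8 lineages** — CK−, single-positive; CD4+CD8+ double positives
  belong to neither lineage and are counted as "other".
* **Treg / Tcon** — FOXP3+ / FOXP3− within a lineage, so
  `CD4Treg ∪ CD4Tcon = CD4all` by construction.

The phenotyping software this emulates emits mutually exclusive classes,
but published analyses rarely state how cross-lineage double positives are
resolved; the hierarchy above is this package's declared convention, fixed
once so that the partition invariant (`Tumor`, `CD4all`, `CD8all` pairwise
disjoint) can be asserted on every simulated core. Target sets such as
"Tregs to CD4+ T cells" use the whole lineage (`CD4all`, Tregs included);
exclusion is available by passing a different pair list.

# The three spatial parameters

All coordinates are micrometres in a local core frame with the origin at
the window corner. For phenotypes $A$ (source) and $B$ (target) in one
core:

* **Density** $D_A$ = count of $A$ cells / core area, reported per mm²
  (the window is known, so the area is exact, not estimated).
* **Mean nearest-neighbor distance**
  $N_{A \to B} = \frac{1}{n(A)} \sum_{i \in A} d_{\min}(i, B)$, in μm.
  Smaller values are read as stronger interaction.
* **Proximity score**
  $P_{A \to B} = \frac{1}{N(B)} \sum_{j \in B} \#\{i \in A : d(i,j) \le r\}$,
  the mean count of $A$ cells within radius $r$ (default 30 μm, the
  scale at which cell-contact interactions are reported) of each $B$ cell.

Numerical conventions, each fixed deliberately:

* "Within radius" is **closed** ($\le r$). Ties have measure zero in real
  coordinates, but a convention must be fixed for integer-exact tests.
* **No edge correction.** Cells near the core boundary have truncated
  neighborhoods; the plain formulas contain no correction and the package
  applies none. The simulator's analytic self-checks instead use toroidal
  (wrap-around) distances, for which the closed forms below hold exactly.
* **Self-pairing is excluded** whenever the two gates can overlap (e.g.
  `CD4Treg → CD4all`): a cell is never its own neighbor, so zero
  self-distances cannot fake interaction.
* **Undefined is not zero.** If the denominator set is empty ($n(A) = 0$
  for mNND, $N(B) = 0$ for proximity, or the only $B$ cell is the $A$ cell
  itself) the metric is undefined and propagates as `NA`. A core with no
  CD8+ Tregs has no Treg–tumor distance; imputing 0 would claim maximal
  interaction.
* One prose description of the proximity score in the source literature
  inverts its direction relative to the formula; the formula (mean $A$
  count around $B$ cells) is implemented literally and this note is the
  documentation of the discrepancy.

The implementation bins points into a uniform grid (expanding-ring search
for nearest neighbors, disc stabbing for radius counts, in C++). The test
suite holds it to *exact* equality — to the floating-point ulp for
distances, integer-exact for counts — against a plain $O(n^2)$ double loop
on randomized cores, so the acceleration can never drift from the
definition.

# The synthetic cohort generator

No patient data ship with the package; every downstream stage is exercised
on synthetic cohorts with known ground truth. A core is a 1000×1000 μm
window (1 mm², the TMA scale):

* **Tumor cells** follow a parent–offspring (Thomas-type) clustered
  process: parents uniform at 50/mm², Gaussian offspring displacement
  (σ = 50 μm), offspring count tuned so the expected tumor intensity
  matches its target (default 2000/mm²).
* **Immune phenotypes** get Poisson counts (defaults, per mm²: CD4 Tcon
  300, CD4 Treg 100, CD8 Tcon 200, CD8 Treg 30 — the order of magnitude
  typical of NSCLC TMA cores, with Tregs a minority and CD8+ Tregs rare)
  and an attraction mixture: with probability $|\rho|$ a cell is placed by
  Gaussian displacement (σ = 20 μm) from a uniformly chosen target-
  phenotype cell ($\rho > 0$), or by rejection sampling away from all
  targets ($\rho < 0$, gap 2σ); otherwise uniformly. $\rho = 0$ is
  complete spatial randomness (CSR). Attraction targets may be composite
  gates (`CD4all`), resolved against all already-placed cells.

The displacement mixture was chosen over a Gibbs pairwise-interaction
process because it samples exactly, and its effect on both mNND and the
proximity score is monotone in $\rho$ — which is what the tests need to
assert. Under CSR with toroidal wrap the generator satisfies two closed
forms used as acceptance checks, with $\lambda$ in cells/μm²:
$E[P_{A \to B}] = \lambda_A \pi r^2$ and
$E[N_{A \to B}] \approx 1/(2\sqrt{\lambda_B})$.

**Survival** is exponential with a log-linear hazard in the cohort-z-scored
planted features: baseline 0.01 events/month, independent exponential
censoring at 0.008/month truncated at 84 months. These defaults give an
event fraction near 40% over a 7-year follow-up, matching operable-NSCLC
recurrence rates. Z-scoring the features before the hazard makes planted
log-HR magnitudes comparable across metrics with different units. The
default planted effects put log-HRs of +0.85, +0.70, −0.67 and −0.56 on
`P(CD8Treg_to_CD4all)@IM`, `P(CD8Treg_to_Tumor)@IM`,
`N(CD4Treg_to_Tumor)@IM` and `N(CD4Tcon_to_Tumor)@IM` — the four-feature
structure (proximity harmful, distance protective) that the signature
construction is designed to recover. Patient-to-patient heterogeneity
comes from log-normal intensity jitter (SD 0.35) and per-patient $\rho$
draws from $U(0, 0.8)$; without it the features would carry no prognostic
information.

What the generator does **not** emulate: tissue morphology, stromal
compartments, marker-intensity distributions, segmentation error, batch
effects across TMAs, or 3-D structure. Passing tests therefore demonstrate
that the estimators and the selection/signature machinery are correct and
well-calibrated under a controlled spatial model — not that the biological
effect sizes of any particular cohort will reproduce.

# Feature matrix and cohort comparisons

Features are named on a fixed grammar,
`{D|N|P}({source}[_to_{target}])@{IM|TC}`, e.g. `N(CD4Treg_to_Tumor)@IM`.
One row per patient; duplicate cores for a (patient, region) are averaged
over their defined values (two cores per patient is the norm and no
weighting is obviously better); metrics undefined in every core stay `NA`.
Group contrasts (e.g. by stage) use the two-sided Mann–Whitney U test with
normal approximation and tie correction. Survival dichotomization of a
feature uses either the median or the "X-tile"-style outcome-driven
cutpoint below. No multiple-testing correction is applied across
feature-level log-rank tests — matching the practice the package
reproduces — and reports should state the number of tests performed.

# Survival machinery

Kaplan–Meier curves, the log-rank test and Cox proportional-hazards fits
delegate to the `survival` package; ties use the Efron approximation (the
better default when event times are recorded in months and ties are
common). Medians are reported as "not reached" when the curve never drops
to 0.5. Two components are implemented in the package:

* **Optimal cutpoint** (`optimalCutpoint()`): scans all midpoints between
  consecutive unique score values leaving at least `minGroupFrac` (default
  10%) of subjects per arm and maximizes the log-rank chi-square, breaking
  ties toward the more balanced split. This emulates outcome-driven
  cutpoint software; the associated p-value is *not* corrected for the
  maximal selection and is flagged optimistic wherever reported.
* **Time-dependent AUC** (`timeDependentAUC()`): cumulative-case /
  dynamic-control AUC with inverse-probability-of-censoring weights from
  the Kaplan–Meier censoring curve (Uno-type; cases weighted by
  $1/G(T^-)$, controls by $1/G(\tau)$). With no censoring it reduces
  exactly to the Mann–Whitney AUC of cases versus survivors, which is how
  it is tested. The estimator choice is a declared default; the
  literature this reproduces does not name its estimator.

# Split, selection, signature

* **Split**: `round(0.7 n)` patients to training, stratified so each
  covariate stratum contributes its proportional share within one patient
  (largest-remainder rounding); strata smaller than 2 are merged with a
  warning. 261 patients yield exactly 183/78.
* **Selection** (`selectFeatures()`): features are median-imputed and
  z-scored with *training-split statistics only* (the same constants are
  reapplied at validation/scoring time — a leakage guard). Three rankings
  are intersected: (1) L1-penalized **Cox** regression (`glmnet`), penalty
  at minimum 10-fold cross-validated deviance, up to ten nonzero
  coefficients ranked by $|\hat\beta|$ — penalized Cox rather than
  logistic because the features feed a survival signature (logistic is
  available by `lassoTarget`); (2) **XGBoost** on the binary event
  indicator, top ten by gain (depth 3, η = 0.1, 100 rounds, single
  thread for bit-reproducibility); (3) **random forest** on the event
  indicator, top ten by Gini mean decrease (500 trees). The "ten
  optimal variables" is enforced as a cap, not a quota. An empty
  intersection is returned with a warning and halts the pipeline.
* **Signature** (`fitSignature()`): multivariate Cox coefficients of the
  intersected features on the training split define the linear score
  $\mathrm{SIS} = \sum_k \hat\beta_k z_k$; the high/low cutoff is the
  optimal cutpoint of the training scores. Whether published signature
  weights come from the training split or the whole cohort is typically
  unstated; this package fits them on the training split, the choice that
  keeps validation untouched. Hand-built signatures (e.g. published
  coefficients) are constructed directly with `SpatialSignature()` and
  score raw feature values.

# Pipeline, determinism, problem sizes

`runPipeline()` executes simulate → metrics → composition → split →
selection → signature → evaluation in a fixed order; any failure halts
with a stage-named diagnostic, every stochastic step derives from the
single configured seed, and two runs with the same configuration are
identical. With `outdir` set, all intermediates (long metric table,
feature matrix, patient table, cell table, signature constants) are
written so every headline number can be re-derived from stored tables.

The shipped test-suite and acceptance-script problem sizes are the
package's chosen compromise between statistical resolution and a
single-CPU run: 100 random cores (up to 500 cells) for oracle equality,
60–100 CSR cores for the closed-form limits, 100 replicates at $n = 400$
for Cox coverage, 25 replicates at $n = 400$ with 4 signal / 40 null
features for selection recovery, and a 300-patient default pipeline run.

# Known limitations

* The spatial model is stationary within a core; real cores have tumor
  nests, stroma and necrosis that induce non-stationarity the metrics
  inherit silently.
* No edge correction means absolute mNND/proximity values are biased near
  boundaries; comparisons across cores of equal geometry are unaffected,
  which is the use the signature makes of them.
* The maximal-chi-square cutpoint inflates type-I error when its p-value
  is taken at face value.
* XGBoost/RF rank features against the *binary* event indicator, ignoring
  censoring times; survival forests are out of scope by design.
* Single-institution-style data (one window geometry, two cores per
  patient) is assumed; multi-TMA harmonization is not addressed.
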