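# spatialSIS

Spatial immune signatures from multiplex-immunofluorescence cell tables.

## The problem

In multiplex-immunofluorescence (mIF) tissue-microarray studies, each
patient contributes small tissue cores — one at the invasive margin (IM),
one in the tumor center (TC) — and phenotyping software emits a table of
segmented cells with 2-D coordinates (μm) and marker positivity
(panel 1: CK, CD4, CD8, FOXP3; panel 2: CK, FOXP3, PD-1, PD-L1). The
question is not just *how many* regulatory T cells (Tregs) a tumor
contains but *where they sit* relative to tumor cells and other T cells,
and whether that spatial interplay predicts recurrence after surgery.

`spatialSIS` is for analysts working with such phenotyped cell tables. It
computes three spatial parameters per core and phenotype pair (A = source,
B = target):

- density `D(A) = n(A) / area` (cells/mm²),
- mean nearest-neighbor distance
  `N(A→B) = Σᵢ∈A d_min(i, B) / n(A)` (μm; smaller = stronger interaction),
- proximity score
  `P(A→B) = Σⱼ∈B #{i ∈ A : d(i,j) ≤ r} / N(B)` (mean A-count within
  r = 30 μm of each B cell),

assembles them into a per-patient feature matrix, selects prognostic
features by the intersection of LASSO-Cox, XGBoost and random-forest
rankings on a stratified 7:3 training split, and fits the Spatial Immune
Signature — a linear risk score `SIS = Σ βₖ·zₖ` with multivariate Cox
coefficients — evaluated by Kaplan–Meier/log-rank, stage-adjusted Cox
models and IPCW time-dependent ROC at 1/3/5 years. A synthetic cohort
generator with planted spatial attraction (ρ) and hazard effects makes
every stage testable without patient data.

## Worked example

```r
library(spatialSIS)
set.seed(11)
core <- simulateCore(spatialSimParams(attraction = c("CD4Treg->Tumor" = 0.7)),
                     region = "IM", coreId = "P001_IM", patientId = "P001")
core
#> CellCore 'P001_IM' (patient P001)
#>   region: IM  panel: panel1  area: 1 mm^2
#>   cells: 2611
#>   phenotypes: Tumor=1973, CD4all=382, CD8all=256, CD4Treg=113,
#>               CD4Tcon=269, CD8Treg=35, CD8Tcon=221, FOXP3pos=148

cellDensity(core, "CD4Treg")$value        # 113 cells/mm^2
meanNNDist(core, "CD4Treg", "Tumor")$value
#> [1] 16.22415                            # um; attraction pulls Tregs close
proximityScore(core, "CD4Treg", "Tumor", r = 30)$value
#> [1] 0.5854029                           # mean Tregs within 30 um of a tumor cell
```

The 113 cells/mm² is the planted Treg intensity (Poisson around 100);
16.2 μm is below the ≈20 μm this clustered tumor process gives when Tregs
are placed uniformly, reflecting the planted attraction ρ = 0.7 that pulls
70% of Tregs to within a 20 μm Gaussian of a tumor cell. A published
coefficient set can be scored directly:

```r
sis <- SpatialSignature(
  c("P(CD8Treg_to_CD4all)@IM", "P(CD8Treg_to_Tumor)@IM",
    "N(CD4Treg_to_Tumor)@IM", "N(CD4Tcon_to_Tumor)@IM"),
  c(1.25, 0.70, -0.67, -0.56))
sis
#> SpatialSignature with 4 features
#>   SIS = 1.25 x [P(CD8Treg_to_CD4all)@IM] + 0.70 x [P(CD8Treg_to_Tumor)@IM]
#>       - 0.67 x [N(CD4Treg_to_Tumor)@IM] - 0.56 x [N(CD4Tcon_to_Tumor)@IM]
scoreSIS(sis, c(1, 1, 1, 1))
#> [1] 0.72
```

`runPipeline(pipelineConfig(nPatients = 300, seed = 1))` runs the whole
design — simulation, metrics, stratified split, three-algorithm selection,
signature fit, survival evaluation — and prints a report whose every
number is re-derivable from the intermediate tables it writes. A thin CLI
wrapper with `simulate` / `metrics` / `run-all` / `score` subcommands is
installed at `inst/scripts/sis-pipeline.R`. See the vignette
(`vignettes/spatial-immune-signature.Rmd`) for the model, parameter
defaults and design decisions.

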