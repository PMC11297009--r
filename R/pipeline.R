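## End-to-end orchestration reproducing the study design on a conforming
## dataset (synthetic by default): metrics -> features -> split ->
## selection -> signature -> survival evaluation. Every stage failure is
## reported with the stage name; identical seeds give identical reports.

#' Pipeline configuration
#'
#' @param nPatients Cohort size when simulating.
#' @param seed Integer seed for simulation, split and selection.
#' @param r Proximity radius in um.
#' @param ratio Training fraction.
#' @param stratifyOn Covariates balanced across the split.
#' @param cutpointPolicy `"xtile"` or `"median"` for score dichotomization.
#' @param horizons AUC horizons in months (positive, ascending).
#' @param sampler,hazard Simulation inputs (see [simulateCohort()]);
#'   defaults are used when `NULL`.
#' @param cohort An existing `SimulatedCohort` (or list with `featureSet`
#'   and `cores`) to analyze instead of simulating.
#' @param outdir Directory for intermediate tables, or `NULL`.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(nPatients = 300, seed = 1, r = 30, ratio = 0.7,
                           stratifyOn = "stage_group",
                           cutpointPolicy = "xtile",
                           horizons = c(12, 36, 60), sampler = NULL,
                           hazard = NULL, cohort = NULL, outdir = NULL) {
  if (r <= 0) stop("radius r must be positive")
  if (any(horizons <= 0) || is.unsorted(horizons, strictly = TRUE))
    stop("horizons must be positive and ascending")
  structure(list(nPatients = nPatients, seed = seed, r = r, ratio = ratio,
                 stratifyOn = stratifyOn, cutpointPolicy = cutpointPolicy,
                 horizons = horizons, sampler = sampler, hazard = hazard,
                 cohort = cohort, outdir = outdir),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(name, " stage: ", conditionMessage(e), call. = FALSE))
}

#' Phenotype composition per region
#'
#' Fractions of CD4+ and CD8+ Tregs among FOXP3+ T cells, and the FOXP3+
#' fractions within the CD4 and CD8 lineages, per region. Fractions with
#' an empty denominator are `NA`.
#'
#' @param cores list of panel-1 [CellCore] objects.
#' @return data.frame with one row per region.
#' @export
compositionSummary <- function(cores) {
  if (is(cores, "CellCore")) cores <- list(cores)
  regions <- vapply(cores, region, character(1))
  do.call(rbind, lapply(c("IM", "TC"), function(reg) {
    sub <- cores[regions == reg]
    if (!length(sub)) return(NULL)
    cts <- Reduce(`+`, lapply(sub, phenotypeCounts,
                              phenotypes = c("CD4Treg", "CD8Treg",
                                             "CD4all", "CD8all")))
    nTreg <- cts["CD4Treg"] + cts["CD8Treg"]
    frac <- function(num, den) if (den > 0) num / den else NA_real_
    data.frame(region = reg, n_treg = unname(nTreg),
               frac_cd4treg_of_treg = frac(cts["CD4Treg"], nTreg),
               frac_cd8treg_of_treg = frac(cts["CD8Treg"], nTreg),
               frac_foxp3_in_cd4 = frac(cts["CD4Treg"], cts["CD4all"]),
               frac_foxp3_in_cd8 = frac(cts["CD8Treg"], cts["CD8all"]),
               stringsAsFactors = FALSE)
  }))
}

#' PD-1/PD-L1 interplay by FOXP3 burden (panel 2)
#'
#' Groups patients by their FOXP3+ cell count (survival-optimal cutoff or
#' median), compares `N(PDL1->PD1)` and `P(PDL1->PD1)` between the high-
#' and low-FOXP3 groups per region (Mann-Whitney), and dichotomizes both
#' metrics against survival.
#'
#' @param cores list of panel-2 [CellCore] objects.
#' @param patients Patient table with survival outcome.
#' @param grouping `"xtile"` or `"median"` for the FOXP3-count cutoff.
#' @param r Proximity radius in um.
#' @return list with `foxp3Cutoff`, `groups`, `comparisons` (per region
#'   and metric: U, p, group medians), `survival` (per region and metric:
#'   cutoff and log-rank test).
#' @export
panel2Interplay <- function(cores, patients, grouping = c("xtile", "median"),
                            r = 30) {
  grouping <- match.arg(grouping)
  patients <- as.data.frame(patients)
  if (!all(vapply(cores, function(cc) panel(cc) == "panel2", logical(1))))
    stop("panel2Interplay needs panel-2 cores")
  foxp3 <- vapply(split(cores, vapply(cores, patientId, character(1))),
                  function(ccs) sum(vapply(ccs, function(cc)
                    sum(gateMask(cc, "FOXP3pos")), numeric(1))),
                  numeric(1))
  idx <- match(patients$patient_id, names(foxp3))
  counts <- foxp3[idx]
  grp <- dichotomizeFeature(counts, patients$rfs_months, patients$event,
                            policy = grouping)
  if (any(table(grp$labels) == 0L))
    stop("FOXP3 grouping empties one arm")
  mt <- cohortMetrics(cores, r = r)
  wide <- .featureWide(mt)
  wide <- wide[match(patients$patient_id, rownames(wide)), , drop = FALSE]
  comparisons <- list(); survival <- list()
  for (reg in intersect(c("IM", "TC"), unique(mt$region))) {
    for (metric in c("N", "P")) {
      fn <- featureName(metric, "PDL1pos", "PD1pos", reg)
      if (!fn %in% colnames(wide)) next
      v <- wide[, fn]
      cmp <- compareGroups(v, grp$labels)
      cmp$medianLow <- median(v[grp$labels == "low"], na.rm = TRUE)
      cmp$medianHigh <- median(v[grp$labels == "high"], na.rm = TRUE)
      comparisons[[fn]] <- cmp
      sv <- tryCatch({
        d <- dichotomizeFeature(v, patients$rfs_months, patients$event,
                                policy = grouping)
        ok <- !is.na(d$labels)
        lr <- logrankTest(patients$rfs_months[ok], patients$event[ok],
                          d$labels[ok])
        list(cutoff = d$cutoff, chisq = lr$chisq, p = lr$p)
      }, error = function(e) list(error = conditionMessage(e)))
      survival[[fn]] <- sv
    }
  }
  list(foxp3Cutoff = grp$cutoff, groups = grp$labels,
       comparisons = comparisons, survival = survival)
}

#' Evaluate a signature on a split cohort
#'
#' Scores all patients, assigns high/low groups at the training cutoff,
#' and reports per-cohort (train / validation / entire) Kaplan-Meier
#' medians, log-rank tests, time-dependent AUCs, plus the multivariate Cox
#' model of stage group and SIS group on the entire cohort.
#'
#' @param signature A [SpatialSignature-class] with a cutoff.
#' @param featureSet A [SpatialFeatureSet] whose `colData` has a `split`
#'   column.
#' @param horizons AUC horizons (months).
#' @return list of class `SignatureEvaluation`.
#' @export
evaluateSignature <- function(signature, featureSet,
                              horizons = c(12, 36, 60)) {
  cd <- as.data.frame(colData(featureSet))
  if (!"split" %in% colnames(cd)) stop("featureSet lacks a split column")
  if (!any(cd$split == "validation")) stop("empty validation split")
  score <- scoreSIS(signature, featureSet)
  grp <- factor(ifelse(score > signature@cutoff, "high", "low"),
                levels = c("low", "high"))
  subsets <- list(train = cd$split == "train",
                  validation = cd$split == "validation",
                  entire = rep(TRUE, nrow(cd)))
  cohorts <- lapply(subsets, function(sel) {
    t <- cd$rfs_months[sel]; e <- cd$event[sel]; g <- grp[sel]
    lr <- if (nlevels(droplevels(g)) == 2L) logrankTest(t, e, g) else NULL
    aucs <- lapply(horizons, function(h)
      tryCatch(timeDependentAUC(score[sel], t, e, h),
               error = function(err) list(horizon = h, auc = NA_real_,
                                          error = conditionMessage(err))))
    list(n = sum(sel), events = sum(e),
         kmHigh = kmEstimate(t[g == "high"], e[g == "high"]),
         kmLow = kmEstimate(t[g == "low"], e[g == "low"]),
         logrank = lr,
         auc = setNames(vapply(aucs, function(a) a$auc, numeric(1)),
                        paste0(horizons, "m")))
  })
  covs <- data.frame(stage_III = as.numeric(cd$stage_group == "III"),
                     sis_high = as.numeric(grp == "high"))
  mv <- coxFit(covs, cd$rfs_months, cd$event)
  structure(list(score = score, group = grp, cutoff = signature@cutoff,
                 cohorts = cohorts, multivariate = mv),
            class = "SignatureEvaluation")
}

#' @export
print.SignatureEvaluation <- function(x, ...) {
  cat("Signature evaluation (cutoff ", format(x$cutoff, digits = 4),
      ")\n", sep = "")
  for (nm in names(x$cohorts)) {
    co <- x$cohorts[[nm]]
    med <- function(km) if (km$medianReached)
      format(km$median, digits = 4) else "not reached"
    cat(sprintf("  %-10s n=%3d events=%3d  median high/low: %s vs %s", nm,
                co$n, co$events, med(co$kmHigh), med(co$kmLow)))
    if (!is.null(co$logrank))
      cat(sprintf("  log-rank p=%.3g", co$logrank$p))
    cat("\n    AUC:", paste(names(co$auc),
                            format(co$auc, digits = 3), collapse = "  "),
        "\n")
  }
  cat("  multivariate Cox (entire cohort):\n")
  print(x$multivariate)
  invisible(x)
}

#' Run the full spatial-immune-signature pipeline
#'
#' Simulates (or accepts) a cohort, computes spatial features, splits the
#' cohort with covariate stratification, selects features by the
#' three-algorithm intersection, fits the SIS on the training split and
#' evaluates it. Stages run in a fixed order and any failure halts with a
#' stage-named diagnostic; the run is deterministic given the seed.
#'
#' @param config A [pipelineConfig()].
#' @return list of class `RunReport` with elements `config`, `cohort`,
#'   `composition`, `split`, `selection`, `signature`, `evaluation`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  cohort <- .stage("simulation", {
    if (!is.null(config$cohort)) config$cohort
    else simulateCohort(
      config$nPatients,
      sampler = config$sampler %||% defaultCohortSampler(),
      hazard = config$hazard %||% hazardSimParams(),
      r = config$r, seed = config$seed)
  })
  fs <- cohort$featureSet
  composition <- .stage("composition", {
    if (all(vapply(cohort$cores, function(cc) panel(cc) == "panel1",
                   logical(1))))
      compositionSummary(cohort$cores)
    else NULL
  })
  cd <- as.data.frame(colData(fs))
  split <- .stage("split", {
    if (config$ratio >= 1 || config$ratio <= 0)
      stop("ratio must be in (0, 1) so both splits are non-empty")
    splitCohort(cd, ratio = config$ratio,
                stratifyOn = intersect(config$stratifyOn, colnames(cd)),
                seed = config$seed)
  })
  fs$split <- split
  train <- split == "train"
  X <- featureMatrix(fs)
  selection <- .stage("feature selection",
    selectFeatures(X[train, , drop = FALSE], cd$rfs_months[train],
                   cd$event[train], seed = config$seed))
  if (!length(selectedFeatures(selection)))
    stop("feature selection stage: empty three-algorithm intersection; ",
         "no signature can be fit")
  signature <- .stage("signature fit",
    fitSignature(X[train, , drop = FALSE], cd$rfs_months[train],
                 cd$event[train], selectedFeatures(selection),
                 cutpointPolicy = config$cutpointPolicy))
  evaluation <- .stage("evaluation",
    evaluateSignature(signature, fs, horizons = config$horizons))
  report <- structure(
    list(config = config, cohort = cohort, composition = composition,
         split = split, selection = selection, signature = signature,
         evaluation = evaluation),
    class = "RunReport")
  if (!is.null(config$outdir)) .stage("output", .writeReport(report))
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("== spatialSIS pipeline report ==\n")
  cat("cohort:", nrow(as.data.frame(colData(x$cohort$featureSet))),
      "patients; split:", sum(x$split == "train"), "train /",
      sum(x$split == "validation"), "validation\n")
  if (!is.null(x$composition)) {
    cat("-- phenotype composition --\n")
    print(x$composition, row.names = FALSE, digits = 3)
  }
  cat("-- feature selection --\n")
  show(x$selection)
  cat("-- signature --\n")
  show(x$signature)
  cat("-- evaluation --\n")
  print(x$evaluation)
  invisible(x)
}

.writeReport <- function(report) {
  dir <- report$config$outdir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$cohort$metricTable,
            file.path(dir, "metrics_long.csv"), row.names = FALSE)
  X <- featureMatrix(report$cohort$featureSet)
  write.csv(data.frame(patient_id = rownames(X), X, check.names = FALSE),
            file.path(dir, "feature_matrix.csv"), row.names = FALSE)
  pts <- report$cohort$patients
  pts$split <- report$split
  writePatientTable(pts, file.path(dir, "patients.csv"))
  writeCellTable(report$cohort$cores, file.path(dir, "cells.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report$cohort$manifest,
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  sig <- report$signature
  write.csv(data.frame(feature = sig@features, coefficient = sig@coefficients,
                       center = sig@center, scale = sig@scale,
                       impute = sig@impute, cutoff = sig@cutoff),
            file.path(dir, "signature.csv"), row.names = FALSE)
  invisible(dir)
}
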