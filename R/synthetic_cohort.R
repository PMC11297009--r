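## Synthetic mIF cohort generator. Cores are ~1 mm^2 windows with clustered
## tumor cells (parent-offspring process) and immune phenotypes whose
## spatial association with a target phenotype is controlled by an
## attraction parameter rho in [-1, 1]: with probability |rho| a cell is
## displaced by an isotropic Gaussian from a uniformly chosen target cell
## (toward targets for rho > 0, pushed away from them for rho < 0), else
## placed uniformly (rho = 0 is complete spatial randomness). Survival
## times are exponential with a log-linear hazard in z-scored spatial
## features, so planted effects are recoverable in closed form.

#' Spatial simulation parameters for one core
#'
#' @param window `c(width, height)` in um (default the 1 mm-square TMA
#'   frame).
#' @param intensities Named vector, expected cells/mm^2 per phenotype
#'   (counts are Poisson). Placement follows the given order, so attraction
#'   targets must precede their sources; `Tumor` is always placed first.
#' @param attraction Named vector of rho in `[-1, 1]`, names
#'   `"source->target"`, e.g. `c("CD4Treg->Tumor" = 0.8)`.
#' @param clusterSigma Gaussian displacement scale in um for attracted
#'   cells (default 20).
#' @param tumorParents Parent intensity (parents/mm^2) of the clustered
#'   tumor process; offspring count per parent is set so the expected tumor
#'   intensity matches `intensities["Tumor"]`. `NULL` places tumor cells
#'   uniformly.
#' @param tumorSigma Offspring displacement scale in um.
#' @param panel Marker panel the phenotypes belong to.
#' @return A validated `SpatialSimParams` list.
#' @export
spatialSimParams <- function(window = c(1000, 1000),
                             intensities = c(Tumor = 2000, CD4Tcon = 300,
                                             CD4Treg = 100, CD8Tcon = 200,
                                             CD8Treg = 30),
                             attraction = numeric(),
                             clusterSigma = 20,
                             tumorParents = 50, tumorSigma = 50,
                             panel = "panel1") {
  stopifnot(length(window) == 2L, all(window > 0))
  if (length(intensities) && (is.null(names(intensities)) ||
      !all(names(intensities) %in% phenotypeNames())))
    stop("intensities must be named by phenotypes from phenotypeNames()")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  if (length(attraction)) {
    if (any(abs(attraction) > 1)) stop("|rho| must be <= 1")
    parts <- strsplit(names(attraction), "->", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("attraction names must be 'source->target'")
  }
  stopifnot(clusterSigma > 0)
  structure(list(window = unname(window), intensities = intensities,
                 attraction = attraction, clusterSigma = clusterSigma,
                 tumorParents = tumorParents, tumorSigma = tumorSigma,
                 panel = panel),
            class = "SpatialSimParams")
}

#' Hazard simulation parameters
#'
#' Survival is exponential: `rate = baselineHazard * exp(sum(beta * z))`
#' with `z` the cohort-z-scored planted features; censoring is an
#' independent exponential truncated at `maxFollowup` months. Defaults give
#' an event fraction near the 40% recurrence rate typical of operable
#' NSCLC cohorts over a 7-year follow-up.
#'
#' @param baselineHazard Events/month (> 0).
#' @param betas Named log-hazard coefficients on canonical feature names.
#' @param censorRate Censoring events/month (>= 0).
#' @param maxFollowup Administrative censoring horizon in months.
#' @return A validated `HazardSimParams` list.
#' @export
hazardSimParams <- function(baselineHazard = 0.01,
                            betas = c("P(CD8Treg_to_CD4all)@IM" = 0.85,
                                      "P(CD8Treg_to_Tumor)@IM" = 0.70,
                                      "N(CD4Treg_to_Tumor)@IM" = -0.67,
                                      "N(CD4Tcon_to_Tumor)@IM" = -0.56),
                            censorRate = 0.008, maxFollowup = 84) {
  stopifnot(baselineHazard > 0, censorRate >= 0, maxFollowup > 0)
  if (length(betas) && is.null(names(betas)))
    stop("betas must be named by feature")
  structure(list(baselineHazard = baselineHazard, betas = betas,
                 censorRate = censorRate, maxFollowup = maxFollowup),
            class = "HazardSimParams")
}

.runif_xy <- function(n, W, H) cbind(runif(n, 0, W), runif(n, 0, H))

## does a simulated cell of phenotype `ph` satisfy the gate of `gatePheno`?
## (e.g. placed CD4Treg cells are members of the CD4all target set)
.phenoInGate <- function(ph, gatePheno, panel) {
  markers <- panelMarkers(panel)
  m <- as.data.frame(as.list(setNames(
    markers %in% .PHENOTYPE_MARKER_ON[[ph]], markers)))
  def <- .PHENOTYPE_GATES[[gatePheno]]
  if (!all(def$markers %in% markers)) return(FALSE)
  isTRUE(def$gate(m))
}

## Gaussian displacement from sampled anchors, resampled until inside window
.displaced <- function(anchors, sigma, W, H) {
  n <- nrow(anchors)
  xy <- anchors + matrix(rnorm(2L * n, 0, sigma), ncol = 2L)
  for (iter in 1:100) {
    out <- xy[, 1] < 0 | xy[, 1] > W | xy[, 2] < 0 | xy[, 2] > H
    if (!any(out)) break
    xy[out, ] <- anchors[out, , drop = FALSE] +
      matrix(rnorm(2L * sum(out), 0, sigma), ncol = 2L)
  }
  xy[, 1] <- pmin(pmax(xy[, 1], 0), W)
  xy[, 2] <- pmin(pmax(xy[, 2], 0), H)
  xy
}

## uniform points conditioned on nearest target farther than `gap`
.repelled <- function(n, tx, ty, gap, W, H) {
  keep <- matrix(numeric(0), ncol = 2L)
  for (iter in 1:50) {
    need <- n - nrow(keep)
    if (need <= 0L) break
    cand <- .runif_xy(max(need * 2L, 16L), W, H)
    d <- nn_dist_cpp(cand[, 1], cand[, 2], rep.int(-1L, nrow(cand)),
                     tx, ty, seq_along(tx), FALSE, W, H)
    ok <- cand[d > gap, , drop = FALSE]
    keep <- rbind(keep, ok)
  }
  if (nrow(keep) < n)  # dense targets: fall back to uniform for remainder
    keep <- rbind(keep, .runif_xy(n - nrow(keep), W, H))
  keep[seq_len(n), , drop = FALSE]
}

#' Simulate one TMA core
#'
#' Draws a phenotyped point pattern in the window of `params`: tumor cells
#' from a parent-offspring clustered process, each immune phenotype from
#' the attraction-mixture described in [spatialSimParams()]. Requesting
#' attraction toward a phenotype with zero placed cells falls back to
#' uniform placement with a warning.
#'
#' @param params A [spatialSimParams()] object.
#' @param region `"IM"` or `"TC"`.
#' @param coreId,patientId Identifiers.
#' @return A [CellCore].
#' @examples
#' core <- withr::with_seed(1, simulateCore(spatialSimParams(), "IM"))
#' @export
simulateCore <- function(params, region, coreId = paste0("sim_", region),
                         patientId = "sim") {
  stopifnot(inherits(params, "SpatialSimParams"))
  W <- params$window[1]; H <- params$window[2]
  area <- W * H / 1e6
  lambda <- params$intensities
  phenos <- names(lambda)
  if ("Tumor" %in% phenos)  # tumor first so it can anchor attraction
    phenos <- c("Tumor", setdiff(phenos, "Tumor"))

  placed <- list()
  for (ph in phenos) {
    n <- rpois(1L, lambda[[ph]] * area)
    if (n == 0L) { placed[[ph]] <- matrix(numeric(0), ncol = 2L); next }
    if (ph == "Tumor" && !is.null(params$tumorParents)) {
      nPar <- max(1L, rpois(1L, params$tumorParents * area))
      parents <- .runif_xy(nPar, W, H)
      anchors <- parents[sample.int(nPar, n, replace = TRUE), , drop = FALSE]
      placed[[ph]] <- .displaced(anchors, params$tumorSigma, W, H)
      next
    }
    key <- grep(paste0("^", ph, "->"), names(params$attraction), value = TRUE)
    rho <- if (length(key)) params$attraction[[key[1]]] else 0
    target <- if (length(key)) sub("^.*->", "", key[1]) else NA
    tpts <- NULL
    if (!is.na(target)) {
      ## target set = all already-placed cells satisfying the target gate
      members <- names(placed)[vapply(names(placed), .phenoInGate,
                                      logical(1), gatePheno = target,
                                      panel = params$panel)]
      if (length(members))
        tpts <- do.call(rbind, placed[members])
    }
    if (rho != 0 && (is.null(tpts) || nrow(tpts) == 0L)) {
      warning("attraction ", ph, "->", target,
              " requested but no target cells placed; using uniform")
      rho <- 0
    }
    if (rho == 0) {
      placed[[ph]] <- .runif_xy(n, W, H)
    } else {
      attracted <- runif(n) < abs(rho)
      xy <- .runif_xy(n, W, H)
      na <- sum(attracted)
      if (na > 0L) {
        if (rho > 0) {
          anchors <- tpts[sample.int(nrow(tpts), na, replace = TRUE), ,
                          drop = FALSE]
          xy[attracted, ] <- .displaced(anchors, params$clusterSigma, W, H)
        } else {
          xy[attracted, ] <- .repelled(na, tpts[, 1], tpts[, 2],
                                       2 * params$clusterSigma, W, H)
        }
      }
      placed[[ph]] <- xy
    }
  }

  markers <- panelMarkers(params$panel)
  nTotal <- sum(vapply(placed, nrow, integer(1)))
  cells <- data.frame(
    cell_id = sprintf("%s_c%05d", coreId, seq_len(nTotal)),
    x = numeric(nTotal), y = numeric(nTotal), stringsAsFactors = FALSE)
  for (mk in markers) cells[[mk]] <- logical(nTotal)
  cells$true_phenotype <- rep(NA_character_, nTotal)
  at <- 0L
  for (ph in names(placed)) {
    xy <- placed[[ph]]
    if (!nrow(xy)) next
    idx <- at + seq_len(nrow(xy)); at <- at + nrow(xy)
    cells$x[idx] <- xy[, 1]; cells$y[idx] <- xy[, 2]
    for (mk in intersect(.PHENOTYPE_MARKER_ON[[ph]], markers))
      cells[[mk]][idx] <- TRUE
    cells$true_phenotype[idx] <- ph
  }
  CellCore(cells, coreId = coreId, patientId = patientId, region = region,
           panel = params$panel, bounds = c(W, H))
}

#' Draw survival outcomes from a planted log-linear hazard
#'
#' Features named in `hazard$betas` are median-imputed and z-scored across
#' the cohort, the linear predictor is formed, and event/censoring times
#' are drawn from independent exponentials (censoring truncated at
#' `maxFollowup`).
#'
#' @param features Patients x features numeric matrix.
#' @param hazard A [hazardSimParams()] object.
#' @return data.frame `rfs_months`, `event`, `lp` (one row per feature-row).
#' @export
simulateSurvival <- function(features, hazard) {
  stopifnot(inherits(hazard, "HazardSimParams"))
  n <- nrow(features)
  if (n < 2L) stop("need at least 2 patients")
  lp <- rep(0, n)
  betas <- hazard$betas
  if (length(betas)) {
    missing <- setdiff(names(betas), colnames(features))
    if (length(missing))
      stop("hazard betas name feature(s) absent from the matrix: ",
           paste(missing, collapse = ", "))
    for (nm in names(betas)) {
      v <- features[, nm]
      v[is.na(v)] <- median(v, na.rm = TRUE)
      s <- sd(v)
      z <- if (is.finite(s) && s > 0) (v - mean(v)) / s else rep(0, n)
      lp <- lp + betas[[nm]] * z
    }
  }
  tEvent <- rexp(n, rate = hazard$baselineHazard * exp(lp))
  tCens <- if (hazard$censorRate > 0)
    pmin(rexp(n, rate = hazard$censorRate), hazard$maxFollowup)
  else rep(hazard$maxFollowup, n)
  data.frame(rfs_months = pmin(tEvent, tCens),
             event = as.integer(tEvent <= tCens), lp = lp)
}

#' Per-patient spatial-parameter sampler
#'
#' Returns a sampler function (called once per patient) that draws
#' heterogeneous core parameters: intensities jittered log-normally around
#' their base values, and attraction rho for each planted source->target
#' pair drawn uniformly from its range. This patient-to-patient variation
#' is what makes the spatial features informative for the planted hazard.
#'
#' @param base A [spatialSimParams()] giving base intensities/window/panel.
#' @param plantedRho Named list of `c(min, max)` rho ranges, names
#'   `"source->target"`. Defaults plant association of both Treg subsets
#'   and CD4 Tcons with tumor cells and of CD8 Tregs with CD4 T cells,
#'   the pairs entering the default planted hazard.
#' @param intensitySD SD of the log-normal intensity jitter.
#' @return function(i) -> `SpatialSimParams`.
#' @export
defaultCohortSampler <- function(base = spatialSimParams(),
                                 plantedRho = list(
                                   "CD8Treg->CD4all" = c(0, 0.8),
                                   "CD8Treg->Tumor" = c(0, 0.8),
                                   "CD4Treg->Tumor" = c(0, 0.8),
                                   "CD4Tcon->Tumor" = c(0, 0.8)),
                                 intensitySD = 0.35) {
  force(base); force(plantedRho); force(intensitySD)
  sampler <- function(i) {
    lam <- base$intensities *
      exp(rnorm(length(base$intensities), 0, intensitySD))
    rho <- vapply(plantedRho, function(rg) runif(1L, rg[1], rg[2]),
                  numeric(1))
    spatialSimParams(window = base$window, intensities = lam,
                     attraction = rho, clusterSigma = base$clusterSigma,
                     tumorParents = base$tumorParents,
                     tumorSigma = base$tumorSigma, panel = base$panel)
  }
  attr(sampler, "manifest") <- list(base = unclass(base),
                                    plantedRho = plantedRho,
                                    intensitySD = intensitySD)
  sampler
}

.simulateCovariates <- function(n) {
  ## marginals near a typical operable-NSCLC cohort
  data.frame(
    age_group = ifelse(runif(n) < 0.322, ">65", "<=65"),
    gender = ifelse(runif(n) < 0.356, "Female", "Male"),
    histology = ifelse(runif(n) < 0.341, "LUSC", "LUAD"),
    smoking_index_group = ifelse(runif(n) < 0.433, ">=400", "<400"),
    stage_group = ifelse(runif(n) < 0.184, "III", "I-II"),
    stringsAsFactors = FALSE)
}

#' Simulate a full cohort with planted spatial and hazard effects
#'
#' For each patient, an IM and a TC core are simulated from
#' patient-specific parameters drawn by `sampler`, spatial metrics are
#' computed, the patient feature matrix assembled, and recurrence-free
#' survival drawn from the planted hazard. Identical seeds give identical
#' cohorts.
#'
#' @param nPatients Number of patients (>= 2).
#' @param sampler Per-patient parameter sampler, see
#'   [defaultCohortSampler()].
#' @param hazard A [hazardSimParams()].
#' @param r Proximity radius in um.
#' @param seed Integer seed for all randomness.
#' @return list of class `SimulatedCohort`: `cores` (list of [CellCore]),
#'   `patients` (clinical table incl. simulated survival), `featureSet`
#'   (a [SpatialFeatureSet]), `metricTable`, `trueBetas`, `manifest`.
#' @export
simulateCohort <- function(nPatients, sampler = defaultCohortSampler(),
                           hazard = hazardSimParams(), r = 30, seed = 1) {
  if (nPatients < 2L) stop("nPatients must be >= 2")
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(nPatients))
  cores <- list()
  for (i in seq_len(nPatients)) {
    params <- sampler(i)
    for (reg in c("IM", "TC")) {
      cid <- paste0(ids[i], "_", reg)
      cores[[cid]] <- simulateCore(params, reg, coreId = cid,
                                   patientId = ids[i])
    }
  }
  metricTable <- cohortMetrics(cores, r = r)
  features <- .featureWide(metricTable)
  surv <- simulateSurvival(features, hazard)
  patients <- cbind(
    data.frame(patient_id = ids, stringsAsFactors = FALSE),
    surv[match(ids, rownames(features)), c("rfs_months", "event")],
    .simulateCovariates(nPatients))
  patients$split <- "unassigned"
  rownames(patients) <- NULL
  fs <- SpatialFeatureSet(t(features), patients)
  structure(list(cores = cores, patients = patients, featureSet = fs,
                 metricTable = metricTable, trueBetas = hazard$betas,
                 manifest = list(seed = seed, nPatients = nPatients,
                                 r = r, hazard = unclass(hazard),
                                 sampler = attr(sampler, "manifest"))),
            class = "SimulatedCohort")
}

#' @export
print.SimulatedCohort <- function(x, ...) {
  cat("SimulatedCohort:", length(unique(x$patients$patient_id)),
      "patients,", length(x$cores), "cores\n")
  cat("  events:", sum(x$patients$event), "/", nrow(x$patients), "\n")
  cat("  planted betas:",
      paste(names(x$trueBetas), format(x$trueBetas, digits = 2),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
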