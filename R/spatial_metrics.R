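## Per-core spatial immune parameters: density D, mean nearest-neighbor
## distance N (mNND), proximity score P. Input coordinates are um; densities
## are reported per mm^2, mNND in um. No edge correction is applied: cells
## near the core boundary have truncated neighborhoods, matching the plain
## formulas. The toroidal option serves the simulator's closed-form checks
## only.

.metricRow <- function(metric, source, target, region, radius, value,
                       n_source, n_target, defined) {
  data.frame(metric = metric, source = source,
             target = if (is.null(target)) NA_character_ else target,
             region = region, radius_um = radius,
             value = value, n_source = n_source, n_target = n_target,
             defined = defined, stringsAsFactors = FALSE)
}

## gate a core, returning coordinates plus the global row index as identity
.gatedPoints <- function(core, phenotype) {
  mask <- gateMask(core, phenotype)
  cl <- cells(core)
  list(x = cl$x[mask], y = cl$y[mask], id = which(mask))
}

#' Cell density of a phenotype in a core
#'
#' `D(A) = count(A) / core area`, in cells per mm^2. A phenotype with zero
#' cells has density 0 (defined), unlike the pairwise metrics whose empty
#' denominators yield undefined values.
#'
#' @param core A [CellCore].
#' @param phenotype Phenotype name, see [phenotypeNames()].
#' @return One-row data.frame with columns `metric, source, target, region,
#'   radius_um, value, n_source, n_target, defined`.
#' @examples
#' core <- CellCore(data.frame(cell_id = 1:3, x = c(1, 2, 3), y = 1,
#'                             CK = c(1, 1, 0), CD4 = 0, CD8 = 0, FOXP3 = 0),
#'                  "c1", "p1", "TC")
#' cellDensity(core, "Tumor")$value  # 2 cells / 1 mm^2
#' @export
cellDensity <- function(core, phenotype) {
  stopifnot(is(core, "CellCore"))
  area <- coreArea(core)
  if (area <= 0) stop("core area must be positive")
  n <- sum(gateMask(core, phenotype))
  .metricRow("D", phenotype, NULL, region(core), NA_real_,
             n / area, n, NA_integer_, TRUE)
}

#' Mean nearest-neighbor distance between two phenotypes
#'
#' `N(A to B)`: the average, over all A cells, of the Euclidean distance to
#' the closest B cell (um). When the A and B gates can overlap, a cell is
#' never its own neighbor (zero self-distances are excluded). The metric is
#' undefined (`defined = FALSE`, `value = NA`) when there are no A cells,
#' no B cells, or the only B cell is the A cell itself. A smaller mNND is
#' read as a stronger spatial interaction.
#'
#' @param core A [CellCore].
#' @param source,target Phenotype names (A and B).
#' @param torus Use toroidal (wrap-around) distances; intended for
#'   simulation closed-form checks, not data analysis.
#' @return One-row metric data.frame (see [cellDensity()]).
#' @examples
#' core <- CellCore(data.frame(cell_id = 1:2, x = c(0, 3), y = c(0, 4),
#'                             CK = c(0, 1), CD4 = c(1, 0), CD8 = 0,
#'                             FOXP3 = c(1, 0)),
#'                  "c1", "p1", "IM")
#' meanNNDist(core, "CD4Treg", "Tumor")$value  # 5
#' @export
meanNNDist <- function(core, source, target, torus = FALSE) {
  stopifnot(is(core, "CellCore"))
  A <- .gatedPoints(core, source)
  B <- .gatedPoints(core, target)
  reg <- region(core)
  nA <- length(A$id); nB <- length(B$id)
  if (nA == 0L || nB == 0L || (nB == 1L && B$id %in% A$id))
    return(.metricRow("N", source, target, reg, NA_real_, NA_real_,
                      nA, nB, FALSE))
  b <- coreBounds(core)
  d <- nn_dist_cpp(A$x, A$y, as.integer(A$id), B$x, B$y, as.integer(B$id),
                   torus = torus,
                   width = unname(b["xmax"] - b["xmin"]),
                   height = unname(b["ymax"] - b["ymin"]))
  .metricRow("N", source, target, reg, NA_real_, mean(d), nA, nB, TRUE)
}

#' Proximity score between two phenotypes
#'
#' `P(A to B)`: the mean count of A cells within a closed radius `r`
#' (default 30 um) of each B cell. Self-counting is excluded when the gates
#' can overlap. Undefined when there are no B cells.
#'
#' @inheritParams meanNNDist
#' @param r Radius in um (> 0).
#' @return One-row metric data.frame (see [cellDensity()]).
#' @examples
#' core <- CellCore(data.frame(cell_id = 1:3, x = c(0, 0, 0), y = c(0, 5, 10),
#'                             CK = c(0, 0, 1), CD4 = c(1, 1, 0), CD8 = 0,
#'                             FOXP3 = 0),
#'                  "c1", "p1", "IM")
#' proximityScore(core, "CD4all", "Tumor")$value  # 2
#' @export
proximityScore <- function(core, source, target, r = 30, torus = FALSE) {
  stopifnot(is(core, "CellCore"))
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("radius r must be a positive number (um)")
  A <- .gatedPoints(core, source)
  B <- .gatedPoints(core, target)
  reg <- region(core)
  nA <- length(A$id); nB <- length(B$id)
  if (nB == 0L)
    return(.metricRow("P", source, target, reg, r, NA_real_, nA, nB, FALSE))
  b <- coreBounds(core)
  cnt <- count_within_cpp(A$x, A$y, as.integer(A$id),
                          B$x, B$y, as.integer(B$id), r,
                          torus = torus,
                          width = unname(b["xmax"] - b["xmin"]),
                          height = unname(b["ymax"] - b["ymin"]))
  .metricRow("P", source, target, reg, r, sum(cnt) / nB, nA, nB, TRUE)
}

#' Default metric pair lists per panel
#'
#' Panel 1 pairs every Treg/Tcon subset against tumor cells and the two
#' T-cell lineages; panel 2 pairs PD-L1+ cells against PD-1+ cells.
#'
#' @param panel `"panel1"` or `"panel2"`.
#' @return list with `densities` (phenotype names) and `pairs` (data.frame
#'   `source`, `target`).
#' @export
defaultMetricPairs <- function(panel = c("panel1", "panel2")) {
  panel <- match.arg(panel)
  if (panel == "panel1") {
    src <- c("CD4Treg", "CD8Treg", "CD4Tcon", "CD8Tcon")
    tgt <- c("Tumor", "CD4all", "CD8all")
    list(densities = c("Tumor", "CD4all", "CD8all", src),
         pairs = expand.grid(source = src, target = tgt,
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE))
  } else {
    list(densities = c("Tumor", "FOXP3pos", "PD1pos", "PDL1pos"),
         pairs = data.frame(source = "PDL1pos", target = "PD1pos",
                            stringsAsFactors = FALSE))
  }
}

#' All spatial metrics for one core
#'
#' Computes densities plus mNND and proximity for every requested
#' source/target pair, in a deterministic order, as a long-format table.
#'
#' @param core A [CellCore].
#' @param pairs data.frame with `source` and `target` columns, or `NULL`
#'   for [defaultMetricPairs()] of the core's panel.
#' @param densities Phenotypes to report densities for (`NULL` = default).
#' @param r Proximity radius in um.
#' @return data.frame `patient_id, core_id, region, metric, source, target,
#'   radius_um, value, n_source, n_target, defined`.
#' @export
coreMetrics <- function(core, pairs = NULL, densities = NULL, r = 30) {
  stopifnot(is(core, "CellCore"))
  defaults <- defaultMetricPairs(panel(core))
  if (is.null(pairs)) pairs <- defaults$pairs
  if (is.null(densities)) densities <- defaults$densities
  avail <- panelMarkers(panel(core))
  for (p in unique(c(densities, pairs$source, pairs$target))) {
    need <- .checkPhenotype(p)$markers
    if (!all(need %in% avail))
      stop("phenotype '", p, "' requires marker(s) ",
           paste(setdiff(need, avail), collapse = ", "),
           " absent from ", panel(core))
  }
  rows <- lapply(densities, function(p) cellDensity(core, p))
  for (i in seq_len(nrow(pairs))) {
    rows[[length(rows) + 1L]] <-
      meanNNDist(core, pairs$source[i], pairs$target[i])
    rows[[length(rows) + 1L]] <-
      proximityScore(core, pairs$source[i], pairs$target[i], r = r)
  }
  out <- do.call(rbind, rows)
  cbind(data.frame(patient_id = patientId(core), core_id = coreId(core),
                   stringsAsFactors = FALSE),
        out[, c("region", "metric", "source", "target", "radius_um",
                "value", "n_source", "n_target", "defined")])
}

#' Metrics for a list of cores
#'
#' @param cores list of [CellCore] objects.
#' @inheritParams coreMetrics
#' @return Long-format metric table over all cores.
#' @export
cohortMetrics <- function(cores, pairs = NULL, densities = NULL, r = 30) {
  do.call(rbind, lapply(cores, coreMetrics, pairs = pairs,
                        densities = densities, r = r))
}
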