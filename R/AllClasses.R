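#' CellCore: one phenotyped tissue-microarray core
#'
#' Container for the segmented cells of a single TMA core: 2-D coordinates
#' in micrometres (local core frame, origin at the window corner), boolean
#' marker positivity, and the core's bounded window, from which the area
#' used for densities is derived. Each core carries exactly one region
#' label, `IM` (invasive margin) or `TC` (tumor center).
#'
#' @slot coreId character(1) core identifier.
#' @slot patientId character(1) owning patient.
#' @slot region `"IM"` or `"TC"`.
#' @slot panel `"panel1"` (CK/CD4/CD8/FOXP3) or `"panel2"`
#'   (CK/FOXP3/PD1/PDL1).
#' @slot bounds named numeric(4) `xmin, xmax, ymin, ymax` in um.
#' @slot cells data.frame with columns `cell_id`, `x`, `y` and one logical
#'   column per panel marker; extra columns are preserved.
#'
#' @aliases CellCore
#' @export
setClass("CellCore",
  slots = c(coreId = "character", patientId = "character",
            region = "character", panel = "character",
            bounds = "numeric", cells = "data.frame"))

setValidity("CellCore", function(object) {
  msg <- character()
  if (length(object@region) != 1L || !object@region %in% c("IM", "TC"))
    msg <- c(msg, "region must be one of 'IM', 'TC'")
  if (length(object@panel) != 1L || !object@panel %in% c("panel1", "panel2"))
    msg <- c(msg, "panel must be 'panel1' or 'panel2'")
  b <- object@bounds
  if (length(b) != 4L || !all(c("xmin", "xmax", "ymin", "ymax") %in% names(b)))
    msg <- c(msg, "bounds must be named numeric(4): xmin, xmax, ymin, ymax")
  else if (!all(is.finite(b)) || b["xmax"] <= b["xmin"] || b["ymax"] <= b["ymin"])
    msg <- c(msg, "bounds must be finite with positive extent")
  cl <- object@cells
  need <- c("cell_id", "x", "y", panelMarkers(object@panel))
  missing <- setdiff(need, colnames(cl))
  if (length(missing))
    msg <- c(msg, paste0("cells lack column(s): ", paste(missing, collapse = ", ")))
  if (!length(msg) && nrow(cl)) {
    if (!all(is.finite(cl$x)) || !all(is.finite(cl$y)))
      msg <- c(msg, "cell coordinates must be finite")
    else if (any(cl$x < b["xmin"] | cl$x > b["xmax"] |
                 cl$y < b["ymin"] | cl$y > b["ymax"]))
      msg <- c(msg, "cells fall outside the core bounds")
    for (mk in panelMarkers(object@panel))
      if (!is.logical(cl[[mk]]))
        msg <- c(msg, paste0("marker column '", mk, "' must be logical"))
    if (anyDuplicated(cl$cell_id))
      msg <- c(msg, "duplicated cell_id within core")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellCore
#'
#' @param cells data.frame with `cell_id`, `x`, `y` and marker columns
#'   (logical or 0/1; coerced to logical).
#' @param coreId,patientId identifiers.
#' @param region `"IM"` or `"TC"`.
#' @param panel `"panel1"` or `"panel2"`.
#' @param bounds named numeric(4) `xmin, xmax, ymin, ymax` in um, or a
#'   `c(width, height)` pair interpreted as a window with origin 0.
#' @return A [CellCore-class] object.
#' @examples
#' cc <- CellCore(data.frame(cell_id = "c1", x = 10, y = 20,
#'                           CK = 1, CD4 = 0, CD8 = 0, FOXP3 = 0),
#'                coreId = "P1_IM", patientId = "P1", region = "IM")
#' coreArea(cc)
#' @export
CellCore <- function(cells, coreId, patientId, region,
                     panel = "panel1", bounds = c(1000, 1000)) {
  if (length(bounds) == 2L)
    bounds <- c(xmin = 0, xmax = unname(bounds[1]),
                ymin = 0, ymax = unname(bounds[2]))
  cells <- as.data.frame(cells)
  if (!nrow(cells)) {
    cells <- data.frame(cell_id = character(), x = numeric(), y = numeric())
    for (mk in panelMarkers(panel)) cells[[mk]] <- logical()
  }
  cells$cell_id <- as.character(cells$cell_id)
  for (mk in intersect(panelMarkers(panel), colnames(cells)))
    cells[[mk]] <- as.logical(cells[[mk]])
  new("CellCore", coreId = as.character(coreId),
      patientId = as.character(patientId), region = region,
      panel = panel, bounds = bounds, cells = cells)
}

#' @rdname CellCore
#' @param object,x A `CellCore`.
#' @export
setGeneric("coreId", function(x) standardGeneric("coreId"))
#' @rdname CellCore
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname CellCore
#' @export
setGeneric("region", function(x) standardGeneric("region"))
#' @rdname CellCore
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))
#' @rdname CellCore
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname CellCore
#' @export
setGeneric("coreBounds", function(x) standardGeneric("coreBounds"))
#' @rdname CellCore
#' @export
setGeneric("coreArea", function(x) standardGeneric("coreArea"))

#' @rdname CellCore
#' @export
setMethod("coreId", "CellCore", function(x) x@coreId)
#' @rdname CellCore
#' @export
setMethod("patientId", "CellCore", function(x) x@patientId)
#' @rdname CellCore
#' @export
setMethod("region", "CellCore", function(x) x@region)
#' @rdname CellCore
#' @export
setMethod("panel", "CellCore", function(x) x@panel)
#' @rdname CellCore
#' @export
setMethod("cells", "CellCore", function(x) x@cells)
#' @rdname CellCore
#' @export
setMethod("coreBounds", "CellCore", function(x) x@bounds)

#' @rdname CellCore
#' @export
setMethod("coreArea", "CellCore", function(x) {
  b <- x@bounds
  ## um^2 -> mm^2
  unname((b["xmax"] - b["xmin"]) * (b["ymax"] - b["ymin"]) / 1e6)
})

setMethod("show", "CellCore", function(object) {
  cat("CellCore '", object@coreId, "' (patient ", object@patientId, ")\n",
      sep = "")
  cat("  region: ", object@region, "  panel: ", object@panel,
      "  area: ", format(coreArea(object), digits = 4), " mm^2\n", sep = "")
  cat("  cells: ", nrow(object@cells), "\n", sep = "")
  cts <- tryCatch(phenotypeCounts(object), error = function(e) NULL)
  if (!is.null(cts)) {
    cts <- cts[cts > 0]
    if (length(cts))
      cat("  phenotypes: ",
          paste(names(cts), cts, sep = "=", collapse = ", "), "\n", sep = "")
  }
})

#' SpatialFeatureSet: patient-by-feature container
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `features` assay
#' holds one row per canonical spatial feature (e.g.
#' `N(CD4Treg_to_Tumor)@IM`) and one column per patient; `colData` carries
#' survival outcome (`rfs_months`, `event`), clinical covariates and the
#' train/validation `split`. Undefined metrics (empty denominator sets) are
#' `NA`, never 0.
#'
#' @aliases SpatialFeatureSet
#' @export
setClass("SpatialFeatureSet", contains = "SummarizedExperiment")

setValidity("SpatialFeatureSet", function(object) {
  msg <- character()
  if (!"features" %in% assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  cd <- colData(object)
  for (col in c("patient_id", "rfs_months", "event"))
    if (!col %in% colnames(cd))
      msg <- c(msg, paste0("colData column '", col, "' is required"))
  if ("rfs_months" %in% colnames(cd) && any(cd$rfs_months < 0, na.rm = TRUE))
    msg <- c(msg, "rfs_months must be >= 0")
  if ("event" %in% colnames(cd) && !all(cd$event %in% c(0, 1)))
    msg <- c(msg, "event must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Construct a SpatialFeatureSet
#'
#' @param features numeric matrix, features x patients; rownames are
#'   canonical feature names, colnames patient ids.
#' @param patients data.frame with `patient_id`, `rfs_months`, `event` and
#'   any covariate columns, one row per patient (matched to columns of
#'   `features` by `patient_id`).
#' @return A [SpatialFeatureSet-class].
#' @export
SpatialFeatureSet <- function(features, patients) {
  patients <- as.data.frame(patients)
  stopifnot(!anyDuplicated(patients$patient_id))
  idx <- match(colnames(features), patients$patient_id)
  if (anyNA(idx))
    stop("patients table lacks id(s): ",
         paste(head(colnames(features)[is.na(idx)]), collapse = ", "))
  cd <- DataFrame(patients[idx, , drop = FALSE])
  rownames(cd) <- colnames(features)
  rd <- DataFrame(parseFeatureName(rownames(features)))
  new("SpatialFeatureSet", SummarizedExperiment(
    assays = list(features = features), colData = cd, rowData = rd))
}

#' @rdname SpatialFeatureSet
#' @param x A `SpatialFeatureSet`.
#' @return `featureMatrix` returns the patients x features numeric matrix
#'   (the transposed assay, the orientation model fitters expect).
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname SpatialFeatureSet
#' @export
setMethod("featureMatrix", "SpatialFeatureSet",
          function(x) t(assay(x, "features")))

#' SelectionResult: three-algorithm feature selection outcome
#'
#' Ranked feature lists from LASSO-Cox (nonzero coefficients by
#' `|coefficient|`), XGBoost (top importance) and random forest (top
#' importance), and their intersection.
#'
#' @slot lassoFeatures,xgbTop,rfTop ordered character vectors (at most 10).
#' @slot intersection character, features present in all three lists.
#' @slot config list of seeds and hyperparameters used.
#' @aliases SelectionResult
#' @export
setClass("SelectionResult",
  slots = c(lassoFeatures = "character", xgbTop = "character",
            rfTop = "character", intersection = "character",
            config = "list"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  for (nm in c("lassoFeatures", "xgbTop", "rfTop")) {
    v <- slot(object, nm)
    if (length(v) > 10L) msg <- c(msg, paste0(nm, " longer than 10"))
    if (!all(object@intersection %in% v))
      msg <- c(msg, paste0("intersection not contained in ", nm))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult\n")
  cat("  LASSO nonzero (", length(object@lassoFeatures), "): ",
      paste(object@lassoFeatures, collapse = ", "), "\n", sep = "")
  cat("  XGBoost top (", length(object@xgbTop), "): ",
      paste(object@xgbTop, collapse = ", "), "\n", sep = "")
  cat("  RF top (", length(object@rfTop), "): ",
      paste(object@rfTop, collapse = ", "), "\n", sep = "")
  cat("  intersection (", length(object@intersection), "): ",
      paste(object@intersection, collapse = ", "), "\n", sep = "")
})

#' @rdname SelectionResult
#' @param x A `SelectionResult`.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname SelectionResult
#' @export
setMethod("selectedFeatures", "SelectionResult",
          function(x) x@intersection)

#' SpatialSignature: the linear spatial immune signature (SIS)
#'
#' A linear risk score `SIS = sum(coefficient * standardized feature)` over
#' the selected spatial features, with multivariate Cox log-hazard
#' coefficients, the training-derived standardization (center/scale and
#' median imputation values), and the optimal high/low cutoff.
#'
#' @slot features canonical feature names.
#' @slot coefficients log-hazard weights, same length as `features`.
#' @slot center,scale,impute per-feature standardization and imputation
#'   constants fitted on the training split.
#' @slot cutoff numeric(1) score cutoff separating high from low risk
#'   (`NA` until set).
#' @slot trainingSummary data.frame of per-feature HR, 95% CI and p from
#'   the multivariate fit (possibly empty for hand-built models).
#' @slot config list (seeds, cutpoint policy, ...).
#' @aliases SpatialSignature
#' @export
setClass("SpatialSignature",
  slots = c(features = "character", coefficients = "numeric",
            center = "numeric", scale = "numeric", impute = "numeric",
            cutoff = "numeric", trainingSummary = "data.frame",
            config = "list"))

setValidity("SpatialSignature", function(object) {
  msg <- character()
  p <- length(object@features)
  if (length(object@coefficients) != p)
    msg <- c(msg, "features and coefficients differ in length")
  for (nm in c("center", "scale", "impute"))
    if (length(slot(object, nm)) != p)
      msg <- c(msg, paste0(nm, " must have one value per feature"))
  if (any(object@scale <= 0))
    msg <- c(msg, "scale must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SpatialSignature directly
#'
#' Builds a signature from given coefficients, e.g. a published formula,
#' without refitting. Default `center = 0`, `scale = 1` scores raw feature
#' values.
#'
#' @param features canonical feature names.
#' @param coefficients numeric weights (same length).
#' @param center,scale,impute optional standardization/imputation constants
#'   (recycled to length of `features`).
#' @param cutoff optional score cutoff.
#' @return A [SpatialSignature-class].
#' @examples
#' sig <- SpatialSignature(
#'   c("P(CD8Treg_to_CD4all)@IM", "P(CD8Treg_to_Tumor)@IM",
#'     "N(CD4Treg_to_Tumor)@IM", "N(CD4Tcon_to_Tumor)@IM"),
#'   c(1.25, 0.70, -0.67, -0.56))
#' scoreSIS(sig, rbind(c(1, 1, 1, 1)))
#' @export
SpatialSignature <- function(features, coefficients, center = 0, scale = 1,
                             impute = NA_real_, cutoff = NA_real_) {
  p <- length(features)
  new("SpatialSignature", features = features,
      coefficients = as.numeric(coefficients),
      center = rep_len(as.numeric(center), p),
      scale = rep_len(as.numeric(scale), p),
      impute = rep_len(as.numeric(impute), p),
      cutoff = as.numeric(cutoff),
      trainingSummary = data.frame(), config = list())
}

setMethod("show", "SpatialSignature", function(object) {
  cat("SpatialSignature with", length(object@features), "features\n")
  sgn <- ifelse(object@coefficients >= 0, "+", "-")
  terms <- paste0(sgn, " ", format(abs(object@coefficients), digits = 3),
                  " x [", object@features, "]")
  terms[1] <- sub("^\\+ ", "", terms[1])
  cat("  SIS =", paste(terms, collapse = " "), "\n")
  if (!is.na(object@cutoff))
    cat("  high/low cutoff:", format(object@cutoff, digits = 4), "\n")
  if (nrow(object@trainingSummary))
    cat("  trained on", object@config$n %||% "?", "patients\n")
})

#' @rdname SpatialSignature
#' @param x A `SpatialSignature`.
#' @export
setGeneric("signatureCoefficients",
           function(x) standardGeneric("signatureCoefficients"))
#' @rdname SpatialSignature
#' @export
setMethod("signatureCoefficients", "SpatialSignature",
          function(x) setNames(x@coefficients, x@features))
#' @rdname SpatialSignature
#' @export
setGeneric("signatureCutoff", function(x) standardGeneric("signatureCutoff"))
#' @rdname SpatialSignature
#' @export
setMethod("signatureCutoff", "SpatialSignature", function(x) x@cutoff)

`%||%` <- function(a, b) if (is.null(a)) b else a
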