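## Patient-level feature assembly. Canonical feature-name grammar:
##   {D|N|P}({source}[_to_{target}])@{IM|TC}
## e.g. "N(CD4Treg_to_Tumor)@IM", "D(CD8Treg)@TC". Undefined per-core
## metrics stay NA in the matrix (a core without CD8+ Tregs has no mNND
## from them; imputing 0 would claim maximal interaction) and are only
## imputed at the model-fitting boundary.

#' Canonical feature names
#'
#' @param metric `"D"`, `"N"` or `"P"`.
#' @param source,target Phenotype names (`target` ignored for `"D"`).
#' @param region `"IM"` or `"TC"`.
#' @return Character vector of canonical names.
#' @examples
#' featureName("N", "CD4Treg", "Tumor", "IM")
#' @export
featureName <- function(metric, source, target = NA, region) {
  ifelse(metric == "D",
         paste0("D(", source, ")@", region),
         paste0(metric, "(", source, "_to_", target, ")@", region))
}

#' @rdname featureName
#' @param name Canonical feature name(s) to parse.
#' @return `parseFeatureName` returns a data.frame with `metric`, `source`,
#'   `target`, `region`.
#' @export
parseFeatureName <- function(name) {
  m <- regmatches(name,
    regexec("^([DNP])\\(([^)_]+)(_to_([^)]+))?\\)@(IM|TC)$", name))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("malformed feature name(s): ", paste(head(name[bad]), collapse = ", "))
  data.frame(
    metric = vapply(m, `[`, character(1), 2L),
    source = vapply(m, `[`, character(1), 3L),
    target = ifelse(vapply(m, `[`, character(1), 5L) == "",
                    NA_character_, vapply(m, `[`, character(1), 5L)),
    region = vapply(m, `[`, character(1), 6L),
    row.names = name, stringsAsFactors = FALSE)
}

## long metric table -> patients x features matrix; duplicate cores per
## (patient, region) averaged over their defined values
.featureWide <- function(metricTable) {
  mt <- metricTable
  mt$feature <- featureName(mt$metric, mt$source, mt$target, mt$region)
  mt$value[!mt$defined] <- NA_real_
  feats <- unique(mt$feature)
  pats <- unique(mt$patient_id)
  out <- matrix(NA_real_, nrow = length(pats), ncol = length(feats),
                dimnames = list(pats, feats))
  agg <- tapply(mt$value, list(mt$patient_id, mt$feature),
                function(v) if (all(is.na(v))) NA_real_
                            else mean(v, na.rm = TRUE))
  out[rownames(agg), colnames(agg)] <- agg
  out
}

#' Assemble the patient-by-feature matrix
#'
#' Combines a long-format metric table (from [cohortMetrics()]) with the
#' patient clinical table into a [SpatialFeatureSet]. Duplicate cores for
#' the same patient and region are averaged over their defined values;
#' metrics undefined in every core remain `NA`. Patients with no cores are
#' dropped with a warning.
#'
#' @param metricTable Long-format metrics
#'   (`patient_id, core_id, region, metric, source, target, radius_um,
#'   value, n_source, n_target, defined`).
#' @param patients Patient clinical table ([readPatientTable()] format).
#' @return A [SpatialFeatureSet].
#' @export
buildFeatureMatrix <- function(metricTable, patients) {
  patients <- as.data.frame(patients)
  wide <- .featureWide(metricTable)
  noCores <- setdiff(patients$patient_id, rownames(wide))
  if (length(noCores)) {
    warning("excluding patient(s) with zero cores: ",
            paste(head(noCores), collapse = ", "))
    patients <- patients[!patients$patient_id %in% noCores, , drop = FALSE]
  }
  wide <- wide[match(patients$patient_id, rownames(wide)), , drop = FALSE]
  SpatialFeatureSet(t(wide), patients)
}

#' Mann-Whitney U comparison of a feature between two groups
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie
#' correction). The reported `U` is the number of (group1, group2) pairs
#' won by group 1, counting ties as half.
#'
#' @param values Numeric feature values (`NA` dropped).
#' @param groups Two-level factor/character vector aligned to `values`.
#' @return list `U`, `p`, `n1`, `n2`, `groups`.
#' @examples
#' compareGroups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
#' @export
compareGroups <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  lv <- unique(groups)
  if (length(lv) != 2L)
    stop("need exactly two groups, got ", length(lv))
  x <- values[groups == lv[1]]; y <- values[groups == lv[2]]
  if (!length(x) || !length(y)) stop("a group is empty")
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = FALSE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # zero-variance rank configuration
  list(U = unname(wt$statistic), p = p,
       n1 = length(x), n2 = length(y), groups = lv)
}

#' Dichotomize a feature for survival analysis
#'
#' Splits patients into high/low groups, either at the survival-optimal
#' cutpoint (policy `"xtile"`, see [optimalCutpoint()]) or at the median.
#'
#' @param values Feature values (>= 20 defined values required).
#' @param times,events Survival outcome aligned to `values` (needed for
#'   `"xtile"`).
#' @param policy `"xtile"` or `"median"`.
#' @param minGroupFrac Minimum fraction of patients per arm for `"xtile"`.
#' @return list `labels` (factor `low`/`high`, `NA` where value missing),
#'   `cutoff`, `policy`.
#' @export
dichotomizeFeature <- function(values, times = NULL, events = NULL,
                               policy = c("xtile", "median"),
                               minGroupFrac = 0.1) {
  policy <- match.arg(policy)
  ok <- !is.na(values)
  if (sum(ok) < 20L)
    stop("need >= 20 patients with defined values, got ", sum(ok))
  if (length(unique(values[ok])) < 2L)
    stop("all feature values identical; no admissible cutoff")
  if (policy == "median") {
    cutoff <- median(values[ok])
    if (!any(values[ok] > cutoff))  # all mass at/below the median value
      stop("median split leaves one group empty")
  } else {
    if (is.null(times) || is.null(events))
      stop("policy 'xtile' needs survival times and events")
    cp <- optimalCutpoint(values[ok], times[ok], events[ok],
                          minGroupFrac = minGroupFrac)
    cutoff <- cp$cutoff
  }
  labels <- factor(ifelse(values > cutoff, "high", "low"),
                   levels = c("low", "high"))
  list(labels = labels, cutoff = cutoff, policy = policy)
}
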