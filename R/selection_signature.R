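## Feature selection by three-algorithm intersection and the Spatial
## Immune Signature (SIS). LASSO is an L1-penalized Cox fit (the features
## feed a survival signature; a logistic variant on the event indicator is
## available), XGBoost and random forest are fit to the binary event
## indicator and ranked by gain / Gini importance. The SIS is the linear
## combination of the intersected features weighted by multivariate Cox
## coefficients estimated on the training split, with standardization and
## median imputation fitted on the training split only and re-applied at
## scoring time (a leakage guard).

#' Stratified train/validation split
#'
#' Assigns patients to training and validation sets at the given ratio.
#' With stratification, each stratum contributes its proportional share of
#' training patients (largest-remainder rounding, so per-stratum
#' proportions match within one patient); strata smaller than 2 are merged
#' into a pooled stratum with a warning.
#'
#' @param patients Patient table with `patient_id`.
#' @param ratio Training fraction in (0, 1); training size is
#'   `round(ratio * n)`.
#' @param stratifyOn Covariate column names to balance, or `NULL`.
#' @param seed Integer seed.
#' @return Character vector (`"train"`/`"validation"`) aligned to the rows
#'   of `patients`.
#' @examples
#' pts <- data.frame(patient_id = sprintf("P%03d", 1:261))
#' table(splitCohort(pts, 0.7, seed = 1))  # 183 train / 78 validation
#' @export
splitCohort <- function(patients, ratio = 0.7, stratifyOn = NULL, seed = 1) {
  patients <- as.data.frame(patients)
  n <- nrow(patients)
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("ratio must be in (0, 1)")
  nTrain <- round(ratio * n)
  set.seed(seed)
  if (is.null(stratifyOn)) {
    strata <- factor(rep("all", n))
  } else {
    strata <- interaction(patients[stratifyOn], drop = TRUE)
    small <- names(which(table(strata) < 2L))
    if (length(small)) {
      warning("merging stratum(s) with < 2 patients: ",
              paste(small, collapse = ", "))
      levels(strata)[levels(strata) %in% small] <- ".merged"
    }
  }
  sizes <- table(strata)
  quota <- ratio * as.numeric(sizes)
  alloc <- floor(quota)
  rem <- nTrain - sum(alloc)
  if (rem > 0) {
    ord <- order(quota - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(quota - alloc)
    take <- ord[seq_len(-rem)]
    alloc[take] <- alloc[take] - 1L
  }
  split <- rep("validation", n)
  for (s in seq_along(sizes)) {
    idx <- which(strata == names(sizes)[s])
    split[sample(idx, alloc[s])] <- "train"
  }
  split
}

## training-fitted standardization: median imputation then z-score
.fitStandardizer <- function(X) {
  impute <- apply(X, 2L, median, na.rm = TRUE)
  impute[!is.finite(impute)] <- 0
  Xi <- X
  for (j in seq_len(ncol(X))) Xi[is.na(Xi[, j]), j] <- impute[j]
  center <- colMeans(Xi)
  scale <- apply(Xi, 2L, sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  list(impute = impute, center = center, scale = scale)
}

.applyStandardizer <- function(X, std) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- std$impute[j]
  scale(X, center = std$center, scale = std$scale)[, , drop = FALSE]
}

#' Feature selection by LASSO / XGBoost / random-forest intersection
#'
#' Fits the three learners on the (training) feature matrix and returns
#' their ranked top features and the intersection. LASSO: L1-penalized Cox
#' (or logistic) with the penalty chosen by 10-fold cross-validation at
#' minimum deviance; up to ten nonzero-coefficient features ranked by
#' absolute coefficient. XGBoost: gradient boosting on the event
#' indicator, top ten by gain. Random forest: classification forest on the
#' event indicator, top ten by mean decrease in Gini impurity. Features
#' are median-imputed and z-scored (training statistics) before fitting.
#'
#' @param X Patients x features matrix (training split, raw scale).
#' @param times,events Survival outcome for the same patients.
#' @param nTop List length cap (default 10).
#' @param lassoTarget `"cox"` or `"logistic"`.
#' @param seed Integer seed governing the CV folds and both forests.
#' @param xgbParams,rfParams Hyperparameter overrides.
#' @return A [SelectionResult-class]. An empty LASSO set yields an empty
#'   intersection with a warning.
#' @export
selectFeatures <- function(X, times, events, nTop = 10,
                           lassoTarget = c("cox", "logistic"), seed = 1,
                           xgbParams = list(), rfParams = list()) {
  lassoTarget <- match.arg(lassoTarget)
  X <- as.matrix(X)
  if (nrow(X) < 20L) stop("need >= 20 training patients")
  .checkSurv(times, events)
  std <- .fitStandardizer(X)
  Z <- .applyStandardizer(X, std)

  ## LASSO
  set.seed(seed)
  y <- if (lassoTarget == "cox")
    survival::Surv(times, events) else as.numeric(events)
  cv <- glmnet::cv.glmnet(Z, y,
                          family = if (lassoTarget == "cox") "cox"
                                   else "binomial",
                          nfolds = 10, standardize = FALSE)
  cf <- as.matrix(glmnet::coef.glmnet(cv, s = "lambda.min"))
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  nz <- cf[cf[, 1] != 0, 1]
  lassoFeatures <- as.character(head(names(sort(abs(nz),
                                                decreasing = TRUE)), nTop))
  if (!length(lassoFeatures))
    warning("LASSO retained no features; intersection is empty")

  ## XGBoost on the event indicator, gain importance
  xp <- modifyList(list(max_depth = 3, eta = 0.1, nrounds = 100,
                        subsample = 1, nthread = 1), xgbParams)
  set.seed(seed + 1L)
  dtrain <- xgboost::xgb.DMatrix(Z, label = as.numeric(events))
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = xp$max_depth,
                  eta = xp$eta, subsample = xp$subsample,
                  nthread = xp$nthread),
    data = dtrain, nrounds = xp$nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  xgbTop <- head(imp$Feature, nTop)

  ## random forest on the event indicator, Gini importance
  rp <- modifyList(list(ntree = 500), rfParams)
  set.seed(seed + 2L)
  rf <- randomForest::randomForest(x = Z, y = factor(events),
                                   ntree = rp$ntree)
  gini <- sort(rf$importance[, "MeanDecreaseGini"], decreasing = TRUE)
  rfTop <- head(names(gini), nTop)

  xgbTop <- as.character(xgbTop)
  inter <- intersect(intersect(lassoFeatures, xgbTop), rfTop)
  new("SelectionResult", lassoFeatures = lassoFeatures, xgbTop = xgbTop,
      rfTop = rfTop, intersection = inter,
      config = list(seed = seed, nTop = nTop, lassoTarget = lassoTarget,
                    lambda = unname(cv$lambda.min), xgb = xp, rf = rp))
}

#' Fit the Spatial Immune Signature
#'
#' Multivariate Cox regression of the selected features on the training
#' split; the signature score is the Cox linear predictor
#' `sum(coef * z-scored feature)`, and the high/low cutoff is the
#' survival-optimal cutpoint of the training scores (or their median).
#'
#' @param X Training patients x features matrix (raw scale).
#' @param times,events Training survival outcome.
#' @param features Selected canonical feature names (non-empty).
#' @param cutpointPolicy `"xtile"` or `"median"`.
#' @param minGroupFrac Passed to [optimalCutpoint()].
#' @return A [SpatialSignature-class].
#' @export
fitSignature <- function(X, times, events, features,
                         cutpointPolicy = c("xtile", "median"),
                         minGroupFrac = 0.1) {
  cutpointPolicy <- match.arg(cutpointPolicy)
  if (!length(features)) stop("no features selected")
  X <- as.matrix(X)
  missing <- setdiff(features, colnames(X))
  if (length(missing))
    stop("feature(s) absent from matrix: ", paste(missing, collapse = ", "))
  if (sum(events) < 10L)
    stop("too few events (", sum(events), ") to fit the signature")
  Xs <- X[, features, drop = FALSE]
  std <- .fitStandardizer(Xs)
  Z <- .applyStandardizer(Xs, std)
  fit <- coxFit(Z, times, events)
  sig <- new("SpatialSignature", features = features,
             coefficients = fit$table$coef,
             center = unname(std$center), scale = unname(std$scale),
             impute = unname(std$impute), cutoff = NA_real_,
             trainingSummary = fit$table,
             config = list(n = fit$n, nEvent = fit$nEvent,
                           cutpointPolicy = cutpointPolicy))
  score <- scoreSIS(sig, X)
  cutoff <- if (cutpointPolicy == "xtile")
    optimalCutpoint(score, times, events, minGroupFrac)$cutoff
  else median(score)
  sig@cutoff <- cutoff
  validObject(sig)
  sig
}

#' Score patients with a SpatialSignature
#'
#' `SIS = sum(coefficient * standardized feature)`; standardization and
#' median imputation use the constants stored in the signature (identity
#' for hand-built signatures). Missing values without a stored imputation
#' constant are an error.
#'
#' @param signature A [SpatialSignature-class].
#' @param x A [SpatialFeatureSet], a patients x features matrix, or a
#'   single named feature vector.
#' @return Numeric score vector, one per patient.
#' @export
scoreSIS <- function(signature, x) {
  stopifnot(is(signature, "SpatialSignature"))
  if (is(x, "SpatialFeatureSet")) x <- featureMatrix(x)
  if (is.null(dim(x))) {
    if (is.null(names(x)) && length(x) == length(signature@features))
      names(x) <- signature@features
    x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  }
  missing <- setdiff(signature@features, colnames(x))
  if (length(missing))
    stop("feature(s) absent: ", paste(missing, collapse = ", "))
  M <- x[, signature@features, drop = FALSE]
  for (j in seq_along(signature@features)) {
    nas <- is.na(M[, j])
    if (any(nas)) {
      if (is.na(signature@impute[j]))
        stop("missing value for '", signature@features[j],
             "' and no imputation constant stored")
      M[nas, j] <- signature@impute[j]
    }
  }
  Z <- sweep(sweep(M, 2L, signature@center), 2L, signature@scale, `/`)
  drop(Z %*% signature@coefficients)
}
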