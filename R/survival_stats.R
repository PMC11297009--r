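## Survival machinery used across the pipeline. Standard estimators are
## delegated to the `survival` package (product-limit curves, log-rank,
## Cox partial likelihood with Efron tie handling); the outcome-driven
## optimal cutpoint and the IPCW time-dependent AUC are implemented here.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with simultaneous handling of tied event times.
#' The median is the earliest time with survival <= 0.5, or "not reached".
#'
#' @param times Follow-up in months (>= 0).
#' @param events 0/1 event indicator.
#' @return Object of class `KMCurve`: `time`, `surv`, `nRisk`, `nEvent`,
#'   `median` (`NA` if not reached), `medianReached`, `n`.
#' @examples
#' km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
#' km$surv  # 2/3, 1/3, 0
#' @export
kmEstimate <- function(times, events) {
  .checkSurv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  medianIdx <- which(fit$surv <= 0.5)
  med <- if (length(medianIdx)) fit$time[min(medianIdx)] else NA_real_
  structure(list(time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
                 nEvent = fit$n.event, median = med,
                 medianReached = !is.na(med), n = length(times)),
            class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
  cat("Kaplan-Meier curve, n =", x$n, "\n")
  cat("  median survival:",
      if (x$medianReached) paste(format(x$median, digits = 4), "months")
      else "not reached", "\n")
  invisible(x)
}

.checkSurv <- function(times, events) {
  if (!length(times)) stop("no subjects")
  if (any(!is.finite(times)) || any(times < 0))
    stop("survival times must be finite and >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (length(times) != length(events))
    stop("times and events differ in length")
}

#' Log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance;
#' two-sided p from a chi-square with (groups - 1) df.
#'
#' @param times,events Survival outcome.
#' @param group Group labels (>= 2 non-empty groups).
#' @return list `chisq`, `df`, `p`, `n`, `obs`, `exp`.
#' @export
logrankTest <- function(times, events, group) {
  .checkSurv(times, events)
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L)
    stop("need >= 2 non-empty groups, got ", nlevels(group))
  if (any(table(group) == 0L)) stop("a group is empty")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group, rho = 0)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df = df, lower.tail = FALSE),
       n = length(times), obs = unname(sd$obs), exp = unname(sd$exp))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event
#' times; Wald confidence intervals and p-values.
#'
#' @param x Covariate matrix or data.frame (patients in rows).
#' @param times,events Survival outcome.
#' @param conf Confidence level for the hazard-ratio intervals.
#' @return Object of class `CoxFit`: `table` (term, coef, se, HR, lower,
#'   upper, p), `n`, `nEvent`, `loglik`, `fit` (the underlying
#'   `survival::coxph` fit).
#' @export
coxFit <- function(x, times, events, conf = 0.95) {
  .checkSurv(times, events)
  x <- as.data.frame(x)
  if (sum(events) < ncol(x) + 1L)
    stop("too few events (", sum(events), ") for ", ncol(x), " covariates")
  degenerate <- vapply(x, function(v) length(unique(v[!is.na(v)])) < 2L,
                       logical(1))
  if (any(degenerate))
    stop("covariate(s) with no variation: ",
         paste(colnames(x)[degenerate], collapse = ", "))
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ ., data = x,
                    ties = "efron"),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w), call. = FALSE))
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("Cox fit produced undefined coefficient(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  se <- sqrt(diag(stats::vcov(fit)))
  zq <- qnorm(1 - (1 - conf) / 2)
  tab <- data.frame(term = names(beta), coef = unname(beta),
                    se = unname(se), HR = exp(unname(beta)),
                    lower = exp(unname(beta - zq * se)),
                    upper = exp(unname(beta + zq * se)),
                    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n = fit$n, nEvent = fit$nevent,
                 loglik = fit$loglik[2], fit = fit),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, digits = 3, ...) {
  cat("Cox proportional-hazards fit (Efron ties): n =", x$n,
      ", events =", x$nEvent, "\n")
  tab <- x$table
  tab$`HR (95% CI)` <- sprintf("%.2f (%.2f, %.2f)", tab$HR, tab$lower,
                               tab$upper)
  print(tab[, c("term", "coef", "HR (95% CI)", "p")], digits = digits,
        row.names = FALSE)
  invisible(x)
}

#' Survival-optimal cutpoint (X-tile-style)
#'
#' Scans every midpoint between consecutive unique score values that
#' leaves at least `minGroupFrac` of subjects in each arm and returns the
#' cutoff maximizing the two-group log-rank chi-square; ties are broken
#' toward the more balanced split. The maximal chi-square is selected
#' without a multiple-testing correction, so the associated p-value is
#' optimistic and flagged as such.
#'
#' @param score Numeric risk score (non-constant).
#' @param times,events Survival outcome.
#' @param minGroupFrac Minimum fraction of subjects per arm.
#' @return list `cutoff`, `chisq`, `p` (uncorrected, optimistic), `nLow`,
#'   `nHigh`.
#' @export
optimalCutpoint <- function(score, times, events, minGroupFrac = 0.1) {
  .checkSurv(times, events)
  if (length(score) != length(times)) stop("score length mismatch")
  if (anyNA(score)) stop("score contains NA")
  u <- sort(unique(score))
  if (length(u) < 2L) stop("score is constant; no admissible cutoff")
  mids <- (u[-length(u)] + u[-1]) / 2
  n <- length(score)
  minN <- ceiling(minGroupFrac * n)
  best <- NULL
  for (ct in mids) {
    nLow <- sum(score <= ct)
    if (nLow < minN || (n - nLow) < minN) next
    grp <- score > ct
    sd <- survival::survdiff(survival::Surv(times, events) ~ grp, rho = 0)
    bal <- abs(nLow - n / 2)
    if (is.null(best) || sd$chisq > best$chisq + 1e-12 ||
        (abs(sd$chisq - best$chisq) <= 1e-12 && bal < best$bal)) {
      best <- list(cutoff = ct, chisq = unname(sd$chisq), bal = bal,
                   nLow = nLow, nHigh = n - nLow)
    }
  }
  if (is.null(best))
    stop("no cutpoint leaves >= ", minN, " subjects in each arm")
  best$bal <- NULL
  best$p <- pchisq(best$chisq, df = 1, lower.tail = FALSE)
  best[c("cutoff", "chisq", "p", "nLow", "nHigh")]
}

## left-continuous censoring-survival G(t-): KM of the censoring process
.censoringSurvLeft <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  function(t) {
    idx <- which(fit$time < t)
    if (!length(idx)) 1 else fit$surv[max(idx)]
  }
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative-case / dynamic-control AUC at a horizon: cases are subjects
#' with an observed event by the horizon (weighted by `1/G(T-)`, `G` the
#' Kaplan-Meier censoring-survival curve), controls are subjects still
#' event-free past the horizon (weighted by `1/G(horizon)`). With no
#' censoring this reduces to the plain Mann-Whitney AUC of cases versus
#' survivors.
#'
#' @param score Risk score (higher = riskier).
#' @param times,events Survival outcome.
#' @param horizon Evaluation time in months.
#' @return Object of class `TimeROC`: `horizon`, `auc`, `nCases`,
#'   `nControls`, `weighting`.
#' @export
timeDependentAUC <- function(score, times, events, horizon) {
  .checkSurv(times, events)
  if (length(score) != length(times)) stop("score length mismatch")
  caseIdx <- which(times <= horizon & events == 1)
  ctrlIdx <- which(times > horizon)
  if (!length(caseIdx)) stop("no events before the horizon")
  if (!length(ctrlIdx)) stop("no subjects at risk past the horizon")
  G <- .censoringSurvLeft(times, events)
  wCase <- vapply(times[caseIdx], function(t) {
    g <- G(t)
    if (g <= 0) 0 else 1 / g
  }, numeric(1))
  gH <- G(horizon)
  wCtrl <- rep(if (gH <= 0) 0 else 1 / gH, length(ctrlIdx))
  sc <- score[caseIdx]; sv <- score[ctrlIdx]
  num <- 0
  for (i in seq_along(sc)) {
    num <- num + wCase[i] *
      sum(wCtrl * ((sc[i] > sv) + 0.5 * (sc[i] == sv)))
  }
  den <- sum(wCase) * sum(wCtrl)
  structure(list(horizon = horizon, auc = num / den,
                 nCases = length(caseIdx), nControls = length(ctrlIdx),
                 weighting = "ipcw"),
            class = "TimeROC")
}

#' @export
print.TimeROC <- function(x, ...) {
  cat(sprintf("Time-dependent AUC (IPCW) at %g months: %.3f (%d cases, %d controls)\n",
              x$horizon, x$auc, x$nCases, x$nControls))
  invisible(x)
}
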