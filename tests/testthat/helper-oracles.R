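# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use plain O(n^2) double loops / closed formulas so they share
# no code with the package implementations they check.

# nearest-neighbor distances: plain double loop, excluding identical ids
bfNNDist <- function(ax, ay, aid, bx, by, bid) {
  vapply(seq_along(ax), function(i) {
    keep <- bid != aid[i]
    if (!any(keep)) return(Inf)
    min(sqrt((ax[i] - bx[keep])^2 + (ay[i] - by[keep])^2))
  }, numeric(1))
}

# count of A points within closed radius r of each B point, excluding ids
bfCountWithin <- function(ax, ay, aid, bx, by, bid, r) {
  vapply(seq_along(bx), function(j) {
    keep <- aid != bid[j]
    sum(sqrt((ax[keep] - bx[j])^2 + (ay[keep] - by[j])^2) <= r)
  }, numeric(1))
}

# brute-force mNND / proximity on a CellCore via row scans over gated cells
bfCoreMNND <- function(core, src, tgt) {
  cl <- cells(core)
  a <- which(gateMask(core, src)); b <- which(gateMask(core, tgt))
  if (!length(a) || !length(b)) return(NA_real_)
  d <- bfNNDist(cl$x[a], cl$y[a], a, cl$x[b], cl$y[b], b)
  if (any(!is.finite(d))) return(NA_real_)
  mean(d)
}

bfCoreProximity <- function(core, src, tgt, r = 30) {
  cl <- cells(core)
  a <- which(gateMask(core, src)); b <- which(gateMask(core, tgt))
  if (!length(b)) return(NA_real_)
  if (!length(a)) return(0)
  mean(bfCountWithin(cl$x[a], cl$y[a], a, cl$x[b], cl$y[b], b, r))
}

# random core with independent marker positivities (overlapping gates on
# purpose: CK+FOXP3+ cells, CD4+CD8+ cells etc. exercise the hierarchy)
randomCore <- function(n, seed, panel = "panel1", width = 1000,
                       height = 1000, coreId = "rc", patientId = "rp",
                       region = "IM", probs = NULL) {
  set.seed(seed)
  markers <- panelMarkers(panel)
  if (is.null(probs))
    probs <- setNames(rep(0.3, length(markers)), markers)
  cl <- data.frame(cell_id = sprintf("c%04d", seq_len(n)),
                   x = runif(n, 0, width), y = runif(n, 0, height))
  for (mk in markers) cl[[mk]] <- runif(n) < probs[[mk]]
  CellCore(cl, coreId = coreId, patientId = patientId, region = region,
           panel = panel, bounds = c(width, height))
}

# a core from an explicit coordinate/marker table (1 mm^2 window)
miniCore <- function(df, region = "IM", panel = "panel1",
                     bounds = c(1000, 1000)) {
  if (!"cell_id" %in% colnames(df))
    df$cell_id <- sprintf("c%03d", seq_len(nrow(df)))
  for (mk in setdiff(panelMarkers(panel), colnames(df)))
    df[[mk]] <- logical(nrow(df))
  CellCore(df, coreId = paste0("mini_", region), patientId = "pm",
           region = region, panel = panel, bounds = bounds)
}

# hand product-limit estimator
bfKM <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- numeric(length(ut)); cur <- 1
  for (k in seq_along(ut)) {
    nRisk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events == 1)
    cur <- cur * (1 - d / nRisk)
    s[k] <- cur
  }
  list(time = ut, surv = s)
}

# hand two-group log-rank chi-square (hypergeometric variance)
bfLogrank <- function(times, events, group) {
  g1 <- group == sort(unique(group))[1]
  ut <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    atRisk <- times >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# hand Efron log partial-likelihood for a single covariate
bfEfronLoglik <- function(beta, x, times, events) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    sumR <- sum(exp(x[R] * beta))
    sumD <- sum(exp(x[D] * beta))
    ll <- ll + sum(x[D]) * beta -
      sum(log(sumR - (seq_len(d) - 1) / d * sumD))
  }
  ll
}

# plain Mann-Whitney AUC of scores: cases vs controls
bfAUC <- function(scoreCases, scoreControls) {
  s <- 0
  for (sc in scoreCases)
    s <- s + sum(sc > scoreControls) + 0.5 * sum(sc == scoreControls)
  s / (length(scoreCases) * length(scoreControls))
}
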