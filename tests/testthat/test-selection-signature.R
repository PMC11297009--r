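test_that("cohort splitting hits the 7:3 arithmetic and stratum balance", {
  pts <- data.frame(patient_id = sprintf("P%03d", 1:261))
  sp <- splitCohort(pts, ratio = 0.7, seed = 1)
  expect_equal(sum(sp == "train"), 183L)
  expect_equal(sum(sp == "validation"), 78L)

  sp2 <- splitCohort(data.frame(patient_id = letters[1:10]), ratio = 0.5,
                     seed = 2)
  expect_equal(as.integer(table(sp2)), c(5L, 5L))

  expect_error(splitCohort(pts, ratio = 1), "ratio")

  # stratified: per-stratum training proportion within one patient of 0.7
  set.seed(5)
  for (seed in 1:20) {
    pts$stage_group <- sample(c("I-II", "III"), 261, TRUE, c(0.8, 0.2))
    sp <- splitCohort(pts, 0.7, stratifyOn = "stage_group", seed = seed)
    expect_equal(sum(sp == "train"), 183L)
    for (s in unique(pts$stage_group)) {
      ns <- sum(pts$stage_group == s)
      nt <- sum(sp == "train" & pts$stage_group == s)
      expect_lte(abs(nt - 0.7 * ns), 1)
    }
  }

  # singleton strata are merged with a warning
  pts$stage_group[1] <- "III"
  pts$odd <- c("rare", rep(c("u", "v"), 130))
  expect_warning(splitCohort(pts, 0.7, stratifyOn = "odd", seed = 1),
                 "merging")
})

test_that("the three-algorithm selection recovers a planted signal", {
  set.seed(42)
  n <- 250; pSignal <- 3; pNull <- 15
  X <- matrix(rnorm(n * (pSignal + pNull)), nrow = n)
  colnames(X) <- c(paste0("sig", seq_len(pSignal)),
                   paste0("null", seq_len(pNull)))
  betas <- setNames(c(1.0, 0.9, 0.8), paste0("sig", 1:3))
  s <- simulateSurvival(X, hazardSimParams(betas = betas))
  res <- selectFeatures(X, s$rfs_months, s$event, seed = 7)
  expect_s4_class(res, "SelectionResult")
  expect_true(all(selectedFeatures(res) %in% res@lassoFeatures))
  expect_true(all(selectedFeatures(res) %in% res@xgbTop))
  expect_true(all(selectedFeatures(res) %in% res@rfTop))
  expect_lte(length(res@lassoFeatures), 10L)
  expect_true(all(paste0("sig", 1:3) %in% selectedFeatures(res)))

  # reproducibility under a fixed seed
  res2 <- selectFeatures(X, s$rfs_months, s$event, seed = 7)
  expect_identical(res@lassoFeatures, res2@lassoFeatures)
  expect_identical(res@xgbTop, res2@xgbTop)
  expect_identical(res@rfTop, res2@rfTop)

  expect_error(selectFeatures(X[1:10, ], s$rfs_months[1:10], s$event[1:10]),
               ">= 20")
})

test_that("an all-null cohort mostly yields an empty intersection", {
  set.seed(77)
  empties <- replicate(5, {
    X <- matrix(rnorm(120 * 20), nrow = 120,
                dimnames = list(NULL, paste0("f", 1:20)))
    s <- simulateSurvival(X, hazardSimParams(betas = numeric()))
    res <- suppressWarnings(
      selectFeatures(X, s$rfs_months, s$event, seed = 1))
    length(selectedFeatures(res)) <= 2
  })
  expect_gte(mean(empties), 0.6)
})

test_that("the SIS linear form reproduces the published arithmetic", {
  sig <- SpatialSignature(
    c("P(CD8Treg_to_CD4all)@IM", "P(CD8Treg_to_Tumor)@IM",
      "N(CD4Treg_to_Tumor)@IM", "N(CD4Tcon_to_Tumor)@IM"),
    c(1.25, 0.70, -0.67, -0.56))
  v <- function(...) {
    m <- rbind(c(...))
    colnames(m) <- sig@features
    m
  }
  expect_equal(scoreSIS(sig, v(0, 0, 0, 0)), 0)
  expect_equal(scoreSIS(sig, v(1, 0, 0, 0)), 1.25)
  expect_equal(scoreSIS(sig, v(1, 1, 1, 1)), 0.72)

  # linearity: score(a v) = a score(v); score(v + w) = score(v) + score(w)
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(1); vv <- rnorm(4); ww <- rnorm(4)
    expect_equal(scoreSIS(sig, v(a * vv)), a * scoreSIS(sig, v(vv)),
                 tolerance = 1e-12)
    expect_equal(scoreSIS(sig, v(vv + ww)),
                 scoreSIS(sig, v(vv)) + scoreSIS(sig, v(ww)),
                 tolerance = 1e-12)
  }

  expect_error(scoreSIS(sig, rbind(c(x = 1))), "absent")
})

test_that("fitSignature estimates Cox weights and a training cutoff", {
  set.seed(55)
  n <- 200
  X <- matrix(rnorm(n * 4), nrow = n,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  s <- simulateSurvival(X, hazardSimParams(betas = c(a = 0.9, b = -0.8)))
  sig <- fitSignature(X, s$rfs_months, s$event, c("a", "b", "c", "d"))
  co <- signatureCoefficients(sig)
  expect_gt(co["a"], 0); expect_lt(co["b"], 0)
  expect_lt(abs(co["c"]), 0.4)
  expect_false(is.na(signatureCutoff(sig)))
  expect_equal(nrow(sig@trainingSummary), 4L)

  # scoring equals the Cox linear predictor on standardized features
  sc <- scoreSIS(sig, X)
  grp <- sc > signatureCutoff(sig)
  expect_true(all(table(grp) >= 0.1 * n - 1))

  # scoring with NA falls back to the stored training medians
  X2 <- X[1:5, ]; X2[2, "a"] <- NA
  expect_length(scoreSIS(sig, X2), 5L)

  expect_error(fitSignature(X, s$rfs_months, rep(0, n), c("a", "b")),
               "few events|events")
  expect_error(fitSignature(X, s$rfs_months, s$event, character()),
               "no features")
})

test_that("null planted coefficients straddle zero with nominal coverage", {
  set.seed(66)
  cover <- replicate(40, {
    X <- matrix(rnorm(150), ncol = 1, dimnames = list(NULL, "f"))
    s <- simulateSurvival(X, hazardSimParams(betas = c(f = 0)))
    fit <- coxFit(data.frame(f = X[, 1]), s$rfs_months, s$event)
    fit$table$lower <= 1 && fit$table$upper >= 1
  })
  expect_gte(mean(cover), 0.85)
})
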