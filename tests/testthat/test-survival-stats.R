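test_that("Kaplan-Meier estimates match hand-computed product limits", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)

  allc <- kmEstimate(c(5, 8, 12), c(0, 0, 0))
  expect_true(all(allc$surv == 1))
  expect_false(allc$medianReached)

  # 10-subject mixed example against the hand product-limit oracle
  t10 <- c(1, 2, 2, 3, 4, 4, 5, 6, 8, 9)
  e10 <- c(1, 1, 0, 1, 1, 0, 0, 1, 1, 0)
  km <- kmEstimate(t10, e10)
  hand <- bfKM(t10, e10)
  expect_equal(km$surv[km$nEvent > 0], hand$surv)

  # without censoring, KM is the empirical survival function
  set.seed(2)
  t <- sample(1:50, 25, replace = TRUE)
  km <- kmEstimate(t, rep(1, 25))
  expect_equal(km$surv, vapply(km$time, function(u) mean(t > u), numeric(1)))

  expect_error(kmEstimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("log-rank matches the hand statistic and is label-invariant", {
  t <- c(1, 3, 4, 5, 7, 10); e <- c(1, 1, 0, 1, 1, 0)
  g <- c("a", "a", "a", "b", "b", "b")
  got <- logrankTest(t, e, g)
  expect_equal(got$chisq, bfLogrank(t, e, g), tolerance = 1e-12)
  expect_equal(got$df, 1L)
  relab <- logrankTest(t, e, ifelse(g == "a", "z", "y"))
  expect_equal(relab$chisq, got$chisq)

  # identical groups: statistic 0, p = 1
  t2 <- rep(c(2, 5, 9), 2); e2 <- rep(c(1, 1, 0), 2)
  same <- logrankTest(t2, e2, rep(c("x", "y"), each = 3))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  expect_error(logrankTest(t, e, rep("a", 6)), "groups")

  # power check: planted HR well above 1 is detected
  set.seed(14)
  hits <- replicate(30, {
    g <- rep(0:1, each = 150)
    tt <- rexp(300, 0.02 * 2.5^g)
    ee <- as.integer(tt < 60); tt <- pmin(tt, 60)
    logrankTest(tt, ee, g)$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Cox fits maximize the Efron partial likelihood", {
  # tiny fixture with ties: fitted loglik equals the hand Efron
  # log partial-likelihood at the fitted coefficient, and the fitted
  # coefficient matches a grid search
  x <- c(0, 0, 1, 1, 0, 1, 0, 1)
  t <- c(2, 3, 3, 4, 6, 6, 8, 9)
  e <- c(1, 1, 1, 0, 1, 1, 1, 1)
  fit <- coxFit(data.frame(x = x), t, e)
  b <- fit$table$coef
  expect_equal(fit$loglik, bfEfronLoglik(b, x, t, e), tolerance = 1e-6)
  grid <- seq(-3, 3, by = 1e-3)
  ll <- vapply(grid, bfEfronLoglik, numeric(1), x = x, times = t, events = e)
  expect_equal(b, grid[which.max(ll)], tolerance = 2e-3)
  expect_true(all(fit$table$lower > 0))
  expect_equal(fit$table$HR, exp(b))

  # recovery: true HR 2 on a binary covariate
  set.seed(6)
  g <- rep(0:1, each = 500)
  tt <- rexp(1000, 0.02 * 2^g)
  ee <- as.integer(tt < 72); tt <- pmin(tt, 72)
  hr <- coxFit(data.frame(g = g), tt, ee)$table$HR
  expect_gt(hr, 1.7); expect_lt(hr, 2.35)

  expect_error(coxFit(data.frame(x = rep(1, 8)), t, e), "variation")
  expect_error(coxFit(data.frame(x = x), t, rep(0, 8)), "few events")
})

test_that("the optimal cutpoint maximizes log-rank separation", {
  # planted hazard jump at score 60
  set.seed(19)
  hits <- replicate(20, {
    score <- 1:100
    tt <- rexp(100, ifelse(score > 60, 0.15, 0.02))
    ee <- as.integer(tt < 60); tt <- pmin(tt, 60)
    cp <- optimalCutpoint(score, tt, ee)
    cp$cutoff >= 55 && cp$cutoff <= 65
  })
  expect_gte(mean(hits), 0.9)

  # by construction the maximum dominates the median split
  set.seed(20)
  score <- rnorm(80); tt <- rexp(80, 0.05 * exp(0.5 * score))
  ee <- as.integer(tt < 40); tt <- pmin(tt, 40)
  cp <- optimalCutpoint(score, tt, ee)
  med <- logrankTest(tt, ee, score > median(score))$chisq
  expect_gte(cp$chisq, med - 1e-9)

  # min_group_frac = 0.5 with n = 10 leaves only the median midpoint
  score <- 1:10; t10 <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3); e10 <- rep(1, 10)
  cp <- optimalCutpoint(score, t10, e10, minGroupFrac = 0.5)
  expect_equal(cp$cutoff, 5.5)
  expect_equal(cp$nLow, 5)

  expect_error(optimalCutpoint(rep(2, 30), rexp(30), rbinom(30, 1, 0.5)),
               "constant")
})

test_that("time-dependent AUC reduces to the static AUC without censoring", {
  set.seed(23)
  score <- rnorm(120)
  tt <- rexp(120, 0.05 * exp(0.9 * score))
  ee <- rep(1, 120)
  horizon <- 20
  got <- timeDependentAUC(score, tt, ee, horizon)
  cases <- score[tt <= horizon]; ctrls <- score[tt > horizon]
  expect_equal(got$auc, bfAUC(cases, ctrls), tolerance = 1e-12)

  # a perfect risk ranking has AUC 1
  perfect <- timeDependentAUC(-tt, tt, ee, horizon)
  expect_equal(perfect$auc, 1)

  # IPCW weights keep the AUC sane under independent censoring
  set.seed(24)
  tt2 <- rexp(400, 0.05 * exp(0.9 * rep(score, length.out = 400)))
  sc2 <- rep(score, length.out = 400)
  cc <- rexp(400, 0.03)
  ee2 <- as.integer(tt2 <= cc); to <- pmin(tt2, cc)
  a <- timeDependentAUC(sc2, to, ee2, 20)$auc
  expect_gt(a, 0.6); expect_lt(a, 1)

  expect_error(timeDependentAUC(score, tt + 100, ee, horizon), "no events")
  expect_error(timeDependentAUC(score, pmin(tt, 5), pmin(ee, 1), horizon),
               "at risk")
})
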