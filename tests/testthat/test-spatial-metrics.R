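test_that("worked examples: density, mNND and proximity by hand", {
  tumor100 <- data.frame(x = runif(100, 0, 1000), y = runif(100, 0, 1000),
                         CK = TRUE)
  core <- miniCore(tumor100)
  d <- cellDensity(core, "Tumor")
  expect_equal(d$value, 100)           # 100 cells in 1 mm^2
  expect_true(d$defined)
  z <- cellDensity(core, "CD8Treg")
  expect_equal(z$value, 0)             # absent phenotype: density 0, defined
  expect_true(z$defined)

  # 3-4-5 triangle
  core <- miniCore(data.frame(x = c(0, 3), y = c(0, 4),
                              CD4 = c(TRUE, FALSE), FOXP3 = c(TRUE, FALSE),
                              CK = c(FALSE, TRUE)))
  expect_equal(meanNNDist(core, "CD4Treg", "Tumor")$value, 5)

  # two sources averaged: (1 + 3) / 2
  core <- miniCore(data.frame(x = c(0, 10, 0, 10), y = c(0, 0, 1, 3),
                              CD4 = c(TRUE, TRUE, FALSE, FALSE),
                              CK = c(FALSE, FALSE, TRUE, TRUE)))
  expect_equal(meanNNDist(core, "CD4all", "Tumor")$value, 2)

  # proximity: both A cells within 30 um of the single B cell
  core <- miniCore(data.frame(x = c(0, 0, 0), y = c(0, 5, 10),
                              CD4 = c(TRUE, TRUE, FALSE),
                              CK = c(FALSE, FALSE, TRUE)))
  expect_equal(proximityScore(core, "CD4all", "Tumor")$value, 2)

  # far apart: zero
  core <- miniCore(data.frame(x = c(100, 0), y = c(100, 0),
                              CD4 = c(TRUE, FALSE), CK = c(FALSE, TRUE)))
  expect_equal(proximityScore(core, "CD4all", "Tumor", r = 30)$value, 0)

  # empty target set is undefined, not zero
  core <- miniCore(data.frame(x = 0, y = 0, CD4 = TRUE))
  expect_false(meanNNDist(core, "CD4all", "Tumor")$defined)
  expect_true(is.na(meanNNDist(core, "CD4all", "Tumor")$value))
  expect_false(proximityScore(core, "CD4all", "Tumor")$defined)

  expect_error(proximityScore(core, "CD4all", "Tumor", r = 0), "positive")
})

test_that("self-pairing is excluded for overlapping gates", {
  # CD4Treg is a subset of CD4all: a lone Treg has no CD4 neighbor
  core <- miniCore(data.frame(x = c(0, 50), y = 0,
                              CD4 = c(TRUE, FALSE), FOXP3 = c(TRUE, FALSE),
                              CK = c(FALSE, TRUE)))
  expect_false(meanNNDist(core, "CD4Treg", "CD4all")$defined)
  # with a second CD4 cell the self-distance (0) must not be used
  core <- miniCore(data.frame(x = c(0, 7), y = 0,
                              CD4 = TRUE, FOXP3 = c(TRUE, FALSE)))
  expect_equal(meanNNDist(core, "CD4Treg", "CD4all")$value, 7)
  expect_equal(proximityScore(core, "CD4all", "CD4all", r = 10)$value, 1)
})

test_that("grid-accelerated metrics equal the brute-force double loop", {
  for (seed in 1:20) {
    n <- sample(50:400, 1)
    core <- randomCore(n, seed = seed * 11)
    for (pair in list(c("CD4Treg", "Tumor"), c("CD8Treg", "CD4all"),
                      c("CD4Tcon", "CD4all"), c("CD4all", "CD4all"))) {
      got <- meanNNDist(core, pair[1], pair[2])
      exp <- bfCoreMNND(core, pair[1], pair[2])
      if (is.na(exp)) expect_false(got$defined)
      else expect_identical(got$value, exp)
      gp <- proximityScore(core, pair[1], pair[2], r = 30)
      ep <- bfCoreProximity(core, pair[1], pair[2], r = 30)
      if (is.na(ep)) expect_false(gp$defined)
      else expect_identical(gp$value, ep)
    }
  }
})

test_that("metrics are invariant under rigid motions and scale correctly", {
  core <- randomCore(300, seed = 5)
  ref_n <- meanNNDist(core, "CD4all", "Tumor")$value
  ref_p <- proximityScore(core, "CD4all", "Tumor", r = 30)$value

  # rotation by 37 degrees about the window centre + translation
  th <- 37 * pi / 180
  cl <- cells(core)
  xc <- cl$x - 500; yc <- cl$y - 500
  cl2 <- cl
  cl2$x <- cos(th) * xc - sin(th) * yc + 2000
  cl2$y <- sin(th) * xc + cos(th) * yc + 3000
  rot <- CellCore(cl2, "r", "p", "IM", bounds = c(
    xmin = min(cl2$x) - 1, xmax = max(cl2$x) + 1,
    ymin = min(cl2$y) - 1, ymax = max(cl2$y) + 1))
  expect_equal(meanNNDist(rot, "CD4all", "Tumor")$value, ref_n,
               tolerance = 1e-9)
  expect_equal(proximityScore(rot, "CD4all", "Tumor", r = 30)$value, ref_p,
               tolerance = 1e-9)

  # doubling coordinates doubles mNND and maps P(r) to P(2r)
  cl3 <- cl; cl3$x <- 2 * cl$x; cl3$y <- 2 * cl$y
  dbl <- CellCore(cl3, "d", "p", "IM", bounds = c(2000, 2000))
  expect_equal(meanNNDist(dbl, "CD4all", "Tumor")$value, 2 * ref_n,
               tolerance = 1e-12)
  expect_equal(proximityScore(dbl, "CD4all", "Tumor", r = 60)$value, ref_p)
})

test_that("proximity is monotone in r, bounded by n(A), and asymmetric", {
  core <- randomCore(250, seed = 9)
  rs <- c(5, 10, 20, 30, 50, 100)
  ps <- vapply(rs, function(r)
    proximityScore(core, "CD4all", "Tumor", r = r)$value, numeric(1))
  expect_true(all(diff(ps) >= 0))
  nA <- sum(gateMask(core, "CD4all"))
  expect_true(all(ps <= nA))

  # asymmetric fixture: one CD4 cell near a tumor clump
  core <- miniCore(data.frame(
    x = c(0, 1, 2, 3), y = 0,
    CD4 = c(TRUE, FALSE, FALSE, FALSE), CK = c(FALSE, TRUE, TRUE, TRUE)))
  nAB <- meanNNDist(core, "CD4all", "Tumor")$value  # 1
  nBA <- meanNNDist(core, "Tumor", "CD4all")$value  # (1+2+3)/3 = 2
  expect_equal(nAB, 1)
  expect_equal(nBA, 2)
  expect_false(isTRUE(all.equal(nAB, nBA)))
})

test_that("coreMetrics batches pairs deterministically per panel", {
  core <- randomCore(200, seed = 2)
  mt <- coreMetrics(core)
  # 7 densities + (12 pairs) x (N, P)
  expect_equal(nrow(mt), 7 + 24)
  expect_identical(coreMetrics(core), mt)
  expect_setequal(unique(mt$metric), c("D", "N", "P"))
  expect_true(all(mt$value[mt$defined] >= 0))

  core2 <- randomCore(150, seed = 3, panel = "panel2",
                      probs = c(CK = 0.3, FOXP3 = 0.2, PD1 = 0.25,
                                PDL1 = 0.25))
  mt2 <- coreMetrics(core2)
  expect_true(any(mt2$metric == "N" & mt2$source == "PDL1pos" &
                  mt2$target == "PD1pos"))
  expect_true(any(mt2$metric == "P" & mt2$source == "PDL1pos" &
                  mt2$target == "PD1pos"))

  # a pair whose markers are absent from the panel errors
  expect_error(coreMetrics(core2, pairs = data.frame(source = "CD4Treg",
                                                     target = "Tumor")),
               "CD4")

  # empty core: densities defined (0), pairwise metrics undefined
  empty <- miniCore(data.frame(x = numeric(), y = numeric()))
  me <- coreMetrics(empty)
  expect_true(all(me$value[me$metric == "D"] == 0))
  expect_true(all(me$defined[me$metric == "D"]))
  expect_true(all(!me$defined[me$metric != "D"]))
})
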