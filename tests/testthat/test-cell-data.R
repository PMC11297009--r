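test_that("phenotype gating applies the CK-dominant exclusive hierarchy", {
  cl <- data.frame(
    cell_id = paste0("c", 1:6),
    x = 1:6, y = 1,
    CK    = c(TRUE,  FALSE, FALSE, TRUE,  FALSE, FALSE),
    CD4   = c(FALSE, TRUE,  FALSE, TRUE,  TRUE,  FALSE),
    CD8   = c(FALSE, FALSE, TRUE,  FALSE, TRUE,  FALSE),
    FOXP3 = c(FALSE, TRUE,  FALSE, TRUE,  TRUE,  TRUE))
  core <- miniCore(cl)
  cts <- phenotypeCounts(core,
    c("Tumor", "CD4Treg", "CD4Tcon", "CD8Treg", "CD8Tcon", "CD4all",
      "CD8all", "FOXP3pos"))
  # c4 is CK+CD4+ -> tumor only; c5 is CD4+CD8+ -> neither lineage
  expect_equal(unname(cts["Tumor"]), 2L)
  expect_equal(unname(cts["CD4Treg"]), 1L)
  expect_equal(unname(cts["CD8Tcon"]), 1L)
  expect_equal(unname(cts["CD4all"]), 1L)
  expect_equal(unname(cts["CD8all"]), 1L)
  expect_equal(unname(cts["FOXP3pos"]), 4L)
  # CK+ cells never in a T-cell gate
  for (ph in c("CD4all", "CD8all", "CD4Treg", "CD4Tcon", "CD8Treg",
               "CD8Tcon"))
    expect_false(any(gatePhenotype(core, ph)$CK))
})

test_that("gates partition panel-1 cells and unions are consistent", {
  for (seed in 1:5) {
    core <- randomCore(200, seed = seed)
    n <- nrow(cells(core))
    cts <- phenotypeCounts(core, c("Tumor", "CD4all", "CD8all"))
    masks <- lapply(c("Tumor", "CD4all", "CD8all"), gateMask, x = core)
    # pairwise disjoint
    expect_true(all(Reduce(`+`, masks) <= 1L))
    # union with "others" covers everything
    expect_lte(sum(cts), n)
    # CD4Treg + CD4Tcon = CD4all, same for CD8
    expect_equal(sum(gateMask(core, "CD4Treg") | gateMask(core, "CD4Tcon")),
                 unname(cts["CD4all"]))
    expect_equal(sum(gateMask(core, "CD4Treg") & gateMask(core, "CD4Tcon")),
                 0L)
    # every gate equals a brute-force row scan
    cl <- cells(core)
    expect_equal(sum(gateMask(core, "CD4Treg")),
                 sum(!cl$CK & cl$CD4 & !cl$CD8 & cl$FOXP3))
    expect_equal(sum(gateMask(core, "Tumor")), sum(cl$CK))
  }
})

test_that("gating a marker absent from the panel errors with its name", {
  core <- randomCore(10, seed = 1, panel = "panel2")
  expect_error(gatePhenotype(core, "CD4Treg"), "CD4")
  expect_error(gateMask(cells(core), "unknown_thing"), "unknown phenotype")
})

test_that("cell tables round-trip and malformed input is rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  core <- randomCore(500, seed = 42, coreId = "P9_IM", patientId = "P9")
  writeCellTable(core, path)
  back <- readCellTable(path)
  expect_length(back, 1L)
  b <- back[["P9_IM"]]
  expect_equal(region(b), "IM")
  ord <- order(cells(b)$cell_id)
  orig <- cells(core)[order(cells(core)$cell_id),
                      c("cell_id", "x", "y", panelMarkers("panel1"))]
  got <- cells(b)[ord, c("cell_id", "x", "y", panelMarkers("panel1"))]
  rownames(orig) <- rownames(got) <- NULL
  expect_equal(got, orig)

  # 3-row worked example: direct gating after read
  tiny <- data.frame(cell_id = c("a", "b", "c"), x_um = c(1, 2, 3),
                     y_um = 1, region = "TC", core_id = "k1",
                     patient_id = "p1", panel = "panel1",
                     CK = c(1, 0, 0), CD4 = c(0, 1, 0), CD8 = c(0, 0, 1),
                     FOXP3 = c(0, 1, 0))
  write.csv(tiny, path, row.names = FALSE)
  cc <- readCellTable(path)[[1]]
  expect_equal(unname(phenotypeCounts(cc, c("Tumor", "CD4Treg", "CD8Tcon"))),
               c(1L, 1L, 1L))

  # unknown region vocabulary
  bad <- tiny; bad$region <- "edge"
  write.csv(bad, path, row.names = FALSE)
  expect_error(readCellTable(path), "region")

  # missing mandatory column is named
  write.csv(tiny[, setdiff(colnames(tiny), "core_id")], path,
            row.names = FALSE)
  expect_error(readCellTable(path), "core_id")

  # malformed marker rows are reported with line numbers
  bad <- tiny; bad$CD4[2] <- 7
  write.csv(bad, path, row.names = FALSE)
  expect_error(readCellTable(path), "line")
})

test_that("tab-separated cell tables are auto-detected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  core <- randomCore(50, seed = 3, coreId = "T1_TC", patientId = "T1",
                     region = "TC")
  writeCellTable(core, path, sep = "\t")
  back <- readCellTable(path)
  expect_equal(nrow(cells(back[[1]])), 50L)
})

test_that("patient tables validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  pts <- data.frame(
    patient_id = sprintf("P%03d", 1:100),
    rfs_months = round(runif(100, 0, 84), 2),
    event = rbinom(100, 1, 0.4),
    age_group = sample(c("<=65", ">65"), 100, TRUE),
    gender = sample(c("Male", "Female"), 100, TRUE),
    histology = sample(c("LUAD", "LUSC"), 100, TRUE),
    smoking_index_group = sample(c("<400", ">=400"), 100, TRUE),
    stage_group = sample(c("I-II", "III"), 100, TRUE),
    split = "unassigned", stringsAsFactors = FALSE)
  writePatientTable(pts, path)
  back <- readPatientTable(path)
  expect_equal(back, pts)

  two <- pts[1:2, ]; two$rfs_months <- c(12, 30); two$event <- c(1, 0)
  writePatientTable(two, path)
  got <- readPatientTable(path)
  expect_equal(nrow(got), 2L)
  expect_equal(sum(got$event), 1)

  bad <- pts[1:3, ]; bad$rfs_months[2] <- -3
  writePatientTable(bad, path)
  expect_error(readPatientTable(path), "rfs_months")

  dup <- pts[c(1, 1, 2), ]
  writePatientTable(dup, path)
  expect_error(readPatientTable(path), "duplicate")

  voc <- pts[1:3, ]; voc$stage_group[1] <- "IV"
  writePatientTable(voc, path)
  expect_error(readPatientTable(path), "stage_group")
})
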