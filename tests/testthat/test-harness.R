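test_that("one cell result per fitted scheme, per the non-invariance rule", {
  res0 <- runCondition(study1Condition(0, c(0.1, 0.1), "none", 200),
                       reps = 4, baseSeed = 42)
  expect_equal(nrow(res0), 1)
  expect_identical(res0$scheme, "MI")
  res2 <- runCondition(study1Condition(2, c(0.1, 0.1), "X", 200),
                       reps = 4, baseSeed = 42)
  expect_equal(nrow(res2), 2)
  expect_setequal(res2$scheme, c("MI", "pMI"))
  expect_true(all(res2$converged <= res2$requested))
  expect_true(all(res2$rejectWald >= 0 & res2$rejectWald <= 100))
})

test_that("full grids yield the documented row counts", {
  ## row structure only: one MI row per cell plus a pMI row where pNI > 0
  g1 <- designGrid(1)
  rows1 <- sum(vapply(g1, function(cnd) if (cnd@pNI > 0) 2L else 1L, 0L))
  expect_equal(length(g1), 40)
  expect_equal(rows1, 72)
  g2 <- designGrid(2)
  rows2 <- sum(vapply(g2, function(cnd) if (cnd@pNI > 0) 2L else 1L, 0L))
  expect_equal(length(g2), 32)
  expect_equal(rows2, 48)
})

test_that("runStudy is deterministic at a fixed base seed", {
  a <- runStudy(1, cells = c(1, 2), reps = 5, baseSeed = 7)
  b <- runStudy(1, cells = c(1, 2), reps = 5, baseSeed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 3)   # cell 1 is fully invariant, cell 2 is not
  c2 <- runStudy(1, cells = c(1, 2), reps = 5, baseSeed = 8)
  expect_false(identical(a$meanDelta, c2$meanDelta))
  ## a cell's stream does not depend on which other cells run alongside it
  solo <- runStudy(1, cells = 2, reps = 5, baseSeed = 7)
  expect_identical(solo$meanDelta, a$meanDelta[a$cell == 2])
})

test_that("the config object drives runStudy like the explicit arguments", {
  cfg <- simulationConfig(2, cells = 1, reps = 3, seed = 5)
  expect_identical(runStudy(cfg), runStudy(2, cells = 1, reps = 3, baseSeed = 5))
  expect_error(simulationConfig(3), "study")
  expect_error(simulationConfig(1, reps = 0), "reps")
  expect_error(simulationConfig(1, alpha = 1.2), "alpha")
})

test_that("results tables round-trip exactly through comma-separated text", {
  tab <- runStudy(1, cells = c(1, 2), reps = 4, baseSeed = 42, lrt = TRUE)
  path <- tempfile(fileext = ".csv")
  writeResults(tab, path)
  back <- readResults(path)
  for (nm in names(tab)) {
    if (is.numeric(tab[[nm]])) expect_equal(back[[nm]], tab[[nm]], tolerance = 0)
    else expect_equal(as.character(back[[nm]]), as.character(tab[[nm]]))
  }
  ## column order is fixed regardless of which cells ran first
  rev <- runStudy(1, cells = c(2, 1), reps = 4, baseSeed = 42, lrt = TRUE)
  expect_identical(names(rev), names(tab))
  expect_error(writeResults(tab[0, ], tempfile()), "empty")
})

test_that("paper-layout output leaves pMI columns empty for invariant cells", {
  tab <- runStudy(1, cells = c(1, 2), reps = 4, baseSeed = 42)
  path <- tempfile(fileext = ".csv")
  writeResults(tab, path, layout = "wide")
  wide <- utils::read.csv(path)
  expect_equal(nrow(wide), 2)                      # one row per cell
  inv <- wide[wide$pNI == 0, ]
  expect_true(all(is.na(inv$rate_pMI)))
  expect_true(all(is.na(inv$bias_pMI)))
  ni <- wide[wide$pNI > 0, ]
  expect_false(any(is.na(ni$rate_pMI)))
})

test_that("raw per-replication estimates are persisted on request", {
  dir <- tempfile()
  dir.create(dir)
  runCondition(study1Condition(2, c(0.1, 0.1), "X", 200),
               reps = 3, baseSeed = 42, lrt = TRUE, rawDir = dir)
  files <- list.files(file.path(dir, "raw"), full.names = TRUE)
  expect_length(files, 1)
  raw <- utils::read.csv(files[1])
  expect_equal(nrow(raw), 6)   # 3 replications x 2 schemes
  expect_true(all(c("delta", "pWald", "pLRT", "converged") %in% names(raw)))
  ## the persisted estimates reproduce the cell summary without refitting
  res <- runCondition(study1Condition(2, c(0.1, 0.1), "X", 200),
                      reps = 3, baseSeed = 42)
  mi <- raw[raw$scheme == "MI" & raw$converged, ]
  expect_equal(standardizedBias(mi$delta, 0), res$stdBias[res$scheme == "MI"])
})
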