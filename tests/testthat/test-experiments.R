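deskCfg <- function(preset = "control_EphB2_ephrinB1", nReplicates = 2L, ...) {
  experimentConfig(preset = preset, scale = 0.1, nSteps = 200L,
                   recordEvery = 100L, nReplicates = nReplicates, ...)
}

test_that("segregation assays start intermingled with exact counts", {
  cfg <- deskCfg(assay = "segregation")
  set.seed(1); st <- initSegregation(cfg)
  expect_equal(unname(table(populations(st))), c(40L, 40L), ignore_attr = TRUE)
  expect_lt(abs(segregationIndex(st) - 0.5), 0.1)
  set.seed(2); st2 <- initSegregation(cfg)
  expect_false(identical(centroids(st)$x, centroids(st2)$x))
})

test_that("boundary assays start as a fuzzy interface with exact counts", {
  cfg0 <- deskCfg(mixingBand = 0)
  set.seed(3); straight <- initBoundary(cfg0)
  v0 <- relativeBorderLength(straight)
  expect_lt(v0, 1.1)   # about the straight interface width
  expect_gt(v0, 0.6)
  cfg <- deskCfg()
  set.seed(3); fuzzy <- initBoundary(cfg)
  expect_gt(relativeBorderLength(fuzzy), v0)
  expect_equal(unname(table(populations(fuzzy))), c(40L, 40L),
               ignore_attr = TRUE)
  # the two sides sit on opposite halves
  cc <- centroids(straight)
  expect_true(mean(cc$x[cc$population == "EphB2"]) <
              mean(cc$x[cc$population == "ephrinB1"]))
})

test_that("a zero-step experiment reports the initial metrics", {
  cfg <- deskCfg()
  cfg@nSteps <- 0L
  res <- runExperiment(cfg)
  for (r in res@replicates) {
    expect_equal(nrow(r$timecourse), 1L)
  }
  expect_equal(finalValues(res), initialValues(res))
})

test_that("experiments are deterministic byte-for-byte", {
  cfg <- deskCfg()
  d1 <- file.path(tempfile("runA"))
  d2 <- file.path(tempfile("runB"))
  runExperiment(cfg, outDir = d1)
  runExperiment(cfg, outDir = d2)
  f1 <- list.files(d1)
  expect_true(length(f1) > 3)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("aggregates equal the mean of the replicate time courses", {
  cfg <- deskCfg(assay = "segregation")
  res <- runExperiment(cfg)
  vals <- sapply(res@replicates, function(r) r$timecourse$value)
  expect_equal(res@aggregate$mean, rowMeans(vals))
  expect_equal(res@aggregate$se, apply(vals, 1, stats::sd) / sqrt(ncol(vals)))
})

test_that("condition comparison is an exact two-sided Mann-Whitney test", {
  cfg <- deskCfg(nReplicates = 3L)
  res <- runExperiment(cfg)
  self <- compareConditions(res, res)
  expect_equal(self$p, 1)
  # complete separation of 10 vs 10 gives the exact enumeration value
  a <- res; b <- res
  fake <- function(res, vals) {
    res@replicates <- rep(res@replicates, length.out = length(vals))
    for (i in seq_along(vals))
      res@replicates[[i]]$timecourse$value[] <- vals[i]
    res
  }
  a <- fake(a, 1:10)
  b <- fake(b, 11:20)
  cmp <- compareConditions(a, b)
  expect_equal(cmp$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_error(compareConditions(res,
    runExperiment(deskCfg(assay = "segregation", nReplicates = 3L))),
    "different metrics")
})

test_that("fixture generators record their ground truth", {
  pts <- generateFixture("labelled_points", list(width = 100, height = 100),
                         seed = 2)
  truth <- jsonlite::read_json(pts$truth)
  df <- utils::read.csv(pts$points)
  expect_equal(borderLength(df)$length, truth$border_length_um,
               tolerance = 0.05)
  masks <- generateFixture("boundary_masks", list(areas = c(600, 600)),
                           seed = 2)
  m <- as.matrix(utils::read.csv(masks$mask, header = FALSE))
  rep <- clusterParticleAnalysis(m)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$n_cells, c(3L, 3L))
  expect_error(generateFixture("nope"), "unknown fixture")
})

test_that("the command line front end dispatches to package operations", {
  out <- capture.output(cliMain(c("presets")))
  expect_true("control_EphB2_ephrinB1" %in% out)
  fdir <- tempfile("clifix")
  out2 <- capture.output(cliMain(c("fixtures", "--kind", "boundary_masks",
                                   "--out", fdir)))
  expect_true(file.exists(file.path(fdir, "ground_truth.json")))
  expect_output(cliMain(character(0)), "usage")
})
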