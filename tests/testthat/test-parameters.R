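test_that("per-minute break probabilities follow 1 - exp(-1/duration)", {
  expect_equal(signif(pBreakFromDuration(72), 2), 0.014)
  expect_equal(signif(pBreakFromDuration(24), 2), 0.041)
  expect_equal(pBreakFromDuration(Inf), 0)
  expect_error(pBreakFromDuration(0), "positive")
  expect_error(pBreakFromDuration(-3), "positive")
  # strictly decreasing in duration
  d <- c(0.1, 1, 5, 15, 24, 45, 72, 89, 500)
  expect_true(all(diff(pBreakFromDuration(d)) < 0))
})

test_that("repulsion frequencies and ratios reproduce the summary statistic", {
  expect_equal(repulsionFrequencyPerMin(0.84, 24), 0.035)
  expect_equal(repulsionFrequencyPerMin(0.47, 72), 0.00653, tolerance = 1e-3)
  expect_equal(repulsionFrequencyPerMin(0, 10), 0)
  het <- list(collapse_freq = 0.84, duration_min = 24)
  hom <- list(collapse_freq = 0.47, duration_min = 72)
  expect_equal(round(repulsionRatio(het, hom), 2), 5.36)
  expect_equal(repulsionRatio(het, het), 1)
  expect_error(repulsionRatio(het, list(collapse_freq = 0, duration_min = 72)),
               "undefined")
})

test_that("the shipped behaviour table drives the preset catalog", {
  bm <- behaviourMeasurements()
  expect_equal(nrow(bm), 10L)
  ctl <- buildPreset("control_EphB2_ephrinB1")
  im <- ctl@interaction
  expect_identical(im@popNames, c("EphB2", "ephrinB1"))
  expect_equal(im@durationMin["EphB2", "EphB2"], 72)
  expect_equal(im@durationMin["EphB2", "ephrinB1"], 24)
  expect_equal(im@durationMin["ephrinB1", "EphB2"], 26)
  expect_equal(im@durationMin["ephrinB1", "ephrinB1"], 57)
  expect_equal(im@pRepulsion["EphB2", "ephrinB1"], 0.84)
  expect_equal(im@pRepulsion["ephrinB1", "EphB2"], 0.92)
  expect_equal(im@pRepulsion["EphB2", "EphB2"], 0.47)
  expect_equal(im@pRepulsion["ephrinB1", "ephrinB1"], 0.62)
  expect_true(all(im@directed))
  # derived per-minute break probabilities
  expect_equal(signif(pBreakFromDuration(im@durationMin["EphB2", "ephrinB1"]), 2),
               0.041)
  ki <- buildPreset("kiEphB2_ephrinB1")@interaction
  expect_equal(ki@durationMin["kiEphB2", "kiEphB2"], 89)
  expect_equal(ki@pRepulsion["kiEphB2", "kiEphB2"], 0.44)
  expect_equal(signif(pBreakFromDuration(89), 2), 0.011)
  expect_equal(ki@pRepulsion["kiEphB2", "ephrinB1"], 0.69)
})

test_that("adhesion-only presets switch off directed repulsion", {
  adh <- buildPreset("adhesion_only_measured")@interaction
  expect_false(any(adh@directed))
  a5 <- buildPreset("adhesion_only_500to1")@interaction
  expect_false(any(a5@directed))
  # heterotypic duration is homotypic / 500 per focal population
  expect_equal(a5@durationMin["EphB2", "ephrinB1"],
               a5@durationMin["EphB2", "EphB2"] / 500)
  expect_equal(a5@durationMin["ephrinB1", "EphB2"],
               a5@durationMin["ephrinB1", "ephrinB1"] / 500)
})

test_that("unknown presets fail with the catalog listed", {
  expect_error(buildPreset("nonsense"), "control_EphB2_ephrinB1")
  expect_setequal(presetNames(),
    c("control_EphB2_ephrinB1", "kiEphB2_ephrinB1", "adhesion_only_measured",
      "adhesion_only_500to1", "ncad_kd", "ncad_kd_het8", "ncad_kd_hom45",
      "ncad_kd_homfreq", "control_hetfreq_mid", "control_hetfreq_low"))
})

test_that("presets survive a YAML round trip", {
  pr <- buildPreset("ncad_kd")
  path <- tempfile(fileext = ".yml")
  presetToYAML(pr, path)
  pr2 <- presetFromYAML(path)
  expect_identical(pr2@name, pr@name)
  expect_equal(pr2@interaction@durationMin, pr@interaction@durationMin)
  expect_equal(pr2@interaction@pRepulsion, pr@interaction@pRepulsion)
  expect_identical(pr2@interaction@directed, pr@interaction@directed)
  expect_equal(pr2@interaction@escapeMin, pr@interaction@escapeMin)
  expect_equal(pr2@motility@speed, pr@motility@speed)
  expect_equal(pr2@motility@contactDist, pr@motility@contactDist)
  expect_identical(pr2@notes, pr@notes)
})

test_that("simulated contact durations close the loop with the inputs", {
  # Monte-Carlo round trip: links broken at the hazard derived from a
  # measured duration live, on average, for that duration (within 5%)
  set.seed(17)
  lt <- linkLifetimes(2000, duration = 24)
  expect_gte(length(lt), 1000)
  expect_equal(mean(lt), 24, tolerance = 0.05)
})
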