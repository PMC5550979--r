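gridPoints <- function(width = 100, height = 100, spacing = 2.5,
                       arrangement = "split") {
  gx <- seq(spacing / 2, width - spacing / 2, by = spacing)
  gy <- seq(spacing / 2, height - spacing / 2, by = spacing)
  g <- expand.grid(x = gx, y = gy)
  lab <- switch(arrangement,
    split = ifelse(g$x < width / 2, "A", "B"),
    checkerboard = ifelse((floor(g$x / spacing) + floor(g$y / spacing)) %% 2 == 0,
                          "A", "B"))
  data.frame(x = g$x, y = g$y, population = lab)
}

test_that("border length of a straight split equals the interface width", {
  pts <- gridPoints()
  bl <- borderLength(pts)
  expect_equal(bl$length, 100, tolerance = 0.05)
  # all interface midpoints sit on the dividing line
  expect_true(all(abs(bl$midpoints[, 1] - 50) < 1e-9))
})

test_that("raggedness increases the border length monotonically", {
  set.seed(2)
  jitterPts <- function(pts) {
    pts$x <- pts$x + runif(nrow(pts), -0.4, 0.4)
    pts$y <- pts$y + runif(nrow(pts), -0.4, 0.4)
    pts
  }
  base <- jitterPts(gridPoints())
  checkLab <- gridPoints(arrangement = "checkerboard")$population
  straight <- borderLength(base)$length
  checker <- borderLength(transform(base, population = checkLab))$length
  expect_gt(checker, straight)
  # random 50:50 labels exceed the straight split in nearly every draw
  set.seed(123)
  exceed <- replicate(100, {
    pts <- gridPoints(spacing = 10)
    pts$population <- sample(pts$population)
    borderLength(pts)$length
  }) > borderLength(gridPoints(spacing = 10))$length
  expect_gte(mean(exceed), 0.95)
})

test_that("border length is invariant under rigid motions", {
  set.seed(4)
  pts <- gridPoints()
  pts$x <- pts$x + runif(nrow(pts), -0.3, 0.3)  # break grid ties
  pts$y <- pts$y + runif(nrow(pts), -0.3, 0.3)
  pts$population[sample.int(nrow(pts), 30)] <- "A"  # make it irregular
  b0 <- borderLength(pts)$length
  th <- 0.83
  rot <- data.frame(x = cos(th) * pts$x - sin(th) * pts$y + 12,
                    y = sin(th) * pts$x + cos(th) * pts$y - 40,
                    population = pts$population)
  expect_equal(borderLength(rot)$length, b0, tolerance = 1e-9)
})

test_that("borders are undefined without both populations", {
  pts <- gridPoints()
  pts$population <- "A"
  expect_error(borderLength(pts), "undefined")
})

test_that("particle analysis counts clusters and cells like a binary image", {
  # one disc of ~1000 um^2 -> one cluster of 5 cells
  ax <- seq(0.5, 59.5, 1)
  disc <- function(cx, cy, area) {
    r <- sqrt(area / pi)
    outer((ax - cx)^2, (ax - cy)^2, "+") <= r^2
  }
  m1 <- matrix(0L, 60, 60); m1[disc(30, 30, 1000)] <- 1L
  rep1 <- clusterParticleAnalysis(m1)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$n_cells, 5L)
  # a blob below the minimum cluster size is discarded
  m2 <- matrix(0L, 60, 60); m2[disc(30, 30, 400)] <- 1L
  expect_equal(nrow(clusterParticleAnalysis(m2)), 0L)
  # two separated discs -> two clusters; diagonal contact merges them
  ax80 <- seq(0.5, 79.5, 1)
  disc80 <- function(cx, cy, area) {
    r <- sqrt(area / pi)
    outer((ax80 - cx)^2, (ax80 - cy)^2, "+") <= r^2
  }
  m3 <- matrix(0L, 80, 80)
  m3[disc80(20, 20, 600)] <- 1L; m3[disc80(60, 60, 600)] <- 1L
  expect_equal(nrow(clusterParticleAnalysis(m3)), 2L)
  m4 <- matrix(0L, 10, 10); m4[2, 2] <- 1L; m4[3, 3] <- 1L
  lab <- clusterParticleAnalysis(m4, minArea = 0, cellArea = 1)
  expect_equal(nrow(lab), 1L)  # 8-connectivity joins diagonals
  # empty mask -> empty report
  expect_equal(nrow(clusterParticleAnalysis(matrix(0L, 5, 5))), 0L)
})

test_that("particle analysis of states never exceeds the population size", {
  set.seed(8)
  cfg <- experimentConfig(assay = "segregation", scale = 0.1, nSteps = 0L,
                          nReplicates = 1L)
  st <- initSegregation(cfg)
  rep <- clusterParticleAnalysis(st, population = "EphB2")
  expect_lte(attr(rep, "total_cells"), sum(populations(st) == "EphB2") + 2)
})

test_that("scripted contacts are recovered with exact durations", {
  paths <- generateFixture("scripted_tracks",
                           list(nContacts = 4, contactFrames = 4), seed = 1)
  tr <- utils::read.csv(paths$tracks)
  ev <- extractContactEvents(tr)
  focal <- ev[ev$cell_id == 1, ]
  expect_equal(nrow(focal), 4L)
  expect_equal(focal$duration, rep(12, 4))
  expect_true(all(focal$collapse))
  expect_false(any(focal$censored))
  # durations are invariant to frame renumbering
  tr2 <- tr
  tr2$frame <- tr2$frame + 1000
  ev2 <- extractContactEvents(tr2)
  expect_equal(ev2$duration, ev$duration)
  # five frames in contact give 15 minutes
  p5 <- generateFixture("scripted_tracks",
                        list(nContacts = 2, contactFrames = 5), seed = 1)
  ev5 <- extractContactEvents(utils::read.csv(p5$tracks))
  expect_equal(ev5$duration[ev5$cell_id == 1], rep(15, 2))
})

test_that("a stationary cell has no defined post-contact direction", {
  paths <- generateFixture("scripted_tracks", seed = 1)
  tr <- utils::read.csv(paths$tracks)
  ev <- extractContactEvents(tr)
  still <- ev[ev$cell_id == 2, ]  # the scripted partner never moves
  expect_false(any(still$theta_defined))
  expect_true(all(is.na(still$theta)))
})

test_that("irregular frame spacing is rejected", {
  paths <- generateFixture("scripted_tracks", seed = 1)
  tr <- utils::read.csv(paths$tracks)
  tr$time_min[tr$frame == 3] <- 9.7
  expect_error(extractContactEvents(tr), "irregular")
})

test_that("the migrate-away rule is the literal angular band", {
  expect_false(migratesAway(0))
  expect_true(migratesAway(0.6 * pi))
  expect_true(migratesAway(pi / 2))
  expect_true(migratesAway(3 * pi / 4))
  expect_false(migratesAway(0.9 * pi))   # outside the literal band
  expect_false(migratesAway(0.49 * pi))
  # the inclusive variant counts straight-back movement
  expect_true(migratesAway(0.9 * pi, upper = pi))
  expect_false(migratesAway(NA_real_))
})

test_that("displacement after repulsion profiles scripted speed bursts", {
  flat <- generateFixture("scripted_tracks", list(burstFactor = 1), seed = 1)
  tr <- utils::read.csv(flat$tracks)
  ev <- extractContactEvents(tr)
  d <- displacementAfterRepulsion(ev[ev$cell_id == 1, ], tr)
  expect_equal(d$mean_disp_um, rep(9, 6))  # 3 um/min x 3-min bins
  burst <- generateFixture("scripted_tracks", list(burstFactor = 2), seed = 1)
  trb <- utils::read.csv(burst$tracks)
  evb <- extractContactEvents(trb)
  db <- displacementAfterRepulsion(evb[evb$cell_id == 1, ], trb)
  expect_equal(db$mean_disp_um[1:2], c(18, 18))  # 6-min burst
  expect_equal(db$mean_disp_um[3:6], rep(9, 4))
  # censored-only input yields an empty profile with a warning
  evc <- ev[ev$cell_id == 1, ]
  evc$censored <- TRUE
  expect_warning(dc <- displacementAfterRepulsion(evc, tr), "uncensored")
  expect_equal(nrow(dc), 0L)
})

test_that("segregation index separates split, random and checkerboard", {
  pts <- gridPoints()
  expect_gt(segregationIndex(pts), 0.85)
  set.seed(5)
  rand <- pts
  rand$population <- sample(rand$population)
  si <- segregationIndex(rand)
  expect_lt(abs(si - 0.5), 0.06)
  expect_lt(segregationIndex(gridPoints(arrangement = "checkerboard")), 0.5)
  expect_error(segregationIndex(pts[1:5, ]), "at least")
})

test_that("the random-mixture baseline sits at one half for 800 cells", {
  set.seed(99)
  cfg <- experimentConfig(assay = "segregation", scale = 1, nSteps = 0L,
                          nReplicates = 1L)
  si <- replicate(3, segregationIndex(initSegregation(cfg)))
  expect_lt(abs(mean(si) - 0.5), 0.02)
})
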