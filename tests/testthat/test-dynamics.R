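test_that("a free cell moves at the configured speed", {
  set.seed(3)
  st <- pointState(rbind(c(0, 0)), "A", arenaDiameter = 600)
  pr <- abPreset()
  pr@motility@pChangeDir <- 0  # no spontaneous turns
  out <- runSim(st, pr, 120)   # one simulated minute
  disp <- sqrt(mean(rowMeans(out$state@nodesX))^2 +
               mean(rowMeans(out$state@nodesY))^2)
  expect_equal(disp, 0.75, tolerance = 1e-9)
  # with turns the net displacement can only shrink, and the path speed is
  # exact: direction changes only happen on tick boundaries, so per-minute
  # path increments all equal speed x 1 min
  set.seed(3)
  pr@motility@pChangeDir <- 0.2
  out2 <- runSim(st, pr, 10000, recordEvery = 120)
  sn <- out2$snapshots
  steps <- unique(sn$step)
  path <- 0
  for (k in 2:length(steps)) {
    a <- sn[sn$step == steps[k - 1], ]
    b <- sn[sn$step == steps[k], ]
    path <- path + sqrt((b$x - a$x)^2 + (b$y - a$y)^2)
  }
  speed <- path / (10000 * 0.5 / 60)
  expect_equal(speed, 0.75, tolerance = 0.02 * 0.75)
  net <- sqrt(sum((sn[sn$step == max(steps), c("x", "y")] -
                   sn[sn$step == 0, c("x", "y")])^2))
  expect_lt(net, path)
})

test_that("links form exactly for membranes within the contact distance", {
  # far apart: no links
  st <- pointState(rbind(c(-50, 0), c(50, 0)), c("A", "B"))
  expect_equal(nrow(adhesionLinks(formLinks(st, 2)$state)), 0L)
  # nearest nodes exactly at the contact distance: exactly one link
  st2 <- pointState(rbind(c(-8.5, 0), c(8.5, 0)), c("A", "B"))
  # nearest node separation is 17 - 15 = 2 um
  f <- formLinks(st2, 2)
  expect_equal(nrow(adhesionLinks(f$state)), 1L)
  expect_identical(f$events$event, "link_form")
  # three mutually touching cells: a link on every touching interface
  # (the sensing distance is widened to bridge the octagon-facet mismatch
  # on the 60-degree interfaces)
  d <- 16.2
  st3 <- pointState(rbind(c(0, 0), c(d, 0), c(d / 2, d * sqrt(3) / 2)),
                    c("A", "B", "A"))
  lk <- adhesionLinks(formLinks(st3, 5)$state)
  pairs <- unique(paste(pmin(lk$cell_a, lk$cell_b), pmax(lk$cell_a, lk$cell_b)))
  expect_setequal(pairs, c("1 2", "1 3", "2 3"))
})

test_that("link lifetimes follow the per-minute break hazard", {
  # never breaks at zero hazard
  st <- pairGridState(4)
  prNever <- abPreset(duration = 1e12)
  st <- formLinks(st, 3)$state
  n0 <- nrow(adhesionLinks(st))
  expect_gt(n0, 0)
  set.seed(1)
  for (k in 1:50) st <- breakLinks(st, prNever)$state
  expect_equal(nrow(adhesionLinks(st)), n0)
  # near-certain breaking: mean lifetime below one evaluation interval
  set.seed(2)
  lt <- linkLifetimes(100, duration = 1e-4)
  expect_true(all(lt < 1))
  # empirical means match the geometric-lifetime expectation 1/p(break)
  set.seed(3)
  lt24 <- linkLifetimes(600, duration = 24)
  expect_equal(mean(lt24), 1 / pBreakFromDuration(24), tolerance = 0.05)
  set.seed(4)
  lt72 <- linkLifetimes(600, duration = 72)
  expect_equal(mean(lt72), 1 / pBreakFromDuration(72), tolerance = 0.05)
})

test_that("link lifetime distribution is exponential at the per-minute scale", {
  set.seed(9)
  lt <- linkLifetimes(1100, duration = 24)
  expect_gte(length(lt), 1000)
  ks <- suppressWarnings(stats::ks.test(lt, "pexp", rate = 1 / 24))
  expect_gt(ks$p.value, 0.01)
})

test_that("repulsion reassigns the leader to the opposite membrane point", {
  st <- pointState(rbind(c(0, 0)), "A")
  # certain repulsion: broken node 0 -> leader 4
  set.seed(1)
  tr <- triggerRepulsion(st, 1, 0, pRepulsion = 1, directed = TRUE)
  expect_true(tr$repelled)
  expect_identical(tr$state@leader[1], 4L)
  expect_equal(tr$state@heading[1], pi, tolerance = 1e-9)
  # zero repulsion probability: nothing happens
  tr0 <- triggerRepulsion(st, 1, 0, pRepulsion = 0, directed = TRUE)
  expect_false(tr0$repelled)
  expect_identical(tr0$state@leader[1], st@leader[1])
  # undirected mode: the new leader is uniform over the ring
  set.seed(7)
  counts <- integer(8)
  for (k in 1:800) {
    trr <- triggerRepulsion(st, 1, 0, pRepulsion = 1, directed = FALSE)
    counts[trr$state@leader[1] + 1L] <- counts[trr$state@leader[1] + 1L] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("collapse fraction per break matches the configured probability", {
  set.seed(21)
  st <- pairGridState(400)
  pRep <- 0.7
  pr <- abPreset(duration = 4, pRepulsion = pRep)
  st <- formLinks(st, 3)$state
  nBreak <- 0; nRep <- 0
  for (tick in 1:40) {
    out <- breakLinks(st, pr)
    st <- out$state
    nBreak <- nBreak + 2 * sum(out$events$event == "link_break")  # two endpoints
    nRep <- nRep + sum(out$events$event == "repulsion")
    st@avoidSteps[!is.na(st@avoidCell)] <- 10000L
  }
  expect_gt(nBreak, 400)
  ci <- stats::binom.test(nRep, nBreak, p = pRep)$conf.int
  expect_true(pRep >= ci[1] && pRep <= ci[2])
})

test_that("cohesive pulling rotates linked neighbours toward the escape", {
  st <- pointState(rbind(c(-8.4, 0), c(8.4, 0), c(25.2, 0)),
                   c("A", "A", "A"), arenaDiameter = 300)
  st <- formLinks(st, 2)$state
  expect_equal(nrow(adhesionLinks(st)), 2L)
  st@heading[] <- 0
  st@heading[2] <- pi / 2  # middle cell repelled upward
  # zero weight: no effect
  st0 <- cohesionPull(st, 2L, 0)
  expect_identical(st0@heading, st@heading)
  # full weight: direct neighbours adopt the repelled cell's direction
  st1 <- cohesionPull(st, 2L, 1)
  expect_equal(st1@heading[1], pi / 2, tolerance = 1e-9)
  expect_equal(st1@heading[3], pi / 2, tolerance = 1e-9)
  # half weight rotates along the shorter arc by half the difference
  st2 <- cohesionPull(st, 2L, 0.5)
  expect_equal(st2@heading[1], pi / 4, tolerance = 1e-9)
  # single-step locality: in a 3-chain with an end cell repelled, the far
  # end is not touched (influence propagates only over subsequent steps)
  st@heading[] <- 0
  st@heading[1] <- pi / 2
  st3 <- cohesionPull(st, 1L, 1)
  expect_equal(st3@heading[2], pi / 2, tolerance = 1e-9)
  expect_equal(st3@heading[3], 0, tolerance = 1e-12)
})

test_that("identical undirected populations are statistically exchangeable", {
  set.seed(31)
  cfg <- experimentConfig(preset = "adhesion_only_measured",
                          assay = "segregation", scale = 0.12,
                          nSteps = 0L, nReplicates = 1L)
  pr <- abPreset(duration = 40, pRepulsion = 0, directed = FALSE)
  pr@interaction@popNames <- c("EphB2", "ephrinB1")
  dimnames(pr@interaction@durationMin) <-
    dimnames(pr@interaction@pRepulsion) <-
    dimnames(pr@interaction@directed) <-
    dimnames(pr@interaction@escapeMin) <-
    list(c("EphB2", "ephrinB1"), c("EphB2", "ephrinB1"))
  si <- replicate(4, {
    st <- initSegregation(cfg)
    segregationIndex(runSim(st, pr, 3000)$state)
  })
  # stays at the random-mixture baseline
  expect_true(all(abs(si - 0.5) < 0.08))
})

test_that("runs with equal seed and configuration are bit-reproducible", {
  cfg <- experimentConfig(scale = 0.1, nSteps = 500L, nReplicates = 1L)
  set.seed(99); st1 <- initBoundary(cfg)
  set.seed(99); st2 <- initBoundary(cfg)
  pr <- buildPreset("control_EphB2_ephrinB1")
  set.seed(7); r1 <- runSim(st1, pr, 500)
  set.seed(7); r2 <- runSim(st2, pr, 500)
  expect_identical(r1$state@nodesX, r2$state@nodesX)
  expect_identical(r1$state@heading, r2$state@heading)
  expect_identical(r1$counts, r2$counts)
})
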