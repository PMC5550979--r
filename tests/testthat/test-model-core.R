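test_that("makeCell places a regular octagon with one leader", {
  set.seed(1)
  cell <- makeCell(c(0, 0), "A", radius = 7.5)
  d <- sqrt(rowSums(sweep(cell$nodes, 2, cell$centroid)^2))
  expect_equal(d, rep(7.5, 8), tolerance = 1e-12)
  spacing <- sqrt(rowSums((cell$nodes[c(2:8, 1), ] - cell$nodes)^2))
  expect_equal(spacing, rep(2 * 7.5 * sin(pi / 8), 8), tolerance = 1e-12)
  expect_equal(spacing[1], 5.7403, tolerance = 1e-4)
  expect_true(cell$leader %in% 0:7)
  expect_equal(cell$idealBond, 2 * 7.5 * sin(pi / 8))
})

test_that("degenerate cell construction is rejected", {
  expect_error(makeCell(c(0, 0), "A", radius = 0), "radius")
  expect_error(makeCell(c(0, 0), "A", radius = -1), "radius")
  expect_error(makeCell(c(248, 0), "A", radius = 7.5, arenaDiameter = 500),
               "inside the arena")
})

test_that("structural invariants survive simulation steps", {
  set.seed(11)
  st <- pointState(rbind(c(-9, 0), c(9, 0), c(0, 15)), c("A", "B", "A"),
                   arenaDiameter = 120)
  pr <- abPreset(duration = 5, pRepulsion = 0.8)
  out <- runSim(st, pr, 2400)  # 20 simulated minutes
  st2 <- out$state
  expect_true(validObject(st2))
  expect_equal(nCells(st2), 3L)  # cell count conserved
  expect_true(all(st2@leader %in% 0:7))
  cx <- rowMeans(st2@nodesX); cy <- rowMeans(st2@nodesY)
  nodeR <- sqrt((st2@nodesX - cx)^2 + (st2@nodesY - cy)^2)
  expect_true(all(nodeR <= 2 * st2@radius + 1e-6))
  # links are mutual
  lk <- adhesionLinks(st2)
  if (nrow(lk)) {
    for (r in seq_len(nrow(lk)))
      expect_identical(st2@linkCell[lk$cell_b[r], lk$node_b[r] + 1L],
                       lk$cell_a[r])
  }
})

test_that("constraint enforcement resolves overlap and arena escape", {
  # two cells displaced to overlap
  st <- pointState(rbind(c(-7, 0), c(7, 0)), c("A", "B"), arenaDiameter = 200)
  st2 <- enforceConstraints(st, maxSweeps = 100)
  expect_gte(minCellSeparation(st2), 0)
  expect_gte(minCellSeparation(st2), 1 - 0.2)  # >= minSeparation - tolerance
  # a single free cell is left untouched (up to tolerance)
  st3 <- pointState(rbind(c(10, -5)), c("A"), arenaDiameter = 200)
  st4 <- enforceConstraints(st3)
  expect_equal(st4@nodesX, st3@nodesX, tolerance = 1e-6)
  expect_equal(st4@nodesY, st3@nodesY, tolerance = 1e-6)
  # nodes pushed outside the arena are projected back
  st5 <- st3
  st5@nodesX <- st5@nodesX + 95
  st6 <- enforceConstraints(st5, maxSweeps = 50)
  expect_true(all(sqrt(st6@nodesX^2 + st6@nodesY^2) <= 100 + 1e-9))
})

test_that("bond lengths relax back toward the ideal bond", {
  st <- pointState(rbind(c(0, 0)), c("A"), arenaDiameter = 200)
  st@nodesX[1, 1] <- st@nodesX[1, 1] + 3  # distort the membrane
  st2 <- enforceConstraints(st, maxSweeps = 200)
  spacing <- sqrt(diff(c(st2@nodesX[1, ], st2@nodesX[1, 1]))^2 +
                  diff(c(st2@nodesY[1, ], st2@nodesY[1, 1]))^2)
  expect_true(all(abs(spacing - st2@idealBond[1]) < 0.35))
})

test_that("dense packings are feasible at the study density", {
  set.seed(42)
  # desk scale: 200 cells in a 250-um arena (packing fraction ~0.72)
  cfg <- experimentConfig(scale = 0.25, nSteps = 0L, nReplicates = 1L)
  st <- initSegregation(cfg)
  expect_equal(nCells(st), 200L)
  expect_equal(unname(table(populations(st))), c(100L, 100L), ignore_attr = TRUE)
  expect_gte(minCellSeparation(st), 1 - 0.5)  # minSeparation - overlapTol
  # full scale feasibility: 800 cells in a 500-um arena
  cfg2 <- experimentConfig(scale = 1, nSteps = 0L, nReplicates = 1L)
  st2 <- initSegregation(cfg2)
  expect_equal(nCells(st2), 800L)
  expect_gte(minCellSeparation(st2), 1 - 0.5)
})

test_that("state checkpoints round-trip bit-exactly through CSV", {
  set.seed(5)
  st <- pointState(rbind(c(-9, 0), c(9, 0), c(2, 16)), c("A", "B", "B"),
                   arenaDiameter = 150)
  st <- runSim(st, abPreset(duration = 3, pRepulsion = 0.9), 600)$state
  path <- tempfile(fileext = ".csv")
  writeStateCSV(st, path)
  st2 <- readStateCSV(path)
  for (nm in slotNames(st)) {
    a <- slot(st, nm); b <- slot(st2, nm)
    dimnames(a) <- NULL; dimnames(b) <- NULL
    names(a) <- NULL; names(b) <- NULL
    expect_identical(a, b, label = paste("slot", nm))
  }
})
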