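# Replicated in-silico assays: initial conditions, experiment runner,
# across-condition statistics, fixture generators.

#' Configure a replicated in-silico assay
#'
#' Defaults reproduce the full-scale setup: 400 cells per population in a
#' 500-um arena, 50 000 steps of 0.5 s, 10 replicates.  \code{scale} shrinks
#' cells and arena together so that the packing density is preserved
#' (\code{scale = 0.25} gives 100 cells per population in a 250-um arena,
#' the desk-scale setting used by the package's own test battery together
#' with \code{nSteps = 10000}).
#'
#' @param preset condition name (see \code{\link{presetNames}}).
#' @param assay "segregation" or "boundary".
#' @param scale joint scaling of cell number (by \code{scale}) and arena
#'   diameter (by \code{sqrt(scale)}).
#' @param nCellsPerPop,arenaDiameter,nSteps,stepSec,recordEvery,nReplicates
#'   see \linkS4class{ExperimentConfig}.
#' @param seeds one seed per replicate; defaults to \code{baseSeed + 1:n}.
#' @param baseSeed base for the default seed list.
#' @param mixingBand width (um) of the initial label-mixing band in the
#'   boundary assay; kept in absolute units (about three cell diameters)
#'   at every scale because the cells themselves do not scale.
#' @return an \linkS4class{ExperimentConfig}
#' @export
experimentConfig <- function(preset = "control_EphB2_ephrinB1",
                             assay = c("boundary", "segregation"),
                             scale = 1,
                             nCellsPerPop = round(400 * scale),
                             arenaDiameter = 500 * sqrt(scale),
                             nSteps = 50000L, stepSec = 0.5,
                             recordEvery = 500L, nReplicates = 10L,
                             seeds = NULL, baseSeed = 20170338L,
                             mixingBand = 50) {
  assay <- match.arg(assay)
  if (is.null(seeds)) seeds <- baseSeed + seq_len(nReplicates)
  cfg <- new("ExperimentConfig", preset = preset, assay = assay,
             nCellsPerPop = as.integer(nCellsPerPop),
             arenaDiameter = arenaDiameter, nSteps = as.integer(nSteps),
             stepSec = stepSec, recordEvery = as.integer(recordEvery),
             nReplicates = as.integer(nReplicates),
             seeds = as.integer(seeds), mixingBand = mixingBand)
  validObject(cfg)
  cfg
}

# internal: randomized dense non-overlapping packing. Cells are laid on a
# jittered hexagonal lattice sized to the target count, then relaxed by the
# constraint solver so that membranes respect the minimum separation.
packCells <- function(nTotal, arenaDiameter, radius = 7.5, jitter = 1,
                      stepSec = 0.5, contactDist = 2, relaxSweeps = 300L) {
  R <- arenaDiameter / 2
  Reff <- R - radius
  if (Reff <= 0) stop("arena too small for the cell radius")
  s <- sqrt(2 * pi * Reff^2 / (sqrt(3) * nTotal))
  for (try in 1:60) {
    nxg <- ceiling(2 * Reff / s) + 2
    pts <- list()
    for (row in -nxg:nxg) {
      y <- row * s * sqrt(3) / 2
      off <- if (row %% 2 == 0) 0 else s / 2
      xs <- seq(-nxg, nxg) * s + off
      pts[[length(pts) + 1]] <- cbind(xs, y)
    }
    pts <- do.call(rbind, pts)
    keep <- sqrt(rowSums(pts^2)) <= Reff
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) >= nTotal) break
    s <- s * 0.985
    if (try == 60)
      stop("packing failed: could not fit ", nTotal,
           " cells; lower the density or enlarge the arena")
  }
  ord <- order(rowSums(pts^2))
  pts <- pts[ord[seq_len(nTotal)], , drop = FALSE]
  pts <- pts + matrix(runif(2 * nTotal, -jitter, jitter), nTotal, 2)
  # keep jittered centres strictly inside the feasible disc
  rr <- sqrt(rowSums(pts^2))
  out <- rr > Reff - 1e-6
  pts[out, ] <- pts[out, ] * ((Reff - 1e-6) / rr[out])
  pts
}

# internal: assemble a state from packed centres + labels, then relax
packedState <- function(centres, labels, popNames, arenaDiameter,
                        radius = 7.5, stepSec = 0.5, relaxSweeps = 300L,
                        contactDist = 2) {
  cells <- lapply(seq_len(nrow(centres)), function(i)
    makeCell(centres[i, ], labels[i], radius = radius,
             arenaDiameter = arenaDiameter))
  st <- newSimState(cells, arenaDiameter = arenaDiameter,
                    popNames = popNames, stepSec = stepSec)
  enforceConstraints(st, maxSweeps = relaxSweeps)
}

#' Initial state of a segregation assay
#'
#' Both populations intermingled at the start: cells are packed densely at
#' random and labels are assigned uniformly at random in exactly equal
#' numbers.
#'
#' @param config an \linkS4class{ExperimentConfig}
#' @return a \linkS4class{SimState}
#' @export
initSegregation <- function(config) {
  pr <- buildPreset(config@preset)
  pops <- pr@interaction@popNames
  n <- 2L * config@nCellsPerPop
  centres <- packCells(n, config@arenaDiameter, stepSec = config@stepSec,
                       contactDist = pr@motility@contactDist)
  labels <- sample(rep(pops, each = config@nCellsPerPop))
  packedState(centres, labels, pops, config@arenaDiameter,
              stepSec = config@stepSec,
              contactDist = pr@motility@contactDist)
}

#' Initial state of a boundary assay
#'
#' Each population occupies one half of the field, separated by a fuzzy
#' initial interface that mimics the ragged line along which two advancing
#' cell fronts meet after barrier removal: the dividing line is a smooth
#' curve (two sinusoidal modes with amplitudes proportional to the mixing
#' band; the shape is fixed, like the physical barrier of the wet assay,
#' while packing and interdigitation vary with the seed), and cells within
#' a thin strip of the line exchange labels pairwise, giving local
#' interdigitation.  Label counts stay exactly equal; a mixing band of 0
#' gives a perfectly straight initial border.
#'
#' @param config an \linkS4class{ExperimentConfig}
#' @return a \linkS4class{SimState}
#' @export
initBoundary <- function(config) {
  pr <- buildPreset(config@preset)
  pops <- pr@interaction@popNames
  n <- 2L * config@nCellsPerPop
  centres <- packCells(n, config@arenaDiameter, stepSec = config@stepSec,
                       contactDist = pr@motility@contactDist)
  band <- config@mixingBand
  D <- config@arenaDiameter
  score <- centres[, 1]
  if (band > 0) {
    # the interface shape is part of the assay design and identical across
    # replicates (like the physical barrier of the wet assay); packing,
    # interdigitation and dynamics carry the replicate-to-replicate noise
    a1 <- 0.6 * band; a2 <- 0.25 * band
    bline <- a1 * sin(2 * pi * centres[, 2] / (D / 2.5) + 0.7) +
             a2 * sin(2 * pi * centres[, 2] / (D / 6) + 2.1)
    score <- centres[, 1] - bline
  }
  labels <- rep(pops[2], n)
  labels[rank(score, ties.method = "first") <= config@nCellsPerPop] <- pops[1]
  if (band > 0) {
    # thin interdigitation strip along the meeting line
    cand <- which(abs(score) <= 0.15 * band & runif(n) < 0.5)
    left <- cand[labels[cand] == pops[1]]
    right <- cand[labels[cand] == pops[2]]
    m <- min(length(left), length(right))
    if (m > 0) {
      left <- left[sample.int(length(left), m)]
      right <- right[sample.int(length(right), m)]
      labels[left] <- pops[2]; labels[right] <- pops[1]
    }
  }
  packedState(centres, labels, pops, config@arenaDiameter,
              stepSec = config@stepSec,
              contactDist = pr@motility@contactDist)
}

#' Run a replicated in-silico assay
#'
#' Runs every replicate with its own seed, records the assay metric
#' (normalised border length for boundary assays, segregation index for
#' segregation assays) at the recording cadence, and aggregates the time
#' courses as mean and standard error across replicates.  For segregation
#' assays a cluster particle-analysis report of the first population is
#' attached per replicate.  With \code{outDir} set, per-replicate time
#' courses, final-state checkpoints, the aggregate table and a metadata
#' file are written as CSV/JSON.
#'
#' @param config an \linkS4class{ExperimentConfig}
#' @param outDir optional output directory.
#' @param verbose print progress.
#' @return an \linkS4class{ExperimentResult}
#' @export
runExperiment <- function(config, outDir = NULL, verbose = FALSE) {
  preset <- buildPreset(config@preset)
  preset@motility@stepSec <- config@stepSec
  metricName <- if (config@assay == "boundary") "border_length_norm"
    else "segregation_index"
  reps <- vector("list", config@nReplicates)
  for (r in seq_len(config@nReplicates)) {
    seed <- config@seeds[r]
    set.seed(seed)
    st0 <- if (config@assay == "boundary") initBoundary(config)
      else initSegregation(config)
    res <- runSim(st0, preset, config@nSteps,
                  recordEvery = max(config@recordEvery, 1L))
    sn <- res$snapshots
    steps <- unique(sn$step)
    vals <- vapply(steps, function(s) {
      pts <- sn[sn$step == s, c("x", "y", "population")]
      if (config@assay == "boundary")
        borderLength(pts)$length / config@arenaDiameter
      else segregationIndex(pts)
    }, 0)
    tc <- data.frame(step = steps, time_min = steps * config@stepSec / 60,
                     value = vals)
    rep <- list(seed = seed, timecourse = tc, finalState = res$state,
                eventCounts = res$counts)
    if (config@assay == "segregation")
      rep$clusterReport <- clusterParticleAnalysis(res$state)
    reps[[r]] <- rep
    if (verbose)
      message(sprintf("replicate %d/%d (seed %d): final %s = %.4f",
                      r, config@nReplicates, seed, metricName,
                      tc$value[nrow(tc)]))
  }
  agg <- aggregateTimecourses(reps)
  out <- new("ExperimentResult", config = config, metricName = metricName,
             replicates = reps, aggregate = agg)
  if (!is.null(outDir)) writeExperiment(out, outDir)
  out
}

# internal: mean +/- s.e. time course across replicates
aggregateTimecourses <- function(reps) {
  steps <- reps[[1]]$timecourse$step
  vals <- vapply(reps, function(r) r$timecourse$value, numeric(length(steps)))
  vals <- matrix(vals, nrow = length(steps))
  data.frame(step = steps,
             time_min = reps[[1]]$timecourse$time_min,
             mean = rowMeans(vals),
             se = apply(vals, 1, sd) / sqrt(ncol(vals)))
}

#' Final metric value of every replicate
#'
#' The instantaneous border-length reading fluctuates from one recorded
#' frame to the next (the midpoint chain is sensitive to single-cell
#' moves), so the endpoint values are averaged over a short window of
#' recorded frames.
#'
#' @param result an \linkS4class{ExperimentResult}
#' @param window number of recorded frames to average (from the end).
#' @return numeric vector, one value per replicate
#' @export
finalValues <- function(result, window = 5L) {
  vapply(result@replicates, function(r) {
    k <- nrow(r$timecourse)
    mean(r$timecourse$value[max(1, k - window + 1):k])
  }, 0)
}

#' Initial metric value of every replicate
#' @param result an \linkS4class{ExperimentResult}
#' @param window number of recorded frames to average (from the start);
#'   the default 1 reports the exact initial-state metric.
#' @return numeric vector, one value per replicate
#' @export
initialValues <- function(result, window = 1L) {
  vapply(result@replicates, function(r)
    mean(r$timecourse$value[seq_len(min(window, nrow(r$timecourse)))]), 0)
}

# internal: write an ExperimentResult as CSV + JSON metadata
writeExperiment <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(result@replicates)) {
    rep <- result@replicates[[r]]
    write.csv(rep$timecourse,
              file.path(outDir, sprintf("replicate_%02d_timecourse.csv", r)),
              row.names = FALSE)
    writeStateCSV(rep$finalState,
                  file.path(outDir, sprintf("replicate_%02d_final_state.csv", r)))
    if (!is.null(rep$clusterReport))
      write.csv(rep$clusterReport,
                file.path(outDir, sprintf("replicate_%02d_clusters.csv", r)),
                row.names = FALSE)
  }
  write.csv(result@aggregate, file.path(outDir, "aggregate_timecourse.csv"),
            row.names = FALSE)
  cfg <- result@config
  meta <- list(preset = cfg@preset, assay = cfg@assay,
               n_cells_per_pop = cfg@nCellsPerPop,
               arena_diameter_um = cfg@arenaDiameter, n_steps = cfg@nSteps,
               step_sec = cfg@stepSec, record_every = cfg@recordEvery,
               n_replicates = cfg@nReplicates, seeds = cfg@seeds,
               metric = result@metricName,
               package_version = as.character(packageVersion("repelsim")))
  jsonlite::write_json(meta, file.path(outDir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}

#' Compare the final metric of two conditions
#'
#' Two-sided Mann-Whitney U test (exact when there are no ties) on the
#' final per-replicate metric values of two experiment results.
#'
#' @param resultA,resultB \linkS4class{ExperimentResult} objects recording
#'   the same metric.
#' @return list with U, p, and the two condition medians
#' @export
compareConditions <- function(resultA, resultB) {
  if (resultA@metricName != resultB@metricName)
    stop("results record different metrics: ",
         resultA@metricName, " vs ", resultB@metricName)
  if (length(resultA@replicates) < 3 || length(resultB@replicates) < 3)
    stop("need at least 3 replicates per condition")
  a <- finalValues(resultA)
  b <- finalValues(resultB)
  wt <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       medianA = median(a), medianB = median(b),
       conditionA = resultA@config@preset, conditionB = resultB@config@preset)
}

# ---- fixture generators ---------------------------------------------------

#' Generate deterministic synthetic inputs with known ground truth
#'
#' Writes small synthetic data sets for exercising the metrics: labelled
#' point sets with a straight or checkerboard interface of known border
#' length, scripted two-cell track tables with contacts of known duration
#' (optionally with collapse annotations and a post-contact speed burst),
#' and binary masks containing blobs of specified areas.  A JSON sidecar
#' records the ground truth.
#'
#' @param kind "labelled_points", "scripted_tracks" or "boundary_masks".
#' @param params named list of kind-specific parameters (see Details).
#' @param seed RNG seed for the randomized variants.
#' @param outDir directory to write into.
#' @details
#' \describe{
#'   \item{labelled_points}{\code{width}, \code{height}, \code{spacing}
#'     (um; default 100 x 100 at 10), \code{arrangement} of "split",
#'     "checkerboard" or "random".  Ground truth border length of the
#'     split arrangement is \code{height}.}
#'   \item{scripted_tracks}{\code{nContacts} (default 4),
#'     \code{contactFrames} frames in contact per episode (default 4,
#'     i.e. 12 min at 3-min frames), \code{frameIntervalMin} (default 3),
#'     \code{collapse} (default TRUE: each contact ends with a collapse of
#'     cell 1), \code{burstFactor} speed multiplier for the 6 min after
#'     contact (default 1 = no burst).}
#'   \item{boundary_masks}{\code{areas} blob areas in um^2 (default
#'     c(600, 600)), \code{scale} um/pixel (default 1).}
#' }
#' @return named list of written file paths, invisibly
#' @export
generateFixture <- function(kind, params = list(), seed = 1,
                            outDir = tempfile("fixture")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  P <- function(nm, dflt) if (!is.null(params[[nm]])) params[[nm]] else dflt
  paths <- list()
  if (kind == "labelled_points") {
    width <- P("width", 100); height <- P("height", 100)
    sp <- P("spacing", 2.5); arr <- P("arrangement", "split")
    gx <- seq(sp / 2, width - sp / 2, by = sp)
    gy <- seq(sp / 2, height - sp / 2, by = sp)
    g <- expand.grid(x_um = gx, y_um = gy)
    lab <- switch(arr,
      split = ifelse(g$x_um < width / 2, "A", "B"),
      checkerboard = ifelse((floor(g$x_um / sp) + floor(g$y_um / sp)) %% 2 == 0,
                            "A", "B"),
      random = sample(rep(c("A", "B"), length.out = nrow(g))),
      stop("unknown arrangement"))
    pts <- data.frame(cell_id = seq_len(nrow(g)), population = lab,
                      x_um = g$x_um, y_um = g$y_um)
    paths$points <- file.path(outDir, "labelled_points.csv")
    write.csv(pts, paths$points, row.names = FALSE)
    truth <- list(kind = kind, arrangement = arr,
                  border_length_um = if (arr == "split") height else NA,
                  interface_width_um = height)
  } else if (kind == "scripted_tracks") {
    nC <- P("nContacts", 4); cf <- P("contactFrames", 4)
    dt <- P("frameIntervalMin", 3); collapse <- P("collapse", TRUE)
    burst <- P("burstFactor", 1)
    v <- 3  # um/min: 9 um per frame, so one frame leaves the contact radius
    gapFrames <- 12  # separation between contact episodes (36 min)
    segs <- list()
    frame <- 0
    for (k in seq_len(nC)) {
      # cell 1 approaches from the left, touches for cf frames, retreats
      approach <- 3
      for (ph in seq_len(approach)) {
        segs[[length(segs) + 1]] <- c(frame, -10 - (approach - ph + 1) * v * dt, 0, FALSE)
        frame <- frame + 1
      }
      for (ph in seq_len(cf)) {
        segs[[length(segs) + 1]] <- c(frame, -10, 0, ph == cf && collapse)
        frame <- frame + 1
      }
      for (ph in seq_len(gapFrames)) {
        speed <- if (ph * dt <= 6) v * burst else v
        prev <- segs[[length(segs)]]
        segs[[length(segs) + 1]] <- c(frame, prev[2] - speed * dt, 0, FALSE)
        frame <- frame + 1
      }
    }
    m <- do.call(rbind, segs)
    tr1 <- data.frame(frame = m[, 1], time_min = m[, 1] * dt, cell_id = 1,
                      population = "A", x_um = m[, 2], y_um = m[, 3],
                      collapse = as.logical(m[, 4]))
    tr2 <- data.frame(frame = m[, 1], time_min = m[, 1] * dt, cell_id = 2,
                      population = "B", x_um = 0, y_um = 0, collapse = FALSE)
    tracks <- rbind(tr1, tr2)
    tracks <- tracks[order(tracks$frame, tracks$cell_id), ]
    paths$tracks <- file.path(outDir, "scripted_tracks.csv")
    write.csv(tracks, paths$tracks, row.names = FALSE)
    truth <- list(kind = kind, n_contacts = nC,
                  contact_duration_min = cf * dt,
                  frame_interval_min = dt, collapse = collapse,
                  burst_factor = burst)
  } else if (kind == "boundary_masks") {
    areas <- P("areas", c(600, 600)); scale <- P("scale", 1)
    radii <- sqrt(areas / pi)
    npix <- ceiling((sum(radii * 2) + 40 * length(areas)) / scale)
    mask <- matrix(0L, npix, npix)
    cx <- cumsum(2 * radii + 20) - radii
    cy <- npix * scale / 2
    ax <- (seq_len(npix) - 0.5) * scale
    realAreas <- numeric(length(areas))
    for (i in seq_along(areas)) {
      sub <- outer((ax - cx[i])^2, (ax - cy)^2, "+") <= radii[i]^2
      mask[sub] <- 1L
      realAreas[i] <- sum(sub) * scale^2
    }
    paths$mask <- file.path(outDir, "boundary_mask.csv")
    write.table(mask, paths$mask, row.names = FALSE, col.names = FALSE,
                sep = ",")
    truth <- list(kind = kind, requested_areas_um2 = areas,
                  rasterized_areas_um2 = realAreas, scale_um_per_px = scale)
  } else {
    stop("unknown fixture kind '", kind,
         "'; use labelled_points, scripted_tracks or boundary_masks")
  }
  paths$truth <- file.path(outDir, "ground_truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
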