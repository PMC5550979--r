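# Geometry: cell construction, constraint enforcement, state serialization.

octAngles <- seq(0, 2 * pi, length.out = 9)[1:8]

#' Construct a single cell
#'
#' Places eight membrane nodes on a regular octagon of the given radius
#' around the centre, picks a uniformly random leader node, and sets the
#' ideal bond length to the octagon edge, \code{2 * radius * sin(pi/8)}.
#'
#' @param center numeric length-2 centre position (um).
#' @param population population label.
#' @param radius cell radius (um); default 7.5 (15 um diameter).
#' @param arenaDiameter arena diameter (um) the cell must fit inside.
#' @return a plain list describing the cell; assemble cells into a state
#'   with \code{\link{newSimState}}.
#' @examples
#' cell <- makeCell(c(0, 0), "A")
#' sqrt(rowSums(sweep(cell$nodes, 2, cell$centroid)^2))  # all 7.5
#' @export
makeCell <- function(center, population, radius = 7.5, arenaDiameter = 500) {
  if (radius <= 0) stop("cell radius must be > 0")
  if (sqrt(sum(center^2)) > arenaDiameter / 2 - radius)
    stop("cell centre must be at least one radius inside the arena")
  nodes <- cbind(center[1] + radius * cos(octAngles),
                 center[2] + radius * sin(octAngles))
  leader <- sample.int(8L, 1L) - 1L
  list(centroid = c(center[1], center[2]), nodes = nodes,
       leader = leader, population = population, radius = radius,
       idealBond = 2 * radius * sin(pi / 8))
}

#' Assemble cells into a simulation state
#'
#' @param cells list of cells from \code{\link{makeCell}}.
#' @param arenaDiameter arena diameter (um).
#' @param popNames optional character(2) fixing the population order;
#'   inferred from the cells otherwise.
#' @param stepSec step duration (s).
#' @return a \linkS4class{SimState}
#' @export
newSimState <- function(cells, arenaDiameter = 500, popNames = NULL,
                        stepSec = 0.5) {
  n <- length(cells)
  labs <- vapply(cells, `[[`, "", "population")
  if (is.null(popNames)) popNames <- unique(labs)
  if (length(popNames) == 1L) popNames <- c(popNames, paste0(popNames, "_2"))
  if (!all(labs %in% popNames)) stop("cell population not in popNames")
  nx <- t(vapply(cells, function(c) c$nodes[, 1], numeric(8)))
  ny <- t(vapply(cells, function(c) c$nodes[, 2], numeric(8)))
  st <- new("SimState",
    arenaDiameter = arenaDiameter, nodesX = nx, nodesY = ny,
    heading = vapply(cells, function(c) {
      k <- c$leader + 1L
      atan2(c$nodes[k, 2] - c$centroid[2], c$nodes[k, 1] - c$centroid[1])
    }, 0),
    leader = vapply(cells, function(c) as.integer(c$leader), 0L),
    population = match(labs, popNames),
    popNames = popNames,
    linkCell = matrix(NA_integer_, n, 8), linkNode = matrix(NA_integer_, n, 8),
    avoidCell = matrix(NA_integer_, n, 8), avoidSteps = matrix(0L, n, 8),
    commit = integer(n),
    radius = vapply(cells, `[[`, 0, "radius"),
    idealBond = vapply(cells, `[[`, 0, "idealBond"),
    cellId = seq_len(n), stepCount = 0L, stepSec = stepSec)
  validObject(st)
  st
}

# internal: R <-> C++ state conversion (C++ is fully 0-based, -1 = no link)
stateToCpp <- function(state) {
  lc <- state@linkCell; lc[is.na(lc)] <- 0L
  ln <- state@linkNode; ln[is.na(ln)] <- -1L
  ac <- state@avoidCell; ac[is.na(ac)] <- 0L
  list(nx = state@nodesX, ny = state@nodesY, heading = state@heading,
       leader = state@leader, pop = state@population - 1L,
       linkC = lc - 1L, linkN = ln, avoidC = ac - 1L,
       avoidS = state@avoidSteps, commit = state@commit,
       stepCount = state@stepCount)
}

cppToState <- function(state, out) {
  lc <- out$linkC; ln <- out$linkN
  lc[lc < 0L] <- NA_integer_; ln[ln < 0L] <- NA_integer_
  if (!is.null(out$nx)) { state@nodesX <- out$nx; state@nodesY <- out$ny }
  state@heading <- out$heading; state@leader <- out$leader
  state@linkCell <- lc + 1L; state@linkNode <- ln
  if (!is.null(out$avoidC)) {
    ac <- out$avoidC
    ac[ac < 0L] <- NA_integer_
    state@avoidCell <- ac + 1L
    state@avoidSteps <- out$avoidS
  }
  if (!is.null(out$commit)) state@commit <- out$commit
  if (!is.null(out$stepCount)) state@stepCount <- as.integer(out$stepCount)
  state
}

#' Restore the structural constraints of a state
#'
#' Runs iterative position projection: adjacent-node bonds relax toward the
#' ideal bond length, nodes toward the ideal radius (hard-capped at twice
#' it), linked nodes toward the contact distance, nodes of distinct cells
#' are separated to at least the contact distance, and all nodes are clamped
#' inside the arena.  Sweeps stop early once the largest correction falls
#' below 1e-4 um.
#'
#' @param state a \linkS4class{SimState}
#' @param maxSweeps maximum projection sweeps.
#' @param minSeparation minimum inter-cell node separation (um).
#' @param linkStretch maximum separation (um) of linked nodes before the
#'   compliant tether engages.
#' @return the corrected \linkS4class{SimState}
#' @export
enforceConstraints <- function(state, maxSweeps = 10L, minSeparation = 1,
                               linkStretch = 4) {
  s <- stateToCpp(state)
  out <- cpp_enforce_constraints(s$nx, s$ny, s$linkC, s$linkN,
                                 state@arenaDiameter / 2, state@radius,
                                 state@idealBond, minSeparation, linkStretch,
                                 as.integer(maxSweeps))
  state@nodesX <- out$nx
  state@nodesY <- out$ny
  state
}

#' Minimum node separation between distinct cells
#'
#' Used to check the no-overlap invariant: after constraint enforcement the
#' value should not fall below \code{contactDist - overlapTol}.
#'
#' @param state a \linkS4class{SimState}
#' @return numeric scalar (um); \code{Inf} for fewer than two cells
#' @export
minCellSeparation <- function(state) {
  n <- nCells(state)
  if (n < 2) return(Inf)
  px <- as.vector(t(state@nodesX)); py <- as.vector(t(state@nodesY))
  cell <- rep(seq_len(n), each = 8)
  d <- as.matrix(dist(cbind(px, py)))
  same <- outer(cell, cell, "==")
  d[same] <- Inf
  min(d)
}

# ---- CSV checkpointing ----------------------------------------------------

#' Write a state checkpoint as a flat per-cell CSV table
#'
#' One row per cell: step, time_min, cell_id, population, centroid, leader,
#' heading, geometry constants, the 16 node coordinates and the link/
#' refractory bookkeeping.  Numbers are written with 17 significant digits
#' so that \code{\link{readStateCSV}} restores the state bit-exactly.
#'
#' @param state a \linkS4class{SimState}
#' @param path file to write
#' @return \code{path}, invisibly
#' @export
writeStateCSV <- function(state, path) {
  n <- nCells(state)
  num <- function(x) sprintf("%.17g", x)
  df <- data.frame(
    step = state@stepCount, time_min = num(simTimeMin(state)),
    cell_id = state@cellId, population = populations(state),
    centroid_x = num(rowMeans(state@nodesX)),
    centroid_y = num(rowMeans(state@nodesY)),
    leader_index = state@leader, heading = num(state@heading),
    radius = num(state@radius), ideal_bond = num(state@idealBond),
    arena_diameter = num(state@arenaDiameter),
    step_sec = num(state@stepSec),
    pop_a = state@popNames[1], pop_b = state@popNames[2],
    stringsAsFactors = FALSE)
  for (i in 1:8) df[[paste0("node", i - 1, "_x")]] <- num(state@nodesX[, i])
  for (i in 1:8) df[[paste0("node", i - 1, "_y")]] <- num(state@nodesY[, i])
  for (i in 1:8) df[[paste0("link_cell", i - 1)]] <- state@linkCell[, i]
  for (i in 1:8) df[[paste0("link_node", i - 1)]] <- state@linkNode[, i]
  for (i in 1:8) df[[paste0("avoid_cell", i - 1)]] <- state@avoidCell[, i]
  for (i in 1:8) df[[paste0("avoid_steps", i - 1)]] <- state@avoidSteps[, i]
  df$commit_steps <- state@commit
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a state checkpoint written by \code{\link{writeStateCSV}}
#' @param path CSV file
#' @return a \linkS4class{SimState}
#' @export
readStateCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  n <- nrow(df)
  grab <- function(stem) {
    m <- sapply(0:7, function(i) df[[paste0(stem, i)]])
    if (n == 1L) m <- matrix(m, nrow = 1)
    m
  }
  popNames <- c(df$pop_a[1], df$pop_b[1])
  intm <- function(m) { storage.mode(m) <- "integer"; m }
  nx <- sapply(0:7, function(i) df[[paste0("node", i, "_x")]])
  ny <- sapply(0:7, function(i) df[[paste0("node", i, "_y")]])
  if (n == 1L) { nx <- matrix(nx, 1); ny <- matrix(ny, 1) }
  storage.mode(nx) <- storage.mode(ny) <- "double"
  st <- new("SimState",
    arenaDiameter = as.numeric(df$arena_diameter[1]),
    nodesX = nx, nodesY = ny,
    heading = as.numeric(df$heading), leader = as.integer(df$leader_index),
    population = match(df$population, popNames), popNames = popNames,
    linkCell = intm(grab("link_cell")), linkNode = intm(grab("link_node")),
    avoidCell = intm(grab("avoid_cell")), avoidSteps = intm(grab("avoid_steps")),
    commit = as.integer(df$commit_steps),
    radius = as.numeric(df$radius), idealBond = as.numeric(df$ideal_bond),
    cellId = as.integer(df$cell_id), stepCount = as.integer(df$step[1]),
    stepSec = as.numeric(df$step_sec[1]))
  validObject(st)
  st
}
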