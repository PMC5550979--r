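#' @useDynLib repelsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats runif setNames dist wilcox.test chisq.test sd median
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Motility and numerical parameters of the cell model
#'
#' Holds the per-cell motility parameters and the numerical knobs of one
#' simulation step.  Units: speeds in micrometres per minute, durations in
#' minutes, distances in micrometres.
#'
#' @slot speed free migration speed (um/min); default 0.75.
#' @slot pChangeDir probability of a spontaneous direction change per
#'   decision tick; default 0.2.
#' @slot decisionTickMin interval (min) at which spontaneous direction
#'   changes are evaluated; default 1 simulated minute.
#' @slot stepSec duration of one simulation step in seconds; default 0.5.
#' @slot contactDist distance (um) between membrane nodes of different cells
#'   at or below which an adhesion link forms; also the rest length of a
#'   link; default 2.
#' @slot minSeparation hard minimum distance (um) enforced between membrane
#'   nodes of different cells; smaller than the contact (sensing) distance
#'   so that membranes can slide past each other; default 1.
#' @slot pullWeight cohesive pull in [0,1]: fraction by which a linked
#'   neighbour's heading rotates toward a repelled cell's new direction.
#' @slot linkStretch compliance of an adhesion link (um): the maximum
#'   separation of a linked node pair before the tether pulls it back, so
#'   membranes can slide a little along each other while the cells remain
#'   in contact; default 4 (twice the contact distance).
#' @slot refractoryMin time (min) after a stochastic link break during
#'   which the two cells involved do not re-link to each other (other
#'   partners are unaffected); prevents an instantaneous re-formation of
#'   the just-broken contact.
#' @slot maxSweeps maximum constraint-projection sweeps per step.
#' @slot overlapTol tolerance (um) on the minimum node separation when
#'   checking that no two cells overlap.
#' @export
setClass("SimParams", representation(
  speed = "numeric", pChangeDir = "numeric", decisionTickMin = "numeric",
  stepSec = "numeric", contactDist = "numeric", minSeparation = "numeric",
  linkStretch = "numeric", pullWeight = "numeric", refractoryMin = "numeric",
  maxSweeps = "integer", overlapTol = "numeric"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@speed < 0) msg <- c(msg, "speed must be >= 0")
  if (object@pChangeDir < 0 || object@pChangeDir > 1)
    msg <- c(msg, "pChangeDir must be in [0, 1]")
  if (object@pullWeight < 0 || object@pullWeight > 1)
    msg <- c(msg, "pullWeight must be in [0, 1]")
  if (object@stepSec <= 0) msg <- c(msg, "stepSec must be > 0")
  if (object@contactDist <= 0) msg <- c(msg, "contactDist must be > 0")
  if (object@minSeparation <= 0 || object@minSeparation > object@contactDist)
    msg <- c(msg, "minSeparation must be in (0, contactDist]")
  if (object@linkStretch < object@contactDist)
    msg <- c(msg, "linkStretch must be at least contactDist")
  if (length(msg)) msg else TRUE
})

#' Pairwise interaction parameters of two cell populations
#'
#' A 2 x 2 parameterisation of cell-cell contact behaviour.  Rows index the
#' focal (responding) population, columns the contacted population, so the
#' diagonal holds homotypic behaviour and the off-diagonal heterotypic
#' behaviour, which may be asymmetric.
#'
#' @slot popNames names of the two populations.
#' @slot durationMin mean contact duration (min) per focal/partner pair; the
#'   per-minute link-breaking rate is its inverse.
#' @slot pRepulsion probability that a broken contact triggers a directed
#'   repulsion (leader moved to the node opposite the contact) in the focal
#'   cell.
#' @slot directed logical; if \code{FALSE} the pair interacts in
#'   "adhesion-only" mode and the focal cell re-chooses its leader uniformly
#'   at random when a contact breaks (random migration after contact).
#' @slot escapeMin duration (min) of the focal cell's committed directed
#'   migration away after a collapse response triggered by the given
#'   partner class; longer values encode the measured post-repulsion
#'   migration burst, shorter values its absence.
#' @export
setClass("InteractionParams", representation(
  popNames = "character", durationMin = "matrix",
  pRepulsion = "matrix", directed = "matrix", escapeMin = "matrix"))

setValidity("InteractionParams", function(object) {
  msg <- character()
  if (length(object@popNames) != 2L) msg <- c(msg, "exactly two populations required")
  for (nm in c("durationMin", "pRepulsion", "directed", "escapeMin"))
    if (!all(dim(slot(object, nm)) == c(2L, 2L)))
      msg <- c(msg, paste(nm, "must be a 2 x 2 matrix"))
  if (any(object@durationMin <= 0)) msg <- c(msg, "durations must be > 0")
  if (any(object@pRepulsion < 0 | object@pRepulsion > 1))
    msg <- c(msg, "pRepulsion entries must be in [0, 1]")
  if (any(object@escapeMin < 0)) msg <- c(msg, "escapeMin must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A named simulation condition
#'
#' Bundles the interaction matrix, the motility parameters and provenance
#' notes stating which measured behaviour values the condition encodes.
#'
#' @slot name catalog name of the condition.
#' @slot interaction an \linkS4class{InteractionParams}.
#' @slot motility a \linkS4class{SimParams}.
#' @slot notes provenance notes (one string per remark).
#' @export
setClass("Preset", representation(
  name = "character", interaction = "InteractionParams",
  motility = "SimParams", notes = "character"))

#' Geometric state of a simulation
#'
#' Cells live in a circular arena centred at the origin.  Each cell is a
#' closed ring of eight membrane nodes; ring (and link) node indices run 0-7
#' and the leader index marks the node toward which the cell migrates.  The
#' heading slot carries the continuous migration direction; it is set to the
#' direction of the leader node whenever an event (repulsion, spontaneous
#' change) reassigns the leader, and is rotated continuously by cohesive
#' pulling.
#'
#' @slot arenaDiameter arena diameter (um).
#' @slot nodesX,nodesY N x 8 node coordinates (um).
#' @slot heading migration direction (radians), length N.
#' @slot leader leader node index 0-7, length N.
#' @slot population population index (1 or 2) per cell.
#' @slot popNames the two population labels.
#' @slot linkCell N x 8: partner cell (row index) of the adhesion link held
#'   by each node, \code{NA} if unlinked.
#' @slot linkNode N x 8: partner node index 0-7, \code{NA} if unlinked.
#' @slot avoidCell,avoidSteps N x 8: cells this cell will not re-link to
#'   after a recent break, and the remaining steps of each entry
#'   (\code{NA}/0 when empty).
#' @slot commit remaining steps of the committed post-collapse escape phase
#'   per cell (heading locked while positive).
#' @slot radius ideal cell radius (um) per cell.
#' @slot idealBond ideal adjacent-node distance (um) per cell.
#' @slot cellId integer cell identifiers.
#' @slot stepCount number of steps taken so far.
#' @slot stepSec step duration (s).
#' @export
setClass("SimState", representation(
  arenaDiameter = "numeric", nodesX = "matrix", nodesY = "matrix",
  heading = "numeric", leader = "integer", population = "integer",
  popNames = "character", linkCell = "matrix", linkNode = "matrix",
  avoidCell = "matrix", avoidSteps = "matrix", commit = "integer",
  radius = "numeric",
  idealBond = "numeric", cellId = "integer", stepCount = "integer",
  stepSec = "numeric"))

setValidity("SimState", function(object) {
  msg <- character()
  n <- nrow(object@nodesX)
  if (object@arenaDiameter <= 0) msg <- c(msg, "arenaDiameter must be > 0")
  if (ncol(object@nodesX) != 8L || ncol(object@nodesY) != 8L)
    msg <- c(msg, "cells must have exactly 8 membrane nodes")
  if (!all(dim(object@nodesY) == dim(object@nodesX)))
    msg <- c(msg, "nodesX and nodesY must have matching dimensions")
  for (nm in c("heading", "leader", "population", "radius", "idealBond",
               "cellId", "commit"))
    if (length(slot(object, nm)) != n)
      msg <- c(msg, paste(nm, "must have one entry per cell"))
  if (n > 0 && (any(object@leader < 0L) || any(object@leader > 7L)))
    msg <- c(msg, "leader indices must be in 0-7")
  if (n > 0 && !all(object@population %in% c(1L, 2L)))
    msg <- c(msg, "population must be 1 or 2")
  if (length(object@popNames) != 2L) msg <- c(msg, "two population labels required")
  if (n > 0) {
    rr <- sqrt(object@nodesX^2 + object@nodesY^2)
    if (max(rr) > object@arenaDiameter / 2 + 1e-6)
      msg <- c(msg, "all nodes must lie inside the arena")
    cx <- rowMeans(object@nodesX); cy <- rowMeans(object@nodesY)
    nodeR <- sqrt((object@nodesX - cx)^2 + (object@nodesY - cy)^2)
    if (any(nodeR > 2 * object@radius + 1e-6))
      msg <- c(msg, "centroid-node distance exceeds twice the cell radius")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of a replicated in-silico assay
#'
#' @slot preset catalog name of the condition to simulate.
#' @slot assay \code{"segregation"} (intermingled start) or
#'   \code{"boundary"} (two half-fields with a fuzzy interface).
#' @slot nCellsPerPop cells per population.
#' @slot arenaDiameter arena diameter (um).
#' @slot nSteps steps to run.
#' @slot stepSec step duration (s).
#' @slot recordEvery recording cadence in steps.
#' @slot nReplicates number of independent replicates.
#' @slot seeds one RNG seed per replicate.
#' @slot mixingBand width (um) of the label-mixing band around the midline
#'   in the boundary assay.
#' @export
setClass("ExperimentConfig", representation(
  preset = "character", assay = "character", nCellsPerPop = "integer",
  arenaDiameter = "numeric", nSteps = "integer", stepSec = "numeric",
  recordEvery = "integer", nReplicates = "integer", seeds = "integer",
  mixingBand = "numeric"))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (!object@assay %in% c("segregation", "boundary"))
    msg <- c(msg, "assay must be 'segregation' or 'boundary'")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(object@seeds) != object@nReplicates)
    msg <- c(msg, "one seed per replicate required")
  if (anyDuplicated(object@seeds)) msg <- c(msg, "seeds must be unique")
  if (object@nSteps < 0L) msg <- c(msg, "nSteps must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of a replicated in-silico assay
#'
#' @slot config the \linkS4class{ExperimentConfig} that produced it.
#' @slot metricName the recorded metric ("border_length_norm" for boundary,
#'   "segregation_index" for segregation assays).
#' @slot replicates one list per replicate with elements \code{seed},
#'   \code{timecourse} (data.frame: step, time_min, value), \code{finalState}
#'   (a \linkS4class{SimState}), \code{eventCounts} and, for segregation
#'   assays, \code{clusterReport}.
#' @slot aggregate data.frame with mean and standard error of the metric
#'   time course across replicates.
#' @export
setClass("ExperimentResult", representation(
  config = "ExperimentConfig", metricName = "character",
  replicates = "list", aggregate = "data.frame"))

# ---- show methods ---------------------------------------------------------

setMethod("show", "SimState", function(object) {
  n <- nrow(object@nodesX)
  cat("SimState:", n, "cells in a", object@arenaDiameter, "um arena\n")
  if (n > 0) {
    tab <- table(object@popNames[object@population])
    cat("  populations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  links:", sum(!is.na(object@linkCell)) / 2L,
        " step:", object@stepCount,
        " time:", format(object@stepCount * object@stepSec / 60, digits = 4), "min\n")
  }
})

setMethod("show", "Preset", function(object) {
  cat("Preset:", object@name, "\n")
  im <- object@interaction
  cat("  populations:", paste(im@popNames, collapse = " / "), "\n")
  cat("  contact duration (min), rows = focal:\n")
  print(im@durationMin)
  cat("  p(repulsion):\n")
  print(im@pRepulsion)
  cat("  directed:", paste(im@directed, collapse = " "), "\n")
  if (length(object@notes)) cat("  notes:\n", paste("   -", object@notes, collapse = "\n"), "\n")
})

setMethod("show", "ExperimentResult", function(object) {
  cat("ExperimentResult:", object@config@preset, "/", object@config@assay, "\n")
  cat("  replicates:", length(object@replicates),
      " metric:", object@metricName, "\n")
  fin <- vapply(object@replicates, function(r) utils::tail(r$timecourse$value, 1), 0)
  cat("  final", object@metricName, ": median",
      format(stats::median(fin), digits = 4), "\n")
})

# ---- simple accessors -----------------------------------------------------

#' Number of cells in a simulation state
#' @param x a \linkS4class{SimState}
#' @return integer
#' @export
nCells <- function(x) nrow(x@nodesX)

#' Population label of every cell
#' @param x a \linkS4class{SimState}
#' @return character vector of labels
#' @export
populations <- function(x) x@popNames[x@population]

#' Cell centroids
#' @param x a \linkS4class{SimState}
#' @return data.frame with cell_id, population, x, y (um)
#' @export
centroids <- function(x) {
  data.frame(cell_id = x@cellId, population = populations(x),
             x = rowMeans(x@nodesX), y = rowMeans(x@nodesY))
}

#' Current adhesion links
#' @param x a \linkS4class{SimState}
#' @return data.frame with one row per link: cell_a, node_a, cell_b, node_b
#'   (cells are row indices, nodes are ring indices 0-7)
#' @export
adhesionLinks <- function(x) {
  idx <- which(!is.na(x@linkCell), arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(cell_a = integer(), node_a = integer(),
                      cell_b = integer(), node_b = integer()))
  df <- data.frame(cell_a = idx[, 1], node_a = idx[, 2] - 1L,
                   cell_b = x@linkCell[idx], node_b = x@linkNode[idx])
  df[df$cell_a < df$cell_b, , drop = FALSE]
}

#' Simulated time in minutes
#' @param x a \linkS4class{SimState}
#' @return numeric scalar
#' @export
simTimeMin <- function(x) x@stepCount * x@stepSec / 60
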