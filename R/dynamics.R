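# One stochastic update step: link formation/breaking, repulsion, spontaneous
# direction changes, leader-driven migration, cohesive pulling.

# internal: assemble the C++ parameter list for a preset applied to a state.
# The interaction matrices are reordered to the state's population order and
# the per-minute break hazards are symmetrized over the two endpoints of a
# link (a link is one shared object; its hazard is the mean of the two
# focal-cell hazards).  Breaking is evaluated once per decision tick with
# p(break) = 1 - exp(-eta * tick), the per-minute probability scale on which
# the behaviour measurements are converted.
presetToCpp <- function(state, preset) {
  im <- preset@interaction
  mp <- preset@motility
  ord <- match(state@popNames, im@popNames)
  if (anyNA(ord))
    stop("unknown pair class: state populations (",
         paste(state@popNames, collapse = ", "),
         ") not covered by interaction matrix (",
         paste(im@popNames, collapse = ", "), ")")
  dur <- im@durationMin[ord, ord, drop = FALSE]
  eta <- 1 / dur
  etaSym <- (eta + t(eta)) / 2
  dtMin <- state@stepSec / 60
  dirm <- im@directed[ord, ord, drop = FALSE]
  storage.mode(dirm) <- "integer"
  list(arenaR = state@arenaDiameter / 2,
       radius = state@radius, idealBond = state@idealBond,
       contactDist = mp@contactDist, sep = mp@minSeparation,
       linkStretch = mp@linkStretch,
       stepDist = mp@speed * dtMin,
       pChangeDir = mp@pChangeDir,
       tickSteps = as.integer(round(mp@decisionTickMin * 60 / state@stepSec)),
       pullWeight = mp@pullWeight,
       refractSteps = as.integer(round(mp@refractoryMin * 60 / state@stepSec)),
       escapeSteps = matrix(as.integer(round(im@escapeMin[ord, ord] * 60 /
                                             state@stepSec)), 2, 2),
       maxSweeps = mp@maxSweeps,
       pTickBreak = 1 - exp(-etaSym * mp@decisionTickMin),
       pRepulsion = im@pRepulsion[ord, ord, drop = FALSE],
       directed = dirm)
}

eventTypeNames <- c("link_form", "link_break", "repulsion", "dir_change",
                    "link_release")

# internal: raw C++ event table -> user-facing log (1-based cells, 0-7 nodes)
decodeEvents <- function(ev, stepSec) {
  data.frame(step = ev$step, time_min = ev$step * stepSec / 60,
             event = eventTypeNames[ev$type + 1L],
             cell_a = ev$cell_a + 1L, node_a = ev$node_a,
             cell_b = ifelse(ev$cell_b < 0, NA_integer_, ev$cell_b + 1L),
             node_b = ifelse(ev$node_b < 0, NA_integer_, ev$node_b))
}

#' Run the simulation for a number of steps
#'
#' Each step applies, in order: adhesion-link formation between membrane
#' nodes of distinct cells within the contact distance; stochastic link
#' breaking at the pair-class hazard; repulsion (leader reassigned to the
#' node opposite a broken link with probability p(repulsion), or uniformly
#' at random in undirected "adhesion-only" mode); a spontaneous leader
#' change with probability \code{pChangeDir} once per decision tick;
#' displacement of every cell along its heading by speed x step duration;
#' cohesive pulling of cells linked to a repelled cell; and constraint
#' enforcement.
#'
#' @param state a \linkS4class{SimState}
#' @param preset a \linkS4class{Preset} (see \code{\link{buildPreset}})
#' @param nSteps number of steps.
#' @param recordEvery if > 0, record cell centroids every this many steps
#'   (plus the initial and final step).
#' @param recordEvents keep the full event log (link_form, link_break,
#'   repulsion, dir_change).
#' @return list with elements \code{state} (the advanced
#'   \linkS4class{SimState}), \code{snapshots} (data.frame step, cell, x,
#'   y), \code{events} (data.frame or NULL) and \code{counts} (named event
#'   totals).
#' @export
runSim <- function(state, preset, nSteps, recordEvery = 0L,
                   recordEvents = FALSE) {
  par <- presetToCpp(state, preset)
  out <- cpp_run_sim(stateToCpp(state), par, as.integer(nSteps),
                     as.integer(recordEvery), recordEvents)
  snaps <- out$snapshots
  if (nrow(snaps)) {
    snaps$time_min <- snaps$step * state@stepSec / 60
    snaps$population <- populations(state)[snaps$cell]
  }
  list(state = cppToState(state, out),
       snapshots = snaps,
       events = if (recordEvents) decodeEvents(out$events, state@stepSec) else NULL,
       counts = out$counts)
}

#' Advance the state by single steps
#' @inheritParams runSim
#' @return the advanced \linkS4class{SimState}
#' @export
simStep <- function(state, preset, nSteps = 1L) {
  runSim(state, preset, nSteps)$state
}

#' Form adhesion links between touching cells
#'
#' Every unlinked node pair from distinct, non-avoiding cells with
#' separation at most \code{contactDist} becomes linked; a node holds at
#' most one link, assigned greedily to the nearest eligible partner (ties:
#' lowest cell id, then lowest node index).
#'
#' @param state a \linkS4class{SimState}
#' @param contactDist link-formation distance (um)
#' @return list(state, events)
#' @export
formLinks <- function(state, contactDist = 2) {
  s <- stateToCpp(state)
  out <- cpp_form_links(s$nx, s$ny, s$linkC, s$linkN, s$avoidC,
                        contactDist, state@arenaDiameter / 2, s$stepCount)
  st <- state
  lc <- out$linkC; ln <- out$linkN
  lc[lc < 0L] <- NA_integer_; ln[ln < 0L] <- NA_integer_
  st@linkCell <- lc + 1L; st@linkNode <- ln
  list(state = st, events = decodeEvents(out$events, state@stepSec))
}

#' Break adhesion links stochastically and trigger repulsion
#'
#' Each link breaks independently with the per-step hazard of its pair
#' class; each endpoint cell of a broken link then evaluates repulsion with
#' its own p(repulsion) (or re-chooses its leader at random if the pair is
#' undirected).  The two cells avoid re-linking to each other for the
#' refractory period.
#'
#' @param state a \linkS4class{SimState}
#' @param preset a \linkS4class{Preset} supplying the interaction matrix
#' @return list(state, events, repelled) where \code{repelled} is a logical
#'   vector marking cells whose leader was reassigned by repulsion
#' @export
breakLinks <- function(state, preset) {
  s <- stateToCpp(state)
  par <- presetToCpp(state, preset)
  out <- cpp_break_links(s$nx, s$ny, s$heading, s$leader, s$pop,
                         s$linkC, s$linkN, s$avoidC, s$avoidS,
                         par$refractSteps, par$escapeSteps,
                         par$pTickBreak, par$pRepulsion, par$directed,
                         s$stepCount)
  list(state = cppToState(state, out),
       events = decodeEvents(out$events, state@stepSec),
       repelled = out$repelled == 1L)
}

#' Repulsion response of one cell to a broken contact
#'
#' Implements the directed-repulsion rule for a single cell: if
#' \code{directed} and a Bernoulli(\code{pRepulsion}) draw succeeds, the
#' leader becomes the node four ring positions from the broken node (the
#' opposite point of the membrane) and the cell counts as repelled;
#' if not \code{directed}, the leader is re-chosen uniformly at random.
#'
#' @param state a \linkS4class{SimState}
#' @param cell cell row index
#' @param brokenNode ring index 0-7 of the node whose link broke
#' @param pRepulsion repulsion probability
#' @param directed directed repulsion (TRUE) or adhesion-only mode (FALSE)
#' @return list(state, repelled)
#' @export
triggerRepulsion <- function(state, cell, brokenNode, pRepulsion,
                             directed = TRUE) {
  stopifnot(brokenNode %in% 0:7)
  repelled <- FALSE
  newLeader <- NA_integer_
  if (directed) {
    if (runif(1) < pRepulsion) {
      newLeader <- as.integer((brokenNode + 4) %% 8)
      repelled <- TRUE
    }
  } else {
    newLeader <- sample.int(8L, 1L) - 1L
  }
  if (!is.na(newLeader)) {
    cx <- mean(state@nodesX[cell, ]); cy <- mean(state@nodesY[cell, ])
    state@leader[cell] <- newLeader
    state@heading[cell] <- atan2(state@nodesY[cell, newLeader + 1L] - cy,
                                 state@nodesX[cell, newLeader + 1L] - cx)
  }
  list(state = state, repelled = repelled)
}

#' Cohesive pulling of the neighbours of repelled cells
#'
#' Every cell holding an adhesion link to a repelled cell rotates its
#' heading toward the repelled cell's new direction by the fraction
#' \code{pullWeight} (along the shorter arc); its leader becomes the node
#' closest to the new heading.  Only direct link neighbours are affected in
#' a single call; influence propagates further only over subsequent steps.
#'
#' @param state a \linkS4class{SimState}
#' @param repelledCells indices of cells repelled this step
#' @param pullWeight pull strength in [0, 1]
#' @return the updated \linkS4class{SimState}
#' @export
cohesionPull <- function(state, repelledCells, pullWeight) {
  stopifnot(pullWeight >= 0, pullWeight <= 1)
  if (pullWeight == 0 || length(repelledCells) == 0) return(state)
  for (r in repelledCells) {
    targ <- state@heading[r]
    nbrs <- unique(state@linkCell[r, ])
    nbrs <- nbrs[!is.na(nbrs) & !(nbrs %in% repelledCells)]
    for (c2 in nbrs) {
      d <- atan2(sin(targ - state@heading[c2]), cos(targ - state@heading[c2]))
      h <- state@heading[c2] + pullWeight * d
      state@heading[c2] <- atan2(sin(h), cos(h))
      cx <- mean(state@nodesX[c2, ]); cy <- mean(state@nodesY[c2, ])
      ang <- atan2(state@nodesY[c2, ] - cy, state@nodesX[c2, ] - cx)
      state@leader[c2] <- which.max(cos(ang - state@heading[c2])) - 1L
    }
  }
  state
}
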