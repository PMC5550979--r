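# Shared builders for small deterministic states and custom conditions.

# a state with cells at given centres and labels in a large arena
pointState <- function(centres, labels, arenaDiameter = 500,
                       popNames = c("A", "B")) {
  cells <- lapply(seq_len(nrow(centres)), function(i)
    makeCell(centres[i, ], labels[i], arenaDiameter = arenaDiameter))
  newSimState(cells, arenaDiameter = arenaDiameter, popNames = popNames)
}

# n isolated A-B cell pairs on a wide grid, nearest membranes `gap` um apart;
# used for link-lifetime Monte-Carlo at known hazards
pairGridState <- function(nPairs, gap = 2, arenaDiameter = NULL) {
  side <- ceiling(sqrt(nPairs))
  sp <- 40
  if (is.null(arenaDiameter)) arenaDiameter <- 2 * side * sp + 100
  centres <- list()
  labels <- character()
  k <- 0
  for (i in seq_len(side)) {
    for (j in seq_len(side)) {
      if (k >= nPairs) break
      k <- k + 1
      cx <- (i - (side + 1) / 2) * sp
      cy <- (j - (side + 1) / 2) * sp
      centres[[length(centres) + 1]] <- c(cx - (15 + gap) / 2, cy)
      centres[[length(centres) + 1]] <- c(cx + (15 + gap) / 2, cy)
      labels <- c(labels, "A", "B")
    }
  }
  pointState(do.call(rbind, centres), labels, arenaDiameter = arenaDiameter)
}

# a two-population condition with uniform behaviour values
abPreset <- function(duration = 24, pRepulsion = 0.84, directed = TRUE,
                     escape = 3, motility = defaultMotility()) {
  new("Preset", name = "ab_test",
      interaction = interactionParams(c("A", "B"), duration, pRepulsion,
                                      directed, escape),
      motility = motility, notes = "synthetic test condition")
}

# empirical link lifetimes (in break-evaluation intervals = minutes): links
# are first formed, then the breaking phase is applied repeatedly to a
# geometrically frozen state until all links have broken
linkLifetimes <- function(nPairs, duration, pRepulsion = 0, maxTicks = 5000) {
  st <- pairGridState(nPairs)
  pr <- abPreset(duration = duration, pRepulsion = pRepulsion)
  st <- formLinks(st, contactDist = pr@motility@contactDist)$state
  canonical <- function(s) {
    m <- !is.na(s@linkCell)
    m & !is.na(s@linkCell) & s@linkCell > row(s@linkCell)
  }
  alive <- canonical(st)
  lifetimes <- numeric(0)
  for (tick in seq_len(maxTicks)) {
    st <- breakLinks(st, pr)$state
    nowAlive <- canonical(st)
    nDied <- sum(alive & !nowAlive)
    # a break detected at the end of an evaluation interval occurred at an
    # unknown time inside it; the midpoint removes the half-interval bias
    if (nDied > 0) lifetimes <- c(lifetimes, rep(tick - 0.5, nDied))
    alive <- nowAlive
    if (!any(alive)) break
    # re-linking stays blocked: the pairwise avoidance entries are kept live
    st@avoidSteps[!is.na(st@avoidCell)] <- 10000L
  }
  lifetimes
}
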