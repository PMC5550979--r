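# Quantitation: border length from nearest heterotypic neighbours, cluster
# particle analysis, contact-event statistics, segregation index.

# internal: coerce the accepted point inputs to data.frame(x, y, population)
asLabelledPoints <- function(x) {
  if (is(x, "SimState")) {
    cc <- centroids(x)
    return(data.frame(x = cc$x, y = cc$y, population = cc$population))
  }
  df <- as.data.frame(x)
  nm <- names(df)
  xcol <- if ("x" %in% nm) "x" else if ("x_um" %in% nm) "x_um" else
    stop("points need an 'x' or 'x_um' column")
  ycol <- if ("y" %in% nm) "y" else if ("y_um" %in% nm) "y_um" else
    stop("points need a 'y' or 'y_um' column")
  if (!"population" %in% nm) stop("points need a 'population' column")
  data.frame(x = df[[xcol]], y = df[[ycol]], population = df$population)
}

#' Border length between two cell populations
#'
#' For every cell the nearest heterotypic neighbour is found; the short
#' segments between mutual nearest heterotypic neighbours (cells that are
#' each other's nearest opposite-type cell) trace the interface, while
#' one-sided pairs -- a cell deep inside its own territory whose nearest
#' heterotypic cell lies far away at the border -- do not represent it and
#' are dropped.  Duplicated unordered pairs are removed, the midpoint of
#' each segment is taken, the midpoints are chained greedily (starting from
#' the most peripheral one, each next point is the nearest unused one) and
#' the border length is the summed length of the resulting polyline.
#'
#' @param x a \linkS4class{SimState} or a data.frame with columns x/x_um,
#'   y/y_um and population.
#' @return list with \code{length} (um), \code{midpoints} (ordered matrix)
#'   and \code{n_segments}
#' @export
borderLength <- function(x) {
  pts <- asLabelledPoints(x)
  labs <- unique(pts$population)
  if (length(labs) != 2 || min(table(pts$population)) == 0)
    stop("border is undefined: both populations must be present")
  n <- nrow(pts)
  d <- as.matrix(dist(cbind(pts$x, pts$y)))
  het <- outer(pts$population, pts$population, "!=")
  d[!het] <- Inf
  nn <- max.col(-d, ties.method = "first")
  mutual <- nn[nn] == seq_len(n)
  pair <- cbind(pmin(seq_len(n), nn), pmax(seq_len(n), nn))[mutual, , drop = FALSE]
  pair <- pair[!duplicated(pair), , drop = FALSE]
  mid <- cbind((pts$x[pair[, 1]] + pts$x[pair[, 2]]) / 2,
               (pts$y[pair[, 1]] + pts$y[pair[, 2]]) / 2)
  m <- nrow(mid)
  if (m < 2)
    return(list(length = 0, midpoints = mid, n_segments = m))
  # chain from the most peripheral midpoint (farthest from their centroid)
  ctr <- colMeans(mid)
  cur <- which.max((mid[, 1] - ctr[1])^2 + (mid[, 2] - ctr[2])^2)
  used <- logical(m)
  ord <- integer(m)
  total <- 0
  for (k in seq_len(m)) {
    ord[k] <- cur
    used[cur] <- TRUE
    if (k == m) break
    dd <- (mid[, 1] - mid[cur, 1])^2 + (mid[, 2] - mid[cur, 2])^2
    dd[used] <- Inf
    nxt <- which.min(dd)
    total <- total + sqrt(dd[nxt])
    cur <- nxt
  }
  list(length = total, midpoints = mid[ord, , drop = FALSE], n_segments = m)
}

#' Border length normalised to the straight-interface width
#'
#' @param x as in \code{\link{borderLength}}.
#' @param interfaceWidth length (um) of a perfectly straight interface; for
#'   a \linkS4class{SimState} this defaults to the arena diameter.
#' @return dimensionless relative border length
#' @export
relativeBorderLength <- function(x, interfaceWidth = NULL) {
  if (is.null(interfaceWidth)) {
    if (!is(x, "SimState"))
      stop("interfaceWidth must be given for plain point sets")
    interfaceWidth <- x@arenaDiameter
  }
  borderLength(x)$length / interfaceWidth
}

#' Neighbourhood segregation index
#'
#' Mean over cells of the fraction of the k nearest neighbours sharing the
#' cell's population label; 0.5 is the expectation for a random 50:50
#' mixture, values near 1 indicate full segregation and values below 0.5
#' anti-correlated (checkerboard-like) arrangements.
#'
#' @param x a \linkS4class{SimState} or labelled point data.frame.
#' @param k number of nearest neighbours.
#' @return fraction in [0, 1]
#' @export
segregationIndex <- function(x, k = 6) {
  pts <- asLabelledPoints(x)
  n <- nrow(pts)
  if (n < k + 1) stop("need at least k + 1 cells")
  d <- as.matrix(dist(cbind(pts$x, pts$y)))
  diag(d) <- Inf
  same <- outer(pts$population, pts$population, "==")
  frac <- vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    mean(same[i, nb])
  }, 0)
  mean(frac)
}

# internal: rasterize one population of a state (filled node octagons) or of
# a point set (discs of the mean single-cell area) to a binary mask
rasterizeMask <- function(x, population, scale = 1, cellArea = 200) {
  if (is(x, "SimState")) {
    keep <- which(populations(x) == population)
    if (!length(keep)) stop("no cells of population '", population, "'")
    R <- x@arenaDiameter / 2
    npix <- ceiling(2 * R / scale)
    ax <- -R + (seq_len(npix) - 0.5) * scale
    mask <- matrix(0L, npix, npix)
    for (c in keep) {
      px <- x@nodesX[c, ]; py <- x@nodesY[c, ]
      i1 <- max(1, floor((min(px) + R) / scale)); i2 <- min(npix, ceiling((max(px) + R) / scale))
      j1 <- max(1, floor((min(py) + R) / scale)); j2 <- min(npix, ceiling((max(py) + R) / scale))
      if (i1 > i2 || j1 > j2) next
      gx <- ax[i1:i2]; gy <- ax[j1:j2]
      gg <- expand.grid(x = gx, y = gy)
      inside <- pointInPolygon(gg$x, gg$y, px, py)
      if (any(inside)) {
        ii <- cbind(rep(i1:i2, times = length(gy)),
                    rep(j1:j2, each = length(gx)))[inside, , drop = FALSE]
        mask[ii] <- 1L
      }
    }
    return(list(mask = mask, scale = scale))
  }
  pts <- asLabelledPoints(x)
  pts <- pts[pts$population == population, , drop = FALSE]
  if (!nrow(pts)) stop("no cells of population '", population, "'")
  r <- sqrt(cellArea / pi)
  pad <- r + 2 * scale
  x0 <- min(pts$x) - pad; x1 <- max(pts$x) + pad
  y0 <- min(pts$y) - pad; y1 <- max(pts$y) + pad
  nx <- ceiling((x1 - x0) / scale); ny <- ceiling((y1 - y0) / scale)
  ax <- x0 + (seq_len(nx) - 0.5) * scale
  ay <- y0 + (seq_len(ny) - 0.5) * scale
  mask <- matrix(0L, nx, ny)
  for (p in seq_len(nrow(pts))) {
    ii <- which(abs(ax - pts$x[p]) <= r)
    jj <- which(abs(ay - pts$y[p]) <= r)
    if (!length(ii) || !length(jj)) next
    sub <- outer((ax[ii] - pts$x[p])^2, (ay[jj] - pts$y[p])^2, "+") <= r^2
    mask[ii, jj] <- pmax(mask[ii, jj], as.integer(sub))
  }
  list(mask = mask, scale = scale)
}

# even-odd ray-crossing point-in-polygon test (closed 8-gon)
pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Particle analysis of cell clusters
#'
#' Mirrors threshold-and-count particle analysis of a binary image: the
#' input is rasterized to a binary mask of one population (1 um/pixel by
#' default), connected components are labelled with 8-connectivity, blobs
#' below the minimum cluster size are discarded, and each remaining cluster
#' area is converted to a cell count using the mean single-cell area.
#'
#' @param x a binary matrix (already a mask), a \linkS4class{SimState}
#'   (cells drawn as their filled node octagons) or a labelled point
#'   data.frame (cells drawn as discs of area \code{cellArea}).
#' @param minArea minimum cluster size (um^2); default 500.
#' @param cellArea mean area of one cell (um^2); default 200.
#' @param scale rasterization scale (um/pixel); default 1.
#' @param population which population to analyse (ignored for masks);
#'   defaults to the first.
#' @return data.frame with one row per cluster (cluster, area_um2, n_cells)
#'   and attributes \code{total_cells} and \code{n_clusters}
#' @export
clusterParticleAnalysis <- function(x, minArea = 500, cellArea = 200,
                                    scale = 1, population = NULL) {
  if (is.matrix(x) && !is.data.frame(x)) {
    mask <- x
    storage.mode(mask) <- "integer"
  } else {
    if (is.null(population)) {
      population <- if (is(x, "SimState")) x@popNames[1] else
        asLabelledPoints(x)$population[1]
    }
    mask <- rasterizeMask(x, population, scale = scale, cellArea = cellArea)$mask
  }
  empty <- data.frame(cluster = integer(), area_um2 = numeric(),
                      n_cells = integer())
  if (!any(mask != 0)) {
    attr(empty, "total_cells") <- 0L
    attr(empty, "n_clusters") <- 0L
    return(empty)
  }
  lab <- cpp_label8(mask)
  areas <- tabulate(lab[lab > 0]) * scale^2
  keep <- which(areas >= minArea)
  rep <- data.frame(cluster = seq_along(keep), area_um2 = areas[keep],
                    n_cells = as.integer(round(areas[keep] / cellArea)))
  rep <- rep[order(-rep$area_um2), , drop = FALSE]
  rep$cluster <- seq_len(nrow(rep))
  rownames(rep) <- NULL
  attr(rep, "total_cells") <- sum(rep$n_cells)
  attr(rep, "n_clusters") <- nrow(rep)
  rep
}

# ---- contact events -------------------------------------------------------

#' Extract cell-cell contact events from a track table
#'
#' A contact is a maximal run of consecutive frames during which the
#' centroid distance of a cell pair stays at or below the contact radius.
#' Every contact yields two cell-centric events (one per focal cell) with
#' the contact duration, the pair axis at the start of contact (unit vector
#' focal -> partner), the focal cell's direction after contact computed
#' over \code{dirFrames} frames from the end of contact, the angle theta
#' between the two, a collapse flag, and a censoring flag set when the
#' focal cell has a further collision within \code{censorMin} minutes of
#' the contact end.
#'
#' @param tracks data.frame with columns frame, time_min, cell_id,
#'   population, x_um, y_um, regularly sampled; an optional logical
#'   \code{collapse} column marks frames at which a cell shows a collapse
#'   response.
#' @param contactRadius centroid distance (um) defining contact; the
#'   default 17 is the cell diameter plus the link-formation distance.
#' @param collapseEvents alternative to the \code{collapse} column: a
#'   data.frame with time_min and cell_id of collapse (repulsion)
#'   responses, e.g. the repulsion rows of a simulation event log.
#' @param dirFrames frames over which the post-contact direction is taken.
#' @param censorMin censoring window (min) after the end of contact.
#' @return data.frame of events: cell_id, partner_id, pair_class, t_start,
#'   t_end, duration, axis_x, axis_y, post_x, post_y, theta, theta_defined,
#'   collapse, censored
#' @export
extractContactEvents <- function(tracks, contactRadius = 17,
                                 collapseEvents = NULL, dirFrames = 3L,
                                 censorMin = 20) {
  tr <- as.data.frame(tracks)
  need <- c("frame", "time_min", "cell_id", "population", "x_um", "y_um")
  if (!all(need %in% names(tr)))
    stop("tracks need columns: ", paste(need, collapse = ", "))
  times <- sort(unique(tr$time_min))
  if (length(times) < 2) stop("need at least two frames")
  dts <- diff(times)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-6 * max(dt, 1)))
    stop("irregular frame spacing: tracks must be regularly sampled")
  ids <- sort(unique(tr$cell_id))
  nt <- length(times); nid <- length(ids)
  X <- matrix(NA_real_, nt, nid); Y <- matrix(NA_real_, nt, nid)
  ti <- match(tr$time_min, times); ci <- match(tr$cell_id, ids)
  X[cbind(ti, ci)] <- tr$x_um
  Y[cbind(ti, ci)] <- tr$y_um
  popOf <- tr$population[match(ids, tr$cell_id)]

  collapseAt <- NULL  # data.frame(time_min, cell_id)
  if (!is.null(collapseEvents)) {
    collapseAt <- data.frame(time_min = collapseEvents$time_min,
                             cell_id = collapseEvents$cell_id)
  } else if ("collapse" %in% names(tr)) {
    hit <- tr[which(as.logical(tr$collapse)), c("time_min", "cell_id")]
    collapseAt <- hit
  }

  # contact frame masks for all pairs
  inContact <- array(FALSE, c(nt, nid, nid))
  for (a in seq_len(nid - 1)) {
    for (b in (a + 1):nid) {
      d <- sqrt((X[, a] - X[, b])^2 + (Y[, a] - Y[, b])^2)
      cc <- !is.na(d) & d <= contactRadius
      inContact[, a, b] <- cc
      inContact[, b, a] <- cc
    }
  }
  anyContact <- apply(inContact, c(1, 2), any)

  rows <- list()
  for (a in seq_len(nid - 1)) {
    for (b in (a + 1):nid) {
      cc <- inContact[, a, b]
      if (!any(cc)) next
      r <- rle(cc)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (e in which(r$values)) {
        f0 <- starts[e]; f1 <- ends[e]
        dur <- r$lengths[e] * dt
        for (foc in c(a, b)) {
          par <- if (foc == a) b else a
          ax <- c(X[f0, par] - X[f0, foc], Y[f0, par] - Y[f0, foc])
          axn <- sqrt(sum(ax^2))
          ax <- if (axn > 0) ax / axn else c(NA_real_, NA_real_)
          fpost <- f1 + dirFrames
          post <- if (fpost <= nt && !is.na(X[fpost, foc]) && !is.na(X[f1, foc]))
            c(X[fpost, foc] - X[f1, foc], Y[fpost, foc] - Y[f1, foc])
          else c(NA_real_, NA_real_)
          pn <- sqrt(sum(post^2))
          thetaDef <- !anyNA(c(ax, post)) && pn > 1e-9
          theta <- if (thetaDef) {
            acos(pmin(1, pmax(-1, sum(ax * post) / pn)))
          } else NA_real_
          # censored: any further collision of the focal cell within censorMin
          win <- which(times > times[f1] & times <= times[f1] + censorMin)
          censored <- length(win) > 0 && any(anyContact[win, foc])
          collapse <- FALSE
          if (!is.null(collapseAt)) {
            hit <- collapseAt$cell_id == ids[foc] &
              collapseAt$time_min > times[f1] - dt - 1e-9 &
              collapseAt$time_min <= times[f1] + dt + 1e-9
            collapse <- any(hit)
          }
          rows[[length(rows) + 1]] <- data.frame(
            cell_id = ids[foc], partner_id = ids[par],
            pair_class = if (popOf[foc] == popOf[par]) "homotypic" else "heterotypic",
            t_start = times[f0], t_end = times[f1], duration = dur,
            axis_x = ax[1], axis_y = ax[2],
            post_x = if (thetaDef) post[1] / pn else NA_real_,
            post_y = if (thetaDef) post[2] / pn else NA_real_,
            theta = theta, theta_defined = thetaDef,
            collapse = collapse, censored = censored,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(cell_id = numeric(), partner_id = numeric(),
                      pair_class = character(), t_start = numeric(),
                      t_end = numeric(), duration = numeric(),
                      axis_x = numeric(), axis_y = numeric(),
                      post_x = numeric(), post_y = numeric(),
                      theta = numeric(), theta_defined = logical(),
                      collapse = logical(), censored = logical()))
  do.call(rbind, rows)
}

#' Does a cell migrate away from its contact partner?
#'
#' The literal classification rule: a cell migrates away when theta, the
#' angle between the pair axis at the start of contact and the cell's
#' post-contact direction, lies within pi/2 to 3*pi/4.  The bounds are
#' configurable (set \code{upper = pi} for the inclusive variant that also
#' counts straight-back movement).
#'
#' @param event a single event row from \code{\link{extractContactEvents}},
#'   or a numeric theta.
#' @param lower,upper inclusive bounds on theta (radians).
#' @return logical
#' @export
migratesAway <- function(event, lower = pi / 2, upper = 3 * pi / 4) {
  theta <- if (is.numeric(event)) event else event$theta
  !is.na(theta) & theta >= lower & theta <= upper
}

#' Mean displacement profile after repulsion
#'
#' For uncensored collapse events, the focal cell's displacement is
#' averaged in consecutive time bins after the end of contact, out to a
#' fixed window.  Censored events (a further collision inside the window)
#' are excluded, matching how post-repulsion migration bursts are
#' quantified from tracked cells.
#'
#' @param events data.frame from \code{\link{extractContactEvents}}.
#' @param tracks the track table the events came from.
#' @param binMin bin width (min); default one 3-min frame.
#' @param windowMin window length (min); default 20.
#' @return data.frame with bin_start_min, bin_end_min, mean_disp_um, n;
#'   empty (with a warning) when no uncensored collapse events exist
#' @export
displacementAfterRepulsion <- function(events, tracks, binMin = 3,
                                       windowMin = 20) {
  ev <- events[events$collapse & !events$censored, , drop = FALSE]
  empty <- data.frame(bin_start_min = numeric(), bin_end_min = numeric(),
                      mean_disp_um = numeric(), n = integer())
  if (!nrow(ev)) {
    warning("no uncensored collapse events")
    return(empty)
  }
  tr <- as.data.frame(tracks)
  nb <- floor(windowMin / binMin)
  acc <- matrix(NA_real_, nrow(ev), nb)
  for (i in seq_len(nrow(ev))) {
    sub <- tr[tr$cell_id == ev$cell_id[i], , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    for (b in seq_len(nb)) {
      t0 <- ev$t_end[i] + (b - 1) * binMin
      t1 <- ev$t_end[i] + b * binMin
      p0 <- sub[abs(sub$time_min - t0) < 1e-9, ]
      p1 <- sub[abs(sub$time_min - t1) < 1e-9, ]
      if (nrow(p0) == 1 && nrow(p1) == 1)
        acc[i, b] <- sqrt((p1$x_um - p0$x_um)^2 + (p1$y_um - p0$y_um)^2)
    }
  }
  data.frame(bin_start_min = (seq_len(nb) - 1) * binMin,
             bin_end_min = seq_len(nb) * binMin,
             mean_disp_um = colMeans(acc, na.rm = TRUE),
             n = colSums(!is.na(acc)))
}
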