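# Synthetic 102-chipset sensor layout (one magnetometer + two orthogonal
# planar gradiometers per chipset) and its Delaunay neighbour graph.

#' Construct the synthetic sensor array
#'
#' 102 chipset positions on a helmet-like 2D disc layout (sunflower
#' spiral, slightly jittered to avoid degenerate cocircular quadruples),
#' each carrying one magnetometer and two orthogonal planar gradiometers:
#' 306 channels in total. Chipset neighbours are defined by Delaunay
#' triangulation of the layout, the standard construction for
#' sensor-adjacency templates in cluster-based statistics. The layout is
#' synthetic: it stands in for a whole-head MEG helmet and is not a copy
#' of any vendor geometry. Left/right are identified by the sign of `x`.
#'
#' @param seed Seed for the (tiny) jitter; the default yields one fixed,
#'   documented layout.
#' @param n_chipsets Number of chipsets (default 102).
#' @param jitter Standard deviation of the positional jitter.
#' @return A `sensor_array`: list with `pos` (n x 2 matrix of chipset
#'   coordinates), `neighbours` (n x n logical adjacency matrix),
#'   `channels` (306-row data frame: `channel`, `chipset`, `type`),
#'   `grad_angle` (orientation of the gradiometer pair per chipset).
#' @export
make_sensor_array <- function(seed = 1, n_chipsets = 102, jitter = 0.004) {
  k <- seq_len(n_chipsets)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((k - 0.5) / n_chipsets)
  th <- k * golden
  pos <- cbind(x = r * cos(th), y = r * sin(th))
  if (jitter > 0)
    pos <- pos + with_seed(seed, matrix(stats::rnorm(2 * n_chipsets, 0, jitter),
                                        n_chipsets, 2))
  colnames(pos) <- c("x", "y")
  rownames(pos) <- sprintf("CH%03d", k)
  edges <- delaunay_edges(pos[, 1], pos[, 2])
  adj <- matrix(FALSE, n_chipsets, n_chipsets,
                dimnames = list(rownames(pos), rownames(pos)))
  adj[edges] <- TRUE
  adj[edges[, 2:1, drop = FALSE]] <- TRUE
  channels <- data.frame(
    channel = sprintf("CH%03d%s", rep(k, each = 3), c("1", "2", "3")),
    chipset = rep(k, each = 3),
    type = rep(c("mag", "grad1", "grad2"), n_chipsets),
    stringsAsFactors = FALSE
  )
  structure(list(
    pos = pos,
    neighbours = adj,
    channels = channels,
    grad_angle = (k * golden) %% (2 * pi)
  ), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d chipsets / %d channels, %d neighbour edges\n",
              nrow(x$pos), nrow(x$channels), sum(x$neighbours) / 2))
  invisible(x)
}

#' Delaunay triangulation edges (Bowyer-Watson)
#'
#' Incremental Bowyer-Watson triangulation in 2D. Adequate for the
#' package's layouts (a few hundred points); positions are assumed to be
#' in general position (the array constructor jitters them).
#'
#' @param x,y Point coordinates.
#' @return Two-column integer matrix of unique edges (i < j).
#' @keywords internal
delaunay_edges <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  # super-triangle enclosing all points
  cx <- mean(range(x)); cy <- mean(range(y))
  d <- 3 * max(diff(range(x)), diff(range(y)), 1e-6)
  px <- c(x, cx - 20 * d, cx + 20 * d, cx)
  py <- c(y, cy - 20 * d, cy - 20 * d, cy + 20 * d)
  sup <- n + 1:3
  tris <- matrix(sup, 1, 3)
  cc <- matrix(circumcircle(px[sup], py[sup]), 1, 3)
  for (p in seq_len(n)) {
    bad <- which((px[p] - cc[, 1])^2 + (py[p] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12))
    # boundary of the cavity: edges of bad triangles that are not shared
    ed <- rbind(tris[bad, c(1, 2), drop = FALSE],
                tris[bad, c(2, 3), drop = FALSE],
                tris[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    keep <- !(key %in% key[duplicated(key)])
    ed <- ed[keep, , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(ed, p)
    newc <- t(apply(newt, 1, function(t3) circumcircle(px[t3], py[t3])))
    tris <- rbind(tris, newt)
    cc <- rbind(cc, newc)
  }
  tris <- tris[rowSums(matrix(tris %in% sup, nrow(tris))) == 0, , drop = FALSE]
  ed <- rbind(tris[, c(1, 2), drop = FALSE],
              tris[, c(2, 3), drop = FALSE],
              tris[, c(3, 1), drop = FALSE])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  unique(ed)
}

# circumcenter (cx, cy) and squared radius of a triangle
circumcircle <- function(tx, ty) {
  ax <- tx[1]; ay <- ty[1]; bx <- tx[2]; by <- ty[2]; cx <- tx[3]; cy <- ty[3]
  dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(dd) < 1e-14) return(c(Inf, Inf, Inf))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / dd
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / dd
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

#' Neighbour graph of a sensor array as an igraph object
#'
#' @param array A `sensor_array`.
#' @return An undirected `igraph` graph over the chipsets.
#' @export
sensor_graph <- function(array) {
  igraph::graph_from_adjacency_matrix(array$neighbours, mode = "undirected")
}

#' Indices of temporal-region chipsets
#'
#' Lateral chipsets (|x| above `x_min`, |y| below `y_max`) standing in
#' for the left and right temporal sensor groups where auditory responses
#' concentrate.
#'
#' @param array A `sensor_array`.
#' @param x_min,y_max Region bounds on the unit-disc layout.
#' @return List with integer vectors `left`, `right` and their union `all`.
#' @export
temporal_chipsets <- function(array, x_min = 0.5, y_max = 0.45) {
  x <- array$pos[, 1]; y <- array$pos[, 2]
  left <- which(x <= -x_min & abs(y) <= y_max)
  right <- which(x >= x_min & abs(y) <= y_max)
  list(left = left, right = right, all = sort(c(left, right)))
}

#' Bilateral temporal gain map
#'
#' Gaussian patches centred on the left and right temporal regions,
#' optionally left-dominant (as tritone responses were in the study this
#' simulator emulates).
#'
#' @param array A `sensor_array`.
#' @param centre Absolute x of the patch centres.
#' @param sigma Patch width.
#' @param left_gain,right_gain Peak gains of the two patches.
#' @return Numeric vector of per-chipset gains in [0, max gain].
#' @export
bilateral_topography <- function(array, centre = 0.65, sigma = 0.25,
                                 left_gain = 1, right_gain = 1) {
  x <- array$pos[, 1]; y <- array$pos[, 2]
  dl <- (x + centre)^2 + y^2
  dr <- (x - centre)^2 + y^2
  left_gain * exp(-dl / (2 * sigma^2)) + right_gain * exp(-dr / (2 * sigma^2))
}

#' Plot a chipset topography on the layout
#'
#' Simple 2D layout heatmap: chipsets as filled circles coloured by value,
#' with optional marker rings for selected chipsets (for example sensors
#' in significant clusters).
#'
#' @param array A `sensor_array`.
#' @param values Numeric vector, one value per chipset.
#' @param mark Optional integer indices of chipsets to ring.
#' @param mark2 Optional second marker set (drawn unfilled).
#' @param main Title.
#' @param zlim Colour range (defaults to the data range).
#' @return Invisibly, the colour assignment.
#' @export
plot_topography <- function(array, values, mark = NULL, mark2 = NULL,
                            main = "", zlim = range(values)) {
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  z <- pmin(pmax(values, zlim[1]), zlim[2])
  ci <- 1 + round(63 * (z - zlim[1]) / max(zlim[2] - zlim[1], 1e-12))
  graphics::plot(array$pos, pch = 21, bg = pal[ci], cex = 2.2,
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  if (length(mark))
    graphics::points(array$pos[mark, , drop = FALSE], pch = 21, cex = 2.8,
                     lwd = 2, col = "black", bg = NA)
  if (length(mark2))
    graphics::points(array$pos[mark2, , drop = FALSE], pch = 1, cex = 2.8,
                     lwd = 1, col = "grey30")
  invisible(pal[ci])
}
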