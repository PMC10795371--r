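# Small shared helpers: angle arithmetic, polygon geometry, grid labelling.

#' Wrap an angle into (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @keywords internal
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # %% maps exact pi to -pi; the convention here is (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' Polygon area by the shoelace formula
#'
#' @param xy two-column matrix of vertices (open ring; first vertex not repeated).
#' @return unsigned area in squared input units.
#' @keywords internal
polygon_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

polygon_perimeter <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 2) return(0)
  i2 <- c(2:n, 1)
  sum(sqrt((xy[i2, 1] - xy[, 1])^2 + (xy[i2, 2] - xy[, 2])^2))
}

#' Point-in-convex-polygon test and distance to polygon
#'
#' Distance is 0 for interior points; otherwise the minimum distance to the
#' boundary segments. Works for any simple polygon (ray casting).
#' @keywords internal
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' @keywords internal
dist_to_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- xy[j, 1]; ay <- xy[j, 2]
    bx <- xy[i, 1]; by <- xy[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  d <- sqrt(d2)
  d[point_in_polygon(px, py, xy)] <- 0
  d
}

#' Rook-connected component labelling of a logical matrix
#'
#' Two-pass run-length labelling with union-find; rook (4-neighbour)
#' connectivity. Returns an integer matrix of labels (0 = background).
#' @keywords internal
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  next_label <- 0L
  prev_runs <- NULL # matrix: from, to, label (runs of previous row)
  for (r in seq_len(nr)) {
    row <- mask[r, ]
    if (!any(row)) { prev_runs <- NULL; next }
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    runs <- cbind(from = starts[keep], to = ends[keep], label = 0L)
    for (k in seq_len(nrow(runs))) {
      lab <- 0L
      if (!is.null(prev_runs)) {
        for (m in seq_len(nrow(prev_runs))) {
          if (prev_runs[m, 1] <= runs[k, 2] && prev_runs[m, 2] >= runs[k, 1]) {
            rt <- find_root(prev_runs[m, 3])
            if (lab == 0L) {
              lab <- rt
            } else if (rt != lab) {
              lo <- min(rt, lab)
              parent[rt] <- lo; parent[lab] <- lo
              lab <- lo
            }
          }
        }
      }
      if (lab == 0L) {
        next_label <- next_label + 1L
        parent[next_label] <- next_label
        lab <- next_label
      }
      runs[k, 3] <- lab
      labels[r, runs[k, 1]:runs[k, 2]] <- lab
    }
    prev_runs <- runs
  }
  if (next_label == 0L) return(labels)
  roots <- vapply(seq_len(next_label), find_root, integer(1))
  remap <- match(roots, unique(roots))
  nz <- labels != 0L
  labels[nz] <- remap[labels[nz]]
  labels
}

#' Number of rook-connected foreground components
#' @keywords internal
n_components <- function(mask) {
  lab <- label_components(mask)
  length(unique(lab[lab != 0L]))
}

#' Does a foreground region have interior holes?
#'
#' A hole is a background component that does not touch the matrix border.
#' @keywords internal
has_holes <- function(mask) {
  lab <- label_components(!mask)
  if (all(lab == 0L)) return(FALSE)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  any(!unique(lab[lab != 0L]) %in% border)
}

#' Standard error of the mean (NA-dropped)
#' @keywords internal
se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Format a POSIXct as ISO-8601 UTC
#' @keywords internal
iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Parse ISO-8601 UTC timestamps
#' @keywords internal
parse_iso8601 <- function(s) {
  as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}
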