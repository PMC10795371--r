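# Broad-scale space use: kernel utilisation distributions, 95%-isopleth
# movement ranges, MCPs, buffered availability regions, random circular
# available ranges, zonal raster summaries and the asymptote check.

as_points <- function(points) {
  if (is.data.frame(points)) cbind(points$x, points$y) else as.matrix(points)
}

#' Fixed-kernel utilisation distribution
#'
#' Bivariate Gaussian kernel density with equal bandwidth on both axes,
#' evaluated by fast binned KDE (KernSmooth) on a grid padded at least 3h
#' beyond the point bounding box; cell masses are normalised to sum to 1.
#'
#' @param points two-column matrix or data frame with `x`, `y` (metres).
#' @param h kernel bandwidth (SD of the Gaussian kernel, metres, > 0).
#' @param grid_resolution cell size in metres; default h/4, coarsened so the
#'   grid never exceeds `max_cells` per side.
#' @param max_cells per-side grid cap (default 512).
#' @return object of class `quoll_ud`: `grid` (a [raster_grid()] of
#'   probability mass per cell), `h`, `n_points`, `cell_size`.
#' @export
fit_kde <- function(points, h, grid_resolution = NULL, max_cells = 512) {
  pts <- as_points(points)
  if (nrow(pts) < 5) stop("fit_kde needs at least 5 points")
  if (!is.numeric(h) || h <= 0) stop("bandwidth h must be > 0")
  cell <- if (is.null(grid_resolution)) h / 4 else grid_resolution
  rx <- range(pts[, 1]) + c(-3, 3) * h
  ry <- range(pts[, 2]) + c(-3, 3) * h
  cell <- max(cell, diff(rx) / max_cells, diff(ry) / max_cells)
  nx <- max(8L, ceiling(diff(rx) / cell))
  ny <- max(8L, ceiling(diff(ry) / cell))
  est <- KernSmooth::bkde2D(pts, bandwidth = c(h, h), gridsize = c(nx, ny),
                            range.x = list(rx, ry))
  dx <- est$x1[2] - est$x1[1]; dy <- est$x2[2] - est$x2[1]
  mass <- est$fhat * dx * dy
  mass <- pmax(mass, 0) / sum(pmax(mass, 0))
  # fhat[i, j] is at (x1[i], x2[j]); raster rows run top (max y) down
  vals <- t(mass)[rev(seq_len(ny)), , drop = FALSE]
  grid <- raster_grid(vals, origin_x = est$x1[1] - dx / 2,
                      origin_y = est$x2[ny] + dy / 2,
                      cell_size = dx, name = "ud")
  grid$cell_size_y <- dy
  structure(list(grid = grid, h = h, n_points = nrow(pts),
                 cell_area = dx * dy),
            class = "quoll_ud")
}

#' @export
print.quoll_ud <- function(x, ...) {
  cat(sprintf("<quoll_ud> h = %.1f m, %d points, %d x %d grid (cell %.1f m), total mass %.6f\n",
              x$h, x$n_points, x$grid$n_rows, x$grid$n_cols,
              x$grid$cell_size, sum(x$grid$values)))
  invisible(x)
}

#' Ad-hoc kernel bandwidth
#'
#' Starts from the bivariate normal reference bandwidth
#' h_ref = sigma_hat n^(-1/6) with sigma_hat = sqrt((var_x + var_y)/2), and
#' shrinks h in decrements of `step` x h_ref, returning the smallest h for
#' which the target isopleth is still a single rook-connected region with no
#' interior holes. If even h_ref fragments the isopleth, h_ref is returned.
#'
#' @param points two-column matrix or data frame with `x`, `y`.
#' @param level isopleth level (default 0.95).
#' @param step shrink decrement as a fraction of h_ref (default 0.05).
#' @param grid_resolution optional KDE cell size passed to [fit_kde()].
#' @return the selected bandwidth (metres), with attribute `h_ref`.
#' @export
h_ad_hoc <- function(points, level = 0.95, step = 0.05,
                     grid_resolution = NULL) {
  pts <- as_points(points)
  if (nrow(pts) < 5) stop("h_ad_hoc needs at least 5 points")
  sigma <- sqrt((stats::var(pts[, 1]) + stats::var(pts[, 2])) / 2)
  if (sigma == 0) stop("degenerate point set (zero variance)")
  h_ref <- sigma * nrow(pts)^(-1 / 6)
  contiguous <- function(h) {
    ud <- fit_kde(pts, h, grid_resolution = grid_resolution)
    mask <- isopleth_mask(ud, level)
    n_components(mask) == 1 && !has_holes(mask)
  }
  best <- h_ref
  if (!contiguous(h_ref)) {
    attr(best, "h_ref") <- h_ref
    return(best)
  }
  j <- 1
  while (TRUE) {
    h <- h_ref * (1 - step * j)
    if (h <= h_ref * step / 2) break
    if (!contiguous(h)) break
    best <- h
    j <- j + 1
  }
  attr(best, "h_ref") <- h_ref
  best
}

# logical mask of the smallest cell set reaching `level` cumulative mass
#' @keywords internal
isopleth_mask <- function(ud, level = 0.95) {
  v <- as.vector(ud$grid$values) # column-major
  ord <- order(-v, seq_along(v)) # ties broken by cell index
  cum <- cumsum(v[ord])
  k <- which(cum >= level - 1e-12)[1]
  mask <- matrix(FALSE, ud$grid$n_rows, ud$grid$n_cols)
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Isopleth movement range
#'
#' Sorts UD cells by mass (ties broken in cell-index order) and takes the
#' smallest prefix whose cumulative mass reaches `level`. Area is cell count
#' times cell area.
#'
#' @param ud a `quoll_ud` from [fit_kde()].
#' @param level isopleth level in (0, 1) (default 0.95).
#' @param individual_id,range_type metadata carried on the result.
#' @return object of class `movement_range`: `mask`, `grid`, `area_m2`,
#'   `area_ha`, `equal_area_radius` (= sqrt(area/pi), metres), `centroid`,
#'   `level`, `range_type`.
#' @export
isopleth <- function(ud, level = 0.95, individual_id = NA_character_,
                     range_type = "observed") {
  stopifnot(level > 0, level < 1)
  mask <- isopleth_mask(ud, level)
  area <- sum(mask) * ud$cell_area
  cc <- raster_centres(ud$grid)
  centroid <- c(x = mean(cc$xm[mask]), y = mean(cc$ym[mask]))
  structure(list(individual_id = individual_id, range_type = range_type,
                 level = level, mask = mask, grid = ud$grid,
                 h = ud$h, n_points = ud$n_points,
                 area_m2 = area, area_ha = area / 1e4,
                 equal_area_radius = sqrt(area / pi), centroid = centroid),
            class = "movement_range")
}

#' @export
print.movement_range <- function(x, ...) {
  cat(sprintf("<movement_range %s/%s> %g%% isopleth, %.2f ha (r_eq %.0f m)\n",
              x$individual_id, x$range_type, 100 * x$level, x$area_ha,
              x$equal_area_radius))
  invisible(x)
}

#' Does a movement range contain these points?
#' @param range a `movement_range` (isopleth or circular).
#' @param x,y coordinates (metres).
#' @return logical vector.
#' @export
range_contains <- function(range, x, y) {
  if (!is.null(range$radius)) {
    (x - range$centroid[["x"]])^2 + (y - range$centroid[["y"]])^2 <=
      range$radius^2
  } else {
    rc <- raster_rowcol(range$grid, x, y)
    ok <- !is.na(rc[, 1])
    out <- logical(length(x))
    out[ok] <- range$mask[cbind(rc[ok, 1], rc[ok, 2])]
    out
  }
}

#' Minimum convex polygon
#'
#' Convex hull of the fixes (optionally of the `fraction` of points closest
#' to the centroid); area by the shoelace formula.
#'
#' @param points two-column matrix or data frame with `x`, `y`.
#' @param fraction fraction of points retained (1 = 100% MCP).
#' @return list of class `quoll_mcp`: `vertices` (counter-clockwise open
#'   ring), `area_m2`, `area_ha`.
#' @export
mcp <- function(points, fraction = 1.0) {
  pts <- as_points(points)
  if (fraction < 1) {
    ctr <- colMeans(pts)
    d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    pts <- pts[d <= stats::quantile(d, fraction), , drop = FALSE]
  }
  hull <- grDevices::chull(pts)
  verts <- pts[rev(hull), , drop = FALSE] # counter-clockwise
  colnames(verts) <- c("x", "y")
  area <- polygon_area(verts)
  if (area == 0) warning("degenerate (collinear) MCP with zero area")
  structure(list(vertices = verts, area_m2 = area, area_ha = area / 1e4),
            class = "quoll_mcp")
}

#' Availability region around an MCP
#'
#' The MCP buffered outward by `r_max - r_focal`: the radius of the largest
#' observed movement range in the study minus the equal-area radius of the
#' range being measured. Membership is distance-to-hull <= buffer.
#'
#' @param mcp_poly a [mcp()] result.
#' @param r_max radius of the largest observed movement range (metres).
#' @param r_focal equal-area radius of the focal observed range (metres).
#' @return list of class `availability_region`: `vertices`, `buffer`,
#'   `area_m2` (hull + perimeter*d + pi d^2).
#' @export
availability_region <- function(mcp_poly, r_max, r_focal) {
  d <- r_max - r_focal
  if (d < 0) {
    warning("focal range radius exceeds r_max; using a zero buffer")
    d <- 0
  }
  area <- mcp_poly$area_m2 + polygon_perimeter(mcp_poly$vertices) * d +
    pi * d^2
  structure(list(vertices = mcp_poly$vertices, buffer = d, area_m2 = area),
            class = "availability_region")
}

#' Random circular available ranges
#'
#' Draws `n` circle centres uniformly from the availability region
#' (rejection sampling from its bounding box) and returns circles whose area
#' equals `target_area` exactly (radius sqrt(area/pi)). Circles may overlap
#' each other and the observed range.
#'
#' @param region an [availability_region()].
#' @param target_area area of the focal observed range (m^2).
#' @param n number of available ranges (default 5).
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @param individual_id metadata carried on the results.
#' @return list of `movement_range` objects with `range_type = "available"`,
#'   each with `centroid`, `radius`, `area_m2`, `area_ha`.
#' @export
sample_available_ranges <- function(region, target_area, n = 5, seed = NULL,
                                    individual_id = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  radius <- sqrt(target_area / pi)
  if (region$area_m2 < target_area)
    warning("availability region is smaller than the focal range area")
  v <- region$vertices
  bb <- c(min(v[, 1]) - region$buffer, max(v[, 1]) + region$buffer,
          min(v[, 2]) - region$buffer, max(v[, 2]) + region$buffer)
  centres <- matrix(NA_real_, 0, 2)
  while (nrow(centres) < n) {
    m <- (n - nrow(centres)) * 4 + 8
    px <- stats::runif(m, bb[1], bb[2]); py <- stats::runif(m, bb[3], bb[4])
    ok <- dist_to_polygon(px, py, v) <= region$buffer
    centres <- rbind(centres, cbind(px[ok], py[ok]))
  }
  centres <- centres[seq_len(n), , drop = FALSE]
  lapply(seq_len(n), function(i) {
    structure(list(individual_id = individual_id, range_type = "available",
                   level = NA_real_, radius = radius,
                   centroid = c(x = centres[i, 1], y = centres[i, 2]),
                   area_m2 = target_area, area_ha = target_area / 1e4,
                   equal_area_radius = radius),
              class = "movement_range")
  })
}

#' Zonal summary of a movement range over the landscape
#'
#' Cell-centre membership against the range geometry: proportions of the
#' five analysed habitat types over member cells (water cells count in the
#' denominator but water is not reported as a selectable class), median TRI
#' over member TRI cells, means of the distance layers, mean NDVI when
#' present, and the fraction of the range not covered by the mapped raster.
#'
#' @param range a `movement_range` (isopleth or circular).
#' @param landscape a `quoll_landscape`.
#' @return one-row tibble: `individual_id`, `range_type`, `area_ha`,
#'   habitat proportions (`prop_spinifex` ... `prop_water`), `median_tri`,
#'   `mean_dist_disturbance`, `mean_dist_rocky`, `mean_ndvi`,
#'   `unmapped_fraction`.
#' @export
summarize_range <- function(range, landscape) {
  hab <- landscape$habitat
  cc <- raster_centres(hab)
  inside <- range_contains(range, as.vector(cc$xm), as.vector(cc$ym))
  n_in <- sum(inside)
  if (n_in == 0) {
    warning("movement range covers no mapped cells; summaries are NA")
    out <- tibble::tibble(
      individual_id = range$individual_id, range_type = range$range_type,
      area_ha = range$area_ha,
      prop_spinifex = NA_real_, prop_riparian = NA_real_,
      prop_rocky = NA_real_, prop_pits = NA_real_, prop_disturbed = NA_real_,
      prop_water = NA_real_, median_tri = NA_real_,
      mean_dist_disturbance = NA_real_, mean_dist_rocky = NA_real_,
      unmapped_fraction = 1)
    if (!is.null(landscape$ndvi)) out$mean_ndvi <- NA_real_
    return(out)
  }
  codes <- hab$values[inside]
  props <- vapply(names(habitat_codes), function(nm)
    mean(codes == habitat_codes[[nm]]), numeric(1))
  cct <- raster_centres(landscape$tri)
  tin <- range_contains(range, as.vector(cct$xm), as.vector(cct$ym))
  covered_area <- n_in * hab$cell_size^2
  unmapped <- max(0, 1 - covered_area / range$area_m2)
  out <- tibble::tibble(
    individual_id = range$individual_id, range_type = range$range_type,
    area_ha = range$area_ha,
    prop_spinifex = props[["spinifex"]], prop_riparian = props[["riparian"]],
    prop_rocky = props[["rocky"]], prop_pits = props[["pits"]],
    prop_disturbed = props[["disturbed"]], prop_water = props[["water"]],
    median_tri = stats::median(landscape$tri$values[tin]),
    mean_dist_disturbance = mean(landscape$dist_disturbance$values[inside]),
    mean_dist_rocky = mean(landscape$dist_rocky$values[inside]),
    unmapped_fraction = unmapped)
  if (!is.null(landscape$ndvi))
    out$mean_ndvi <- mean(landscape$ndvi$values[inside])
  out
}

#' Observed movement range for one individual
#'
#' Convenience wrapper: ad-hoc bandwidth, KDE, isopleth.
#' @param points fixes for one individual (`x`, `y`).
#' @param config a [quoll_config()] (isopleth level).
#' @param individual_id metadata.
#' @param grid_resolution optional KDE cell size.
#' @return a `movement_range`.
#' @export
movement_range <- function(points, config = quoll_config(),
                           individual_id = NA_character_,
                           grid_resolution = NULL) {
  h <- h_ad_hoc(points, level = config$isopleth_level,
                grid_resolution = grid_resolution)
  ud <- fit_kde(points, as.numeric(h), grid_resolution = grid_resolution)
  isopleth(ud, config$isopleth_level, individual_id = individual_id)
}

#' Home-range asymptote check
#'
#' Recomputes the isopleth area as fixes are added sequentially (over time)
#' at `interval`-fix increments. The asymptote is `reached` when the last
#' three areas differ pairwise by less than `tol` (relative to the larger of
#' each pair); with fewer than three evaluations it is FALSE by insufficient
#' evidence.
#'
#' @param points time-ordered fixes (`x`, `y`).
#' @param interval fix increment (default 10).
#' @param level isopleth level.
#' @param tol pairwise relative tolerance (default 0.05).
#' @param grid_resolution optional KDE cell size.
#' @return list: `n` (fix counts), `areas_ha`, `reached`.
#' @export
asymptote_check <- function(points, interval = 10, level = 0.95, tol = 0.05,
                            grid_resolution = NULL) {
  pts <- as_points(points)
  ns <- seq(interval, nrow(pts), by = interval)
  ns <- ns[ns >= 5]
  areas <- vapply(ns, function(n) {
    sub <- pts[seq_len(n), , drop = FALSE]
    h <- h_ad_hoc(sub, level = level, grid_resolution = grid_resolution)
    ud <- fit_kde(sub, as.numeric(h), grid_resolution = grid_resolution)
    isopleth(ud, level)$area_ha
  }, numeric(1))
  reached <- FALSE
  if (length(areas) >= 3) {
    last3 <- utils::tail(areas, 3)
    prs <- utils::combn(3, 2)
    reldiff <- apply(prs, 2, function(p)
      abs(last3[p[1]] - last3[p[2]]) / max(last3[p]))
    reached <- all(reldiff < tol)
  }
  list(n = ns, areas_ha = areas, reached = reached)
}
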