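#' Habitat class codes
#'
#' Integer codes used on the categorical habitat raster: spinifex grassland
#' (0), riparian (1), rocky (2), mine pits & waste dumps (3), other disturbed
#' land (4), water (5). Water is mapped but excluded from selection analyses.
#' @export
habitat_codes <- c(spinifex = 0, riparian = 1, rocky = 2,
                   pits = 3, disturbed = 4, water = 5)

#' @keywords internal
habitat_names <- function(codes) names(habitat_codes)[match(codes, habitat_codes)]

# separable Gaussian smoothing with wrap-around edges (synthetic fields only)
#' @keywords internal
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  r <- min(r, floor((min(dim(m)) - 1) / 2)) # kernel must fit the grid
  if (r < 1) return(m)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  m <- stats::filter(m, k, circular = TRUE)            # columns
  t(stats::filter(t(m), k, circular = TRUE))           # rows
}

#' Default patch parameters for synthetic landscapes
#'
#' Target class proportions for a Pilbara mine-site mosaic (spinifex matrix,
#' a rocky range, riparian lines, an active pit/waste-dump complex, other
#' cleared land and scattered water), and a patch smoothness (Gaussian
#' correlation length in cells).
#' @param proportions named numeric over the six habitat classes, summing to 1.
#' @param smoothness patch correlation length in cells.
#' @return a list with elements `proportions` and `smoothness`.
#' @export
patch_params <- function(proportions = c(spinifex = 0.40, riparian = 0.07,
                                         rocky = 0.25, pits = 0.13,
                                         disturbed = 0.12, water = 0.03),
                         smoothness = 15) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("habitat proportions must sum to 1 (got ",
         format(sum(proportions)), ")")
  if (!all(names(habitat_codes) %in% names(proportions)))
    stop("proportions must name all habitat classes: ",
         paste(names(habitat_codes), collapse = ", "))
  list(proportions = proportions, smoothness = smoothness)
}

#' Generate a synthetic landscape
#'
#' Builds a co-registered raster stack emulating the study site's four
#' mapped layers plus NDVI: a categorical habitat mosaic (quantile bands of
#' a smooth Gaussian field, ordered water - riparian - spinifex - rocky -
#' pits - other disturbed so that riparian tracks water and mining tracks
#' rock), a topographic ruggedness index elevated on rocky cells and mapped
#' on its own (coarser) grid, and exact Euclidean cell-centre distance layers
#' to rocky habitat and to mining disturbance (codes 3 and 4). Class
#' proportions are matched exactly up to cell quantization.
#'
#' @param seed integer RNG seed.
#' @param n_rows,n_cols habitat grid dimensions.
#' @param cell_size habitat cell size in metres (default 10, as mapped).
#' @param params a [patch_params()] list.
#' @param tri_cell_size TRI grid cell size in metres (default 12.5, as mapped).
#' @param ndvi logical; also generate an NDVI layer (class-dependent means).
#' @return an object of class `quoll_landscape`: a list of [raster_grid()]
#'   layers `habitat`, `tri`, `dist_disturbance`, `dist_rocky` and optionally
#'   `ndvi`.
#' @export
generate_landscape <- function(seed = 1L, n_rows = 400, n_cols = 400,
                               cell_size = 10, params = patch_params(),
                               tri_cell_size = 12.5, ndvi = TRUE) {
  set.seed(seed)
  props <- params$proportions[names(habitat_codes)]
  u <- gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                       params$smoothness)
  # rank-based quantile bands => exact class counts
  band_order <- c("water", "riparian", "spinifex", "rocky", "pits", "disturbed")
  counts <- round(props[band_order] * n_rows * n_cols)
  counts[length(counts)] <- n_rows * n_cols - sum(counts[-length(counts)])
  rk <- rank(u, ties.method = "first")
  breaks <- cumsum(counts)
  band <- findInterval(rk, breaks + 0.5) + 1L
  habitat_vals <- matrix(habitat_codes[band_order][band], n_rows, n_cols)
  habitat <- raster_grid(habitat_vals, 0, n_rows * cell_size, cell_size,
                         name = "habitat")

  rocky_mask <- habitat_vals == habitat_codes[["rocky"]]
  disturb_mask <- habitat_vals == habitat_codes[["pits"]] |
    habitat_vals == habitat_codes[["disturbed"]]
  dist_rocky <- raster_grid(distance_transform(rocky_mask, cell_size),
                            0, n_rows * cell_size, cell_size,
                            name = "dist_rocky")
  dist_disturbance <- raster_grid(distance_transform(disturb_mask, cell_size),
                                  0, n_rows * cell_size, cell_size,
                                  name = "dist_disturbance")

  # TRI on its own grid over the same extent; rugged on rock
  tr <- ceiling(n_rows * cell_size / tri_cell_size)
  tc <- ceiling(n_cols * cell_size / tri_cell_size)
  tri_noise <- gaussian_smooth(matrix(stats::rnorm(tr * tc), tr, tc), 2)
  tri_noise <- abs(tri_noise) / stats::sd(tri_noise)
  tri_grid <- raster_grid(matrix(0, tr, tc), 0, n_rows * cell_size,
                          tri_cell_size, name = "tri")
  cc <- raster_centres(tri_grid)
  tri_hab <- matrix(raster_lookup(habitat, as.vector(cc$xm), as.vector(cc$ym)),
                    tr, tc)
  tri_hab[is.na(tri_hab)] <- habitat_codes[["spinifex"]] # overhang cells
  tri_vals <- 0.35 * tri_noise +
    ifelse(tri_hab == habitat_codes[["rocky"]], 1.1 + 0.6 * tri_noise, 0.25)
  tri_grid$values <- tri_vals

  land <- list(habitat = habitat, tri = tri_grid,
               dist_disturbance = dist_disturbance, dist_rocky = dist_rocky)
  if (ndvi) {
    ndvi_mean <- c(spinifex = 0.16, riparian = 0.36, rocky = 0.19,
                   pits = 0.09, disturbed = 0.11, water = 0.05)
    nv <- ndvi_mean[habitat_names(habitat_vals)] +
      0.03 * gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols),
                                    n_rows, n_cols), 3)
    land$ndvi <- raster_grid(matrix(pmax(0, nv), n_rows, n_cols),
                             0, n_rows * cell_size, cell_size, name = "ndvi")
  }
  class(land) <- "quoll_landscape"
  land
}

#' @export
print.quoll_landscape <- function(x, ...) {
  cat("<quoll_landscape>\n")
  for (nm in names(x)) {
    g <- x[[nm]]
    cat(sprintf("  %-16s %d x %d @ %g m\n", nm, g$n_rows, g$n_cols, g$cell_size))
  }
  tab <- table(factor(habitat_names(x$habitat$values),
                      levels = names(habitat_codes)))
  cat("  habitat: ", paste(sprintf("%s %.1f%%", names(tab),
                                   100 * tab / sum(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' Query every landscape layer at points
#'
#' @param landscape a `quoll_landscape`.
#' @param x,y point coordinates (metres).
#' @return tibble with one row per point: `habitat` (code), `habitat_class`
#'   (name), `tri`, `dist_disturbance`, `dist_rocky`, and `ndvi` if present.
#' @export
landscape_lookup <- function(landscape, x, y) {
  hab <- raster_lookup(landscape$habitat, x, y)
  out <- tibble::tibble(
    habitat = hab, habitat_class = habitat_names(hab),
    tri = raster_lookup(landscape$tri, x, y),
    dist_disturbance = raster_lookup(landscape$dist_disturbance, x, y),
    dist_rocky = raster_lookup(landscape$dist_rocky, x, y))
  if (!is.null(landscape$ndvi))
    out$ndvi <- raster_lookup(landscape$ndvi, x, y)
  out
}

#' Write / read all landscape layers
#' @param landscape a `quoll_landscape`.
#' @param dir directory for the `<layer>.grid` files.
#' @export
write_landscape <- function(landscape, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(landscape))
    write_raster(landscape[[nm]], file.path(dir, paste0(nm, ".grid")))
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  layers <- c("habitat", "tri", "dist_disturbance", "dist_rocky", "ndvi")
  land <- list()
  for (nm in layers) {
    p <- file.path(dir, paste0(nm, ".grid"))
    if (file.exists(p)) land[[nm]] <- read_raster(p)
  }
  if (is.null(land$habitat)) stop("no habitat.grid found in ", dir)
  class(land) <- "quoll_landscape"
  land
}
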