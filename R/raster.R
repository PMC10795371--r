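#' Planar raster grid
#'
#' A minimal single-layer raster in projected planar metres. `origin_x`,
#' `origin_y` give the top-left corner of the top-left cell; rows run
#' downwards (decreasing y), columns rightwards (increasing x). A cell's
#' value applies to the whole cell; point queries use half-open cells, so a
#' point on a shared edge belongs to the cell to the right/below.
#'
#' @param values numeric matrix, `n_rows` x `n_cols`, top row first.
#' @param origin_x,origin_y top-left corner coordinates in metres.
#' @param cell_size cell edge length in metres (> 0).
#' @param nodata sentinel value for missing cells.
#' @param name layer name.
#' @return an object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:4, 2, 2, byrow = TRUE), 0, 20, 10)
#' raster_lookup(g, 5, 15)  # centre of the top-left cell
#' @export
raster_grid <- function(values, origin_x, origin_y, cell_size,
                        nodata = -9999, name = "layer") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (cell_size <= 0) stop("cell_size must be > 0")
  g <- list(origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
            n_rows = nrow(values), n_cols = ncol(values),
            values = values, nodata = nodata, name = name)
  class(g) <- "raster_grid"
  g
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid '%s'> %d x %d cells of %g m, origin (%g, %g), nodata %g\n",
              x$name, x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$nodata))
  invisible(x)
}

#' Row/column indices of points (half-open cells)
#'
#' @return integer matrix with columns `row`, `col`; NA for points off the grid.
#' @keywords internal
raster_rowcol <- function(grid, x, y) {
  csy <- if (!is.null(grid$cell_size_y)) grid$cell_size_y else grid$cell_size
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / csy) + 1
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Query raster values at points
#'
#' Returns the stored cell value (including the nodata sentinel where the
#' cell is unmapped) and `NA` for points outside the grid extent.
#'
#' @param grid a [raster_grid()].
#' @param x,y point coordinates in metres.
#' @export
raster_lookup <- function(grid, x, y) {
  rc <- raster_rowcol(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- grid$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Cell-centre coordinates
#'
#' @param grid a [raster_grid()].
#' @return list with vectors `x` (length `n_cols`) and `y` (length `n_rows`),
#'   plus matrices `xm`, `ym` aligned with `grid$values`.
#' @keywords internal
raster_centres <- function(grid) {
  csy <- if (!is.null(grid$cell_size_y)) grid$cell_size_y else grid$cell_size
  x <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  y <- grid$origin_y - (seq_len(grid$n_rows) - 0.5) * csy
  list(x = x, y = y,
       xm = matrix(x, grid$n_rows, grid$n_cols, byrow = TRUE),
       ym = matrix(y, grid$n_rows, grid$n_cols))
}

#' Read a plain-text raster grid
#'
#' The package defines a small ASCII dialect so analyses never require
#' geospatial binaries. The header holds `name`, `origin_x`, `origin_y`,
#' `cell_size`, `n_rows`, `n_cols` and `nodata` (one `key value` pair per
#' line after a `QUOLLGRID 1` magic line), followed by `n_rows` lines of
#' `n_cols` space-separated values, top row first. Integer habitat codes are
#' preserved exactly.
#'
#' @param path file path.
#' @return a [raster_grid()].
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 9 || !startsWith(lines[1], "QUOLLGRID"))
    stop("not a QUOLLGRID file: ", path)
  hdr <- list()
  for (i in 2:8) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[kv[1]]] <- kv[2]
  }
  need <- c("name", "origin_x", "origin_y", "cell_size", "n_rows", "n_cols", "nodata")
  if (!all(need %in% names(hdr)))
    stop("QUOLLGRID header missing fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nr <- as.integer(hdr$n_rows); nc <- as.integer(hdr$n_cols)
  body <- lines[-(1:8)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop(sprintf("dimension mismatch in %s: header says %d rows, found %d",
                 path, nr, length(body)))
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("dimension mismatch in %s: expected %d values, found %d",
                 path, nr * nc, length(vals)))
  raster_grid(matrix(vals, nr, nc, byrow = TRUE),
              origin_x = as.numeric(hdr$origin_x),
              origin_y = as.numeric(hdr$origin_y),
              cell_size = as.numeric(hdr$cell_size),
              nodata = as.numeric(hdr$nodata), name = hdr$name)
}

#' Write a raster grid in the package's ASCII dialect
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("QUOLLGRID 1",
               paste("name", grid$name),
               paste("origin_x", format(grid$origin_x, digits = 15)),
               paste("origin_y", format(grid$origin_y, digits = 15)),
               paste("cell_size", format(grid$cell_size, digits = 15)),
               paste("n_rows", grid$n_rows),
               paste("n_cols", grid$n_cols),
               paste("nodata", format(grid$nodata, digits = 15))), con)
  writeLines(apply(grid$values, 1, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

#' Exact Euclidean distance transform of a cell set
#'
#' Distance (in metres) from every cell centre to the nearest cell centre in
#' the source set; 0 on source cells. Two-phase exact transform: per-row
#' horizontal scans, then a bounded vertical sweep over squared distances.
#' Returns `Inf` everywhere when the source set is empty.
#'
#' @param source_mask logical matrix marking source cells.
#' @param cell_size cell edge length in metres.
#' @return numeric matrix of distances.
#' @export
distance_transform <- function(source_mask, cell_size = 1) {
  nr <- nrow(source_mask); nc <- ncol(source_mask)
  g <- matrix(Inf, nr, nc)
  g[source_mask] <- 0
  if (!any(source_mask)) return(g)
  if (nc > 1) {
    for (j in 2:nc) g[, j] <- pmin(g[, j], g[, j - 1] + 1)
    for (j in (nc - 1):1) g[, j] <- pmin(g[, j], g[, j + 1] + 1)
  }
  d2 <- g^2
  if (nr > 1) {
    for (dr in 1:(nr - 1)) {
      if (dr * dr >= max(d2)) break
      shifted_down <- rbind(matrix(Inf, dr, nc), g[1:(nr - dr), , drop = FALSE])
      shifted_up <- rbind(g[(dr + 1):nr, , drop = FALSE], matrix(Inf, dr, nc))
      d2 <- pmin(d2, shifted_down^2 + dr * dr, shifted_up^2 + dr * dr)
    }
  }
  sqrt(d2) * cell_size
}
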