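# Readers/writers for the pipeline's tabular formats. All tables round-trip:
# read(write(x)) reproduces x (timestamps are whole seconds, numerics are
# written at full precision).

fix_columns <- c("id", "timestamp", "x", "y", "hdop")

#' Read GPS fixes
#'
#' Reads a fix table (CSV with header columns `id`, `timestamp` in ISO-8601
#' UTC, `x`, `y` in projected planar metres, `hdop`, and optionally
#' `temperature`). Rows with unparseable fields are dropped and reported via
#' the `rejections` attribute (line numbers and reasons) and a message.
#' Records are returned grouped by individual and time-sorted.
#'
#' Coordinates must be projected planar metres; inputs that look like
#' geographic lon/lat (all |x| <= 180 and |y| <= 90) are rejected, since all
#' distances and speeds downstream are metric.
#'
#' @param path CSV file path.
#' @param config a [quoll_config()] (reserved for schema options).
#' @return a tibble with columns `individual_id`, `timestamp` (POSIXct UTC),
#'   `x`, `y`, `hdop` and, when present, `temperature`; attribute
#'   `rejections` holds a tibble of dropped rows.
#' @export
read_fixes <- function(path, config = quoll_config()) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(fix_columns, names(raw))
  if (length(missing) > 0)
    stop("fix table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  ts <- parse_iso8601(raw$timestamp)
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  hdop <- suppressWarnings(as.numeric(raw$hdop))
  bad_field <- cbind(timestamp = is.na(ts), x = is.na(x), y = is.na(y),
                     hdop = is.na(hdop))
  bad <- rowSums(bad_field) > 0
  rejections <- tibble::tibble(
    line = which(bad) + 1L, # +1 for the header line
    reason = vapply(which(bad), function(i)
      paste("unparseable:",
            paste(colnames(bad_field)[bad_field[i, ]], collapse = ", ")),
      character(1)))
  if (nrow(rejections) > 0)
    message(nrow(rejections), " malformed row(s) rejected from ", path)
  fixes <- tibble::tibble(
    individual_id = raw$id[!bad], timestamp = ts[!bad],
    x = x[!bad], y = y[!bad], hdop = hdop[!bad])
  if ("temperature" %in% names(raw))
    fixes$temperature <- suppressWarnings(as.numeric(raw$temperature))[!bad]
  if (any(fixes$hdop < 0))
    stop("negative HDOP values in ", path)
  if (nrow(fixes) > 0 && all(abs(fixes$x) <= 180) && all(abs(fixes$y) <= 90))
    stop("coordinates in ", path, " look like geographic lon/lat; ",
         "project to planar metres (e.g. UTM) first")
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), , drop = FALSE]
  dup <- stats::ave(as.numeric(fixes$timestamp), fixes$individual_id,
                    FUN = function(t) duplicated(t)) > 0
  if (any(dup))
    stop("duplicate timestamps for individual(s): ",
         paste(unique(fixes$individual_id[dup]), collapse = ", "))
  attr(fixes, "rejections") <- rejections
  fixes
}

#' Write GPS fixes
#'
#' Inverse of [read_fixes()]; numerics are written at full precision so the
#' pair round-trips exactly.
#' @param fixes a fix tibble as returned by [read_fixes()] or [degrade_gps()].
#' @param path output CSV path.
#' @export
write_fixes <- function(fixes, path) {
  out <- data.frame(id = fixes$individual_id,
                    timestamp = iso8601(fixes$timestamp),
                    x = format(fixes$x, digits = 15, trim = TRUE),
                    y = format(fixes$y, digits = 15, trim = TRUE),
                    hdop = format(fixes$hdop, digits = 15, trim = TRUE))
  if ("temperature" %in% names(fixes))
    out$temperature <- format(fixes$temperature, digits = 15, trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read accelerometer records
#'
#' CSV with header `id`, `timestamp` (ISO-8601 UTC), `ax`, `ay`, `az` (g on
#' the surge/heave/sway axes) and `temperature` (degrees C), recorded at a
#' nominal 5-s cadence.
#' @param path CSV file path.
#' @return tibble with columns `individual_id`, `timestamp`, `ax`, `ay`,
#'   `az`, `temperature`.
#' @export
read_accel <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c("id", "timestamp", "ax", "ay", "az", "temperature")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stop("accelerometer table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  acc <- tibble::tibble(
    individual_id = as.character(raw$id),
    timestamp = parse_iso8601(raw$timestamp),
    ax = as.numeric(raw$ax), ay = as.numeric(raw$ay), az = as.numeric(raw$az),
    temperature = as.numeric(raw$temperature))
  if (any(abs(c(acc$ax, acc$ay, acc$az)) > 4 + 1e-9))
    stop("acceleration outside the +-4 g logger range in ", path)
  acc[order(acc$individual_id, acc$timestamp), , drop = FALSE]
}

#' Write accelerometer records
#' @param accel tibble as returned by [read_accel()] or
#'   [simulate_accelerometer()].
#' @param path output CSV path.
#' @export
write_accel <- function(accel, path) {
  out <- data.frame(id = accel$individual_id,
                    timestamp = iso8601(accel$timestamp),
                    ax = format(accel$ax, digits = 15, trim = TRUE),
                    ay = format(accel$ay, digits = 15, trim = TRUE),
                    az = format(accel$az, digits = 15, trim = TRUE),
                    temperature = format(accel$temperature, digits = 15,
                                         trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write/read step tables
#'
#' Steps (observed and available) are stored as plain CSV with ISO-8601
#' timestamps; all numeric columns round-trip at full precision.
#' @param steps a step tibble (see [bursts_to_steps()]).
#' @param path CSV path.
#' @export
write_steps <- function(steps, path) {
  out <- as.data.frame(steps)
  for (cn in names(out)) {
    if (inherits(out[[cn]], "POSIXct")) out[[cn]] <- iso8601(out[[cn]])
    else if (is.numeric(out[[cn]]))
      out[[cn]] <- format(out[[cn]], digits = 15, trim = TRUE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_steps
#' @export
read_steps <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  steps <- tibble::as_tibble(raw)
  for (cn in names(steps)) {
    v <- steps[[cn]]
    if (cn %in% c("t_start", "t_end")) steps[[cn]] <- parse_iso8601(v)
    else if (cn %in% c("individual_id", "season", "case", "habitat_class"))
      steps[[cn]] <- v
    else {
      num <- suppressWarnings(as.numeric(v))
      if (all(is.na(num) == is.na(v))) steps[[cn]] <- num
    }
  }
  if ("flag_drop" %in% names(steps))
    steps$flag_drop <- steps$flag_drop != 0
  steps
}

#' Write polygons as GeoJSON
#'
#' Minimal GeoJSON FeatureCollection writer for MCPs, isopleth outlines and
#' availability regions (planar coordinates; no CRS member is written).
#'
#' @param polygons named list of two-column vertex matrices (open rings).
#' @param path output path.
#' @param properties optional list of per-polygon property lists.
#' @export
write_geojson <- function(polygons, path, properties = NULL) {
  features <- lapply(seq_along(polygons), function(i) {
    ring <- polygons[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE]) # close the ring
    props <- if (!is.null(properties)) properties[[i]] else
      list(name = names(polygons)[i])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
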