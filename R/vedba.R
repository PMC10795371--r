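# Tri-axial acceleration -> VeDBA, and aggregation of VeDBA onto 30-min
# observed steps inside the nocturnal window.

#' Static (gravitational) acceleration by a two-sample running mean
#'
#' The static component at sample i is the mean of samples i-1 and i (a
#' 10-s running mean at the 5-s cadence); the first sample of each
#' contiguous segment takes its own raw value, so its dynamic component is
#' zero by construction. Gaps longer than the cadence restart the window.
#'
#' @param raw numeric vector, one axis.
#' @param timestamps optional POSIXct; when supplied, gaps > `cadence`
#'   seconds restart the smoother.
#' @param cadence nominal sampling interval in seconds.
#' @return numeric vector of static acceleration, same length as `raw`.
#' @export
static_acceleration <- function(raw, timestamps = NULL, cadence = 5) {
  n <- length(raw)
  if (n == 0) return(numeric(0))
  static <- (c(raw[1], raw[-n]) + raw) / 2
  restart <- rep(FALSE, n)
  restart[1] <- TRUE
  if (!is.null(timestamps) && n > 1)
    restart[-1] <- diff(as.numeric(timestamps)) > cadence + 1e-9
  static[restart] <- raw[restart]
  static
}

#' Vectorial dynamic body acceleration
#'
#' Decomposes each axis into static (two-sample running mean) and dynamic
#' components, takes absolute dynamic values, and combines them as
#' VeDBA = sqrt(Ax^2 + Ay^2 + Az^2). VeDBA is preferred over ODBA because it
#' is insensitive to collar rotation: any fixed rotation of the axes leaves
#' the vector norm unchanged once the static field is removed. (Taking
#' absolute dynamic values before squaring is numerically redundant but kept
#' for fidelity to the published processing.)
#'
#' @param accel accelerometer tibble (see [read_accel()]); may hold several
#'   individuals.
#' @param cadence nominal sampling interval in seconds.
#' @return the input tibble with added columns `static_x/y/z`, `dba_x/y/z`
#'   (absolute dynamic components) and `vedba` (g).
#' @export
compute_vedba <- function(accel, cadence = 5) {
  pieces <- lapply(split(accel, accel$individual_id), function(a) {
    a <- a[order(a$timestamp), , drop = FALSE]
    a$static_x <- static_acceleration(a$ax, a$timestamp, cadence)
    a$static_y <- static_acceleration(a$ay, a$timestamp, cadence)
    a$static_z <- static_acceleration(a$az, a$timestamp, cadence)
    a$dba_x <- abs(a$ax - a$static_x)
    a$dba_y <- abs(a$ay - a$static_y)
    a$dba_z <- abs(a$az - a$static_z)
    a$vedba <- sqrt(a$dba_x^2 + a$dba_y^2 + a$dba_z^2)
    a
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Aggregate VeDBA and temperature onto observed steps
#'
#' For each observed step, averages VeDBA and temperature over samples with
#' `t_start < timestamp <= t_end` that also fall inside the nocturnal window
#' (samples between 06:00 and 18:00 local, when collars were not recording
#' GPS, are discarded). Steps with no samples get NA. If an individual's
#' accelerometer and GPS records do not overlap in time at all, a warning is
#' issued and its steps are all-missing.
#'
#' @param vedba output of [compute_vedba()].
#' @param steps observed-step tibble (see [bursts_to_steps()]).
#' @param config a [quoll_config()] (night window and UTC offset).
#' @return `steps` with columns `mean_vedba`, `mean_temperature` and
#'   `n_vedba_samples` added.
#' @export
aggregate_step_vedba <- function(vedba, steps, config = quoll_config()) {
  steps$mean_vedba <- NA_real_
  steps$mean_temperature <- NA_real_
  steps$n_vedba_samples <- 0L
  for (id in unique(steps$individual_id)) {
    srows <- which(steps$individual_id == id)
    v <- vedba[vedba$individual_id == id, , drop = FALSE]
    if (nrow(v) == 0) next
    v <- v[in_night_window(v$timestamp, config), , drop = FALSE]
    tv <- as.numeric(v$timestamp)
    t0 <- as.numeric(steps$t_start[srows]); t1 <- as.numeric(steps$t_end[srows])
    if (nrow(v) == 0 || max(tv) <= min(t0) || min(tv) > max(t1)) {
      warning("accelerometer and GPS records do not overlap for ", id)
      next
    }
    ord <- order(tv)
    tv <- tv[ord]
    cs_v <- cumsum(v$vedba[ord]); cs_t <- cumsum(v$temperature[ord])
    # samples strictly after t_start, up to and including t_end
    i0 <- findInterval(t0 + 1e-9, tv) + 1L
    i1 <- findInterval(t1 + 1e-9, tv)
    cnt <- pmax(i1 - i0 + 1L, 0L)
    ok <- cnt > 0
    prev_v <- ifelse(i0 > 1, cs_v[pmax(i0 - 1, 1)], 0)
    prev_t <- ifelse(i0 > 1, cs_t[pmax(i0 - 1, 1)], 0)
    sum_v <- ifelse(ok, cs_v[pmax(i1, 1)] - prev_v, NA)
    sum_t <- ifelse(ok, cs_t[pmax(i1, 1)] - prev_t, NA)
    steps$mean_vedba[srows] <- sum_v / cnt
    steps$mean_temperature[srows] <- sum_t / cnt
    steps$n_vedba_samples[srows] <- cnt
  }
  steps
}
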