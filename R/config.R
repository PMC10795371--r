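#' Study configuration
#'
#' Bundles the sampling-design constants and screening thresholds used across
#' the pipeline. Defaults mirror the field deployment: GPS fixes every 30 min
#' between 18:00 and 06:00 local time (at most 24 per night), fixes with
#' HDOP > 10 discarded, a 4.5 m s^-1 speed ceiling, five available steps per
#' observed step, five available ranges per individual, 95% isopleth movement
#' ranges, and bursts of at least three locations.
#'
#' @param night_start,night_end local clock hours bounding the nocturnal GPS
#'   window (default 18 and 6; the window wraps midnight).
#' @param fix_interval GPS sampling interval in minutes.
#' @param max_fixes_per_night possible fixes per night; used as the
#'   denominator of fix-success rates.
#' @param hdop_max fixes with HDOP strictly greater than this are removed.
#' @param vmax maximum plausible speed in m s^-1 for the speed filter.
#' @param n_available_steps available steps generated per observed step.
#' @param n_available_ranges random circular available ranges per individual.
#' @param isopleth_level utilisation-distribution isopleth (fraction in (0,1)).
#' @param min_burst_locations minimum fixes for a burst to be retained.
#' @param burst_tolerance allowed schedule jitter in minutes when splitting
#'   bursts (0 reproduces the literal "more than 30 min" rule).
#' @param utc_offset fixed local-time offset from UTC in hours (no DST; the
#'   Pilbara observes none).
#' @param rng_seed integer seed recorded in run manifests.
#' @return an object of class `quoll_config` (a validated named list).
#' @examples
#' cfg <- quoll_config()
#' cfg$hdop_max
#' @export
quoll_config <- function(night_start = 18, night_end = 6,
                         fix_interval = 30, max_fixes_per_night = 24,
                         hdop_max = 10, vmax = 4.5,
                         n_available_steps = 5, n_available_ranges = 5,
                         isopleth_level = 0.95, min_burst_locations = 3,
                         burst_tolerance = 3, utc_offset = 8,
                         rng_seed = 1L) {
  cfg <- list(
    night_start = night_start, night_end = night_end,
    fix_interval = fix_interval, max_fixes_per_night = max_fixes_per_night,
    hdop_max = hdop_max, vmax = vmax,
    n_available_steps = as.integer(n_available_steps),
    n_available_ranges = as.integer(n_available_ranges),
    isopleth_level = isopleth_level,
    min_burst_locations = as.integer(min_burst_locations),
    burst_tolerance = burst_tolerance, utc_offset = utc_offset,
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$isopleth_level > 0, cfg$isopleth_level < 1,
    cfg$fix_interval >= 1, cfg$max_fixes_per_night >= 1,
    cfg$n_available_steps >= 1, cfg$n_available_ranges >= 1,
    cfg$min_burst_locations >= 1, cfg$hdop_max >= 0, cfg$vmax > 0,
    cfg$burst_tolerance >= 0
  )
  class(cfg) <- "quoll_config"
  cfg
}

#' @export
print.quoll_config <- function(x, ...) {
  cat("<quoll_config>\n")
  cat(sprintf("  night window  %02d:00-%02d:00 local (UTC%+d)\n",
              x$night_start, x$night_end, x$utc_offset))
  cat(sprintf("  fix interval  %g min (max %d/night)\n",
              x$fix_interval, x$max_fixes_per_night))
  cat(sprintf("  screening     HDOP > %g removed; vmax %g m/s; bursts >= %d fixes (tol %g min)\n",
              x$hdop_max, x$vmax, x$min_burst_locations, x$burst_tolerance))
  cat(sprintf("  design        %d available steps/stratum; %d available ranges; %g%% isopleth\n",
              x$n_available_steps, x$n_available_ranges, 100 * x$isopleth_level))
  invisible(x)
}

#' Local clock hour (fractional) of a UTC timestamp under the study offset
#' @keywords internal
local_hour <- function(t, config) {
  tl <- as.numeric(t) + config$utc_offset * 3600
  (tl %% 86400) / 3600
}

#' Is a UTC timestamp inside the nocturnal GPS window?
#' @keywords internal
in_night_window <- function(t, config) {
  h <- local_hour(t, config)
  if (config$night_start > config$night_end) {
    h >= config$night_start | h < config$night_end
  } else {
    h >= config$night_start & h < config$night_end
  }
}
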