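# Fix screening and conversion of cleaned fixes into bursts and observed
# movement steps. Filter order is fixed: HDOP -> speed -> exclusion windows
# -> bursts; the cleaning report decomposes removals exactly.

#' HDOP filter
#'
#' Removes fixes with HDOP strictly greater than `hdop_max` (a fix with
#' HDOP exactly equal to the threshold is kept). Order is preserved.
#'
#' @param fixes fix tibble (see [read_fixes()]).
#' @param hdop_max threshold (default 10).
#' @return list with `fixes` (kept rows) and `removed` (count).
#' @export
filter_hdop <- function(fixes, hdop_max = 10) {
  if (any(is.na(fixes$hdop)) || any(fixes$hdop < 0))
    stop("HDOP must be present and non-negative on every fix")
  keep <- fixes$hdop <= hdop_max
  list(fixes = fixes[keep, , drop = FALSE], removed = sum(!keep))
}

#' Speed filter
#'
#' Single forward pass per individual from the first retained fix: a fix is
#' removed when its distance from the last retained fix exceeds
#' `vmax` times the elapsed time to that fix. A pair implying a speed of
#' exactly `vmax` is kept. After filtering, every consecutive retained pair
#' implies a speed of at most `vmax`.
#'
#' @param fixes time-sorted fix tibble.
#' @param vmax maximum speed in m s^-1 (default 4.5, the species' average
#'   maximum).
#' @return list with `fixes` and `removed`.
#' @export
filter_speed <- function(fixes, vmax = 4.5) {
  keep_all <- logical(nrow(fixes))
  for (id in unique(fixes$individual_id)) {
    sel <- which(fixes$individual_id == id)
    if (length(sel) == 0) next
    t <- as.numeric(fixes$timestamp[sel])
    x <- fixes$x[sel]; y <- fixes$y[sel]
    keep <- logical(length(sel))
    keep[1] <- TRUE
    last <- 1
    for (i in seq_along(sel)[-1]) {
      dt <- t[i] - t[last]
      d <- sqrt((x[i] - x[last])^2 + (y[i] - y[last])^2)
      if (dt <= 0) {
        if (d > 0) stop("zero time difference between distinct positions for ", id)
        next # exact duplicate; drop
      }
      if (d / dt <= vmax + 1e-12) {
        keep[i] <- TRUE
        last <- i
      }
    }
    keep_all[sel] <- keep
  }
  list(fixes = fixes[keep_all, , drop = FALSE], removed = sum(!keep_all))
}

#' Capture/event exclusion windows
#'
#' Removes fixes falling in any half-open window `[start, end)`. Used to
#' discard the night before and morning of captures, and post-event fixes
#' (e.g. from 18:00 on the night of a predation).
#'
#' @param fixes fix tibble.
#' @param windows tibble/data.frame with columns `individual_id`, `start`,
#'   `end` (POSIXct UTC). An empty or NULL table is the identity.
#' @return list with `fixes` and `removed`.
#' @export
exclude_windows <- function(fixes, windows = NULL) {
  if (is.null(windows) || nrow(windows) == 0)
    return(list(fixes = fixes, removed = 0L))
  drop <- logical(nrow(fixes))
  for (k in seq_len(nrow(windows))) {
    drop <- drop | (fixes$individual_id == windows$individual_id[k] &
                      fixes$timestamp >= windows$start[k] &
                      fixes$timestamp < windows$end[k])
  }
  list(fixes = fixes[!drop, , drop = FALSE], removed = sum(drop))
}

#' Build bursts from cleaned fixes
#'
#' Splits each individual's fixes at any gap exceeding
#' `fix_interval + tolerance` minutes, then drops bursts with fewer than
#' `min_locations` fixes (a gap of exactly the threshold does not split).
#'
#' @param fixes time-sorted fix tibble.
#' @param fix_interval nominal sampling interval (minutes).
#' @param tolerance allowed jitter (minutes); 0 reproduces the literal
#'   "more than 30 min" rule.
#' @param min_locations minimum burst size (default 3, the minimum needed
#'   for a turning angle).
#' @return list with `fixes` (burst-labelled, short bursts removed; extra
#'   column `burst_id`), `removed` (fix count from dropped bursts), and
#'   `n_bursts`.
#' @export
build_bursts <- function(fixes, fix_interval = 30, tolerance = 3,
                         min_locations = 3) {
  if (nrow(fixes) == 0)
    return(list(fixes = cbind(fixes, burst_id = integer(0)),
                removed = 0L, n_bursts = 0L))
  max_gap <- (fix_interval + tolerance) * 60
  ord <- order(fixes$individual_id, fixes$timestamp)
  fixes <- fixes[ord, , drop = FALSE]
  new_id <- c(TRUE, fixes$individual_id[-1] != fixes$individual_id[-nrow(fixes)])
  gap <- c(0, diff(as.numeric(fixes$timestamp)))
  split_here <- new_id | gap > max_gap + 1e-9
  fixes$burst_id <- cumsum(split_here)
  size <- table(fixes$burst_id)
  small <- as.integer(names(size)[size < min_locations])
  drop <- fixes$burst_id %in% small
  kept <- fixes[!drop, , drop = FALSE]
  if (nrow(kept) > 0) kept$burst_id <- match(kept$burst_id, unique(kept$burst_id))
  list(fixes = kept, removed = sum(drop),
       n_bursts = length(unique(kept$burst_id)))
}

#' Convert bursts to observed movement steps
#'
#' One step per consecutive fix pair within a burst. Step length is the
#' Euclidean start-end distance; the turning angle is the change of heading
#' from the previous step, counter-clockwise positive in (-pi, pi], and is
#' undefined (NA) for the first step of each burst (such steps are retained
#' but excluded from turning-angle fitting). Each observed step receives a
#' unique `stratum_id`.
#'
#' @param bursts burst-labelled fix tibble from [build_bursts()].
#' @param individuals optional design tibble (`individual_id`, `season`,
#'   `age`) to carry metadata onto steps.
#' @return observed-step tibble: `stratum_id`, `individual_id`, `season`,
#'   `age`, `case`, `burst_id`, `start_x/y`, `end_x/y`, `t_start`, `t_end`,
#'   `sl`, `ta`, `log10_sl`, `cos_ta`.
#' @export
bursts_to_steps <- function(bursts, individuals = NULL) {
  pieces <- lapply(split(bursts, list(bursts$individual_id, bursts$burst_id),
                         drop = TRUE), function(b) {
    n <- nrow(b)
    if (n < 2) return(NULL)
    dx <- diff(b$x); dy <- diff(b$y)
    sl <- sqrt(dx^2 + dy^2)
    heading <- atan2(dy, dx)
    ta <- c(NA_real_, wrap_angle(diff(heading)))
    tibble::tibble(
      individual_id = b$individual_id[1], burst_id = b$burst_id[1],
      case = "observed",
      start_x = b$x[-n], start_y = b$y[-n],
      end_x = b$x[-1], end_y = b$y[-1],
      t_start = b$timestamp[-n], t_end = b$timestamp[-1],
      sl = sl, ta = ta)
  })
  steps <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(steps))
    steps <- tibble::tibble(individual_id = character(), burst_id = integer(),
                            case = character(), start_x = numeric(),
                            start_y = numeric(), end_x = numeric(),
                            end_y = numeric(),
                            t_start = as.POSIXct(character(), tz = "UTC"),
                            t_end = as.POSIXct(character(), tz = "UTC"),
                            sl = numeric(), ta = numeric())
  steps <- steps[order(steps$individual_id, steps$t_start), , drop = FALSE]
  steps$log10_sl <- log10(pmax(steps$sl, .Machine$double.eps))
  steps$cos_ta <- cos(steps$ta)
  steps$stratum_id <- seq_len(nrow(steps))
  if (!is.null(individuals)) {
    m <- match(steps$individual_id, individuals$individual_id)
    if ("season" %in% names(individuals)) steps$season <- individuals$season[m]
    if ("age" %in% names(individuals)) steps$age <- individuals$age[m]
  }
  steps
}

#' Run the full fix-screening pipeline
#'
#' Applies, in order: HDOP filter, speed filter, exclusion windows, burst
#' construction, then builds observed steps. The report decomposes removals
#' exactly: `n_output = n_input - sum(removals)` (over fixes).
#'
#' @param fixes raw fix tibble.
#' @param config a [quoll_config()].
#' @param windows optional exclusion windows (see [exclude_windows()]).
#' @param individuals optional design tibble for step metadata.
#' @return list of class `quoll_cleaning`: `fixes` (cleaned, burst-labelled),
#'   `steps` (observed steps), and `report` (named counts).
#' @export
clean_fixes <- function(fixes, config = quoll_config(), windows = NULL,
                        individuals = NULL) {
  n_input <- nrow(fixes)
  s1 <- filter_hdop(fixes, config$hdop_max)
  s2 <- filter_speed(s1$fixes, config$vmax)
  s3 <- exclude_windows(s2$fixes, windows)
  s4 <- build_bursts(s3$fixes, config$fix_interval, config$burst_tolerance,
                     config$min_burst_locations)
  steps <- bursts_to_steps(s4$fixes, individuals)
  report <- list(
    n_input = n_input,
    n_removed_hdop = s1$removed,
    n_removed_speed = s2$removed,
    n_removed_windows = s3$removed,
    n_removed_short_bursts = s4$removed,
    n_output = nrow(s4$fixes),
    n_bursts = s4$n_bursts,
    n_steps = nrow(steps))
  stopifnot(report$n_output ==
              report$n_input - report$n_removed_hdop - report$n_removed_speed -
              report$n_removed_windows - report$n_removed_short_bursts)
  structure(list(fixes = s4$fixes, steps = steps, report = report),
            class = "quoll_cleaning")
}

#' @export
print.quoll_cleaning <- function(x, ...) {
  r <- x$report
  cat("<quoll_cleaning>\n")
  cat(sprintf("  %d fixes in; removed %d (HDOP) + %d (speed) + %d (windows) + %d (short bursts) -> %d kept\n",
              r$n_input, r$n_removed_hdop, r$n_removed_speed,
              r$n_removed_windows, r$n_removed_short_bursts, r$n_output))
  cat(sprintf("  %d bursts, %d observed steps\n", r$n_bursts, r$n_steps))
  invisible(x)
}
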