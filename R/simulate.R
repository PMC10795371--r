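# Habitat-selective trajectory, GPS-degradation and accelerometer simulators.
# These define the synthetic study conditions: 9 collared quolls (4 breeding,
# 5 non-breeding), ~20 nights each, 30-min fixes 18:00-06:00 local, 5-s
# tri-axial acceleration around the clock.

#' Movement parameters with known ground truth
#'
#' Step lengths are gamma(shape, scale) in metres; turning angles are
#' von Mises with mean 0 and concentration `kappa`; `beta` holds log-scale
#' selection coefficients by covariate name (habitat class names contrast
#' against the rocky reference; `tri`, `dist_disturbance`, `dist_rocky`,
#' `ndvi` act linearly). Defaults give a weakly directed forager with mean
#' step 144 m that avoids open and mining habitats and selects rugged ground.
#'
#' @param shape,scale gamma step-length parameters (shape > 0, scale in m).
#' @param kappa von Mises turning-angle concentration (>= 0).
#' @param beta named numeric of selection coefficients.
#' @return a list of class `movement_params`.
#' @export
movement_params <- function(shape = 1.2, scale = 120, kappa = 0.5,
                            beta = c(spinifex = -1.0, pits = -0.8,
                                     disturbed = -0.6, riparian = -0.4,
                                     tri = 0.5)) {
  stopifnot(shape > 0, scale > 0, kappa >= 0)
  structure(list(shape = shape, scale = scale, kappa = kappa, beta = beta),
            class = "movement_params")
}

#' von Mises random angles (Best-Fisher rejection sampler)
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); 0 gives the circular uniform.
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) return(wrap_angle(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    ccr <- kappa * (r - f)
    ok <- (ccr * (2 - ccr) - u2 > 0) | (log(ccr / u2) + 1 - ccr >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
    out <- c(out, theta)
  }
  wrap_angle(out[seq_len(n)] + mu)
}

# selection weight exp(beta' z) at endpoints; 0 off-raster and on water
#' @keywords internal
selection_weight <- function(landscape, params, x, y) {
  hab <- raster_lookup(landscape$habitat, x, y)
  w <- numeric(length(x))
  on <- !is.na(hab) & hab != habitat_codes[["water"]]
  if (!any(on)) return(w)
  b <- params$beta
  hb <- numeric(length(habitat_codes))
  hab_terms <- intersect(names(b), names(habitat_codes))
  hb[habitat_codes[hab_terms] + 1] <- unlist(b[hab_terms])
  eta <- hb[hab[on] + 1]
  for (nm in setdiff(names(b), hab_terms))
    eta <- eta + b[[nm]] * raster_lookup(landscape[[nm]], x[on], y[on])
  w[on] <- exp(eta)
  w
}

#' Simulate one habitat-selective track
#'
#' At each nocturnal 30-min epoch, `n_candidates` candidate endpoints are
#' drawn from the selection-free movement kernel (gamma step length, von
#' Mises turn about the previous heading) and one is chosen with probability
#' proportional to exp(beta' z) at the endpoint (weight 0 off-raster and on
#' water; fully off-raster candidate sets are redrawn up to 20 times). The
#' animal sits at its den (a random rocky cell) through the day and starts
#' each night there with a uniform random heading. Activity level is the
#' realised step length divided by the kernel's mean step.
#'
#' @param landscape a `quoll_landscape`.
#' @param params a [movement_params()].
#' @param n_nights nights to simulate.
#' @param config a [quoll_config()].
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @param individual_id,season,age identity metadata carried through.
#' @param start_date local calendar date of the first night (Date or string).
#' @param n_candidates candidate endpoints per step.
#' @param den optional `c(x, y)` den location in metres; default a random
#'   rocky cell centre.
#' @return a tibble of class `sim_track` with one row per 30-min epoch
#'   (day and night): `individual_id`, `timestamp` (UTC), `x`, `y`,
#'   `activity`, `is_night`, `season`, `age`; the den and parameters are kept
#'   in the `truth` attribute.
#' @export
simulate_track <- function(landscape, params, n_nights = 20,
                           config = quoll_config(), seed = NULL,
                           individual_id = "Q01", season = "breeding",
                           age = 1, start_date = "2021-09-20",
                           n_candidates = 100, den = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hab <- landscape$habitat
  if (is.null(den)) {
    rocky_idx <- which(hab$values == habitat_codes[["rocky"]])
    if (length(rocky_idx) == 0)
      rocky_idx <- which(hab$values != habitat_codes[["water"]])
    den_cell <- rocky_idx[sample.int(length(rocky_idx), 1)]
    cc <- raster_centres(hab)
    den <- c(cc$xm[den_cell], cc$ym[den_cell])
  }

  n_per_night <- config$max_fixes_per_night
  night0_utc <- as.POSIXct(paste(start_date, sprintf("%02d:00:00", config$night_start)),
                           tz = "UTC") - config$utc_offset * 3600
  mean_step <- params$shape * params$scale

  rows <- vector("list", n_nights)
  for (d in seq_len(n_nights)) {
    t0 <- night0_utc + (d - 1) * 86400
    times <- t0 + (seq_len(n_per_night) - 1) * config$fix_interval * 60
    xs <- ys <- act <- numeric(n_per_night)
    xs[1] <- den[1]; ys[1] <- den[2]; act[1] <- 0
    heading <- stats::runif(1, -pi, pi)
    for (j in 2:n_per_night) {
      for (attempt in 1:20) {
        # after repeated off-raster draws, turn freely (a wall forces a turn)
        turns <- if (attempt <= 5) rvonmises(n_candidates, 0, params$kappa)
        else stats::runif(n_candidates, -pi, pi)
        lens <- stats::rgamma(n_candidates, shape = params$shape,
                              scale = params$scale)
        heads <- heading + turns
        ex <- xs[j - 1] + lens * cos(heads)
        ey <- ys[j - 1] + lens * sin(heads)
        w <- selection_weight(landscape, params, ex, ey)
        if (sum(w) > 0) break
        if (attempt == 20) stop("all candidate endpoints off-raster near (",
                                xs[j - 1], ", ", ys[j - 1], ")")
      }
      pick <- sample.int(n_candidates, 1, prob = w)
      xs[j] <- ex[pick]; ys[j] <- ey[pick]
      heading <- heads[pick]
      act[j] <- lens[pick] / mean_step
    }
    # daytime: den occupancy until next evening
    day_times <- times[n_per_night] + seq_len(24) * config$fix_interval * 60
    rows[[d]] <- tibble::tibble(
      timestamp = c(times, day_times),
      x = c(xs, rep(den[1], 24)), y = c(ys, rep(den[2], 24)),
      activity = c(act, rep(0, 24)),
      is_night = c(rep(TRUE, n_per_night), rep(FALSE, 24)))
  }
  track <- do.call(rbind, rows)
  track <- tibble::tibble(individual_id = individual_id,
                          timestamp = track$timestamp, x = track$x,
                          y = track$y, activity = track$activity,
                          is_night = track$is_night,
                          season = season, age = age)
  attr(track, "truth") <- list(den = den, params = params,
                               n_candidates = n_candidates)
  class(track) <- c("sim_track", class(track))
  track
}

#' Simulate the full study design
#'
#' Nine individuals mirroring the deployment: four first-year males tracked
#' in the breeding season (spring) and five individuals (one female, ages
#' alternating 2/1) in the following non-breeding season (winter), each for
#' `n_nights` nights.
#'
#' @inheritParams simulate_track
#' @param n_nights nights per individual.
#' @param seed RNG seed for the whole design.
#' @return list with elements `tracks` (row-bound `sim_track` tibble) and
#'   `individuals` (design tibble: id, season, sex, age, start date).
#' @export
simulate_study <- function(landscape, params = movement_params(),
                           config = quoll_config(), n_nights = 20, seed = 1L) {
  set.seed(seed)
  design <- tibble::tibble(
    individual_id = sprintf("Q%02d", 1:9),
    season = c(rep("breeding", 4), rep("non-breeding", 5)),
    sex = c(rep("M", 4), "F", "M", "M", "M", "M"),
    age = c(1, 1, 1, 1, 2, 1, 2, 1, 2),
    start_date = c(rep("2021-09-20", 4), rep("2022-06-20", 5)))
  tracks <- lapply(seq_len(nrow(design)), function(i) {
    simulate_track(landscape, params, n_nights = n_nights, config = config,
                   seed = NULL, individual_id = design$individual_id[i],
                   season = design$season[i], age = design$age[i],
                   start_date = design$start_date[i])
  })
  out <- do.call(rbind, tracks)
  attr(out, "truth") <- list(params = params,
                             dens = lapply(tracks, function(t) attr(t, "truth")$den))
  list(tracks = out, individuals = design)
}

#' Degrade a true track into GPS fixes
#'
#' Applies isotropic Gaussian position error, Bernoulli fix failure, and an
#' HDOP mixture with a configurable mass above 10 (failed fixes are absent
#' from the output). Only nocturnal epochs produce fixes, matching the
#' collar duty cycle.
#'
#' @param track a `sim_track` (or row-bound tracks).
#' @param gps_sigma per-axis position error SD in metres (trial collars
#'   showed ~8.3 m mean radial error at HDOP < 10).
#' @param fail_rate Bernoulli probability a scheduled fix fails.
#' @param hdop_dist list: `p_high` mass above 10, `meanlog`/`sdlog` of the
#'   below-10 lognormal body, `high_rate` exponential rate of the above-10 tail.
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return fix tibble (`individual_id`, `timestamp`, `x`, `y`, `hdop`).
#' @export
degrade_gps <- function(track, gps_sigma = 8.3, fail_rate = 0.05,
                        hdop_dist = list(p_high = 0.03, meanlog = log(2.2),
                                         sdlog = 0.45, high_rate = 1 / 3),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  night <- track[track$is_night, , drop = FALSE]
  n <- nrow(night)
  keep <- stats::runif(n) >= fail_rate
  night <- night[keep, , drop = FALSE]
  n <- nrow(night)
  if (n == 0)
    return(tibble::tibble(individual_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                          x = numeric(), y = numeric(), hdop = numeric()))
  high <- stats::runif(n) < hdop_dist$p_high
  hdop <- pmin(stats::rlnorm(n, hdop_dist$meanlog, hdop_dist$sdlog), 10)
  hdop[high] <- 10 + stats::rexp(sum(high), rate = hdop_dist$high_rate)
  tibble::tibble(
    individual_id = night$individual_id, timestamp = night$timestamp,
    x = night$x + stats::rnorm(n, 0, gps_sigma),
    y = night$y + stats::rnorm(n, 0, gps_sigma),
    hdop = hdop)
}

#' Simulate tri-axial accelerometer and temperature streams
#'
#' Emits 5-s records around the clock. Each axis is a slowly rotating
#' gravity projection plus a zero-mean Gaussian dynamic component whose SD is
#' `dyn_scale` times the activity level of the containing 30-min epoch
#' (samples at time t belong to the epoch ending at or after t, consistent
#' with the (t_start, t_end] step-membership rule). Output is clipped to the
#' logger's +-4 g range. Temperature follows a sinusoidal diel cycle peaking
#' mid-afternoon local time.
#'
#' @param track a `sim_track` (or row-bound tracks).
#' @param grav gravity magnitude in g.
#' @param dyn_scale dynamic-component SD per unit activity (g).
#' @param rot_sd per-sample SD (radians) of the collar-orientation random
#'   walk; 0 freezes the gravity projection.
#' @param cadence sampling interval in seconds.
#' @param temp_mean,temp_amplitude diel temperature mean and half-range (C).
#' @param config a [quoll_config()] (for the local-time offset).
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return tibble `individual_id`, `timestamp`, `ax`, `ay`, `az`, `temperature`.
#' @export
simulate_accelerometer <- function(track, grav = 1, dyn_scale = 0.35,
                                   rot_sd = 0.02,
                                   cadence = 5, temp_mean = 25,
                                   temp_amplitude = 6,
                                   config = quoll_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(split(track, track$individual_id), function(tr) {
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    epochs <- as.numeric(tr$timestamp)
    t <- seq(epochs[1] - 30 * 60 + cadence, epochs[length(epochs)], by = cadence)
    idx <- pmin(findInterval(t - 1e-9, epochs) + 1L, length(epochs))
    act <- tr$activity[idx]
    n <- length(t)
    # slowly rotating collar orientation
    th <- cumsum(stats::rnorm(n, 0, rot_sd))
    ph <- cumsum(stats::rnorm(n, 0, rot_sd))
    gx <- grav * sin(th) * cos(ph)
    gy <- grav * sin(th) * sin(ph)
    gz <- grav * cos(th)
    sd_dyn <- dyn_scale * act
    ax <- gx + stats::rnorm(n, 0, 1) * sd_dyn
    ay <- gy + stats::rnorm(n, 0, 1) * sd_dyn
    az <- gz + stats::rnorm(n, 0, 1) * sd_dyn
    hour <- (as.numeric(t) / 3600 + config$utc_offset) %% 24
    temp <- temp_mean + temp_amplitude * cos((hour - 15) / 24 * 2 * pi) +
      stats::rnorm(n, 0, 0.2)
    tibble::tibble(individual_id = tr$individual_id[1],
                   timestamp = as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
                   ax = pmin(4, pmax(-4, ax)), ay = pmin(4, pmax(-4, ay)),
                   az = pmin(4, pmax(-4, az)), temperature = temp)
  })
  do.call(rbind, out)
}
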