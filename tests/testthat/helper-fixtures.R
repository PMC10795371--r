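# Shared fixtures, built in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

# small default-mosaic landscape (120 x 120 cells of 10 m)
small_landscape <- function() {
  if (is.null(.fixtures$land))
    .fixtures$land <- generate_landscape(seed = 7, n_rows = 120, n_cols = 120)
  .fixtures$land
}

# a uniform-habitat landscape of one class
mono_landscape <- function(class = "rocky", n = 60) {
  pr <- stats::setNames(rep(0, 6), names(habitat_codes))
  pr[class] <- 1
  generate_landscape(seed = 3, n_rows = n, n_cols = n,
                     params = patch_params(proportions = pr), ndvi = FALSE)
}

# random fixes tibble for io tests (coordinates well outside lon/lat range)
random_fixes <- function(n = 50, n_id = 3, seed = 1) {
  set.seed(seed)
  t0 <- as.POSIXct("2021-09-20 10:00:00", tz = "UTC")
  tibble::tibble(
    individual_id = rep(sprintf("Q%02d", seq_len(n_id)), each = n),
    timestamp = rep(t0 + (seq_len(n) - 1) * 1800, n_id),
    x = stats::runif(n * n_id, 500, 3500),
    y = stats::runif(n * n_id, 500, 3500),
    hdop = stats::rlnorm(n * n_id, log(2.5), 0.6))
}

# deterministic "track" table for degrade/accel tests (no movement model)
toy_track <- function(n_epochs = 48, activity = NULL, seed = 1,
                      id = "T01", season = "breeding", age = 1) {
  set.seed(seed)
  t0 <- as.POSIXct("2021-09-20 10:00:00", tz = "UTC")
  if (is.null(activity)) activity <- stats::runif(n_epochs, 0, 2)
  tibble::tibble(
    individual_id = id,
    timestamp = t0 + (seq_len(n_epochs) - 1) * 1800,
    x = cumsum(stats::rnorm(n_epochs, 0, 50)) + 2000,
    y = cumsum(stats::rnorm(n_epochs, 0, 50)) + 2000,
    activity = activity,
    is_night = rep(TRUE, n_epochs), season = season, age = age)
}

# small end-to-end simulated study shared between test files
small_study <- function() {
  if (is.null(.fixtures$study)) {
    land <- small_landscape()
    st <- simulate_study(land, n_nights = 4, seed = 21)
    fixes <- degrade_gps(st$tracks, seed = 22)
    cleaned <- clean_fixes(fixes, individuals = st$individuals)
    .fixtures$study <- list(land = land, tracks = st$tracks,
                            individuals = st$individuals, fixes = fixes,
                            cleaned = cleaned)
  }
  .fixtures$study
}
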