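# Synthetic landscapes, habitat-selective tracks, GPS degradation and
# accelerometer streams: known-ground-truth properties.

test_that("landscape generator enforces proportions and layer consistency", {
  expect_error(patch_params(proportions = c(spinifex = 0.5, riparian = 0.2,
                                            rocky = 0.2, pits = 0.05,
                                            disturbed = 0.04, water = 0.005)),
               "sum to 1")
  land <- small_landscape()
  hab <- land$habitat$values
  expect_setequal(unique(as.vector(hab)), unname(habitat_codes))
  # distance layers are zero exactly on their source classes
  expect_true(all(land$dist_rocky$values[hab == 2] == 0))
  expect_true(all(land$dist_rocky$values[hab != 2] > 0))
  expect_true(all(land$dist_disturbance$values[hab %in% c(3, 4)] == 0))
  expect_true(all(land$dist_disturbance$values[!hab %in% c(3, 4)] > 0))
  # rocky is the most rugged class by median TRI
  cc <- raster_centres(land$tri)
  tri_hab <- raster_lookup(land$habitat, as.vector(cc$xm), as.vector(cc$ym))
  med <- tapply(as.vector(land$tri$values), tri_hab, median)
  expect_true(all(med[["2"]] > med[names(med) != "2"]))
})

test_that("all-rocky landscape has dist_rocky identically zero", {
  land <- mono_landscape("rocky", n = 30)
  expect_true(all(land$dist_rocky$values == 0))
})

test_that("distance transform equals brute-force all-pairs scan on a 30x30 grid", {
  set.seed(11)
  mask <- matrix(runif(900) < 0.07, 30, 30)
  got <- distance_transform(mask, cell_size = 10)
  src <- which(mask, arr.ind = TRUE)
  brute <- matrix(Inf, 30, 30)
  for (r in 1:30) for (c in 1:30)
    brute[r, c] <- 10 * sqrt(min((src[, 1] - r)^2 + (src[, 2] - c)^2))
  expect_equal(got, brute, tolerance = 1e-12)
  expect_true(all(distance_transform(matrix(FALSE, 3, 3)) == Inf))
})

test_that("selection-free movement uses habitat in proportion to availability", {
  # fine-grained 50/50 two-class mosaic; beta = 0
  pr <- c(spinifex = 0.5, riparian = 0, rocky = 0.5, pits = 0,
          disturbed = 0, water = 0)
  land <- generate_landscape(seed = 5, n_rows = 80, n_cols = 80,
                             params = patch_params(pr, smoothness = 1),
                             ndvi = FALSE)
  par0 <- movement_params(beta = c(tri = 0))
  tr <- simulate_track(land, par0, n_nights = 60, seed = 9,
                       n_candidates = 50)
  ends <- tr[tr$is_night & tr$activity > 0, ]
  hab <- raster_lookup(land$habitat, ends$x, ends$y)
  p_rocky <- mean(hab == 2)
  n <- length(hab)
  expect_lt(abs(p_rocky - 0.5), 4 * sqrt(0.25 / n) + 0.02)
})

test_that("high concentration with no selection gives near-straight paths", {
  # wide open landscape so near-straight nightly paths never meet a wall
  land <- mono_landscape("spinifex", n = 700)
  par <- movement_params(kappa = 50, beta = c(tri = 0))
  tr <- simulate_track(land, par, n_nights = 8, seed = 13, n_candidates = 50,
                       den = c(3500, 3500))
  fx <- tibble::tibble(individual_id = tr$individual_id,
                       timestamp = tr$timestamp, x = tr$x, y = tr$y,
                       hdop = 1)[tr$is_night, ]
  steps <- bursts_to_steps(build_bursts(fx)$fixes)
  # von Mises moment: E cos(ta) = I1(50)/I0(50) ~ 0.99
  expect_gt(mean(steps$cos_ta, na.rm = TRUE), 0.95)
})

test_that("realized selection-free step lengths recover the gamma kernel by MLE", {
  land <- mono_landscape("spinifex", n = 300)
  par <- movement_params(shape = 1.2, scale = 120, beta = c(tri = 0))
  tr <- simulate_track(land, par, n_nights = 435, seed = 17, n_candidates = 40,
                       den = c(1500, 1500))
  night <- tr[tr$is_night, ]
  sl <- sqrt(diff(night$x)^2 + diff(night$y)^2)
  sl <- sl[night$activity[-1] > 0 & sl > 0]
  fit <- fitdistrplus::fitdist(sl, "gamma")
  expect_lt(abs(fit$estimate[["shape"]] - 1.2) / 1.2, 0.05)
  expect_lt(abs(1 / fit$estimate[["rate"]] - 120) / 120, 0.05)
})

test_that("GPS degradation: exactness, total failure and Rayleigh error", {
  tr <- toy_track(48)
  fx0 <- degrade_gps(tr, gps_sigma = 0, fail_rate = 0, seed = 2)
  expect_equal(nrow(fx0), 48)
  expect_equal(fx0$x, tr$x)
  expect_equal(fx0$y, tr$y)
  expect_equal(nrow(degrade_gps(tr, fail_rate = 1, seed = 2)), 0)

  big <- toy_track(10000, seed = 3)
  fx <- degrade_gps(big, gps_sigma = 8.3, fail_rate = 0, seed = 4)
  radial <- sqrt((fx$x - big$x)^2 + (fx$y - big$y)^2)
  expect_lt(abs(mean(radial) - 8.3 * sqrt(pi / 2)) / (8.3 * sqrt(pi / 2)),
            0.02)
  # configurable HDOP mass above 10
  fx2 <- degrade_gps(big, fail_rate = 0,
                     hdop_dist = list(p_high = 0.2, meanlog = log(2),
                                      sdlog = 0.4, high_rate = 1), seed = 5)
  expect_lt(abs(mean(fx2$hdop > 10) - 0.2), 0.02)
})

test_that("accelerometer streams scale with activity, clip at 4 g and obey dyn_scale = 0", {
  tr <- toy_track(8, activity = rep(c(1, 2), 4))
  acc0 <- simulate_accelerometer(tr, dyn_scale = 0, rot_sd = 0, seed = 6)
  vd0 <- compute_vedba(acc0)
  expect_lt(max(vd0$vedba), 1e-12) # static gravity only
  acc0r <- simulate_accelerometer(tr, dyn_scale = 0, seed = 6)
  expect_lt(max(compute_vedba(acc0r)$vedba), 0.05) # slow rotation leaks little
  acc <- simulate_accelerometer(tr, dyn_scale = 0.35, seed = 7)
  expect_true(all(abs(c(acc$ax, acc$ay, acc$az)) <= 4))
  vd <- compute_vedba(acc)
  steps <- tibble::tibble(
    stratum_id = 1:7, individual_id = "T01", case = "observed",
    start_x = 0, start_y = 0, end_x = 1, end_y = 1,
    t_start = tr$timestamp[-8], t_end = tr$timestamp[-1],
    sl = 1, ta = 0, log10_sl = 0, cos_ta = 1)
  agg <- aggregate_step_vedba(vd, steps)
  m1 <- mean(agg$mean_vedba[tr$activity[-1] == 1])
  m2 <- mean(agg$mean_vedba[tr$activity[-1] == 2])
  expect_lt(abs(m2 / m1 - 2), 0.05 * 2)
})

test_that("simulation is seed-deterministic end to end", {
  land <- small_landscape()
  t1 <- simulate_track(land, movement_params(), n_nights = 2, seed = 31)
  t2 <- simulate_track(land, movement_params(), n_nights = 2, seed = 31)
  expect_identical(t1$x, t2$x)
  f1 <- degrade_gps(t1, seed = 32); f2 <- degrade_gps(t2, seed = 32)
  expect_identical(f1, f2)
  a1 <- simulate_accelerometer(t1[1:8, ], seed = 33)
  a2 <- simulate_accelerometer(t2[1:8, ], seed = 33)
  expect_identical(a1, a2)
})

test_that("full-noise pipeline still recovers all selection-coefficient signs", {
  s <- small_study()
  kern <- fit_tentative_kernel(s$cleaned$steps)
  av <- sample_available_steps(s$cleaned$steps, kern, n = 5, seed = 23)
  dat <- attach_covariates(rbind(s$cleaned$steps, av), s$land)
  fit <- fit_clogit(dat, ~ habitat + tri + log10_sl + cos_ta)
  truth_sign <- c(habitatspinifex = -1, habitatriparian = -1,
                  habitatpits = -1, habitatdisturbed = -1, tri = 1)
  expect_equal(unname(sign(fit$coef[names(truth_sign)])),
               unname(truth_sign))
})
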