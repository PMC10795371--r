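# Tentative kernel, available steps, conditional-logistic Newton estimation,
# AICc selection, kernel updating and RSS.

# 2-strata toy with one binary covariate (brute-force oracle target)
toy_strata <- function() {
  tibble::tibble(
    stratum_id = rep(1:2, each = 6),
    individual_id = "A", case = rep(c("observed", rep("available", 5)), 2),
    z = c(1, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0))
}

test_that("tentative kernel recovers gamma and von Mises parameters", {
  set.seed(33)
  steps <- tibble::tibble(case = "observed",
                          sl = rgamma(10000, shape = 2, scale = 100),
                          ta = rvonmises(10000, 0, 1.5))
  kern <- fit_tentative_kernel(steps)
  expect_true(kern$shape > 1.9 && kern$shape < 2.1)
  expect_lt(abs(kern$scale - 100) / 100, 0.06)
  expect_lt(abs(kern$kappa - 1.5) / 1.5, 0.06)
  expect_error(fit_tentative_kernel(steps[1:5, ]), "at least 10")

  # degenerate angles cap kappa with a warning
  deg <- steps; deg$ta <- 0
  expect_warning(kd <- fit_tentative_kernel(deg), "capped")
  expect_equal(kd$kappa, 500)
  # zero mean cosine -> kappa 0
  unif <- steps; unif$ta <- rep(c(pi / 2, -pi / 2, pi / 2, pi), 2500)[1:10000]
  expect_equal(fit_tentative_kernel(unif)$kappa, 0)
})

test_that("available steps share strata, match the kernel, and are seed-deterministic", {
  s <- small_study()
  obs <- s$cleaned$steps
  kern <- tentative <- fit_tentative_kernel(obs)
  av <- sample_available_steps(obs, kern, n = 5, seed = 34)
  expect_equal(nrow(av), 5 * nrow(obs))
  tab <- table(c(obs$stratum_id, av$stratum_id),
               c(obs$case, av$case))
  expect_true(all(tab[, "observed"] == 1))
  expect_true(all(tab[, "available"] == 5))
  # pooled available lengths follow the tentative gamma
  ks <- suppressWarnings(
    ks.test(av$sl[seq_len(5000)], "pgamma", shape = kern$shape,
            scale = kern$scale))
  expect_gt(ks$p.value, 0.01)
  av2 <- sample_available_steps(obs, kern, n = 5, seed = 34)
  expect_identical(av$end_x, av2$end_x)
})

test_that("covariate attachment flags water/off-raster ends and matches brute-force lookups", {
  s <- small_study()
  steps <- s$cleaned$steps[1:200, ]
  out <- attach_covariates(steps, s$land)
  # brute-force point-in-cell scan on the habitat layer
  hab <- s$land$habitat
  brute <- vapply(seq_len(nrow(steps)), function(i) {
    col <- floor((steps$end_x[i] - hab$origin_x) / hab$cell_size) + 1
    row <- floor((hab$origin_y - steps$end_y[i]) / hab$cell_size) + 1
    if (col < 1 || col > hab$n_cols || row < 1 || row > hab$n_rows)
      NA_real_ else hab$values[row, col]
  }, numeric(1))
  expect_equal(out$habitat_code, brute)
  expect_equal(out$flag_drop, is.na(brute) | brute == 5)
  # rocky reference: dummy vector all zero
  mm <- model.matrix(~habitat, out[!out$flag_drop, ])
  rocky_rows <- out$habitat_class[!out$flag_drop] == "rocky"
  expect_true(all(mm[rocky_rows, -1] == 0))

  # off-raster steps are flagged and dropped from fitting
  far <- steps; far$end_x <- far$end_x + 1e6
  out2 <- attach_covariates(far, s$land)
  expect_true(all(out2$flag_drop))
})

test_that("null conditional-logistic log-likelihood is S log(1/6) with 5 available steps", {
  toy <- toy_strata()
  sel <- select_models(toy, list(null = ~1))
  expect_equal(sel$logLik, 2 * log(1 / 6))
})

test_that("Newton MLE matches a brute-force 1-D likelihood maximisation", {
  toy <- toy_strata()
  fit <- fit_clogit(toy, ~z)
  # golden-section oracle on the partial likelihood
  pl <- function(b) {
    p1 <- exp(b) / (exp(b) + 5)
    p2 <- 1 / (1 + exp(b) + 4)
    log(p1) + log(p2)
  }
  gs <- optimize(pl, c(-10, 10), maximum = TRUE)
  expect_lt(abs(fit$coef[["z"]] - gs$maximum), 1e-4)
  expect_lt(abs(fit$logLik - gs$objective), 1e-8)

  # duplicating every stratum doubles lnL, leaves beta unchanged
  toy2 <- rbind(toy, transform(toy, stratum_id = stratum_id + 10))
  fit2 <- fit_clogit(toy2, ~z)
  expect_equal(fit2$coef[["z"]], fit$coef[["z"]], tolerance = 1e-8)
  expect_equal(fit2$logLik, 2 * fit$logLik, tolerance = 1e-8)
})

test_that("conditional likelihood is invariant to stratum order, relabelling and covariate shifts", {
  set.seed(36)
  n_strata <- 120
  d <- tibble::tibble(
    stratum_id = rep(seq_len(n_strata), each = 6),
    individual_id = "A",
    case = rep(c("observed", rep("available", 5)), n_strata),
    z1 = rnorm(n_strata * 6), z2 = rnorm(n_strata * 6))
  # induce selection on z1
  for (s in seq_len(n_strata)) {
    rows <- which(d$stratum_id == s)
    w <- exp(0.8 * d$z1[rows])
    pick <- sample(rows, 1, prob = w)
    d$case[rows] <- "available"; d$case[pick] <- "observed"
  }
  fit <- fit_clogit(d, ~ z1 + z2)
  shuffled <- d[sample(nrow(d)), ]
  fit_s <- fit_clogit(shuffled, ~ z1 + z2)
  expect_equal(fit_s$coef, fit$coef, tolerance = 1e-8)
  expect_equal(fit_s$logLik, fit$logLik, tolerance = 1e-8)
  shifted <- d; shifted$z1 <- shifted$z1 + 100
  fit_c <- fit_clogit(shifted, ~ z1 + z2)
  expect_equal(fit_c$coef, fit$coef, tolerance = 1e-6)
  expect_equal(fit_c$logLik, fit$logLik, tolerance = 1e-8)
})

test_that("Newton estimates agree with survival::clogit", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  set.seed(37)
  n_strata <- 150
  d <- tibble::tibble(
    stratum_id = rep(seq_len(n_strata), each = 6),
    individual_id = "A",
    case = rep(c("observed", rep("available", 5)), n_strata),
    z1 = rnorm(n_strata * 6), z2 = runif(n_strata * 6))
  for (s in seq_len(n_strata)) {
    rows <- which(d$stratum_id == s)
    pick <- sample(rows, 1, prob = exp(0.6 * d$z1[rows] - 0.4 * d$z2[rows]))
    d$case[rows] <- "available"; d$case[pick] <- "observed"
  }
  fit <- fit_clogit(d, ~ z1 + z2)
  ref <- survival::clogit(I(case == "observed") ~ z1 + z2 +
                            survival::strata(stratum_id), data = d)
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(diag(fit$vcov)), unname(diag(vcov(ref))),
               tolerance = 1e-5)
})

test_that("complete separation raises an error naming the covariate", {
  n_strata <- 30
  d <- tibble::tibble(
    stratum_id = rep(seq_len(n_strata), each = 6),
    individual_id = "A",
    case = rep(c("observed", rep("available", 5)), n_strata),
    zsep = rep(c(1, 0, 0, 0, 0, 0), n_strata))
  expect_error(fit_clogit(d, ~zsep), "separation.*zsep")
})

test_that("uninformative strata are dropped with a count", {
  toy <- toy_strata()
  dead <- tibble::tibble(stratum_id = rep(3, 6), individual_id = "A",
                         case = c("observed", rep("available", 5)), z = 1)
  fit <- fit_clogit(rbind(toy, dead), ~z)
  expect_equal(fit$n_strata, 2)
  expect_equal(fit$n_dropped_strata, 1)
})

test_that("AICc arithmetic and model ranking behave", {
  expect_equal(quollmove:::aicc_value(-10, 2, 50),
               20 + 4 + 2 * 2 * 3 / 47, tolerance = 1e-12)
  set.seed(38)
  n_strata <- 200
  d <- tibble::tibble(
    stratum_id = rep(seq_len(n_strata), each = 6),
    individual_id = "A",
    case = rep(c("observed", rep("available", 5)), n_strata),
    z1 = rnorm(n_strata * 6))
  for (s in seq_len(n_strata)) {
    rows <- which(d$stratum_id == s)
    pick <- sample(rows, 1, prob = exp(1.2 * d$z1[rows]))
    d$case[rows] <- "available"; d$case[pick] <- "observed"
  }
  sel <- select_models(d, list(global = ~z1, null = ~1, global_dup = ~z1))
  expect_equal(sel$model[1:2], c("global", "global_dup"))
  expect_equal(sel$dAICc[2], 0) # identical duplicates tie
  expect_false(sel$support[sel$model == "null"])
})

test_that("kernel updating applies the log10 conversion and flags invalid updates", {
  tent <- structure(list(shape = 2, scale = 100, kappa = 1),
                    class = "tentative_kernel")
  fit0 <- list(coef = c(log10_sl = 0, cos_ta = 0))
  upd0 <- update_kernel(tent, fit0)
  expect_equal(upd0$shape, 2); expect_equal(upd0$kappa, 1)
  fit1 <- list(coef = c(log10_sl = 1.1513, cos_ta = 0.4))
  upd1 <- update_kernel(tent, fit1)
  expect_equal(upd1$shape, 2 + 1.1513 / log(10), tolerance = 1e-12)
  expect_equal(upd1$shape, 2.5, tolerance = 1e-4)
  expect_equal(upd1$kappa, 1.4)
  expect_true(upd1$valid)
  fit2 <- list(coef = c(log10_sl = -6, cos_ta = -2))
  expect_false(update_kernel(tent, fit2)$valid)
})

test_that("RSS identities and delta-method CI against a parametric bootstrap", {
  toy <- toy_strata()
  fit <- fit_clogit(toy, ~z)
  same <- log_rss(fit, c(z = 1), c(z = 1))
  expect_equal(same$rss, 1)
  expect_true(same$lower <= 1 && same$upper >= 1)

  fit_fake <- fit
  fit_fake$coef <- c(z = -0.5)
  fit_fake$vcov <- matrix(0.04, 1, 1, dimnames = list("z", "z"))
  r <- log_rss(fit_fake, c(z = 1), c(z = 0))
  expect_equal(r$rss, exp(-0.5), tolerance = 1e-12)
  expect_equal(round(r$rss, 4), 0.6065)
  set.seed(39)
  draws <- exp(rnorm(10000, -0.5, 0.2))
  boot_ci <- quantile(draws, c(0.025, 0.975))
  expect_lt(abs(r$lower - boot_ci[[1]]) / boot_ci[[1]], 0.02)
  expect_lt(abs(r$upper - boot_ci[[2]]) / boot_ci[[2]], 0.02)
})
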