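# Along-path covariates, path models, partial-correlation decomposition,
# relevant-range standardisation and the season model.

mk_psem_steps <- function(n = 400, seed = 40, env_fun = NULL,
                          season = "breeding") {
  set.seed(seed)
  env <- runif(n)
  temp <- rnorm(n, 25, 3)
  sl <- 100 + 40 * env - 2 * (temp - 25) + rnorm(n, 0, 20)
  vedba <- 0.1 + 0.004 * sl - 0.005 * (temp - 25) + rnorm(n, 0, 0.05)
  tibble::tibble(individual_id = rep(sprintf("I%d", 1:8), length.out = n),
                 env = env, mean_temperature = temp, sl = sl,
                 mean_vedba = vedba, season = season)
}

test_that("along-path sampling yields exact proportions on constructed geometry", {
  land <- mono_landscape("rocky", n = 40)
  steps <- tibble::tibble(individual_id = "A", case = "observed",
                          start_x = 55, start_y = 200, end_x = 255,
                          end_y = 200, sl = 200)
  out <- step_env_covariates(steps, land)
  expect_equal(out$path_prop_rocky, 1.0)
  expect_equal(out$path_mean_dist_rocky, 0)

  # 50/50 vertical boundary crossed perpendicularly
  split_hab <- raster_grid(cbind(matrix(0, 40, 20), matrix(2, 40, 20)),
                           0, 400, 10, name = "habitat")
  land2 <- list(habitat = split_hab,
                tri = raster_grid(matrix(1, 40, 40), 0, 400, 10),
                dist_disturbance = raster_grid(matrix(5, 40, 40), 0, 400, 10),
                dist_rocky = raster_grid(matrix(0, 40, 40), 0, 400, 10))
  class(land2) <- "quoll_landscape"
  steps2 <- tibble::tibble(individual_id = "A", case = "observed",
                           start_x = 100, start_y = 205, end_x = 300,
                           end_y = 205, sl = 200)
  out2 <- step_env_covariates(steps2, land2)
  expect_lt(abs(out2$path_prop_rocky - 0.5), 0.05)
  props <- unlist(out2[paste0("path_prop_", names(habitat_codes))])
  expect_equal(sum(props), 1, tolerance = 1e-9)
  expect_equal(out2$path_median_tri, 1)
})

test_that("partial correlation equals the closed form and detects exact dependence", {
  set.seed(41)
  ctrl <- rnorm(500)
  a <- rnorm(500)
  b <- a + ctrl
  expect_equal(partial_correlation(a, b, ctrl), 1, tolerance = 1e-12)
  x <- rnorm(2000); y <- rnorm(2000); cz <- rnorm(2000)
  expect_lt(abs(partial_correlation(x, y, cz)), 3 / sqrt(2000))
  r_ab <- cor(x, y); r_ac <- cor(x, cz); r_bc <- cor(y, cz)
  closed <- (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  expect_equal(partial_correlation(x, y, cz), closed, tolerance = 1e-12)
})

test_that("path model recovers a pure-mediation structure", {
  set.seed(42)
  n <- 600
  d <- tibble::tibble(individual_id = rep(sprintf("I%d", 1:8), length.out = n),
                      env = runif(n))
  d$sl <- 2 * d$env + rnorm(n, 0, 0.3)
  d$mean_vedba <- 3 * d$sl + rnorm(n, 0, 0.3)
  d$mean_temperature <- rnorm(n, 25, 2)
  fit <- fit_path_model(d, "env")
  # GLMM-1: env coefficient ~ 2
  expect_lt(abs(fit$coef_sl$estimate[fit$coef_sl$term == "env"] - 2), 0.15)
  # GLMM-2: no direct env path -> CI contains 0
  row <- fit$coef_vedba[fit$coef_vedba$term == "env", ]
  expect_true(row$lower <= 0 && row$upper >= 0)
  dec <- total_effect(d, "env")
  expect_lt(abs(dec$direct), 0.1)
  expect_gt(dec$indirect, 0.5)
  expect_gt(dec$total, 0)
  expect_equal(dec$total, dec$direct + dec$indirect)

  # an env uncorrelated with everything leaves only the indirect channel
  d$noise_env <- rnorm(n)
  dec2 <- total_effect(d, "noise_env")
  expect_lt(abs(dec2$direct), 0.1)
  expect_equal(dec2$total, dec2$direct + dec2$indirect)

  expect_error(fit_path_model(transform(d, env = 1), "env"), "constant")
})

test_that("conditional R2 collapses to the marginal R2 without group variance", {
  d <- mk_psem_steps(500, seed = 43)
  fit <- fit_path_model(d, "env")
  vcr <- as.data.frame(lme4::VarCorr(fit$m_sl))
  if (vcr$vcov[vcr$grp == "individual_id"] < 1e-8) {
    pred <- model.matrix(fit$m_sl) %*% lme4::fixef(fit$m_sl)
    marginal <- var(as.vector(pred)) /
      (var(as.vector(pred)) + vcr$vcov[vcr$grp == "Residual"])
    expect_equal(fit$r2c_sl, marginal, tolerance = 1e-8)
  }
  expect_true(fit$r2c_sl > 0 && fit$r2c_sl < 1)
  expect_true(fit$r2c_vedba > 0 && fit$r2c_vedba < 1)
})

test_that("relevant-range coefficients standardise by observed ranges and resist rescaling", {
  d <- mk_psem_steps(400, seed = 44)
  fit <- fit_path_model(d, "env")
  rr <- relevant_range(fit)
  row <- rr[rr$equation == "step_length" & rr$term == "env", ]
  expect_equal(row$standardized,
               row$estimate * row$range_x / row$range_y, tolerance = 1e-12)
  expect_equal(sign(row$standardized), sign(row$estimate))
  # rescaling the predictor leaves the standardised value unchanged
  d2 <- d; d2$env <- d2$env * 37
  rr2 <- relevant_range(fit_path_model(d2, "env"))
  row2 <- rr2[rr2$equation == "step_length" & rr2$term == "env", ]
  expect_equal(row2$standardized, row$standardized, tolerance = 1e-6)
  # brute-force re-fit on min-max-scaled variables
  d3 <- d
  sc <- function(x) (x - min(x)) / diff(range(x))
  d3$env <- sc(d$env); d3$mean_temperature <- sc(d$mean_temperature)
  d3$sl_resp <- sc(d$sl)
  m3 <- lme4::lmer(sl_resp ~ env + mean_temperature + (1 | individual_id),
                   data = transform(d3, env = env,
                                    mean_temperature = mean_temperature),
                   REML = FALSE)
  expect_equal(unname(lme4::fixef(m3)[["env"]]), row$standardized,
               tolerance = 1e-6)
})

test_that("the season model recovers injected seasonal structure", {
  set.seed(45)
  b <- mk_psem_steps(300, seed = 46, season = "breeding")
  nb <- mk_psem_steps(300, seed = 47, season = "non-breeding")
  # no true seasonal difference -> effects near zero
  fit0 <- fit_season_model(rbind(b, nb))
  row0 <- fit0$coef_vedba[fit0$coef_vedba$term == "season_breeding", ]
  expect_true(row0$lower <= 0 && row0$upper >= 0)

  # inject: breeding steps 2x longer, temperature offset +6
  b2 <- b; b2$sl <- b2$sl * 2
  b2$mean_temperature <- b2$mean_temperature + 6
  fit1 <- fit_season_model(rbind(b2, nb))
  expect_gt(fit1$decomposition$total, 0)
  temp_eff <- fit1$coef_temp$estimate[fit1$coef_temp$term == "season_breeding"]
  expect_lt(abs(temp_eff - 6) / 6, 0.10)
})
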