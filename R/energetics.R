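# Piecewise path models linking per-step environment, temperature, step
# length and mean VeDBA; relevant-range standardised coefficients; direct/
# indirect/total effect decomposition via partial correlations.

#' Along-path environmental summaries for observed steps
#'
#' Samples the straight segment from step start to step end at intervals of
#' half the habitat cell size (both endpoints included) and summarises the
#' landscape at the sample points: per-class habitat fractions (summing to 1
#' over all classes including water), median TRI, and mean distances from
#' disturbance and from rocky habitat.
#'
#' @param steps observed-step tibble.
#' @param landscape a `quoll_landscape`.
#' @return `steps` with added columns `path_prop_<class>` for each habitat
#'   class, `path_median_tri`, `path_mean_dist_disturbance`,
#'   `path_mean_dist_rocky`.
#' @export
step_env_covariates <- function(steps, landscape) {
  cs <- landscape$habitat$cell_size
  n_steps <- nrow(steps)
  m <- pmax(2L, ceiling(steps$sl / (cs / 2)) + 1L)
  step_idx <- rep.int(seq_len(n_steps), m)
  frac <- unlist(lapply(m, function(k) seq(0, 1, length.out = k)),
                 use.names = FALSE)
  px <- steps$start_x[step_idx] +
    frac * (steps$end_x[step_idx] - steps$start_x[step_idx])
  py <- steps$start_y[step_idx] +
    frac * (steps$end_y[step_idx] - steps$start_y[step_idx])
  z <- landscape_lookup(landscape, px, py)
  cnt <- as.vector(rowsum(rep(1, length(step_idx)), step_idx))
  for (nm in names(habitat_codes)) {
    hit <- as.numeric(!is.na(z$habitat) & z$habitat == habitat_codes[[nm]])
    steps[[paste0("path_prop_", nm)]] <-
      as.vector(rowsum(hit, step_idx)) / cnt
  }
  steps$path_median_tri <- unname(vapply(split(z$tri, step_idx),
                                         stats::median, numeric(1),
                                         na.rm = TRUE))
  steps$path_mean_dist_disturbance <-
    as.vector(rowsum(z$dist_disturbance, step_idx)) / cnt
  steps$path_mean_dist_rocky <-
    as.vector(rowsum(z$dist_rocky, step_idx)) / cnt
  steps
}

# conditional R2 = (var_fixed + var_random) / (var_fixed + var_random + var_resid)
#' @keywords internal
conditional_r2 <- function(fit) {
  vf <- stats::var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vcr <- as.data.frame(lme4::VarCorr(fit))
  vr <- sum(vcr$vcov[vcr$grp != "Residual"])
  ve <- vcr$vcov[vcr$grp == "Residual"]
  (vf + vr) / (vf + vr + ve)
}

# Wald coefficient table for an lmer fit
#' @keywords internal
lmm_coef_table <- function(fit) {
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- co / se
  tibble::tibble(term = names(co), estimate = unname(co), se = unname(se),
                 lower = unname(co - 1.96 * se),
                 upper = unname(co + 1.96 * se),
                 p = unname(2 * stats::pnorm(-abs(z))))
}

#' Fit the two-equation path model for one environmental variable
#'
#' Equation 1: step length ~ environment + mean temperature; equation 2:
#' mean VeDBA ~ environment + mean temperature + step length; both with a
#' random intercept per individual, fitted by maximum likelihood on the
#' identical complete-case observed-step subset. Conditional R^2 uses the
#' fixed-predictor variance plus random-intercept variance over total
#' variance.
#'
#' @param steps observed steps with `sl`, `mean_vedba`, `mean_temperature`
#'   and the environmental columns (see [step_env_covariates()]).
#' @param env_variable column name of the environmental variable.
#' @return object of class `path_model_fit`: `env_variable`, `m_sl`,
#'   `m_vedba` (lmer fits), `coef_sl`, `coef_vedba` (Wald tables), `r2c_sl`,
#'   `r2c_vedba`, `n`.
#' @export
fit_path_model <- function(steps, env_variable) {
  d <- data.frame(env = steps[[env_variable]], sl = steps$sl,
                  vedba = steps$mean_vedba, temp = steps$mean_temperature,
                  individual_id = factor(steps$individual_id))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10) stop("too few complete-case steps")
  if (stats::sd(d$env) == 0)
    stop("environmental variable '", env_variable,
         "' is constant across steps; unidentifiable")
  m_sl <- lme4::lmer(sl ~ env + temp + (1 | individual_id), data = d,
                     REML = FALSE)
  m_vedba <- lme4::lmer(vedba ~ env + temp + sl + (1 | individual_id),
                        data = d, REML = FALSE)
  structure(list(env_variable = env_variable, m_sl = m_sl, m_vedba = m_vedba,
                 coef_sl = lmm_coef_table(m_sl),
                 coef_vedba = lmm_coef_table(m_vedba),
                 r2c_sl = conditional_r2(m_sl),
                 r2c_vedba = conditional_r2(m_vedba),
                 n = nrow(d), data = d),
            class = "path_model_fit")
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat(sprintf("<path_model_fit %s> n = %d complete-case steps\n",
              x$env_variable, x$n))
  cat(sprintf("  step length:  env %.4g (p %.3g), temp %.4g; R2c %.3f\n",
              x$coef_sl$estimate[2], x$coef_sl$p[2], x$coef_sl$estimate[3],
              x$r2c_sl))
  cat(sprintf("  mean VeDBA:   env %.4g (p %.3g), temp %.4g, sl %.4g; R2c %.3f\n",
              x$coef_vedba$estimate[2], x$coef_vedba$p[2],
              x$coef_vedba$estimate[3], x$coef_vedba$estimate[4],
              x$r2c_vedba))
  invisible(x)
}

#' Partial correlation by residualisation
#'
#' Pearson correlation of the residuals from ordinary least-squares
#' regressions of `a` and `b` on the control variable(s). Equals the
#' closed-form (r_ab - r_ac r_bc) / sqrt((1 - r_ac^2)(1 - r_bc^2)) for a
#' single control.
#'
#' @param a,b numeric vectors.
#' @param control numeric vector, matrix or data frame of controls.
#' @return the partial correlation in [-1, 1].
#' @export
partial_correlation <- function(a, b, control) {
  cm <- as.matrix(control)
  ra <- stats::lm.fit(cbind(1, cm), a)$residuals
  rb <- stats::lm.fit(cbind(1, cm), b)$residuals
  stats::cor(ra, rb)
}

#' Direct/indirect/total effect decomposition on mean VeDBA
#'
#' Direct effect: partial correlation between the environmental variable and
#' mean VeDBA controlling for step length. Indirect (step-length-mediated)
#' effect: partial correlation between step length and mean VeDBA
#' controlling for the environmental variable. Total effect Te is their sum.
#' Computed on pooled complete-case observations; set
#' `residualize_individuals = TRUE` to remove individual means first.
#'
#' @param steps observed steps with `sl`, `mean_vedba` and the environmental
#'   column.
#' @param env_variable environmental column name.
#' @param residualize_individuals subtract per-individual means before
#'   correlating (off by default; the pooled variant is the primary output).
#' @return object of class `effect_decomposition`: `direct`, `indirect`,
#'   `total`, `n`.
#' @export
total_effect <- function(steps, env_variable,
                         residualize_individuals = FALSE) {
  d <- data.frame(env = steps[[env_variable]], sl = steps$sl,
                  vedba = steps$mean_vedba,
                  individual_id = steps$individual_id)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (residualize_individuals) {
    for (v in c("env", "sl", "vedba"))
      d[[v]] <- d[[v]] - stats::ave(d[[v]], d$individual_id)
  }
  direct <- partial_correlation(d$env, d$vedba, d$sl)
  indirect <- partial_correlation(d$sl, d$vedba, d$env)
  structure(list(env_variable = env_variable, direct = direct,
                 indirect = indirect, total = direct + indirect,
                 n = nrow(d)),
            class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cat(sprintf("<effect_decomposition %s> direct %.3f + indirect %.3f = total %.3f (n = %d)\n",
              x$env_variable, x$direct, x$indirect, x$total, x$n))
  invisible(x)
}

#' Relevant-range standardised coefficients
#'
#' Each raw coefficient beta is scaled by the observed range (max - min) of
#' its predictor over the observed range of the response:
#' standardised = beta * range(x) / range(y). Rescaling a predictor by any
#' positive constant leaves the standardised value unchanged.
#'
#' @param fit a [path_model_fit()] (both equations are standardised) or a
#'   single lmer fit.
#' @return tibble: `equation`, `term`, `estimate`, `range_x`, `range_y`,
#'   `standardized`.
#' @export
relevant_range <- function(fit) {
  std_one <- function(m, eq) {
    mf <- stats::model.frame(m)
    yr <- diff(range(mf[[1]]))
    tab <- lmm_coef_table(m)
    tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
    xr <- vapply(tab$term, function(tm) diff(range(mf[[tm]])), numeric(1))
    tibble::tibble(equation = eq, term = tab$term, estimate = tab$estimate,
                   range_x = unname(xr), range_y = yr,
                   standardized = tab$estimate * unname(xr) / yr,
                   p = tab$p)
  }
  if (inherits(fit, "path_model_fit"))
    rbind(std_one(fit$m_sl, "step_length"), std_one(fit$m_vedba, "mean_vedba"))
  else std_one(fit, "model")
}

#' Season path model
#'
#' A single piecewise model with season (breeding = 1) as an exogenous
#' predictor of mean temperature, step length and mean VeDBA:
#' temperature ~ season; step length ~ season + temperature;
#' VeDBA ~ season + temperature + step length (all with a random intercept
#' per individual, ML). The total effect of season on mean VeDBA is
#' decomposed as in [total_effect()].
#'
#' @param steps observed steps spanning both seasons with `season`, `sl`,
#'   `mean_vedba`, `mean_temperature`.
#' @return object of class `season_model_fit`: `m_temp`, `m_sl`, `m_vedba`,
#'   coefficient tables, conditional R^2 values, and `decomposition`.
#' @export
fit_season_model <- function(steps) {
  d <- data.frame(season_breeding = as.numeric(steps$season == "breeding"),
                  sl = steps$sl, vedba = steps$mean_vedba,
                  temp = steps$mean_temperature,
                  individual_id = factor(steps$individual_id))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (length(unique(d$season_breeding)) < 2)
    warning("only one season present; season effects are unidentifiable")
  m_temp <- lme4::lmer(temp ~ season_breeding + (1 | individual_id), data = d,
                       REML = FALSE)
  m_sl <- lme4::lmer(sl ~ season_breeding + temp + (1 | individual_id),
                     data = d, REML = FALSE)
  m_vedba <- lme4::lmer(vedba ~ season_breeding + temp + sl +
                          (1 | individual_id), data = d, REML = FALSE)
  direct <- partial_correlation(d$season_breeding, d$vedba, d$sl)
  indirect <- partial_correlation(d$sl, d$vedba, d$season_breeding)
  structure(list(m_temp = m_temp, m_sl = m_sl, m_vedba = m_vedba,
                 coef_temp = lmm_coef_table(m_temp),
                 coef_sl = lmm_coef_table(m_sl),
                 coef_vedba = lmm_coef_table(m_vedba),
                 r2c_temp = conditional_r2(m_temp),
                 r2c_sl = conditional_r2(m_sl),
                 r2c_vedba = conditional_r2(m_vedba),
                 decomposition = structure(
                   list(env_variable = "season_breeding", direct = direct,
                        indirect = indirect, total = direct + indirect,
                        n = nrow(d)),
                   class = "effect_decomposition"),
                 n = nrow(d)),
            class = "season_model_fit")
}

#' @export
print.season_model_fit <- function(x, ...) {
  cat(sprintf("<season_model_fit> n = %d steps\n", x$n))
  cat(sprintf("  season -> temperature %.3g; -> step length %.3g; -> VeDBA %.3g\n",
              x$coef_temp$estimate[2], x$coef_sl$estimate[2],
              x$coef_vedba$estimate[2]))
  print(x$decomposition)
  invisible(x)
}
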