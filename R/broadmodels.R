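# Observed-vs-available comparisons of range summaries: zero-inflated beta
# mixed regressions for habitat proportions, Gaussian mixed models for
# continuous summaries; both by maximum likelihood with Wald 95% CIs and a
# random intercept per individual.

range_type_factor <- function(x) factor(x, levels = c("available", "observed"))

#' Zero-inflated beta mixed regression for a habitat proportion
#'
#' Response: proportion of `habitat_type` within each movement range;
#' predictor: range type (observed vs available, available as reference);
#' random intercept per individual on the beta mean submodel; the
#' zero-inflation probability has its own logit model varying by range type.
#' Fitted by maximum likelihood (glmmTMB; Laplace approximation of the
#' random-intercept integral). Exact 1s are squeezed by
#' y' = (y (n-1) + 0.5) / n before fitting.
#'
#' @param summaries row-bound [summarize_range()] tibble (needs
#'   `individual_id`, `range_type`, `prop_<habitat_type>`).
#' @param habitat_type one of `"spinifex"`, `"riparian"`, `"rocky"`,
#'   `"pits"`, `"disturbed"`.
#' @return object of class `zibeta_fit`: `coef` (logit-scale intercept and
#'   observed-vs-available effect), `se`, `ci` (95% Wald), `phi` (precision),
#'   `zi_prob` (zero probability per range type), `sigma_u2`, `logLik`; or a
#'   singular-fit report (`singular = TRUE`, with `message`) when the model
#'   is unidentifiable (e.g. an all-zero response).
#' @export
fit_zibeta_mixed <- function(summaries, habitat_type) {
  col <- paste0("prop_", habitat_type)
  if (!col %in% names(summaries)) stop("no column ", col, " in summaries")
  d <- data.frame(y = summaries[[col]],
                  range_type = range_type_factor(summaries$range_type),
                  individual_id = factor(summaries$individual_id))
  d <- d[!is.na(d$y), , drop = FALSE]
  if (any(d$y < 0 | d$y > 1)) stop("proportions must lie in [0, 1]")
  n <- nrow(d)
  d$y[d$y == 1] <- (1 * (n - 1) + 0.5) / n
  fit <- tryCatch(
    suppressWarnings(
      glmmTMB::glmmTMB(y ~ range_type + (1 | individual_id),
                       ziformula = ~range_type,
                       family = glmmTMB::beta_family(), data = d,
                       control = glmmTMB::glmmTMBControl(
                         optCtrl = list(iter.max = 500, eval.max = 500)))),
    error = function(e) e)
  bad <- inherits(fit, "condition")
  if (!bad) {
    co_chk <- glmmTMB::fixef(fit)$cond
    se_chk <- tryCatch(sqrt(diag(as.matrix(stats::vcov(fit)$cond))),
                       error = function(e) NA_real_)
    bad <- any(is.na(co_chk)) || any(!is.finite(se_chk))
  }
  if (bad)
    return(structure(list(habitat_type = habitat_type, singular = TRUE,
                          message = if (inherits(fit, "condition"))
                            conditionMessage(fit) else
                              "unidentifiable mean model (degenerate response)"),
                     class = "zibeta_fit"))
  co <- glmmTMB::fixef(fit)$cond
  vc <- as.matrix(stats::vcov(fit)$cond)
  se <- sqrt(diag(vc))
  ci <- cbind(lower = co - 1.96 * se, upper = co + 1.96 * se)
  zi <- glmmTMB::fixef(fit)$zi
  zi_prob <- c(available = stats::plogis(zi[[1]]),
               observed = stats::plogis(zi[[1]] + zi[[2]]))
  vcr <- glmmTMB::VarCorr(fit)$cond
  sigma_u2 <- if (length(vcr) > 0) as.numeric(vcr$individual_id[1, 1]) else 0
  structure(list(habitat_type = habitat_type, singular = FALSE,
                 coef = c(intercept = unname(co[1]), effect = unname(co[2])),
                 se = c(intercept = unname(se[1]), effect = unname(se[2])),
                 ci = ci, phi = stats::sigma(fit), zi_prob = zi_prob,
                 sigma_u2 = sigma_u2, logLik = as.numeric(stats::logLik(fit)),
                 model = fit),
            class = "zibeta_fit")
}

#' @export
print.zibeta_fit <- function(x, ...) {
  if (isTRUE(x$singular)) {
    cat("<zibeta_fit ", x$habitat_type, "> singular fit: ", x$message, "\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf("<zibeta_fit %s> effect (observed vs available, logit) %.3f [%.3f, %.3f], phi %.2f\n",
              x$habitat_type, x$coef[["effect"]], x$ci[2, 1], x$ci[2, 2],
              x$phi))
  cat(sprintf("  zero-inflation: available %.3f, observed %.3f; sigma_u^2 %.3f\n",
              x$zi_prob[["available"]], x$zi_prob[["observed"]], x$sigma_u2))
  invisible(x)
}

#' Gaussian mixed model for a continuous range summary
#'
#' Response: the environmental variable (median TRI, mean distance from
#' disturbance or from rocky habitat); predictor: range type; random
#' intercept per individual; maximum likelihood with Wald 95% CIs.
#'
#' @param summaries row-bound [summarize_range()] tibble.
#' @param variable column name of the response.
#' @return object of class `gaussian_glmm_fit`: `coef`, `se`, `ci`,
#'   `sigma_u2`, `sigma_e2`, `logLik`, `model`.
#' @export
fit_gaussian_glmm <- function(summaries, variable) {
  if (!variable %in% names(summaries)) stop("no column ", variable)
  d <- data.frame(y = summaries[[variable]],
                  range_type = range_type_factor(summaries$range_type),
                  individual_id = factor(summaries$individual_id))
  fit <- lme4::lmer(y ~ range_type + (1 | individual_id), data = d,
                    REML = FALSE)
  co <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(vc))
  ci <- cbind(lower = co - 1.96 * se, upper = co + 1.96 * se)
  vcr <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vcr$vcov[vcr$grp == "individual_id"]
  sigma_e2 <- vcr$vcov[vcr$grp == "Residual"]
  structure(list(variable = variable,
                 coef = c(intercept = unname(co[1]), effect = unname(co[2])),
                 se = c(intercept = unname(se[1]), effect = unname(se[2])),
                 ci = ci, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 logLik = as.numeric(stats::logLik(fit)), model = fit),
            class = "gaussian_glmm_fit")
}

#' @export
print.gaussian_glmm_fit <- function(x, ...) {
  cat(sprintf("<gaussian_glmm_fit %s> effect (observed vs available) %.3f [%.3f, %.3f]\n",
              x$variable, x$coef[["effect"]], x$ci[2, 1], x$ci[2, 2]))
  cat(sprintf("  sigma_u^2 %.4g, sigma_e^2 %.4g\n", x$sigma_u2, x$sigma_e2))
  invisible(x)
}

#' Classify an effect by its 95% confidence interval
#'
#' `positive` / `negative` when the interval excludes zero, `ns` otherwise.
#'
#' @param fit a `zibeta_fit`, `gaussian_glmm_fit`, or a length-2 numeric
#'   interval `c(lower, upper)` for the effect.
#' @return one of `"positive"`, `"negative"`, `"ns"`.
#' @export
significance_from_ci <- function(fit) {
  ci <- if (is.numeric(fit) && length(fit) == 2) fit
  else if (!is.null(fit$ci)) fit$ci["range_typeobserved", ]
  else stop("cannot extract a CI from this object")
  if (ci[1] > 0) "positive" else if (ci[2] < 0) "negative" else "ns"
}

#' Fit all broad-scale observed-vs-available models
#'
#' One zero-inflated beta mixed model per analysed habitat type (water
#' excluded) and one Gaussian mixed model per continuous summary.
#'
#' @param summaries row-bound [summarize_range()] tibble over all observed
#'   and available ranges.
#' @return tibble: `variable`, `model`, `effect`, `se`, `lower`, `upper`,
#'   `classification`.
#' @export
broad_scale_models <- function(summaries) {
  habs <- c("spinifex", "riparian", "rocky", "pits", "disturbed")
  rows <- list()
  for (h in habs) {
    f <- fit_zibeta_mixed(summaries, h)
    rows[[length(rows) + 1]] <- if (isTRUE(f$singular))
      tibble::tibble(variable = paste0("prop_", h), model = "zibeta",
                     effect = NA_real_, se = NA_real_, lower = NA_real_,
                     upper = NA_real_, classification = "singular")
    else tibble::tibble(variable = paste0("prop_", h), model = "zibeta",
                        effect = f$coef[["effect"]], se = f$se[["effect"]],
                        lower = f$ci[2, 1], upper = f$ci[2, 2],
                        classification = significance_from_ci(f$ci[2, ]))
  }
  cont <- intersect(c("median_tri", "mean_dist_disturbance",
                      "mean_dist_rocky", "mean_ndvi"), names(summaries))
  for (v in cont) {
    f <- fit_gaussian_glmm(summaries, v)
    rows[[length(rows) + 1]] <-
      tibble::tibble(variable = v, model = "gaussian_glmm",
                     effect = f$coef[["effect"]], se = f$se[["effect"]],
                     lower = f$ci[2, 1], upper = f$ci[2, 2],
                     classification = significance_from_ci(f$ci[2, ]))
  }
  do.call(rbind, rows)
}
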