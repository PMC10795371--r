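# Integrated step-selection: tentative movement kernel, available-step
# generation, stratified conditional-logistic estimation (Newton-Raphson
# with analytic gradient/Hessian), AICc model selection, kernel updating and
# relative selection strength.

#' Fit the tentative (selection-free) movement kernel
#'
#' Gamma step-length parameters by maximum likelihood and the von Mises
#' turning-angle concentration by solving I1(kappa)/I0(kappa) = mean(cos ta)
#' with the mean direction fixed at 0 (negative mean cosines give kappa = 0;
#' near-degenerate angle sets cap kappa at 500 with a warning).
#'
#' @param steps observed-step tibble (uses `sl` and `ta`; NA turning angles
#'   from burst-start steps are excluded from the angle fit).
#' @return object of class `tentative_kernel`: `shape`, `scale` (m), `kappa`.
#' @export
fit_tentative_kernel <- function(steps) {
  sl <- steps$sl[steps$case == "observed" & steps$sl > 0]
  if (length(sl) < 10) stop("need at least 10 observed steps")
  gf <- fitdistrplus::fitdist(sl, "gamma", method = "mle",
                              lower = c(1e-8, 1e-12))
  shape <- unname(gf$estimate[["shape"]])
  scale <- 1 / unname(gf$estimate[["rate"]])
  ta <- steps$ta[steps$case == "observed"]
  mc <- mean(cos(ta), na.rm = TRUE)
  kappa <- solve_vm_kappa(mc)
  structure(list(shape = shape, scale = scale, kappa = kappa),
            class = "tentative_kernel")
}

# small-sample-corrected AIC with n = number of strata
#' @keywords internal
aicc_value <- function(logLik, K, n) {
  -2 * logLik + 2 * K +
    if (n - K - 1 > 0) 2 * K * (K + 1) / (n - K - 1) else Inf
}

# A1(kappa) = I1/I0 inverse; mc <= 0 -> 0; capped at 500
#' @keywords internal
solve_vm_kappa <- function(mc, cap = 500) {
  if (is.na(mc) || mc <= 0) return(0)
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  if (mc >= a1(cap)) {
    warning("turning angles nearly degenerate; kappa capped at ", cap)
    return(cap)
  }
  stats::uniroot(function(k) a1(k) - mc, c(1e-10, cap), tol = 1e-10)$root
}

#' @export
print.tentative_kernel <- function(x, ...) {
  cat(sprintf("<tentative_kernel> gamma(shape %.3f, scale %.1f m); von Mises kappa %.3f\n",
              x$shape, x$scale, x$kappa))
  invisible(x)
}

#' Generate available steps
#'
#' For each observed step, draws `n` available steps sharing its start point
#' and stratum: lengths from the tentative gamma, turns from the tentative
#' von Mises about the previous observed heading (uniform random previous
#' heading at burst starts, mirroring the estimator's handling of first
#' steps).
#'
#' @param steps observed-step tibble (time-sorted within bursts).
#' @param kernel a [fit_tentative_kernel()] result.
#' @param n available steps per stratum (default 5).
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return tibble of available steps with the same core columns as `steps`.
#' @export
sample_available_steps <- function(steps, kernel, n = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- steps[steps$case == "observed", , drop = FALSE]
  S <- nrow(obs)
  heading <- atan2(obs$end_y - obs$start_y, obs$end_x - obs$start_x)
  prev <- rep(NA_real_, S)
  same_burst <- c(FALSE, obs$individual_id[-1] == obs$individual_id[-S] &
                    obs$burst_id[-1] == obs$burst_id[-S])
  prev[same_burst] <- heading[which(same_burst) - 1]
  prev[is.na(prev)] <- stats::runif(sum(is.na(prev)), -pi, pi)
  idx <- rep(seq_len(S), each = n)
  turns <- rvonmises(S * n, 0, kernel$kappa)
  lens <- stats::rgamma(S * n, shape = kernel$shape, scale = kernel$scale)
  heads <- prev[idx] + turns
  avail <- obs[idx, , drop = FALSE]
  avail$case <- "available"
  avail$end_x <- avail$start_x + lens * cos(heads)
  avail$end_y <- avail$start_y + lens * sin(heads)
  avail$sl <- lens
  avail$ta <- turns
  avail$log10_sl <- log10(pmax(lens, .Machine$double.eps))
  avail$cos_ta <- cos(turns)
  avail
}

#' Attach end-of-step landscape covariates
#'
#' Looks up every landscape layer at the step end point and flags steps that
#' end off-raster or on water (`flag_drop`); flagged steps are excluded from
#' conditional-logistic fitting. The habitat factor uses rocky as its
#' reference level.
#'
#' @param steps step tibble (observed and/or available).
#' @param landscape a `quoll_landscape`.
#' @return `steps` with `habitat`, `habitat_class`, `tri`,
#'   `dist_disturbance`, `dist_rocky` (and `ndvi` if mapped), plus
#'   `flag_drop`.
#' @export
attach_covariates <- function(steps, landscape) {
  z <- landscape_lookup(landscape, steps$end_x, steps$end_y)
  steps$habitat_code <- z$habitat
  steps$habitat_class <- z$habitat_class
  steps$habitat <- factor(z$habitat_class,
                          levels = c("rocky", "spinifex", "riparian",
                                     "pits", "disturbed"))
  steps$tri <- z$tri
  steps$dist_disturbance <- z$dist_disturbance
  steps$dist_rocky <- z$dist_rocky
  if (!is.null(z$ndvi)) steps$ndvi <- z$ndvi
  steps$flag_drop <- is.na(z$habitat) | z$habitat == habitat_codes[["water"]]
  steps
}

# Drop flagged/incomplete rows stratum-wise: the whole stratum goes when its
# observed step is flagged; otherwise only flagged available rows go.
# Strata left without an observed case, without available cases, or without
# any covariate variation are dropped and counted.
#' @keywords internal
prepare_clogit_data <- function(steps, rhs_vars) {
  flagged <- if ("flag_drop" %in% names(steps)) steps$flag_drop else
    rep(FALSE, nrow(steps))
  incomplete <- rowSums(is.na(as.data.frame(steps)[, rhs_vars, drop = FALSE])) > 0
  bad <- flagged | incomplete
  obs_bad <- unique(steps$stratum_id[bad & steps$case == "observed"])
  keep <- !bad & !(steps$stratum_id %in% obs_bad)
  d <- steps[keep, , drop = FALSE]
  tab <- table(d$stratum_id, factor(d$case, levels = c("available", "observed")))
  ok_strata <- rownames(tab)[tab[, "observed"] == 1 & tab[, "available"] >= 1]
  d <- d[d$stratum_id %in% as.numeric(ok_strata), , drop = FALSE]
  n_dropped <- length(unique(steps$stratum_id)) -
    length(unique(d$stratum_id))
  list(data = d, n_dropped_strata = n_dropped)
}

#' Stratified conditional logistic regression (iSSF likelihood)
#'
#' Maximises the stratified partial likelihood
#' prod_s exp(beta' z_obs) / sum_j exp(beta' z_j) by Newton-Raphson with
#' analytic gradient and Hessian; convergence at max |score| < 1e-8;
#' covariance is the inverse observed information. Strata whose endpoints
#' carry no covariate contrast contribute zero information and are dropped
#' with a count. Complete separation (a covariate that perfectly ranks the
#' observed steps) raises an error naming the covariate: |beta| > 50 at any
#' iterate, or |beta| > 15 at convergence.
#'
#' @param steps step tibble with one observed and >= 1 available row per
#'   stratum and end-of-step covariates attached.
#' @param formula one-sided covariate formula, e.g.
#'   `~ habitat + tri + log10_sl + cos_ta`.
#' @return object of class `clogit_fit`: `coef`, `vcov`, `se`, `logLik`,
#'   `n_strata`, `K`, `AICc`, `n_dropped_strata`, `converged`.
#' @export
fit_clogit <- function(steps, formula) {
  rhs_vars <- all.vars(formula)
  prep <- prepare_clogit_data(steps, rhs_vars)
  d <- prep$data
  if (nrow(d) == 0) stop("no usable strata")
  X <- stats::model.matrix(formula, data = d)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  strata <- as.integer(factor(d$stratum_id))
  y <- d$case == "observed"
  S <- max(strata)
  K <- ncol(X)
  # drop strata with no within-stratum variation in any covariate
  if (K > 0) {
    rng <- rowsum(X, strata) / as.vector(table(strata))
    centred <- X - rng[strata, , drop = FALSE]
    info <- rowsum(centred^2, strata)
    dead <- rowSums(info) < 1e-12
    if (any(dead)) {
      keep <- !(strata %in% which(dead))
      d <- d[keep, , drop = FALSE]
      X <- X[keep, , drop = FALSE]
      y <- y[keep]
      strata <- as.integer(factor(strata[keep]))
      S <- max(strata)
      prep$n_dropped_strata <- prep$n_dropped_strata + sum(dead)
    }
  }
  beta <- rep(0, K)
  converged <- K == 0
  H <- matrix(0, K, K)
  if (K > 0) for (iter in 1:50) {
    eta <- as.vector(X %*% beta)
    w <- exp(eta)
    denom <- as.vector(rowsum(w, strata))
    p <- w / denom[strata]
    grad <- colSums(X[y, , drop = FALSE]) - colSums(X * p)
    M <- rowsum(X * p, strata)
    H <- -(crossprod(X, X * p) - crossprod(M))
    if (max(abs(grad)) < 1e-8) { converged <- TRUE; break }
    step_dir <- tryCatch(solve(-H, grad), error = function(e)
      stop("singular information matrix; check covariates for collinearity"))
    beta <- beta + step_dir
    if (any(abs(beta) > 50))
      stop("separation detected: coefficient for ",
           colnames(X)[which.max(abs(beta))], " diverged")
  }
  if (K > 0 && any(abs(beta) > 15))
    stop("separation detected: coefficient for ",
         colnames(X)[which.max(abs(beta))],
         " diverged (observed steps perfectly ranked)")
  eta <- as.vector(X %*% beta)
  denom <- as.vector(rowsum(exp(eta), strata))
  logLik <- sum(eta[y]) - sum(log(denom))
  vcov <- if (K > 0) solve(-H) else matrix(0, 0, 0)
  aicc <- aicc_value(logLik, K, S)
  structure(list(coef = stats::setNames(beta, colnames(X)), vcov = vcov,
                 se = stats::setNames(sqrt(diag(vcov)), colnames(X)),
                 logLik = logLik, n_strata = S, K = K, AICc = aicc,
                 n_dropped_strata = prep$n_dropped_strata,
                 converged = converged, formula = formula),
            class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("<clogit_fit> %d strata, K = %d, lnL = %.2f, AICc = %.2f%s\n",
              x$n_strata, x$K, x$logLik, x$AICc,
              if (x$converged) "" else " (NOT converged)"))
  if (x$K > 0) {
    tab <- cbind(beta = x$coef, se = x$se,
                 lower = x$coef - 1.96 * x$se, upper = x$coef + 1.96 * x$se)
    print(round(tab, 4))
  }
  invisible(x)
}

#' AICc model selection over candidate formulas
#'
#' Fits each candidate and ranks by AICc; models with dAICc < 2 are flagged
#' as having substantial support. A `~ 1` candidate is treated as the null
#' model (no covariates, K = 0).
#'
#' @param steps step tibble with covariates attached.
#' @param formulas named list of one-sided formulas.
#' @return tibble ranked by AICc: `model`, `K`, `logLik`, `AICc`, `dAICc`,
#'   `support`.
#' @export
select_models <- function(steps, formulas) {
  rows <- lapply(names(formulas), function(nm) {
    f <- formulas[[nm]]
    if (length(all.vars(f)) == 0) {
      # null model: uniform choice within each stratum
      prep <- prepare_clogit_data(steps, character(0))
      sizes <- table(prep$data$stratum_id)
      ll <- -sum(log(sizes))
      tibble::tibble(model = nm, K = 0L, logLik = ll,
                     AICc = -2 * ll)
    } else {
      fit <- fit_clogit(steps, f)
      tibble::tibble(model = nm, K = fit$K, logLik = fit$logLik,
                     AICc = fit$AICc)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$AICc), , drop = FALSE]
  out$dAICc <- out$AICc - out$AICc[1]
  out$support <- out$dAICc < 2
  out
}

#' Default candidate model menu
#'
#' Global, habitat-only, terrain-only, movement-only and null formulas; the
#' non-breeding global variant adds age interactions with the movement
#' covariates.
#'
#' @param age_interaction add `age:log10_sl` and `age:cos_ta` to the global
#'   model (used for the non-breeding season).
#' @return named list of one-sided formulas.
#' @export
candidate_formulas <- function(age_interaction = FALSE) {
  global <- if (age_interaction)
    ~ habitat + tri + dist_disturbance + dist_rocky + log10_sl + cos_ta +
      age:log10_sl + age:cos_ta
  else ~ habitat + tri + dist_disturbance + dist_rocky + log10_sl + cos_ta
  list(global = global,
       habitat_only = ~ habitat + log10_sl + cos_ta,
       terrain_only = ~ tri + dist_disturbance + dist_rocky + log10_sl + cos_ta,
       movement_only = ~ log10_sl + cos_ta,
       null = ~ 1)
}

#' Update the tentative kernel with fitted movement coefficients
#'
#' shape = shape0 + beta_log10(sl) / ln 10 (the model's log10 step-length
#' coefficient converted to natural log), kappa = kappa0 + beta_cos(ta);
#' the scale is unchanged because no linear step-length covariate is used.
#' The result is flagged invalid when shape <= 0 or kappa < 0.
#'
#' @param tentative a [fit_tentative_kernel()] result.
#' @param fit a [fit_clogit()] result.
#' @return object of class `updated_kernel`: `shape`, `scale`, `kappa`,
#'   `valid`.
#' @export
update_kernel <- function(tentative, fit) {
  b_sl <- if ("log10_sl" %in% names(fit$coef)) fit$coef[["log10_sl"]] else 0
  b_ta <- if ("cos_ta" %in% names(fit$coef)) fit$coef[["cos_ta"]] else 0
  shape <- tentative$shape + b_sl / log(10)
  kappa <- tentative$kappa + b_ta
  structure(list(shape = shape, scale = tentative$scale, kappa = kappa,
                 valid = shape > 0 && kappa >= 0),
            class = "updated_kernel")
}

#' Relative selection strength between two locations
#'
#' log-RSS = beta' (z(x1) - z(x2)) with a delta-method 95% CI; RSS and its
#' CI are the exponentials. Covariates absent from a location vector are
#' taken as 0, so habitat contrasts against the rocky reference are
#' expressed by the habitat dummy alone.
#'
#' @param fit a [fit_clogit()] result.
#' @param x1,x2 named numeric covariate vectors (names must be coefficient
#'   names of `fit`).
#' @return one-row tibble: `log_rss`, `se`, `rss`, `lower`, `upper`.
#' @export
log_rss <- function(fit, x1, x2) {
  nm <- names(fit$coef)
  z1 <- stats::setNames(rep(0, length(nm)), nm)
  z2 <- z1
  if (length(x1) > 0) {
    if (!all(names(x1) %in% nm)) stop("unknown covariate in x1")
    z1[names(x1)] <- x1
  }
  if (length(x2) > 0) {
    if (!all(names(x2) %in% nm)) stop("unknown covariate in x2")
    z2[names(x2)] <- x2
  }
  dz <- z1 - z2
  lr <- sum(fit$coef * dz)
  se <- sqrt(as.numeric(t(dz) %*% fit$vcov %*% dz))
  tibble::tibble(log_rss = lr, se = se, rss = exp(lr),
                 lower = exp(lr - 1.96 * se), upper = exp(lr + 1.96 * se))
}
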