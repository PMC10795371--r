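# High-level pipeline stages. Each stage reads/writes plain-text products
# and a JSON run manifest, and is callable directly or through run_cli().

write_manifest <- function(dir, subcommand, inputs, params) {
  jsonlite::write_json(
    list(subcommand = subcommand, inputs = inputs, params = params,
         package = "quollmove",
         version = as.character(utils::packageVersion("quollmove"))),
    file.path(dir, paste0(subcommand, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate a full synthetic study to disk
#'
#' Generates a landscape, nine habitat-selective tracks, degraded GPS fixes
#' and accelerometer streams, and writes `landscape/*.grid`, `fixes.csv`,
#' `accel.csv`, `individuals.csv` and `truth.json` (ground-truth parameters
#' and seeds) under `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; all stage seeds derive from it.
#' @param n_nights nights per individual.
#' @param n_rows,n_cols landscape dimensions (cells).
#' @param params a [movement_params()].
#' @param config a [quoll_config()].
#' @return `out_dir`, invisibly.
#' @export
stage_simulate <- function(out_dir, seed = 1L, n_nights = 20,
                           n_rows = 400, n_cols = 400,
                           params = movement_params(),
                           config = quoll_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  land <- generate_landscape(seed = seed, n_rows = n_rows, n_cols = n_cols)
  study <- simulate_study(land, params = params, config = config,
                          n_nights = n_nights, seed = seed + 1L)
  fixes <- degrade_gps(study$tracks, seed = seed + 2L)
  accel <- simulate_accelerometer(study$tracks, config = config,
                                  seed = seed + 3L)
  write_landscape(land, file.path(out_dir, "landscape"))
  write_fixes(fixes, file.path(out_dir, "fixes.csv"))
  write_accel(accel, file.path(out_dir, "accel.csv"))
  utils::write.csv(as.data.frame(study$individuals),
                   file.path(out_dir, "individuals.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(seed = seed, n_nights = n_nights,
         movement = list(shape = params$shape, scale = params$scale,
                         kappa = params$kappa, beta = as.list(params$beta))),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_manifest(out_dir, "simulate", list(), list(seed = seed,
                                                   n_nights = n_nights))
  invisible(out_dir)
}

#' Clean fixes from disk and write observed steps
#'
#' @param fixes_path fixes CSV (see [read_fixes()]).
#' @param out_dir output directory.
#' @param config a [quoll_config()].
#' @param exclusions_path optional CSV of exclusion windows
#'   (`individual_id`, `start`, `end` in ISO-8601 UTC).
#' @param individuals_path optional design CSV carrying `season`/`age`.
#' @return the [clean_fixes()] result, invisibly.
#' @export
stage_clean <- function(fixes_path, out_dir, config = quoll_config(),
                        exclusions_path = NULL, individuals_path = NULL) {
  if (!file.exists(fixes_path))
    stop("missing input: ", fixes_path,
         " (run the simulate stage or point --fixes at a fix table)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fixes <- read_fixes(fixes_path, config)
  windows <- NULL
  if (!is.null(exclusions_path)) {
    w <- utils::read.csv(exclusions_path)
    windows <- tibble::tibble(individual_id = as.character(w$individual_id),
                              start = parse_iso8601(w$start),
                              end = parse_iso8601(w$end))
  }
  individuals <- NULL
  if (!is.null(individuals_path) && file.exists(individuals_path))
    individuals <- utils::read.csv(individuals_path,
                                   colClasses = c(individual_id = "character"))
  cleaned <- clean_fixes(fixes, config, windows, individuals)
  write_steps(cleaned$steps, file.path(out_dir, "steps.csv"))
  write_fixes(cleaned$fixes[, setdiff(names(cleaned$fixes), "burst_id")],
              file.path(out_dir, "fixes_clean.csv"))
  jsonlite::write_json(cleaned$report,
                       file.path(out_dir, "cleaning_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "clean", list(fixes = fixes_path),
                 list(hdop_max = config$hdop_max, vmax = config$vmax,
                      tolerance = config$burst_tolerance))
  invisible(cleaned)
}

#' Attach mean VeDBA and temperature to observed steps on disk
#'
#' @param accel_path accelerometer CSV.
#' @param steps_path observed-steps CSV from [stage_clean()].
#' @param out_dir output directory (writes `steps_vedba.csv`).
#' @param config a [quoll_config()].
#' @return the augmented step tibble, invisibly.
#' @export
stage_vedba <- function(accel_path, steps_path, out_dir,
                        config = quoll_config()) {
  for (p in c(accel_path, steps_path))
    if (!file.exists(p))
      stop("missing input: ", p, " (run the simulate/clean stages first)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  accel <- read_accel(accel_path)
  steps <- read_steps(steps_path)
  vd <- compute_vedba(accel)
  steps <- aggregate_step_vedba(vd, steps, config)
  write_steps(steps, file.path(out_dir, "steps_vedba.csv"))
  write_manifest(out_dir, "vedba",
                 list(accel = accel_path, steps = steps_path), list())
  invisible(steps)
}

#' Movement ranges, availability regions and zonal summaries from disk
#'
#' Per individual: ad-hoc-bandwidth KDE movement range at the configured
#' isopleth, 100% MCP, availability region buffered by the radius of the
#' largest observed range minus the focal range radius, and the configured
#' number of random circular available ranges. Writes
#' `range_summaries.csv` (one row per observed/available range) and
#' `ranges.geojson` (MCPs and availability regions).
#'
#' @param fixes_path cleaned fixes CSV.
#' @param landscape_dir directory of `.grid` layers.
#' @param out_dir output directory.
#' @param seed RNG seed for available-range placement.
#' @param config a [quoll_config()].
#' @return the range-summaries tibble, invisibly.
#' @export
stage_ranges <- function(fixes_path, landscape_dir, out_dir, seed = 1L,
                         config = quoll_config()) {
  if (!file.exists(fixes_path))
    stop("missing input: ", fixes_path, " (run the clean stage first)")
  if (!dir.exists(landscape_dir))
    stop("missing input: ", landscape_dir, " (no landscape directory)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fixes <- read_fixes(fixes_path, config)
  land <- read_landscape(landscape_dir)
  ids <- unique(fixes$individual_id)
  ranges <- lapply(ids, function(id) {
    pts <- fixes[fixes$individual_id == id, c("x", "y")]
    movement_range(pts, config, individual_id = id)
  })
  r_max <- max(vapply(ranges, function(r) r$equal_area_radius, numeric(1)))
  set.seed(seed)
  all_rows <- list()
  polys <- list(); props <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    pts <- fixes[fixes$individual_id == id, c("x", "y")]
    obs <- ranges[[i]]
    all_rows[[length(all_rows) + 1]] <- summarize_range(obs, land)
    hull <- mcp(pts)
    region <- availability_region(hull, r_max, obs$equal_area_radius)
    avail <- sample_available_ranges(region, obs$area_m2,
                                     n = config$n_available_ranges,
                                     individual_id = id)
    for (a in avail)
      all_rows[[length(all_rows) + 1]] <- summarize_range(a, land)
    polys[[paste0("mcp_", id)]] <- hull$vertices
    props[[length(props) + 1]] <- list(individual_id = id, kind = "mcp",
                                       area_ha = hull$area_ha)
  }
  summaries <- do.call(rbind, all_rows)
  utils::write.csv(as.data.frame(summaries),
                   file.path(out_dir, "range_summaries.csv"),
                   row.names = FALSE, quote = FALSE)
  write_geojson(polys, file.path(out_dir, "ranges.geojson"), props)
  write_manifest(out_dir, "ranges", list(fixes = fixes_path,
                                         landscape = landscape_dir),
                 list(seed = seed, r_max = r_max,
                      isopleth = config$isopleth_level))
  invisible(summaries)
}

#' Broad-scale observed-vs-available models from disk
#'
#' @param summaries_path `range_summaries.csv` from [stage_ranges()].
#' @param out_dir output directory (writes `broad_models.csv`).
#' @return the model table, invisibly.
#' @export
stage_broadscale <- function(summaries_path, out_dir) {
  if (!file.exists(summaries_path))
    stop("missing input: ", summaries_path, " (run the ranges stage first)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summaries <- utils::read.csv(summaries_path,
                               colClasses = c(individual_id = "character"))
  tab <- broad_scale_models(summaries)
  utils::write.csv(as.data.frame(tab), file.path(out_dir, "broad_models.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "broadscale", list(summaries = summaries_path),
                 list())
  invisible(tab)
}

#' Integrated step-selection analysis from disk
#'
#' Per season: tentative kernel, available-step generation, AICc selection
#' over the candidate menu, the global fit, the updated kernel, and
#' unit-change relative selection strengths. Writes `clogit_fits.csv`,
#' `model_selection.csv` and `rss.csv`.
#'
#' @param steps_path observed-steps CSV (clean or vedba stage output).
#' @param landscape_dir landscape directory.
#' @param out_dir output directory.
#' @param season `"all"` or a specific season label.
#' @param seed RNG seed for available steps.
#' @param config a [quoll_config()].
#' @return list of per-season results, invisibly.
#' @export
stage_issf <- function(steps_path, landscape_dir, out_dir, season = "all",
                       seed = 1L, config = quoll_config()) {
  if (!file.exists(steps_path))
    stop("missing input: ", steps_path, " (run the clean stage first)")
  if (!dir.exists(landscape_dir))
    stop("missing input: ", landscape_dir, " (no landscape directory)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  steps <- read_steps(steps_path)
  land <- read_landscape(landscape_dir)
  seasons <- if (season == "all") {
    if ("season" %in% names(steps)) unique(steps$season) else "all"
  } else season
  fit_rows <- sel_rows <- rss_rows <- list()
  results <- list()
  for (s in seasons) {
    sub <- if (s == "all") steps else steps[steps$season == s, , drop = FALSE]
    kern <- fit_tentative_kernel(sub)
    avail <- sample_available_steps(sub, kern,
                                    n = config$n_available_steps,
                                    seed = seed + match(s, seasons))
    issf_data <- attach_covariates(rbind(sub, avail), land)
    use_age <- s == "non-breeding" && "age" %in% names(issf_data) &&
      length(unique(issf_data$age)) > 1
    menu <- candidate_formulas(age_interaction = use_age)
    sel <- select_models(issf_data, menu)
    fit <- fit_clogit(issf_data, menu$global)
    upd <- update_kernel(kern, fit)
    for (k in seq_along(fit$coef)) {
      nm <- names(fit$coef)[k]
      rss_rows[[length(rss_rows) + 1]] <- cbind(
        season = s, covariate = nm,
        log_rss(fit, stats::setNames(1, nm), stats::setNames(0, nm)))
    }
    fit_rows[[length(fit_rows) + 1]] <- tibble::tibble(
      season = s, term = names(fit$coef), estimate = unname(fit$coef),
      se = unname(fit$se), lower = unname(fit$coef - 1.96 * fit$se),
      upper = unname(fit$coef + 1.96 * fit$se))
    sel_rows[[length(sel_rows) + 1]] <- cbind(season = s, sel)
    results[[s]] <- list(kernel = kern, updated_kernel = upd, fit = fit,
                         selection = sel)
  }
  utils::write.csv(as.data.frame(do.call(rbind, fit_rows)),
                   file.path(out_dir, "clogit_fits.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(as.data.frame(do.call(rbind, sel_rows)),
                   file.path(out_dir, "model_selection.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(do.call(rbind, rss_rows)),
                   file.path(out_dir, "rss.csv"), row.names = FALSE,
                   quote = FALSE)
  write_manifest(out_dir, "issf", list(steps = steps_path,
                                       landscape = landscape_dir),
                 list(seed = seed, season = season,
                      n_available = config$n_available_steps))
  invisible(results)
}

#' Piecewise path models from disk
#'
#' One two-equation path model per environmental variable (the five
#' along-path habitat proportions, median TRI, and the two mean distances),
#' with relevant-range coefficients and the direct/indirect/total effect
#' decomposition; plus the season model when both seasons are present.
#' Writes `psem_fits.csv` and `season_model.csv`.
#'
#' @param steps_path `steps_vedba.csv` from [stage_vedba()].
#' @param landscape_dir landscape directory.
#' @param out_dir output directory.
#' @return list of fits, invisibly.
#' @export
stage_psem <- function(steps_path, landscape_dir, out_dir) {
  if (!file.exists(steps_path))
    stop("missing input: ", steps_path, " (run the vedba stage first)")
  if (!dir.exists(landscape_dir))
    stop("missing input: ", landscape_dir, " (no landscape directory)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  steps <- read_steps(steps_path)
  land <- read_landscape(landscape_dir)
  steps <- step_env_covariates(steps, land)
  env_vars <- c(paste0("path_prop_", c("spinifex", "riparian", "rocky",
                                       "pits", "disturbed")),
                "path_median_tri", "path_mean_dist_disturbance",
                "path_mean_dist_rocky")
  rows <- list(); fits <- list()
  for (v in env_vars) {
    fit <- tryCatch(fit_path_model(steps, v), error = function(e) e)
    if (inherits(fit, "condition")) next
    dec <- total_effect(steps, v)
    rr <- relevant_range(fit)
    rows[[length(rows) + 1]] <- tibble::tibble(
      env_variable = v,
      r2c_sl = fit$r2c_sl, r2c_vedba = fit$r2c_vedba,
      sl_env = fit$coef_sl$estimate[2], sl_env_p = fit$coef_sl$p[2],
      vedba_env = fit$coef_vedba$estimate[2],
      vedba_env_p = fit$coef_vedba$p[2],
      vedba_sl = fit$coef_vedba$estimate[4],
      std_sl_env = rr$standardized[rr$equation == "step_length" &
                                     rr$term == "env"],
      std_vedba_env = rr$standardized[rr$equation == "mean_vedba" &
                                        rr$term == "env"],
      direct = dec$direct, indirect = dec$indirect, total = dec$total,
      n = fit$n)
    fits[[v]] <- fit
  }
  psem_tab <- do.call(rbind, rows)
  utils::write.csv(as.data.frame(psem_tab),
                   file.path(out_dir, "psem_fits.csv"), row.names = FALSE,
                   quote = FALSE)
  season_fit <- NULL
  if ("season" %in% names(steps) && length(unique(steps$season)) > 1) {
    season_fit <- fit_season_model(steps)
    stab <- rbind(cbind(equation = "temperature", season_fit$coef_temp),
                  cbind(equation = "step_length", season_fit$coef_sl),
                  cbind(equation = "mean_vedba", season_fit$coef_vedba))
    stab$total_effect_season <- season_fit$decomposition$total
    utils::write.csv(as.data.frame(stab),
                     file.path(out_dir, "season_model.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  write_manifest(out_dir, "psem", list(steps = steps_path,
                                       landscape = landscape_dir), list())
  invisible(list(table = psem_tab, fits = fits, season = season_fit))
}
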