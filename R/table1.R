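# Per-individual tracking and body-condition records for the nine collared
# quolls, and the seasonal summary-statistics utility.

#' Tracking and body-condition records of the nine analysed quolls
#'
#' Per-individual values from the field deployment at the active manganese
#' mine: season, collar id, sex, age (years), number of GPS fixes after
#' cleaning, days with GPS locations, body weight (g), hindfoot length (mm),
#' tail-base circumference (mm), testes diameter (mm; NA for the female),
#' and 95%-isopleth movement-range area (ha).
#'
#' @return tibble with one row per individual.
#' @export
quoll_tracking <- function() {
  tibble::tibble(
    season = c(rep("breeding", 4), rep("non-breeding", 5)),
    individual_id = c("33421", "33427", "33411", "33425",
                      "33415", "33413", "33423", "33412", "33422"),
    sex = c("M", "M", "M", "M", "F", "M", "M", "M", "M"),
    age = c(1, 1, 1, 1, 2, 1, 2, 1, 2),
    fixes = c(274, 260, 227, 266, 99, 92, 226, 356, 158),
    days = c(22, 20, 20, 20, 17, 13, 25, 30, 21),
    weight_g = c(640, 540, 545, 640, 450, 855, 805, 760, 700),
    foot_length_mm = c(34.80, 37.90, 36.60, 38.20,
                       31.30, 37.50, 34.30, 38.20, 35.20),
    tail_circumference_mm = c(45, 55, 42, 50, 60, 69, 65, 71, 55),
    testes_diameter_mm = c(23.20, 24.50, 21.20, 24.00,
                           NA, 16.30, 14.90, 20.10, 21.60),
    movement_range_ha = c(6584.67, 6331.69, 3115.55, 8576.21,
                          157.87, 1169.05, 723.78, 85.99, 387.46))
}

#' Seasonal summary statistics over individuals
#'
#' Per-season mean and standard error (sd/sqrt(n), NA dropped) of every
#' numeric per-individual variable: age, fixes, tracking days, weight,
#' hindfoot length, tail circumference, testes diameter and movement-range
#' area.
#'
#' @param tracking per-individual tibble as from [quoll_tracking()].
#' @return tibble in long form: `season`, `variable`, `n`, `mean`, `se`.
#' @export
summarize_individuals <- function(tracking = quoll_tracking()) {
  vars <- c("age", "fixes", "days", "weight_g", "foot_length_mm",
            "tail_circumference_mm", "testes_diameter_mm",
            "movement_range_ha")
  vars <- intersect(vars, names(tracking))
  rows <- lapply(unique(tracking$season), function(s) {
    sub <- tracking[tracking$season == s, , drop = FALSE]
    do.call(rbind, lapply(vars, function(v) {
      x <- sub[[v]][!is.na(sub[[v]])]
      tibble::tibble(season = s, variable = v, n = length(x),
                     mean = mean(x), se = se_mean(x))
    }))
  })
  do.call(rbind, rows)
}
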