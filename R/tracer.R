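R_AIR_15N <- 0.0036765 # 15N/14N isotope ratio of atmospheric N2

#' Convert delta-15N (per mil) to atom percent 15N
#'
#' `R = R_air * (delta/1000 + 1)` with the atmospheric-N2 standard ratio
#' `R_air = 0.0036765`, then `atom% = 100 * R / (1 + R)`. At natural
#' abundance (`delta = 0`) this gives 0.36630 atom%.
#'
#' @param delta15n delta-15N values in per mil (> -1000). Vectorized.
#' @return Atom percent 15N.
#' @export
delta_to_atom_pct <- function(delta15n) {
  if (any(!is.finite(delta15n) | delta15n <= -1000)) {
    abort("delta-15N must be finite and > -1000 per mil.")
  }
  r <- R_AIR_15N * (delta15n / 1000 + 1)
  100 * r / (1 + r)
}

#' Mass of excess 15N in an organ sample
#'
#' Grams of tracer 15N above the pre-labeling baseline:
#' `(atom%_t - atom%_t0)/100 * %N/100 * DW`. Slightly negative values can
#' arise from instrument noise at natural abundance; they are returned as-is
#' (flag downstream, do not clamp).
#'
#' @param atom_pct_t Atom% 15N at harvest time (0-100).
#' @param atom_pct_t0 Atom% 15N baseline, before labeling (0-100).
#' @param pct_n Total nitrogen as % of dry weight (0-100).
#' @param dw_g Organ dry weight in grams (> 0).
#' @return Grams of excess 15N. Vectorized.
#' @export
n15_excess <- function(atom_pct_t, atom_pct_t0, pct_n, dw_g) {
  rng_ok <- function(x) all(is.finite(x) & x >= 0 & x <= 100)
  if (!rng_ok(atom_pct_t) || !rng_ok(atom_pct_t0) || !rng_ok(pct_n)) {
    abort("Atom percentages and %N must lie in [0, 100].")
  }
  if (any(!is.finite(dw_g) | dw_g <= 0)) abort("Dry weights must be positive.")
  (atom_pct_t - atom_pct_t0) / 100 * pct_n / 100 * dw_g
}

#' Add the excess-15N column to a labeling table
#'
#' @param samples Tibble with columns `atom_pct_t`, `atom_pct_t0`, `pct_n`,
#'   `dw_g` (one row per plant x organ x time).
#' @return `samples` with an `excess_g` column.
#' @export
add_n15_excess <- function(samples) {
  dplyr::mutate(samples, excess_g = n15_excess(
    .data$atom_pct_t, .data$atom_pct_t0, .data$pct_n, .data$dw_g
  ))
}

#' Root-to-shoot translocation fraction of tracer 15N
#'
#' The share of the plant's excess 15N found in the shoot,
#' `shoot / (shoot + root)`, computed from the excess-15N masses of the two
#' organs of the same plant at the same time.
#'
#' @param shoot_excess,root_excess Grams of excess 15N per organ. Vectorized.
#' @return Fractions in `[0, 1]` for nonnegative excesses. A non-positive
#'   total is an error (undefined partition).
#' @export
translocation_fraction <- function(shoot_excess, root_excess) {
  total <- shoot_excess + root_excess
  if (any(!is.finite(total) | total <= 0)) {
    abort("Undefined partition: total excess 15N must be positive.")
  }
  shoot_excess / total
}

#' Per-plant tracer partition table
#'
#' Pairs the shoot and root rows of each plant x time, computes organ excess
#' 15N and the root-to-shoot translocation fraction (also as percent).
#' Plants with a negative organ excess are flagged (`noise_flag`) but kept as
#' long as the total is positive.
#'
#' @param samples Labeling tibble: `plant_id`, `organ` ("shoot"/"root"),
#'   `time_min`, `atom_pct_t`, `atom_pct_t0`, `pct_n`, `dw_g`.
#' @return Tibble per plant x time: `shoot_excess_g`, `root_excess_g`,
#'   `translocation`, `translocation_pct`, `noise_flag`.
#' @export
tracer_partition <- function(samples) {
  samples <- add_n15_excess(samples)
  wide <- samples |>
    dplyr::select(dplyr::all_of(c("plant_id", "organ", "time_min", "excess_g"))) |>
    tidyr::pivot_wider(names_from = "organ", values_from = "excess_g")
  if (!all(c("shoot", "root") %in% names(wide))) {
    abort("Both shoot and root rows are required for every plant and time.")
  }
  incomplete <- wide[is.na(wide$shoot) | is.na(wide$root), , drop = FALSE]
  if (nrow(incomplete)) {
    abort(paste0(
      "Missing organ row(s) for plant(s): ",
      paste(unique(incomplete$plant_id), collapse = ", ")
    ))
  }
  wide |>
    dplyr::transmute(
      .data$plant_id, .data$time_min,
      shoot_excess_g = .data$shoot,
      root_excess_g = .data$root,
      translocation = translocation_fraction(.data$shoot, .data$root),
      translocation_pct = 100 * .data$translocation,
      noise_flag = .data$shoot < 0 | .data$root < 0
    )
}

#' Linear uptake trend of plant-total excess 15N
#'
#' OLS fit of total excess 15N on incubation time (the labeling designs use
#' 3, 7, 15 and 30 min, but any increasing set works). The slope is the
#' uptake rate in grams 15N per minute.
#'
#' @param data Tibble of a labeling time series.
#' @param time,excess Column names (strings) of time (min) and plant-total
#'   excess 15N (g).
#' @return One-row tibble: `rate`, `intercept`, `r2`, `p_value`, `n`.
#' @export
uptake_trend <- function(data, time = "time_min", excess = "excess_g") {
  fit <- linear_assoc(data, predictor = time, response = excess)
  if (fit$n < 3L) abort("Need at least 3 time points.")
  tibble::tibble(
    rate = fit$slope, intercept = fit$intercept,
    r2 = fit$r2, p_value = fit$p_value, n = fit$n
  )
}
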