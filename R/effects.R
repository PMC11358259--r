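#' Aggregate organ biomasses into shoot or whole-plant records
#'
#' Whole-plant biomass is the sum of shoot and root biomass; where a study
#' reports stem and leaf separately, shoot biomass is their sum, and for
#' species growing in rosettes the leaf biomass alone stands for the shoot.
#' Variances add under the working assumption that the organ biomasses are
#' independent, i.e. the covariance term is taken as 0; `covariance` exposes
#' that term for sensitivity analysis. The replicate count of an aggregate is
#' the minimum of the part counts: the parts were measured on the same
#' plants, so the smaller arm bounds the information available, and the
#' propagated variance (not n) is what feeds the effect-size variance
#' downstream.
#'
#' @param records Validated study records (SD-normalized) containing the part
#'   organs; other organs are ignored.
#' @param target `"plant"` (shoot + root) or `"shoot"` (stem + leaf, or leaf
#'   alone).
#' @param covariance Covariance between the two part biomasses, in grams
#'   squared. Default 0 (independence assumption).
#' @return A tibble of aggregated records with `organ == target`.
#' @export
aggregate_organs <- function(records, target = c("plant", "shoot"), covariance = 0) {
  target <- match.arg(target)
  if (any(records$dispersion_kind != "sd")) {
    abort("Dispersion must be SD before aggregation; run se_to_sd().")
  }
  parts <- if (target == "plant") c("shoot", "root") else c("stem", "leaf")
  sub <- records[records$organ %in% parts, , drop = FALSE]
  if (!nrow(sub)) abort(paste0("No ", paste(parts, collapse = "/"), " records to aggregate."))

  grp_cols <- c("study_id", "species", "cultivar", "n_form", "ph")
  agg_one <- function(df, key) {
    have <- df$organ
    if (anyDuplicated(have)) {
      abort(paste0("Duplicate ", paste(have[duplicated(have)], collapse = ","),
                   " record within key ", paste(key, collapse = "/"), "."))
    }
    if (target == "plant" && !setequal(have, parts)) {
      abort(paste0("Key ", paste(key, collapse = "/"),
                   " is missing a required part (need shoot and root)."))
    }
    if (target == "shoot" && !("leaf" %in% have)) {
      abort(paste0("Key ", paste(key, collapse = "/"),
                   " is missing leaf biomass (need stem+leaf, or leaf alone for rosettes)."))
    }
    cov_term <- if (length(have) == 2L) 2 * covariance else 0
    tibble::tibble(
      organ = target,
      mean_biomass = sum(df$mean_biomass),
      dispersion = sqrt(sum(df$dispersion^2) + cov_term),
      dispersion_kind = "sd",
      n = min(df$n)
    )
  }

  out <- sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::group_modify(function(df, key) agg_one(df, unlist(key))) |>
    dplyr::ungroup()
  out[, c(grp_cols[1:3], "organ", grp_cols[4:5],
          "mean_biomass", "dispersion", "dispersion_kind", "n")]
}

#' Log biomass response ratio (LnBR)
#'
#' The ammonium-sensitivity effect size: the natural log of the ratio of mean
#' organ biomass under sole-ammonium versus sole-nitrate nutrition,
#' `ln(mean_NH4 / mean_NO3)`. Negative values mean inferior growth on
#' ammonium.
#'
#' @param mean_nh4,mean_no3 Positive mean biomasses (grams) of the ammonium
#'   and nitrate arms. Vectorized.
#' @return LnBR values.
#' @export
log_response_ratio <- function(mean_nh4, mean_no3) {
  if (any(!is.finite(mean_nh4) | mean_nh4 <= 0) ||
      any(!is.finite(mean_no3) | mean_no3 <= 0)) {
    abort("Arm means must be positive and finite for a log ratio.")
  }
  log(mean_nh4 / mean_no3)
}

#' Large-sample variance of the log response ratio
#'
#' The delta-method approximation
#' `SD_NH4^2 / (N_NH4 * mean_NH4^2) + SD_NO3^2 / (N_NO3 * mean_NO3^2)`,
#' i.e. the sum of the squared coefficients of variation of the two arm
#' means. Zero only when both SDs are zero.
#'
#' @param mean_nh4,sd_nh4,n_nh4 Mean, SD and replicate count of the ammonium
#'   arm. Vectorized.
#' @param mean_no3,sd_no3,n_no3 Same for the nitrate arm.
#' @return Variances of LnBR.
#' @export
lrr_variance <- function(mean_nh4, sd_nh4, n_nh4, mean_no3, sd_no3, n_no3) {
  if (any(sd_nh4 < 0) || any(sd_no3 < 0)) abort("SDs must be nonnegative.")
  if (any(n_nh4 < 1) || any(n_no3 < 1)) abort("Replicate counts must be positive.")
  sd_nh4^2 / (n_nh4 * mean_nh4^2) + sd_no3^2 / (n_no3 * mean_no3^2)
}

#' Confidence interval for an effect size
#'
#' `lnbr +/- z * sqrt(variance)`; at the default 95% level the multiplier is
#' 1.96 exactly, matching the SD x 1.96 convention used throughout the
#' meta-analysis.
#'
#' @param lnbr Effect sizes.
#' @param variance Their variances (>= 0).
#' @param level Coverage fraction in (0, 1).
#' @return Tibble with columns `ci_low`, `ci_high`.
#' @export
effect_ci <- function(lnbr, variance, level = 0.95) {
  if (any(variance < 0)) abort("Variances must be nonnegative.")
  z <- z_crit(level)
  half <- z * sqrt(variance)
  tibble::tibble(ci_low = lnbr - half, ci_high = lnbr + half)
}

#' Compute effect sizes for paired comparison cases
#'
#' Adds the LnBR effect size, its variance and the SD x 1.96 confidence
#' interval to a table of comparison cases.
#'
#' @param cases A tibble from [pair_comparisons()].
#' @param level Confidence level (default 0.95, multiplier 1.96 exactly).
#' @return The cases with columns `lnbr`, `variance`, `ci_low`, `ci_high`.
#' @export
compute_effects <- function(cases, level = 0.95) {
  out <- dplyr::mutate(
    cases,
    lnbr = log_response_ratio(.data$mean_nh4, .data$mean_no3),
    variance = lrr_variance(
      .data$mean_nh4, .data$sd_nh4, .data$n_nh4,
      .data$mean_no3, .data$sd_no3, .data$n_no3
    )
  )
  dplyr::bind_cols(out, effect_ci(out$lnbr, out$variance, level))
}
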