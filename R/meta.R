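#' Classify hydroponic solution pH as low or high
#'
#' Studies are stratified at pH 6.5, the usual optimum for nutrient
#' availability in hydroponics: below 6.5 is "low", at or above is "high".
#'
#' @param ph Solution pH values (> 0). Vectorized.
#' @return Factor with levels `low`, `high`.
#' @export
classify_ph <- function(ph) {
  if (any(!is.finite(ph) | ph <= 0)) abort("pH must be positive and finite.")
  factor(ifelse(ph < 6.5, "low", "high"), levels = c("low", "high"))
}

# bare-vector random-effects pooling; hot path shared by pool_effects and
# the bootstrap (no tibble allocation per call)
pool_core <- function(y, v, method = "DL") {
  k <- length(y)
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_fe)^2)
  if (method == "DL") {
    c_dl <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / c_dl)
  } else {
    tau2 <- estimate_tau2(y, v, method = "REML")$tau2
  }
  wstar <- 1 / (v + tau2)
  est <- sum(wstar * y) / sum(wstar)
  list(estimate = est, se = sqrt(1 / sum(wstar)), tau2 = tau2, q = q)
}

# floor zero sampling variances so inverse-variance weights stay finite
floor_variances <- function(v, floor = 1e-8, quiet = FALSE) {
  if (any(v == 0)) {
    if (!quiet) {
      warn(paste0(sum(v == 0), " zero sampling variance(s) floored at ", floor, "."))
    }
    v[v == 0] <- floor
  }
  v
}

#' Between-study variance of a group of effect sizes
#'
#' Method-of-moments (DerSimonian-Laird) estimate
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' `w = 1/variance`, truncated at zero, together with the heterogeneity
#' statistic Q. A restricted maximum likelihood estimate is available with
#' `method = "REML"` (Q is always the moment statistic).
#'
#' @param y Study effect sizes (LnBR values).
#' @param v Their sampling variances (> 0; zeros are floored).
#' @param method `"DL"` (default) or `"REML"`.
#' @return List with elements `tau2` and `q`.
#' @export
estimate_tau2 <- function(y, v, method = c("DL", "REML")) {
  method <- match.arg(method)
  k <- length(y)
  if (k < 2L) abort("At least two studies are required to estimate tau2.")
  v <- floor_variances(v, quiet = TRUE)
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_fe)^2)
  if (method == "DL") {
    c_dl <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / c_dl)
  } else {
    nll <- function(t2) {
      wi <- 1 / (v + t2)
      mu <- sum(wi * y) / sum(wi)
      0.5 * (sum(log(v + t2)) + log(sum(wi)) + sum(wi * (y - mu)^2))
    }
    upper <- max(q / sum(1 / v) * 10, var(y) * 10, 1e-3)
    opt <- optimize(nll, c(0, upper), tol = 1e-9)
    tau2 <- if (nll(0) <= opt$objective) 0 else opt$minimum
  }
  list(tau2 = tau2, q = q)
}

#' Pool a group of effect sizes under a random-effects model
#'
#' Inverse-variance pooling with random-effects weights
#' `w* = 1/(variance + tau2)`: the estimate is `sum(w* y)/sum(w*)`, its
#' standard error `sqrt(1/sum(w*))`, and the confidence interval
#' `estimate +/- 1.96 * se` at the default level (the SD x 1.96 convention).
#' Replicate counts enter through each study's sampling variance.
#'
#' @inheritParams estimate_tau2
#' @param level Confidence level (default 0.95; multiplier 1.96 exactly).
#' @return One-row tibble: `k`, `estimate`, `se`, `tau2`, `q`, `ci_low`,
#'   `ci_high`.
#' @export
pool_effects <- function(y, v, method = c("DL", "REML"), level = 0.95) {
  method <- match.arg(method)
  k <- length(y)
  if (k < 2L) abort("Pooling refused: fewer than two studies (reported-only group).")
  if (all(v == 0) && length(unique(y)) == 1L) {
    return(tibble::tibble(
      k = k, estimate = y[1], se = 0, tau2 = 0, q = 0,
      ci_low = y[1], ci_high = y[1]
    ))
  }
  v <- floor_variances(v, quiet = TRUE)
  pc <- pool_core(y, v, method)
  z <- z_crit(level)
  tibble::tibble(
    k = k, estimate = pc$estimate, se = pc$se, tau2 = pc$tau2, q = pc$q,
    ci_low = pc$estimate - z * pc$se, ci_high = pc$estimate + z * pc$se
  )
}

#' Study-level bootstrap confidence interval for a pooled effect
#'
#' Resamples studies (the random effect) with replacement, re-pools every
#' resample, and returns the percentile interval of the pooled estimates.
#'
#' @inheritParams pool_effects
#' @param iterations Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed; the interval is reproducible for a
#'   fixed seed.
#' @return One-row tibble: `boot_low`, `boot_high`, `iterations`, `seed`.
#' @export
bootstrap_pool <- function(y, v, iterations = 1000, seed = NULL,
                           method = c("DL", "REML"), level = 0.95) {
  method <- match.arg(method)
  k <- length(y)
  if (k < 2L) abort("Bootstrap requires at least two studies.")
  if (iterations < 1L) abort("`iterations` must be >= 1.")
  v <- floor_variances(v, quiet = TRUE)
  run <- function() {
    ests <- vapply(seq_len(iterations), function(b) {
      idx <- sample.int(k, k, replace = TRUE)
      yi <- y[idx]
      vi <- v[idx]
      if (length(unique(yi)) == 1L) return(yi[1])
      pool_core(yi, vi, method = method)$estimate
    }, numeric(1))
    unname(stats::quantile(ests, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  qs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(
    boot_low = qs[1], boot_high = qs[2],
    iterations = as.integer(iterations),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}

#' Rosenthal fail-safe N for publication bias
#'
#' The number of unpublished null studies that would be needed to bring the
#' combined significance below the one-tailed level `alpha`: each study
#' contributes `Z = lnbr / sqrt(variance)` signed toward the pooled
#' direction, and `N_fs = max(0, round((sum(Z)/z_alpha)^2 - k))` (round half
#' away from zero). At the conventional `alpha = 0.05`, `z_alpha = 1.645`.
#' The result is flagged robust when `N_fs > 5k + 10`.
#'
#' @inheritParams estimate_tau2
#' @param alpha One-tailed significance level (default 0.05).
#' @return One-row tibble: `failsafe_n` (integer), `robust` (logical).
#' @export
failsafe_n <- function(y, v, alpha = 0.05) {
  k <- length(y)
  if (k < 1L) abort("At least one study is required.")
  if (any(v <= 0)) {
    abort(paste0(
      "Zero sampling variance gives an infinite Z score (study ",
      paste(which(v <= 0), collapse = ", "), "); fail-safe N undefined."
    ))
  }
  direction <- if (k >= 2L) {
    sign(pool_effects(y, v)$estimate)
  } else {
    sign(y[1])
  }
  if (direction == 0) direction <- 1
  z_alpha <- if (isTRUE(all.equal(alpha, 0.05))) 1.645 else qnorm(1 - alpha)
  z_sum <- sum(direction * y / sqrt(v))
  nfs <- max(0, round_half_away((z_sum / z_alpha)^2 - k))
  tibble::tibble(
    failsafe_n = as.integer(nfs),
    robust = nfs > 5 * k + 10
  )
}

#' Random-effects meta-analysis over groups of effect sizes
#'
#' Pools LnBR effect sizes per group (by default species x organ x pH class)
#' under the random-effects model, with bootstrap confidence intervals,
#' heterogeneity Q and Rosenthal fail-safe N per group. Groups with a single
#' study are never pooled: they are carried in a separate reported-only table
#' with their per-study SD x 1.96 interval, mirroring the manual inclusion of
#' single-study species in the forest plots.
#'
#' @param effects A tibble from [compute_effects()] (columns `lnbr`,
#'   `variance` plus grouping columns). If `"ph_class"` is requested in `by`
#'   but absent, it is derived from `ph` with [classify_ph()].
#' @param by Character vector of grouping columns.
#' @param method Between-study variance estimator, `"DL"` or `"REML"`.
#' @param iterations Bootstrap iterations per group (default 1000); set to 0
#'   to skip the bootstrap.
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level (default 0.95, multiplier 1.96 exactly).
#' @param failsafe_alpha One-tailed level for the fail-safe N.
#' @return An object of class `lnbr_meta`: a list with `results` (one row per
#'   pooled group), `singles` (reported-only groups), and the call settings.
#'   Use [tidy()], [glance()], [forest_table()] or [ggplot2::autoplot()].
#' @export
meta_pool <- function(effects, by = c("species", "organ", "ph_class"),
                      method = c("DL", "REML"), iterations = 1000,
                      seed = NULL, level = 0.95, failsafe_alpha = 0.05) {
  method <- match.arg(method)
  if ("ph_class" %in% by && !"ph_class" %in% names(effects)) {
    if (!"ph" %in% names(effects)) abort("Need a `ph` column to derive `ph_class`.")
    effects$ph_class <- classify_ph(effects$ph)
  }
  missing_by <- setdiff(by, names(effects))
  if (length(missing_by)) {
    abort(paste0("Grouping column(s) missing: ", paste(missing_by, collapse = ", ")))
  }
  effects$variance <- floor_variances(effects$variance)

  grouped <- effects |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    tidyr::nest() |>
    dplyr::ungroup()

  pool_one <- function(df, boot_seed) {
    res <- pool_effects(df$lnbr, df$variance, method = method, level = level)
    res <- dplyr::bind_cols(res, failsafe_n(df$lnbr, df$variance, failsafe_alpha))
    if (iterations > 0) {
      res <- dplyr::bind_cols(
        res,
        bootstrap_pool(df$lnbr, df$variance, iterations = iterations,
                       seed = boot_seed, method = method, level = level)[
                         , c("boot_low", "boot_high")]
      )
    }
    res
  }

  ks <- vapply(grouped$data, nrow, integer(1))
  pooled_idx <- which(ks >= 2L)
  # one derived seed per group keeps groups independent yet reproducible
  boot_seeds <- if (is.null(seed)) rep(list(NULL), nrow(grouped)) else
    as.list((as.integer(seed) + seq_len(nrow(grouped))) %% .Machine$integer.max)

  result_template <- tibble::tibble(
    k = integer(), estimate = numeric(), se = numeric(), tau2 = numeric(),
    q = numeric(), ci_low = numeric(), ci_high = numeric(),
    failsafe_n = integer(), robust = logical()
  )
  if (iterations > 0) {
    result_template$boot_low <- numeric()
    result_template$boot_high <- numeric()
  }
  results <- purrr::map2(
    grouped$data[pooled_idx], boot_seeds[pooled_idx], pool_one
  ) |> purrr::list_rbind()
  if (!nrow(results)) results <- result_template
  results <- dplyr::bind_cols(grouped[pooled_idx, by, drop = FALSE], results)

  singles <- grouped[ks == 1L, , drop = FALSE] |>
    tidyr::unnest("data") |>
    dplyr::mutate(reported_only = TRUE)

  structure(
    list(
      results = results, singles = singles, by = by, method = method,
      level = level, iterations = as.integer(iterations),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "lnbr_meta"
  )
}

#' @export
print.lnbr_meta <- function(x, ...) {
  cat("Random-effects meta-analysis of LnBR (", x$method, " tau2)\n", sep = "")
  cat("  ", nrow(x$results), " pooled group(s) [", paste(x$by, collapse = " x "),
      "], ", nrow(x$singles), " reported-only single(s)\n", sep = "")
  print(x$results, ...)
  invisible(x)
}

#' Forest-plot table of pooled and single-study effects
#'
#' Emits the table behind a forest plot: pooled groups and reported-only
#' single studies on a common scale, sorted by estimate, plus OVERALL rows
#' per pH class (or one overall row when pH is not a grouping factor)
#' computed over the pooled groups only. The overall rows are means of the
#' pooled effect sizes, unweighted by default.
#'
#' @param meta An `lnbr_meta` object.
#' @param weighted If `TRUE`, the OVERALL rows weight pooled groups by the
#'   inverse squared standard error; default `FALSE` (plain mean).
#' @return Tibble with `label`, `estimate`, `ci_low`, `ci_high`, `k`, `flag`
#'   (`pooled`, `reported_only` or `overall`), plus the grouping columns.
#' @export
forest_table <- function(meta, weighted = FALSE) {
  stopifnot(inherits(meta, "lnbr_meta"))
  by <- meta$by
  lab <- function(df) {
    apply(df[, by, drop = FALSE], 1L, function(r) paste(r, collapse = " / "))
  }
  empty <- tibble::tibble(
    label = character(), estimate = numeric(), ci_low = numeric(),
    ci_high = numeric(), k = integer(), flag = character()
  )
  pooled <- if (nrow(meta$results)) tibble::tibble(
    label = lab(meta$results),
    meta$results[, by, drop = FALSE],
    estimate = meta$results$estimate,
    ci_low = meta$results$ci_low,
    ci_high = meta$results$ci_high,
    k = meta$results$k,
    flag = "pooled"
  ) else empty
  singles <- if (nrow(meta$singles)) tibble::tibble(
    label = lab(meta$singles),
    meta$singles[, by, drop = FALSE],
    estimate = meta$singles$lnbr,
    ci_low = meta$singles$lnbr - z_crit(meta$level) * sqrt(meta$singles$variance),
    ci_high = meta$singles$lnbr + z_crit(meta$level) * sqrt(meta$singles$variance),
    k = 1L,
    flag = "reported_only"
  ) else empty

  body <- dplyr::arrange(dplyr::bind_rows(pooled, singles), .data$estimate)

  overall <- empty
  if (nrow(pooled)) {
    grp <- if ("ph_class" %in% by) "ph_class" else character()
    wmean <- function(x, w) if (weighted) sum(w * x) / sum(w) else mean(x)
    overall <- pooled |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(
        estimate = wmean(.data$estimate, 1 / ((.data$ci_high - .data$ci_low) / 2)^2),
        ci_low = wmean(.data$ci_low, 1 / ((.data$ci_high - .data$ci_low) / 2)^2),
        ci_high = wmean(.data$ci_high, 1 / ((.data$ci_high - .data$ci_low) / 2)^2),
        k = sum(.data$k),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        label = if (length(grp)) paste("OVERALL", toupper(as.character(.data[[grp]]))) else "OVERALL",
        flag = "overall"
      )
  }
  dplyr::bind_rows(body, overall)
}
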