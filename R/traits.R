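#' Normalize species names for joining
#'
#' Case-folds and squeezes whitespace in Latin binomials so that trait tables
#' and pooled-effect tables written with different capitalization still
#' match.
#'
#' @param x Character vector of species names.
#' @return Normalized names ("Genus species" form, single spaces).
#' @export
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x <- tolower(x)
  # capitalize the genus only
  sub("^(\\w)", "\\U\\1", x, perl = TRUE)
}

#' Merge species-level pooled effects with the trait table
#'
#' Inner join on the normalized species name. Species present on one side
#' only are reported in attributes, never silently lost; duplicated species
#' in the trait table are an error.
#'
#' @param pooled Tibble of species-level pooled effects (needs a `species`
#'   column, e.g. `tidy()` of an [meta_pool()] fit grouped by species).
#' @param traits Tibble of species traits: `species`, `ellenberg_n`,
#'   `ellenberg_r`, `spread`, `npf_count`, `nrt2_count`, `amt1_count`,
#'   `amt2_count` (missing trait values stay `NA`, never zero-filled).
#' @return Merged tibble; `attr(, "unmatched_pooled")` and
#'   `attr(, "unmatched_traits")` list the species without a partner.
#' @export
merge_traits <- function(pooled, traits) {
  if (!"species" %in% names(pooled) || !"species" %in% names(traits)) {
    abort("Both tables need a `species` column.")
  }
  pooled <- dplyr::mutate(tibble::as_tibble(pooled),
                          species = normalize_species(.data$species))
  traits <- dplyr::mutate(tibble::as_tibble(traits),
                          species = normalize_species(.data$species))
  dup <- unique(traits$species[duplicated(traits$species)])
  if (length(dup)) {
    abort(paste0("Duplicate species in trait table: ", paste(dup, collapse = ", ")))
  }
  merged <- dplyr::inner_join(pooled, traits, by = "species")
  attr(merged, "unmatched_pooled") <- setdiff(pooled$species, traits$species)
  attr(merged, "unmatched_traits") <- setdiff(traits$species, pooled$species)
  n_un <- length(attr(merged, "unmatched_pooled")) + length(attr(merged, "unmatched_traits"))
  if (n_un) inform(paste0(n_un, " unmatched species; see attr(, 'unmatched_*')."))
  merged
}

#' Linear association between a trait and pooled LnBR
#'
#' Ordinary least squares of the response on one predictor over complete
#' cases, reporting the slope, intercept, squared Pearson correlation and the
#' two-sided p-value of the zero-slope test. An inverse-variance weighted fit
#' is available when a variance column for the response is supplied.
#'
#' @param data A merged tibble from [merge_traits()] (or any data frame).
#' @param predictor,response Column names (strings) of the trait and the
#'   LnBR value.
#' @param weight_var Optional column name of response variances; when given,
#'   the fit uses weights `1/variance`.
#' @return One-row tibble: `predictor`, `response`, `slope`, `intercept`,
#'   `r2`, `p_value`, `n`.
#' @export
linear_assoc <- function(data, predictor, response = "lnbr", weight_var = NULL) {
  for (col in c(predictor, response, weight_var)) {
    if (!col %in% names(data)) abort(paste0("Column not found: ", col))
  }
  x <- data[[predictor]]
  y <- data[[response]]
  w <- if (is.null(weight_var)) NULL else 1 / data[[weight_var]]
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(w)) keep <- keep & !is.na(w) & is.finite(w)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("Fewer than 3 complete pairs.")
  if (var(x) == 0) abort(paste0("Degenerate predictor: `", predictor, "` is constant."))
  fit <- if (is.null(w)) {
    lm(y ~ x)
  } else {
    w <- w[keep]
    lm(y ~ x, weights = w)
  }
  # collinear inputs are legitimate here (r2 = 1); keep summary.lm quiet
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble::tibble(
    predictor = predictor,
    response = response,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    n = length(x)
  )
}

#' Trait associations for several predictors at once
#'
#' Runs [linear_assoc()] for each predictor (complete-case per predictor) and
#' stacks the one-row results.
#'
#' @inheritParams linear_assoc
#' @param predictors Character vector of trait columns.
#' @return Tibble with one row per predictor.
#' @export
assoc_table <- function(data, predictors, response = "lnbr", weight_var = NULL) {
  purrr::map(predictors, function(p) {
    linear_assoc(data, p, response = response, weight_var = weight_var)
  }) |> purrr::list_rbind()
}

#' Principal component analysis of traits and pooled effects
#'
#' PCA on centered, unit-variance variables (the correlation matrix), since
#' Ellenberg scores (ordinal 1-9), spread (country counts) and LnBR are on
#' incommensurate scales. Components are ordered by variance explained.
#'
#' @param data A merged tibble.
#' @param vars Character vector of at least two numeric columns.
#' @param id Optional column naming the rows (default `"species"` if
#'   present).
#' @return Object of class `lnbr_pca`: list with the `prcomp` fit,
#'   `loadings` and `scores` tibbles, `pct_var` (percent variance per
#'   component, sums to 100) and `n` (complete cases used). Supports
#'   [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
pca_traits <- function(data, vars, id = NULL) {
  if (length(vars) < 2L) abort("Need at least two variables for a PCA.")
  missing <- setdiff(vars, names(data))
  if (length(missing)) abort(paste0("Column(s) not found: ", paste(missing, collapse = ", ")))
  if (is.null(id) && "species" %in% names(data)) id <- "species"
  mat <- as.matrix(data[, vars])
  keep <- complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 3L) abort("Need at least 3 complete rows for a PCA.")
  flagged <- nrow(mat) < length(vars)
  if (flagged) {
    warn("Fewer complete cases than variables; components beyond the case count are degenerate.")
  }
  fit <- prcomp(mat, center = TRUE, scale. = TRUE)
  pct <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  pcs <- colnames(fit$rotation)
  loadings <- tibble::as_tibble(fit$rotation, rownames = "variable")
  scores <- tibble::as_tibble(fit$x)
  if (!is.null(id)) scores <- dplyr::bind_cols(
    tibble::tibble(!!id := data[[id]][keep]), scores
  )
  structure(
    list(
      fit = fit, loadings = loadings, scores = scores,
      pct_var = setNames(pct, pcs), n = nrow(mat),
      vars = vars, low_n_flag = flagged
    ),
    class = "lnbr_pca"
  )
}

#' @export
print.lnbr_pca <- function(x, ...) {
  cat("PCA of", length(x$vars), "standardized variables over", x$n, "complete cases\n")
  cat("Percent variance:",
      paste(sprintf("%s %.1f%%", names(x$pct_var), x$pct_var), collapse = ", "), "\n")
  invisible(x)
}
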