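#' Tidy a random-effects meta-analysis fit
#'
#' @param x An `lnbr_meta` object from [meta_pool()].
#' @param which `"pooled"` (default) for the per-group results or
#'   `"singles"` for the reported-only single-study groups.
#' @param ... Unused.
#' @return A tibble, one row per group.
#' @method tidy lnbr_meta
#' @export
tidy.lnbr_meta <- function(x, which = c("pooled", "singles"), ...) {
  which <- match.arg(which)
  if (which == "pooled") x$results else x$singles
}

#' One-row summary of a meta-analysis fit
#'
#' @param x An `lnbr_meta` object.
#' @param ... Unused.
#' @return Tibble with group counts, total studies pooled, estimator and
#'   bootstrap settings.
#' @method glance lnbr_meta
#' @export
glance.lnbr_meta <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$results),
    n_singles = nrow(x$singles),
    k_total = sum(x$results$k) + nrow(x$singles),
    method = x$method,
    level = x$level,
    iterations = x$iterations,
    seed = x$seed
  )
}

#' Tidy a trait PCA
#'
#' @param x An `lnbr_pca` object from [pca_traits()].
#' @param matrix `"loadings"` (default, long format), `"scores"`, or
#'   `"pct_var"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lnbr_pca
#' @export
tidy.lnbr_pca <- function(x, matrix = c("loadings", "scores", "pct_var"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    loadings = tidyr::pivot_longer(x$loadings, -"variable",
                                   names_to = "component", values_to = "loading"),
    scores = x$scores,
    pct_var = tibble::tibble(component = names(x$pct_var),
                             pct_var = unname(x$pct_var))
  )
}

#' One-row summary of a trait PCA
#'
#' @param x An `lnbr_pca` object.
#' @param ... Unused.
#' @return Tibble with the case count, variable count and the variance
#'   explained by the first two components.
#' @method glance lnbr_pca
#' @export
glance.lnbr_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_vars = length(x$vars),
    pc1_pct = unname(x$pct_var[1]),
    pc2_pct = if (length(x$pct_var) >= 2L) unname(x$pct_var[2]) else NA_real_,
    low_n_flag = x$low_n_flag
  )
}
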