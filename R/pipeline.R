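as_run_config <- function(config, required) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or the path to a YAML file.")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort(paste0("Config field(s) missing: ", paste(missing, collapse = ", ")))
  }
  config
}

write_manifest <- function(out_dir, stage, config, outputs, seed = NULL) {
  inputs <- config[names(config) %in% c("input", "pooled", "traits")]
  in_digests <- lapply(inputs, function(p) {
    if (is.character(p) && length(p) == 1L && file.exists(p)) {
      unname(tools::md5sum(p))
    } else {
      "in-memory"
    }
  })
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("ammsens")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config[setdiff(names(config), "out")],
    input_digests = in_digests,
    outputs = outputs,
    output_digests = lapply(outputs, function(p) unname(tools::md5sum(p)))
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run the meta-analysis stage end to end
#'
#' Ingest -> SE normalization -> (optional whole-plant aggregation) -> arm
#' pairing -> effect sizes -> random-effects pooling -> forest table, with
#' every output written to `out` and a JSON run manifest recording seeds,
#' settings and file digests.
#'
#' @param config A list or YAML file path with fields: `input` (study CSV
#'   path, or an in-memory data frame), `out` (output directory); optional
#'   `schema` (column map, see [read_study_table()]), `by` (grouping columns,
#'   default species x organ x pH class), `method` (`"DL"`/`"REML"`),
#'   `iterations` (bootstrap, default 1000), `seed` (default 1), `level`
#'   (default 0.95), `aggregate_plant` (also derive whole-plant records from
#'   shoot + root, default `FALSE`).
#' @return Invisibly, a list with the `lnbr_meta` fit and the output paths
#'   (`effects`, `pooled`, `reported_only`, `forest`, `unpaired`,
#'   `manifest`).
#' @export
run_meta <- function(config) {
  config <- as_run_config(config, c("input", "out"))
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  by <- config$by %||% c("species", "organ", "ph_class")
  iterations <- config$iterations %||% 1000L

  records <- if (is.data.frame(config$input)) {
    validate_study_records(config$input)
  } else {
    read_study_table(config$input, schema = config$schema)
  }
  records <- se_to_sd(records, quiet = TRUE)
  if (isTRUE(config$aggregate_plant)) {
    records <- dplyr::bind_rows(records, aggregate_organs(records, "plant"))
  }
  cases <- pair_comparisons(records)
  effects <- compute_effects(cases, level = config$level %||% 0.95)
  meta <- meta_pool(
    effects, by = by, method = config$method %||% "DL",
    iterations = iterations, seed = seed, level = config$level %||% 0.95
  )
  forest <- forest_table(meta)

  paths <- list(
    effects = file.path(out_dir, "effects.csv"),
    pooled = file.path(out_dir, "pooled_effects.csv"),
    reported_only = file.path(out_dir, "reported_only.csv"),
    forest = file.path(out_dir, "forest.tsv"),
    unpaired = file.path(out_dir, "unpaired.csv")
  )
  readr::write_csv(effects, paths$effects, progress = FALSE)
  readr::write_csv(meta$results, paths$pooled, progress = FALSE)
  readr::write_csv(meta$singles, paths$reported_only, progress = FALSE)
  readr::write_tsv(forest, paths$forest, progress = FALSE)
  readr::write_csv(unpaired_records(cases), paths$unpaired, progress = FALSE)
  paths$manifest <- write_manifest(out_dir, "meta", config, paths, seed)
  invisible(c(list(meta = meta), paths))
}

#' Run the trait-association stage
#'
#' Joins species-level pooled effects with the trait table, fits the
#' per-trait linear associations for each organ, and runs the PCA of
#' Ellenberg scores, spread and LnBR.
#'
#' @param config A list or YAML file path with fields: `pooled` (CSV path or
#'   data frame of pooled effects with `species`, `organ`, `estimate`
#'   columns), `traits` (CSV path or data frame, see [merge_traits()]),
#'   `out`; optional `predictors` (default: the Ellenberg scores, spread and
#'   the four gene-count columns), `organs` (default root and shoot),
#'   `pca_vars` (default `ellenberg_n`, `ellenberg_r`, `spread`, `estimate`),
#'   `weight_var` (variance column for weighted fits).
#' @return Invisibly, a list with the merged table, association results, PCA
#'   fits per organ and output paths.
#' @export
run_assoc <- function(config) {
  config <- as_run_config(config, c("pooled", "traits", "out"))
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  read_tab <- function(x) {
    if (is.data.frame(x)) tibble::as_tibble(x)
    else readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  pooled <- read_tab(config$pooled)
  traits <- read_tab(config$traits)
  if (!nrow(traits)) abort("Trait table is empty.")
  predictors <- config$predictors %||% c(
    "ellenberg_n", "ellenberg_r", "spread",
    "npf_count", "nrt2_count", "amt1_count", "amt2_count"
  )
  predictors <- intersect(predictors, names(traits))
  organs <- config$organs %||% intersect(c("root", "shoot"), unique(pooled$organ))
  pca_vars <- config$pca_vars %||% c("ellenberg_n", "ellenberg_r", "spread", "estimate")

  merged <- merge_traits(pooled, traits)
  if (!nrow(merged)) {
    mismatch <- tibble::tibble(
      side = c(rep("pooled", length(attr(merged, "unmatched_pooled"))),
               rep("traits", length(attr(merged, "unmatched_traits")))),
      species = c(attr(merged, "unmatched_pooled"), attr(merged, "unmatched_traits"))
    )
    readr::write_csv(mismatch, file.path(out_dir, "species_mismatch.csv"),
                     progress = FALSE)
    abort("Join failure: no species shared between pooled effects and traits; see species_mismatch.csv.")
  }

  assoc <- purrr::map(organs, function(og) {
    sub <- merged[merged$organ == og, , drop = FALSE]
    dplyr::mutate(
      assoc_table(sub, predictors, response = "estimate",
                  weight_var = config$weight_var),
      organ = og, .before = 1L
    )
  }) |> purrr::list_rbind()

  pcas <- lapply(setNames(organs, organs), function(og) {
    pca_traits(merged[merged$organ == og, , drop = FALSE], pca_vars)
  })
  pca_var <- purrr::imap(pcas, function(p, og) {
    tibble::tibble(organ = og, component = names(p$pct_var),
                   pct_var = unname(p$pct_var))
  }) |> purrr::list_rbind()
  pca_load <- purrr::imap(pcas, function(p, og) {
    dplyr::mutate(p$loadings, organ = og, .before = 1L)
  }) |> purrr::list_rbind()
  pca_scores <- purrr::imap(pcas, function(p, og) {
    dplyr::mutate(p$scores, organ = og, .before = 1L)
  }) |> purrr::list_rbind()

  paths <- list(
    merged = file.path(out_dir, "merged_traits.csv"),
    associations = file.path(out_dir, "associations.csv"),
    pca_variance = file.path(out_dir, "pca_variance.csv"),
    pca_loadings = file.path(out_dir, "pca_loadings.csv"),
    pca_scores = file.path(out_dir, "pca_scores.csv")
  )
  readr::write_csv(merged, paths$merged, progress = FALSE)
  readr::write_csv(assoc, paths$associations, progress = FALSE)
  readr::write_csv(pca_var, paths$pca_variance, progress = FALSE)
  readr::write_csv(pca_load, paths$pca_loadings, progress = FALSE)
  readr::write_csv(pca_scores, paths$pca_scores, progress = FALSE)
  paths$manifest <- write_manifest(out_dir, "assoc", config, paths)
  invisible(c(list(merged = merged, associations = assoc, pca = pcas), paths))
}

#' Run the 15N tracer stage
#'
#' Computes organ excess 15N, the per-plant root-to-shoot translocation
#' partition (labeled harvests only) and the linear uptake trend of
#' plant-total excess over incubation time (baseline included).
#'
#' @param config A list or YAML file path with fields: `input` (labeling CSV
#'   path or data frame, see [tracer_partition()]), `out`.
#' @return Invisibly, a list with the partition table, the trend fit and
#'   output paths.
#' @export
run_tracer <- function(config) {
  config <- as_run_config(config, c("input", "out"))
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- if (is.data.frame(config$input)) {
    tibble::as_tibble(config$input)
  } else {
    readr::read_csv(config$input, show_col_types = FALSE, progress = FALSE)
  }
  no_baseline <- is.na(samples$atom_pct_t0)
  if (any(no_baseline)) {
    abort(paste0(
      "Missing time-zero baseline for plant(s): ",
      paste(unique(samples$plant_id[no_baseline]), collapse = ", ")
    ))
  }
  labeled <- samples[samples$time_min > 0, , drop = FALSE]
  partition <- tracer_partition(labeled)
  totals <- add_n15_excess(samples) |>
    dplyr::summarise(excess_g = sum(.data$excess_g),
                     .by = c("plant_id", "time_min"))
  trend <- uptake_trend(totals)

  paths <- list(
    partition = file.path(out_dir, "tracer_results.csv"),
    totals = file.path(out_dir, "plant_totals.csv"),
    trend = file.path(out_dir, "uptake_trend.csv")
  )
  readr::write_csv(partition, paths$partition, progress = FALSE)
  readr::write_csv(totals, paths$totals, progress = FALSE)
  readr::write_csv(trend, paths$trend, progress = FALSE)
  paths$manifest <- write_manifest(out_dir, "tracer", config, paths)
  invisible(c(list(partition = partition, trend = trend), paths))
}
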