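#' Canonical column names of a study-level biomass table
#'
#' One row is one organ x nitrogen-form biomass measurement from one study:
#' `study_id`, `species` (Latin binomial), `cultivar` (may be empty), `organ`
#' (root, shoot, stem, leaf or plant), `n_form` (ammonium or nitrate), `ph`
#' (solution pH), `mean_biomass` (grams), `dispersion` (SD or SE, grams),
#' `dispersion_kind` ("sd" or "se"), `n` (biological replicates).
#'
#' @format Character vector of the ten required column names.
#' @export
study_columns <- c(
  "study_id", "species", "cultivar", "organ", "n_form", "ph",
  "mean_biomass", "dispersion", "dispersion_kind", "n"
)

organ_levels <- c("root", "shoot", "stem", "leaf", "plant")
n_form_levels <- c("ammonium", "nitrate")

#' Read and validate a study-level biomass table
#'
#' Reads a CSV of per-arm biomass records extracted from the literature and
#' validates each row against the inclusion rules of the quantitative
#' synthesis: positive mean biomass, a reported dispersion (SD or SE), and a
#' minimum of three biological replicates. Rows that fail are rejected with
#' row-indexed diagnostics, not silently dropped.
#'
#' @param path Path to a CSV file (RFC-4180, UTF-8).
#' @param schema Optional column map when the source headers differ from
#'   [study_columns]: a named character vector `c(canonical = "source header")`
#'   or the path to a YAML/JSON file holding such a map. Header matching is
#'   case-insensitive.
#' @param strict If `TRUE`, any invalid row is an error instead of a warning.
#'
#' @return A tibble of validated records (canonical columns, `dispersion_kind`
#'   kept as reported). Rejected rows are attached as a tibble in
#'   `attr(, "rejected")` with their source row number and reason, and
#'   retrievable with [rejected_records()].
#' @seealso [validate_study_records()], [se_to_sd()], [pair_comparisons()]
#' @export
read_study_table <- function(path, schema = NULL, strict = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw <- apply_schema(raw, schema)
  validate_study_records(raw, strict = strict)
}

apply_schema <- function(df, schema) {
  if (is.character(schema) && length(schema) == 1L && is.null(names(schema))) {
    schema <- unlist(yaml::read_yaml(schema))
  }
  if (!is.null(schema)) {
    if (is.null(names(schema))) {
      abort("`schema` must be a named map: c(canonical = \"source header\").")
    }
    idx <- match(tolower(schema), tolower(names(df)))
    missing <- names(schema)[is.na(idx)]
    if (length(missing)) {
      abort(paste0(
        "Schema error: mapped source column(s) not found for: ",
        paste(missing, collapse = ", ")
      ))
    }
    names(df)[idx] <- names(schema)
  }
  names(df) <- tolower(names(df))
  missing <- setdiff(study_columns, names(df))
  if (length(missing)) {
    abort(paste0(
      "Schema error: required column(s) missing: ",
      paste(missing, collapse = ", ")
    ))
  }
  df
}

#' Validate study records against the inclusion rules
#'
#' @param records A data frame with the columns in [study_columns].
#' @param strict If `TRUE`, invalid rows raise an error; otherwise they are
#'   removed with a warning and reported via `attr(, "rejected")`.
#' @return A tibble of valid records with a `rejected` attribute.
#' @export
validate_study_records <- function(records, strict = FALSE) {
  records <- apply_schema(tibble::as_tibble(records), NULL)
  records <- dplyr::mutate(
    records,
    study_id = as.character(.data$study_id),
    species = as.character(.data$species),
    cultivar = dplyr::coalesce(as.character(.data$cultivar), ""),
    organ = tolower(as.character(.data$organ)),
    n_form = tolower(as.character(.data$n_form)),
    dispersion_kind = tolower(as.character(.data$dispersion_kind))
  )

  reasons <- list(
    "unknown organ (expected root/shoot/stem/leaf/plant)" =
      !records$organ %in% organ_levels,
    "unknown n_form (expected ammonium/nitrate)" =
      !records$n_form %in% n_form_levels,
    "non-positive solution pH" =
      !is.finite(records$ph) | records$ph <= 0,
    "non-positive mean biomass" =
      !is.finite(records$mean_biomass) | records$mean_biomass <= 0,
    "dispersion (SD or SE) not reported" =
      is.na(records$dispersion),
    "negative dispersion" =
      !is.na(records$dispersion) & records$dispersion < 0,
    "dispersion_kind must be 'sd' or 'se'" =
      !records$dispersion_kind %in% c("sd", "se"),
    "fewer than the minimum of three biological replicates" =
      !is.finite(records$n) | records$n < 3 | records$n != round(records$n)
  )
  bad <- Reduce(`|`, reasons)
  bad[is.na(bad)] <- TRUE

  rejected <- tibble::tibble(row = integer(), reason = character())
  if (any(bad)) {
    idx <- which(bad)
    reason <- vapply(idx, function(i) {
      hit <- vapply(reasons, function(r) isTRUE(r[i]), logical(1))
      paste(names(reasons)[hit], collapse = "; ")
    }, character(1))
    rejected <- tibble::tibble(row = idx, reason = reason)
    msg <- paste0(
      nrow(rejected), " row(s) rejected during validation, e.g. row ",
      rejected$row[1], ": ", rejected$reason[1]
    )
    if (strict) abort(msg) else warn(msg)
  }

  out <- records[!bad, , drop = FALSE]
  out$n <- as.integer(out$n)
  attr(out, "rejected") <- rejected
  out
}

#' Retrieve the rejected-row report of a validated table
#' @param records A tibble returned by [read_study_table()] or
#'   [validate_study_records()].
#' @return Tibble with columns `row` and `reason`.
#' @export
rejected_records <- function(records) {
  attr(records, "rejected") %||% tibble::tibble(row = integer(), reason = character())
}

#' Write a study table to CSV
#'
#' Canonical columns first; any extra columns (e.g. a fresh/dry biomass
#' basis flag) are carried through untouched.
#'
#' @param records Validated study records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(records, path) {
  extra <- setdiff(names(records), study_columns)
  readr::write_csv(records[, c(study_columns, extra)], path, progress = FALSE)
  invisible(path)
}

#' Normalize standard errors to standard deviations
#'
#' Source studies report either the SD or the SE of each arm; the effect-size
#' variance needs the SD, so SE rows are rescaled by `SE * sqrt(n)`. The
#' operation is idempotent: rows already carrying an SD are left untouched.
#'
#' @param records Validated study records.
#' @param quiet Suppress the conversion message.
#' @return The records with `dispersion` in SD units and
#'   `dispersion_kind == "sd"` everywhere.
#' @export
se_to_sd <- function(records, quiet = FALSE) {
  is_se <- records$dispersion_kind == "se"
  if (any(is_se) && !quiet) {
    inform(paste0("Converted ", sum(is_se), " SE value(s) to SD via SE * sqrt(n)."))
  }
  records$dispersion[is_se] <- records$dispersion[is_se] * sqrt(records$n[is_se])
  records$dispersion_kind[is_se] <- "sd"
  records
}

case_key_cols <- c("study_id", "species", "cultivar", "organ", "ph")

#' Pair ammonium and nitrate arms into comparison cases
#'
#' The unit of analysis is the matched ammonium-versus-nitrate comparison
#' within one study, species, cultivar, organ and solution pH. Keys with
#' exactly one arm of each nitrogen form become one comparison case; arms
#' without a partner are reported, never silently dropped.
#'
#' @param records Validated records with `dispersion_kind == "sd"` throughout
#'   (run [se_to_sd()] first).
#' @return A tibble with one row per comparison case: the key columns plus
#'   `mean_nh4`, `sd_nh4`, `n_nh4`, `mean_no3`, `sd_no3`, `n_no3`. Unpaired
#'   records are attached as `attr(, "unpaired")` and retrievable with
#'   [unpaired_records()].
#' @export
pair_comparisons <- function(records) {
  if (any(records$dispersion_kind != "sd")) {
    abort("Dispersion must be normalized to SD before pairing; run se_to_sd().")
  }
  counts <- records |>
    dplyr::count(dplyr::across(dplyr::all_of(c(case_key_cols, "n_form"))))
  dup <- counts[counts$n > 1L, , drop = FALSE]
  if (nrow(dup)) {
    lab <- paste(
      apply(dup[case_key_cols], 1L, paste, collapse = "/"),
      dup$n_form,
      sep = ":"
    )
    abort(paste0(
      "Ambiguous arms: more than one record for the same key and nitrogen form: ",
      paste(unique(lab), collapse = "; ")
    ))
  }

  wide <- records |>
    dplyr::select(dplyr::all_of(c(case_key_cols, "n_form", "mean_biomass", "dispersion", "n"))) |>
    tidyr::pivot_wider(
      names_from = "n_form",
      values_from = c("mean_biomass", "dispersion", "n")
    )
  for (col in c(
    "mean_biomass_ammonium", "dispersion_ammonium", "n_ammonium",
    "mean_biomass_nitrate", "dispersion_nitrate", "n_nitrate"
  )) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  paired <- !is.na(wide$mean_biomass_ammonium) & !is.na(wide$mean_biomass_nitrate)

  cases <- wide[paired, , drop = FALSE] |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(case_key_cols)),
      mean_nh4 = .data$mean_biomass_ammonium,
      sd_nh4 = .data$dispersion_ammonium,
      n_nh4 = as.integer(.data$n_ammonium),
      mean_no3 = .data$mean_biomass_nitrate,
      sd_no3 = .data$dispersion_nitrate,
      n_no3 = as.integer(.data$n_nitrate)
    )

  unpaired <- dplyr::semi_join(
    records, wide[!paired, case_key_cols, drop = FALSE],
    by = case_key_cols
  )
  if (nrow(unpaired)) {
    inform(paste0(
      nrow(unpaired), " unpaired record(s) (missing the opposite nitrogen-form arm); ",
      "see attr(, 'unpaired')."
    ))
  }
  attr(cases, "unpaired") <- unpaired
  cases
}

#' Retrieve the unpaired-arm report of a paired table
#' @param cases A tibble returned by [pair_comparisons()].
#' @return Tibble of study records lacking the opposite nitrogen-form arm.
#' @export
unpaired_records <- function(cases) {
  attr(cases, "unpaired") %||% tibble::tibble()
}

#' Cohen's kappa for two-reviewer screening agreement
#'
#' Chance-corrected agreement, `(p_o - p_e) / (1 - p_e)`, between two
#' screeners whose include/exclude decisions are cross-tabulated in a 2x2
#' table (rows = reviewer 1, columns = reviewer 2).
#'
#' @param table A 2x2 matrix or table of nonnegative agreement counts.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) abort("`table` must be 2x2.")
  if (any(m < 0) || any(m != round(m))) abort("Counts must be nonnegative integers.")
  total <- sum(m)
  if (total <= 0) abort("Total count must be positive.")
  p_o <- sum(diag(m)) / total
  p_e <- sum(rowSums(m) * colSums(m)) / total^2
  if (isTRUE(all.equal(p_e, 1))) {
    abort("Kappa undefined: degenerate marginals give expected agreement 1.")
  }
  (p_o - p_e) / (1 - p_e)
}
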