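test_that("a valid table round-trips through write and read unchanged", {
  df <- make_study_df()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  got <- read_study_table(path)
  expect_equal(nrow(got), 4L)
  expect_equal(nrow(rejected_records(got)), 0L)

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_study_table(got, path2)
  again <- read_study_table(path2)
  expect_equal(as.data.frame(again), as.data.frame(got))
})

test_that("rows violating the inclusion rules are rejected with diagnostics", {
  df <- make_study_df()
  df$n[2] <- 2L
  got <- suppressWarnings(validate_study_records(df))
  expect_equal(nrow(got), 3L)
  rej <- rejected_records(got)
  expect_equal(rej$row, 2L)
  expect_match(rej$reason, "three biological replicates")
  expect_warning(validate_study_records(df), "three biological replicates")

  df2 <- make_study_df()
  df2$mean_biomass[1] <- 0
  expect_match(rejected_records(suppressWarnings(validate_study_records(df2)))$reason,
               "non-positive mean")

  df3 <- make_study_df()
  df3$dispersion[3] <- NA_real_
  expect_match(rejected_records(suppressWarnings(validate_study_records(df3)))$reason,
               "not reported")

  expect_error(validate_study_records(df, strict = TRUE), "three biological")
})

test_that("missing columns and schema maps are handled", {
  df <- make_study_df()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df[, -6], path) # drop ph
  expect_error(read_study_table(path), "Schema error.*ph")

  # arbitrary source headers, matched case-insensitively through the map
  renamed <- df
  names(renamed)[names(renamed) == "ph"] <- "Solution.PH"
  names(renamed)[names(renamed) == "mean_biomass"] <- "Biomass Mean (g)"
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(renamed, path2)
  got <- read_study_table(
    path2,
    schema = c(ph = "solution.ph", mean_biomass = "biomass mean (g)")
  )
  expect_equal(got$ph, df$ph)
  expect_equal(got$mean_biomass, df$mean_biomass)
  expect_error(read_study_table(path2, schema = c(ph = "nope")),
               "Schema error.*mapped")
})

test_that("se_to_sd rescales by sqrt(n), is idempotent and touches nothing else", {
  rec <- one_record(dispersion = 0.5, dispersion_kind = "se", n = 4L)
  got <- se_to_sd(rec, quiet = TRUE)
  expect_identical(got$dispersion, 1.0) # 0.5 * sqrt(4), by hand
  expect_identical(got$dispersion_kind, "sd")

  rec9 <- one_record(dispersion = 2, dispersion_kind = "se", n = 9L)
  expect_identical(se_to_sd(rec9, quiet = TRUE)$dispersion, 6.0)

  rec0 <- one_record(dispersion = 0, dispersion_kind = "se", n = 5L)
  expect_identical(se_to_sd(rec0, quiet = TRUE)$dispersion, 0)

  once <- se_to_sd(rec, quiet = TRUE)
  twice <- se_to_sd(once, quiet = TRUE)
  expect_identical(once, twice)
  non_disp <- setdiff(names(rec), c("dispersion", "dispersion_kind"))
  expect_identical(got[non_disp], rec[non_disp])
})

test_that("pairing forms one case per complete key and reports the rest", {
  df <- se_to_sd(make_study_df(), quiet = TRUE)
  cases <- pair_comparisons(df)
  expect_equal(nrow(cases), 2L)
  expect_equal(nrow(unpaired_records(cases)), 0L)

  lone <- one_record(n_form = "ammonium")
  got <- suppressMessages(pair_comparisons(lone))
  expect_equal(nrow(got), 0L)
  expect_equal(nrow(unpaired_records(got)), 1L)

  # 6 records, 3 keys, one key missing its nitrate arm -> 2 cases + 1 unpaired
  six <- dplyr::bind_rows(
    make_study_df(),
    one_record(study_id = "S3", n_form = "ammonium"),
    one_record(study_id = "S3", n_form = "ammonium", organ = "root")
  )
  got6 <- suppressMessages(pair_comparisons(six))
  expect_equal(nrow(got6), 2L)
  expect_equal(nrow(unpaired_records(got6)), 2L)
  expect_true(all(unpaired_records(got6)$study_id == "S3"))

  dup <- dplyr::bind_rows(make_study_df(), make_study_df()[1, ])
  expect_error(pair_comparisons(dup), "Ambiguous")
  expect_error(pair_comparisons(one_record(dispersion_kind = "se")),
               "se_to_sd")
})

test_that("paired cases + unpaired keys account for every distinct key", {
  cfg <- sim_config(seed = 11, n_species = 6)
  recs <- se_to_sd(simulate_study_set(cfg), quiet = TRUE)
  # knock out some nitrate arms so unpaired keys exist
  drop <- withr::with_seed(5, sample(which(recs$n_form == "nitrate"), 7))
  recs <- recs[-drop, ]
  cases <- suppressMessages(pair_comparisons(recs))
  n_keys <- nrow(dplyr::distinct(recs[, c("study_id", "species", "cultivar", "organ", "ph")]))
  n_unpaired_keys <- nrow(dplyr::distinct(
    unpaired_records(cases)[, c("study_id", "species", "cultivar", "organ", "ph")]
  ))
  expect_equal(nrow(cases) + n_unpaired_keys, n_keys)
})

test_that("cohen_kappa matches hand values and is transpose-symmetric", {
  expect_identical(cohen_kappa(matrix(c(10, 0, 0, 10), 2)), 1.0)
  expect_identical(cohen_kappa(matrix(c(25, 25, 25, 25), 2)), 0.0)
  # p_o = 0.9, p_e = 0.5 -> kappa = 0.8, by hand
  expect_equal(cohen_kappa(matrix(c(45, 5, 5, 45), 2)), 0.8, tolerance = 1e-12)

  for (s in 1:20) {
    m <- withr::with_seed(s, matrix(rpois(4, 20), 2))
    if (sum(m) == 0) next
    expect_equal(cohen_kappa(m), cohen_kappa(t(m)), tolerance = 1e-12)
  }
  expect_error(cohen_kappa(matrix(c(10, 0, 0, 0), 2)), "degenerate|undefined|Kappa")
  expect_error(cohen_kappa(matrix(c(1, -1, 1, 1), 2)), "nonnegative")
})
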