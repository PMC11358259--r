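# Hand-built study table: two complete ammonium/nitrate comparisons
# (one study x species x organ each) plus knobs for invalid-row tests.
make_study_df <- function() {
  tibble::tibble(
    study_id = c("S1", "S1", "S2", "S2"),
    species = c("Spinacia oleracea", "Spinacia oleracea",
                "Pisum sativum", "Pisum sativum"),
    cultivar = c("Winter-Giant", "Winter-Giant", "Sugar-Snap", "Sugar-Snap"),
    organ = c("shoot", "shoot", "root", "root"),
    n_form = c("ammonium", "nitrate", "ammonium", "nitrate"),
    ph = c(6.0, 6.0, 7.2, 7.2),
    mean_biomass = c(1.2, 3.0, 0.8, 1.0),
    dispersion = c(0.2, 0.5, 0.1, 0.15),
    dispersion_kind = "sd",
    n = c(4L, 4L, 5L, 3L)
  )
}

# one-arm record builder for pairing tests
one_record <- function(study_id = "S9", organ = "shoot", n_form = "ammonium",
                       ph = 6.0, mean_biomass = 1, dispersion = 0.1, n = 3L,
                       species = "Zea mays", cultivar = "",
                       dispersion_kind = "sd") {
  tibble::tibble(
    study_id = study_id, species = species, cultivar = cultivar,
    organ = organ, n_form = n_form, ph = ph, mean_biomass = mean_biomass,
    dispersion = dispersion, dispersion_kind = dispersion_kind, n = n
  )
}

# quick effects table with explicit lnbr/variance for meta tests
make_effects <- function(lnbr, variance, species = "Sp", organ = "shoot",
                         ph = 6) {
  tibble::tibble(
    study_id = sprintf("S%02d", seq_along(lnbr)),
    species = species, cultivar = "", organ = organ, ph = ph,
    lnbr = lnbr, variance = variance
  )
}
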