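#' Configuration for the synthetic-data generators
#'
#' Bundles the ground truth and nuisance parameters for the three generators:
#' hierarchical study sets with species-level true LnBR values and
#' between-study variance `tau2`, trait tables with a prescribed linear
#' relation between Ellenberg nitrogen score and the true effect, and linear
#' 15N-uptake labeling time courses. Every source of randomness flows from
#' `seed` (each generator uses its own offset stream), so identical configs
#' give identical tables.
#'
#' Species-level true effects are drawn once, at configuration time, from
#' `Normal(theta_mean, theta_sd^2)` unless `theta_by_species` is supplied
#' directly (a named vector, names = species).
#'
#' @param seed Integer master seed.
#' @param n_species Number of synthetic species.
#' @param studies_per_species Integer range `c(min, max)` of studies per
#'   species.
#' @param theta_mean,theta_sd Mean and SD of species-level true LnBR values
#'   (defaults -0.6 and 0.6: most species grow worse on ammonium, a few
#'   tolerate it, spanning the range seen across crop species).
#' @param theta_by_species Optional named numeric vector of true effects,
#'   overriding the draw.
#' @param tau2 Between-study variance of true study effects around the
#'   species effect.
#' @param replicate_n Integer range of biological replicates per arm (>= 3,
#'   the inclusion rule).
#' @param cv Within-arm coefficient of variation of replicate biomass.
#' @param ph_mix Proportion of studies run at low pH (< 6.5).
#' @param se_fraction Fraction of rows reporting SE rather than SD, to
#'   exercise normalization.
#' @param trait_model List: `r2` (true fraction of Ellenberg-score variance
#'   explained by the species effect, before rounding to the 1-9 scale),
#'   `slope_n`, `intercept_n`, `slope_r`, `intercept_r` (linear links for the
#'   N and R scores), `nrt2`, `amt2`, `spread` (2-vectors `c(a, b)` of
#'   log-link Poisson coefficients on theta), `npf_log`, `amt1_log`
#'   (constant log-means).
#' @param tracer_model List: `rate` (g 15N per min taken up by the plant),
#'   `translocation` (true shoot share), `noise_sd` (multiplicative Gaussian
#'   noise SD on organ excesses), `times` (harvest minutes), `n_plants`
#'   (plants per time point), `pct_n` (% N of dry weight), `dw_shoot`,
#'   `dw_root` (g), `baseline` (natural-abundance atom% 15N).
#' @return A list of class `sim_config` (with `theta_by_species` resolved).
#' @export
sim_config <- function(seed = 1L,
                       n_species = 10L,
                       studies_per_species = c(2L, 6L),
                       theta_mean = -0.6,
                       theta_sd = 0.6,
                       theta_by_species = NULL,
                       tau2 = 0.1,
                       replicate_n = c(3L, 6L),
                       cv = 0.15,
                       ph_mix = 0.5,
                       se_fraction = 0.25,
                       trait_model = list(),
                       tracer_model = list()) {
  stopifnot(
    tau2 >= 0, cv > 0,
    length(studies_per_species) == 2L,
    studies_per_species[1] >= 1L,
    studies_per_species[2] >= studies_per_species[1],
    length(replicate_n) == 2L, replicate_n[1] >= 3L,
    replicate_n[2] >= replicate_n[1],
    ph_mix >= 0, ph_mix <= 1, se_fraction >= 0, se_fraction <= 1
  )
  trait_defaults <- list(
    r2 = 0.30,
    slope_n = -2.0, intercept_n = 4.5,
    slope_r = -1.5, intercept_r = 5.0,
    nrt2 = c(a = 1.5, b = -0.8),
    amt2 = c(a = 1.2, b = 0.8),
    spread = c(a = 2.0, b = -0.5),
    npf_log = log(45), amt1_log = log(5)
  )
  tracer_defaults <- list(
    rate = 1e-5, translocation = 0.3, noise_sd = 0.05,
    times = c(3, 7, 15, 30), n_plants = 5L,
    pct_n = 4, dw_shoot = 0.5, dw_root = 0.2,
    baseline = 0.3663
  )
  trait_model <- utils::modifyList(trait_defaults, trait_model)
  tracer_model <- utils::modifyList(tracer_defaults, tracer_model)
  stopifnot(
    trait_model$r2 > 0, trait_model$r2 < 1,
    tracer_model$translocation >= 0, tracer_model$translocation <= 1,
    tracer_model$noise_sd >= 0
  )
  seed <- as.integer(seed)
  if (is.null(theta_by_species)) {
    theta_by_species <- withr::with_seed(seed, {
      setNames(
        rnorm(n_species, theta_mean, theta_sd),
        sprintf("Simulatia species%02d", seq_len(n_species))
      )
    })
  } else {
    if (is.null(names(theta_by_species))) {
      names(theta_by_species) <- sprintf("Simulatia species%02d",
                                         seq_along(theta_by_species))
    }
    n_species <- length(theta_by_species)
  }
  structure(
    list(
      seed = seed, n_species = as.integer(n_species),
      studies_per_species = as.integer(studies_per_species),
      theta_by_species = theta_by_species, tau2 = tau2,
      replicate_n = as.integer(replicate_n), cv = cv,
      ph_mix = ph_mix, se_fraction = se_fraction,
      trait_model = trait_model, tracer_model = tracer_model
    ),
    class = "sim_config"
  )
}

# seed offsets keep the three generators on independent reproducible streams
sim_seed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

# sample() treats a length-1 x as 1:x; draw from an integer range safely
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(lo, n) else sample(seq(lo, hi), n, replace = TRUE)
}

#' Simulate a study-level biomass table with known ground truth
#'
#' For each species `s` and study `i`, a true study effect
#' `theta_i ~ Normal(theta_s, tau2)` is drawn; the nitrate arm's true mean
#' biomass is lognormal per organ (root and shoot, so organ aggregation is
#' exercised) and the ammonium arm's true mean is `nitrate * exp(theta_i)`.
#' Observed arm means and SDs are computed from `n` lognormal replicates
#' with the configured coefficient of variation (lognormal keeps biomass
#' strictly positive, the domain of the log ratio; `sigma^2 = log(1+cv^2)`).
#' A configurable fraction of rows report SE instead of SD.
#'
#' @param config A [sim_config()].
#' @return A tibble in the [study_columns] layout that passes
#'   [validate_study_records()] with zero rejections. The ground truth
#'   (species effects and per-study effects) is in `attr(, "truth")`.
#' @export
simulate_study_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sim_seed(config, 1L), {
    theta_s <- config$theta_by_species
    sdlog_rep <- sqrt(log(1 + config$cv^2))
    organ_base <- c(root = 1, shoot = 3)

    # study-level draws
    n_studies <- sample_range(config$studies_per_species[1],
                              config$studies_per_species[2],
                              length(theta_s))
    species_of_study <- rep(names(theta_s), n_studies)
    total <- length(species_of_study)
    study_id <- sprintf("S%04d", seq_len(total))
    theta_i <- rnorm(total, theta_s[species_of_study], sqrt(config$tau2))
    is_low <- runif(total) < config$ph_mix
    ph <- ifelse(is_low, runif(total, 4.5, 6.4), runif(total, 6.5, 8.5))

    # row-level frame: study x organ x arm
    idx <- rep(seq_len(total), each = 4L)
    organ <- rep(rep(names(organ_base), each = 2L), times = total)
    n_form <- rep(c("ammonium", "nitrate"), times = 2L * total)
    m_no3_organ <- rlnorm(2L * total,
                          log(organ_base[rep(names(organ_base), times = total)]),
                          0.3)
    m_no3 <- m_no3_organ[rep(seq_len(2L * total), each = 2L)]
    m_true <- ifelse(n_form == "ammonium", m_no3 * exp(theta_i[idx]), m_no3)
    n_rep <- sample_range(config$replicate_n[1], config$replicate_n[2],
                          length(m_true))
    obs <- mapply(function(m, n) {
      reps <- rlnorm(n, log(m) - sdlog_rep^2 / 2, sdlog_rep)
      c(mean(reps), sd(reps))
    }, m_true, n_rep)
    as_se <- runif(length(m_true)) < config$se_fraction

    out <- tibble::tibble(
      study_id = study_id[idx],
      species = species_of_study[idx],
      cultivar = "",
      organ = organ,
      n_form = n_form,
      ph = ph[idx],
      mean_biomass = obs[1, ],
      dispersion = ifelse(as_se, obs[2, ] / sqrt(n_rep), obs[2, ]),
      dispersion_kind = ifelse(as_se, "se", "sd"),
      n = as.integer(n_rep)
    )
    attr(out, "truth") <- list(
      theta_by_species = theta_s, tau2 = config$tau2,
      studies = tibble::tibble(
        study_id = study_id, species = species_of_study,
        theta_study = theta_i, ph = ph
      )
    )
    out
  })
}

#' Simulate a species trait table linked to the true effects
#'
#' Ellenberg nitrogen and reaction scores are generated from a linear model
#' on the true species effect, `score = a + b * theta + noise`, with the
#' noise SD chosen so the linear relation explains the configured fraction
#' `r2` of the score variance (before rounding and clipping to the 1-9
#' ordinal scale). Gene counts follow log-link Poisson models: NRT2
#' decreasing in theta (sensitive species carry more high-affinity nitrate
#' transporters), AMT2 increasing (tolerant species carry more), NPF and
#' AMT1 unrelated.
#'
#' @param config A [sim_config()].
#' @return A tibble (`species`, `ellenberg_n`, `ellenberg_r`, `spread`,
#'   `npf_count`, `nrt2_count`, `amt1_count`, `amt2_count`) with the
#'   generative parameters and latent (pre-rounding) scores in
#'   `attr(, "truth")`.
#' @export
simulate_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tm <- config$trait_model
  theta <- config$theta_by_species
  n <- length(theta)
  v_theta <- var(theta)
  noise_sd_n <- abs(tm$slope_n) * sqrt(v_theta * (1 - tm$r2) / tm$r2)
  noise_sd_r <- abs(tm$slope_r) * sqrt(v_theta * (1 - tm$r2) / tm$r2)
  clip19 <- function(x) pmin(9, pmax(1, round_half_away(x)))
  withr::with_seed(sim_seed(config, 2L), {
    latent_n <- tm$intercept_n + tm$slope_n * theta + rnorm(n, 0, noise_sd_n)
    latent_r <- tm$intercept_r + tm$slope_r * theta + rnorm(n, 0, noise_sd_r)
    out <- tibble::tibble(
      species = names(theta),
      ellenberg_n = clip19(latent_n),
      ellenberg_r = clip19(latent_r),
      spread = rpois(n, exp(tm$spread[["a"]] + tm$spread[["b"]] * theta)),
      npf_count = rpois(n, exp(tm$npf_log)),
      nrt2_count = rpois(n, exp(tm$nrt2[["a"]] + tm$nrt2[["b"]] * theta)),
      amt1_count = rpois(n, exp(tm$amt1_log)),
      amt2_count = rpois(n, exp(tm$amt2[["a"]] + tm$amt2[["b"]] * theta))
    )
    attr(out, "truth") <- list(
      params = tm, theta = theta,
      latent_n = latent_n, latent_r = latent_r,
      noise_sd_n = noise_sd_n, noise_sd_r = noise_sd_r
    )
    out
  })
}

#' Simulate a 15N labeling time course
#'
#' Plant-total excess 15N grows linearly at the configured uptake rate and is
#' split between shoot and root at the configured translocation fraction;
#' each organ excess then receives independent multiplicative Gaussian
#' noise. Separate plants are generated per harvest time (as in destructive
#' labeling assays), plus baseline plants at time 0 sitting exactly at
#' natural abundance.
#'
#' @param config A [sim_config()].
#' @return A labeling tibble (`plant_id`, `organ`, `time_min`, `atom_pct_t`,
#'   `atom_pct_t0`, `pct_n`, `dw_g`) consumable by [tracer_partition()] and
#'   [uptake_trend()]; truth in `attr(, "truth")`.
#' @export
simulate_tracer <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tm <- config$tracer_model
  withr::with_seed(sim_seed(config, 3L), {
    grid <- expand.grid(
      organ = c("shoot", "root"),
      plant = seq_len(tm$n_plants),
      time_min = c(0, tm$times),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    total_ex <- tm$rate * grid$time_min
    share <- ifelse(grid$organ == "shoot", tm$translocation,
                    1 - tm$translocation)
    ex <- total_ex * share
    if (tm$noise_sd > 0) {
      labeled <- grid$time_min > 0
      ex[labeled] <- ex[labeled] *
        (1 + rnorm(sum(labeled), 0, tm$noise_sd))
    }
    dw <- ifelse(grid$organ == "shoot", tm$dw_shoot, tm$dw_root)
    out <- tibble::tibble(
      plant_id = sprintf("P_t%03d_%02d", round(grid$time_min), grid$plant),
      organ = grid$organ,
      time_min = grid$time_min,
      atom_pct_t = tm$baseline + 100 * ex / (tm$pct_n / 100 * dw),
      atom_pct_t0 = tm$baseline,
      pct_n = tm$pct_n,
      dw_g = dw
    )
    attr(out, "truth") <- tm
    out
  })
}
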