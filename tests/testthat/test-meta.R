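test_that("pH stratification splits at 6.5", {
  expect_equal(as.character(classify_ph(c(6.0, 6.5, 8.0))),
               c("low", "high", "high"))
  expect_error(classify_ph(0), "positive")
})

test_that("DerSimonian-Laird tau2 and Q match hand arithmetic and metafor", {
  # homogeneous group: Q = 0, tau2 = 0
  hom <- estimate_tau2(c(-1, -1, -1), c(0.1, 0.1, 0.1))
  expect_equal(hom$q, 0, tolerance = 1e-12)
  expect_equal(hom$tau2, 0, tolerance = 1e-12)

  # y = {0, 1}, v = {0.1, 0.1}: w = 10 each, fixed mean 0.5,
  # Q = 10*0.25 + 10*0.25 = 5; C = 20 - 200/20 = 10; tau2 = (5-1)/10 = 0.4
  ht <- estimate_tau2(c(0, 1), c(0.1, 0.1))
  expect_equal(ht$q, 5, tolerance = 1e-12)
  expect_equal(ht$tau2, 0.4, tolerance = 1e-12)

  library(metafor)
  for (s in 1:10) {
    dat <- withr::with_seed(s, list(
      y = rnorm(sample(3:12, 1), -0.5, 0.5)
    ))
    dat$v <- withr::with_seed(s + 100, runif(length(dat$y), 0.02, 0.2))
    fit <- rma(yi = dat$y, vi = dat$v, method = "DL")
    ours <- estimate_tau2(dat$y, dat$v)
    pooled <- pool_effects(dat$y, dat$v)
    expect_equal(ours$tau2, fit$tau2, tolerance = 1e-8)
    expect_equal(ours$q, fit$QE, tolerance = 1e-8)
    expect_equal(pooled$estimate, as.numeric(fit$beta), tolerance = 1e-8)
    expect_equal(pooled$se, fit$se, tolerance = 1e-8)
    # REML flag against metafor's REML
    reml <- rma(yi = dat$y, vi = dat$v, method = "REML")
    expect_lt(abs(estimate_tau2(dat$y, dat$v, method = "REML")$tau2 - reml$tau2),
              1e-5)
  }
  expect_error(estimate_tau2(1, 0.1), "two studies")
})

test_that("random-effects pooling behaves on degenerate and symmetric groups", {
  dup <- pool_effects(c(-1, -1), c(0.1, 0.1))
  expect_equal(dup$estimate, -1, tolerance = 1e-12)

  sym <- pool_effects(c(1, -1), c(0.2, 0.2))
  expect_equal(sym$estimate, 0, tolerance = 1e-12)

  degen <- pool_effects(c(0.7, 0.7, 0.7), c(0, 0, 0))
  expect_equal(degen$estimate, 0.7)
  expect_equal(degen$se, 0)

  expect_error(pool_effects(-1, 0.1), "fewer than two")
})

test_that("tau2 = 0 reduces pooling to the fixed-effect inverse-variance mean", {
  for (s in 1:10) {
    y0 <- withr::with_seed(s, rnorm(1))
    y <- rep(y0, 5) # identical effects force Q < k-1, so tau2 truncates to 0
    v <- withr::with_seed(s + 50, runif(5, 0.02, 0.3))
    got <- pool_effects(y, v)
    expect_equal(got$tau2, 0)
    expect_equal(got$estimate, sum(y / v) / sum(1 / v), tolerance = 1e-12)
    # normalized RE weights sum to 1
    w <- 1 / (v + got$tau2)
    expect_equal(sum(w / sum(w)), 1, tolerance = 1e-12)
  }
})

test_that("pooled estimates stay inside the convex hull of the studies", {
  for (s in 1:25) {
    k <- withr::with_seed(s, sample(2:10, 1))
    y <- withr::with_seed(s + 1, rnorm(k, -0.5, 0.8))
    v <- withr::with_seed(s + 2, runif(k, 0.01, 0.3))
    est <- pool_effects(y, v)$estimate
    expect_gte(est, min(y) - 1e-12)
    expect_lte(est, max(y) + 1e-12)
  }
})

test_that("the study-level bootstrap is seeded and collapses when studies agree", {
  ident <- bootstrap_pool(rep(-0.8, 4), rep(0.05, 4), iterations = 200, seed = 1)
  expect_equal(ident$boot_low, -0.8)
  expect_equal(ident$boot_high, -0.8)

  y <- c(-1.2, -0.4, -0.9, 0.1, -0.6)
  v <- c(0.05, 0.08, 0.03, 0.1, 0.06)
  a <- bootstrap_pool(y, v, iterations = 300, seed = 42)
  b <- bootstrap_pool(y, v, iterations = 300, seed = 42)
  expect_identical(a, b)
  c2 <- bootstrap_pool(y, v, iterations = 300, seed = 43)
  expect_false(identical(a$boot_low, c2$boot_low))
  expect_error(bootstrap_pool(-1, 0.1, seed = 1), "two studies")
})

test_that("fail-safe N matches Rosenthal's arithmetic and is monotone in |Z|", {
  # single study at exactly z_alpha: (1.645/1.645)^2 - 1 = 0
  expect_equal(failsafe_n(1.645 * sqrt(0.1), 0.1)$failsafe_n, 0L)
  # three studies each Z = 3.29: (9.87/1.645)^2 - 3 = 33, by hand
  y <- rep(3.29 * sqrt(0.04), 3)
  expect_equal(failsafe_n(y, rep(0.04, 3))$failsafe_n, 33L)
  expect_true(failsafe_n(y, rep(0.04, 3))$robust) # 33 > 5*3 + 10 = 25
  # sum below threshold truncates to 0
  expect_equal(failsafe_n(c(0.01, -0.01), c(0.1, 0.1))$failsafe_n, 0L)
  expect_error(failsafe_n(c(1, 1), c(0.1, 0)), "Zero sampling variance")

  base <- abs(withr::with_seed(7, rnorm(5, 1, 0.3)))
  v <- rep(0.09, 5)
  nfs <- vapply(seq(1, 2, by = 0.25), function(scale) {
    failsafe_n(base * scale, v)$failsafe_n
  }, integer(1))
  expect_true(all(diff(nfs) >= 0))
})

test_that("meta_pool separates pooled groups from reported-only singles", {
  eff <- dplyr::bind_rows(
    make_effects(c(-1.0, -0.8, -1.1), c(0.05, 0.04, 0.06), species = "A"),
    make_effects(-0.2, 0.05, species = "B")
  )
  m <- meta_pool(eff, by = "species", iterations = 50, seed = 3)
  expect_s3_class(m, "lnbr_meta")
  expect_equal(nrow(m$results), 1L)
  expect_equal(m$results$k, 3L)
  expect_true(all(c("boot_low", "boot_high", "failsafe_n") %in% names(m$results)))
  expect_equal(nrow(m$singles), 1L)
  expect_true(m$singles$reported_only)
  expect_equal(tidy(m), m$results)
  expect_equal(glance(m)$k_total, 4L)

  # all-singles input still yields a well-formed empty results table
  all_single <- make_effects(-0.5, 0.05, species = "C")
  m2 <- meta_pool(all_single, by = "species", iterations = 10, seed = 1)
  expect_equal(nrow(m2$results), 0L)
  expect_true(all(c("estimate", "ci_low", "boot_high") %in% names(m2$results)))
  expect_equal(nrow(m2$singles), 1L)

  expect_warning(
    meta_pool(make_effects(c(-1, -2), c(0, 0.1)), by = "species",
              iterations = 0),
    "floored"
  )
})

test_that("95% pooled CIs reach nominal coverage on homogeneous groups", {
  theta <- -0.7
  hits <- vapply(1:500, function(s) {
    withr::with_seed(1000 + s, {
      v <- runif(10, 0.02, 0.1)
      y <- rnorm(10, theta, sqrt(v))
      p <- pool_effects(y, v)
      p$ci_low <= theta && theta <= p$ci_high
    })
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("forest tables sort by estimate and average pooled rows only", {
  empty <- meta_pool(make_effects(numeric(0), numeric(0)), by = "species",
                     iterations = 0)
  expect_equal(nrow(forest_table(empty)), 0L)

  eff <- dplyr::bind_rows(
    make_effects(c(-1.6, -1.8), c(0.05, 0.05), species = "A"),
    make_effects(c(-0.5, -0.3), c(0.05, 0.05), species = "B"),
    make_effects(0.3, 0.05, species = "C")
  )
  m <- meta_pool(eff, by = "species", iterations = 0)
  ft <- forest_table(m)
  body <- ft[ft$flag != "overall", ]
  expect_equal(body$estimate, sort(body$estimate))
  expect_equal(body$flag, c("pooled", "pooled", "reported_only"))
  # overall mean over the two pooled rows only: (-1.7 + -0.4)/2
  expect_equal(ft$estimate[ft$flag == "overall"], (-1.7 + -0.4) / 2,
               tolerance = 1e-12)

  # pH-stratified pooling emits one OVERALL row per pH class
  eff2 <- dplyr::bind_rows(
    make_effects(c(-1, -0.9), c(0.05, 0.05), species = "A", ph = 6),
    make_effects(c(-0.2, -0.1), c(0.05, 0.05), species = "A", ph = 8)
  )
  m2 <- meta_pool(eff2, by = c("species", "ph_class"), iterations = 0)
  ft2 <- forest_table(m2)
  expect_setequal(ft2$label[ft2$flag == "overall"],
                  c("OVERALL LOW", "OVERALL HIGH"))
})
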