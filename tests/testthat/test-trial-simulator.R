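test_that("degenerate variances give phenotype = mean + replicate offset", {
  cfg <- sim_config(n_subraces = 3, families_per_subrace = 4,
    trees_per_family = 3, n_replicates = 3, n_iblocks_per_replicate = 2,
    trait_names = "y", grand_means = 7,
    sigma2_subrace = 0, sigma2_family = 0, sigma2_iblock = 0,
    sigma2_resid = 1e-300, replicate_effects = matrix(c(-1, 0, 1), 3, 1),
    seed = 4)
  tab <- simulate_trial(cfg)
  expected <- 7 + c(r1 = -1, r2 = 0, r3 = 1)[tab$replicate]
  expect_equal(tab$y, unname(expected), tolerance = 1e-6)
})

test_that("the draw is reproducible and respects the design invariants", {
  cfg <- small_config(seed = 99)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1, t2)

  # at most one tree per family per replicate
  expect_false(any(duplicated(t1[, c("family", "replicate")])))
  # each family maps to exactly one subrace
  expect_true(all(tapply(t1$subrace, t1$family,
    function(s) length(unique(s))) == 1L))
  # family count and tree count match the config
  expect_equal(length(unique(t1$family)), 60L)
  expect_equal(nrow(t1), 60L * 4L)
  # iblock labels stay within the configured range
  expect_lte(length(unique(t1$iblock)), cfg$n_iblocks_per_replicate)
})

test_that("empirical moments match the configured variance components", {
  # family-level check: variance of family effects recovered from family
  # mean deviations within subrace, pooled over replicate simulations
  n_rep <- 120
  s2f_hat <- vapply(seq_len(n_rep), function(i) {
    cfg <- sim_config(n_subraces = 5, families_per_subrace = 12,
      trees_per_family = 5, n_replicates = 5, n_iblocks_per_replicate = 4,
      trait_names = "y", grand_means = 0, sigma2_subrace = 0.27,
      sigma2_family = 0.05, sigma2_iblock = 0, sigma2_resid = 0.7,
      replicate_effects = matrix(0, 5, 1), seed = 1000 + i)
    tab <- simulate_trial(cfg)
    fm <- tapply(tab$y, tab$family, mean)
    sub_of_fam <- tapply(tab$subrace, tab$family, `[`, 1L)
    dev <- fm - tapply(fm, sub_of_fam, mean)[sub_of_fam]
    # between-family mean square within subraces minus residual share
    k <- 5
    sum(dev^2) / (length(fm) - 5) - 0.7 / k
  }, numeric(1))
  mc_se <- sd(s2f_hat) / sqrt(n_rep)
  expect_lt(abs(mean(s2f_hat) - 0.05), 3 * mc_se)

  # law of total variance on one large draw (no replicate offsets)
  cfg <- sim_config(n_subraces = 40, families_per_subrace = 30,
    trees_per_family = 5, n_replicates = 5, n_iblocks_per_replicate = 10,
    trait_names = "y", grand_means = 0, sigma2_subrace = 0.3,
    sigma2_family = 0.2, sigma2_iblock = 0.1, sigma2_resid = 1,
    replicate_effects = matrix(0, 5, 1), seed = 7)
  tab <- simulate_trial(cfg)
  expect_equal(var(tab$y), 1.6, tolerance = 0.12)
})

test_that("the latitudinal cline is recovered from subrace means", {
  cfg <- sim_config(n_subraces = 12, families_per_subrace = 20,
    trees_per_family = 4, n_replicates = 4, n_iblocks_per_replicate = 4,
    trait_names = "y", grand_means = 2, sigma2_subrace = 0,
    sigma2_family = 0.005, sigma2_iblock = 0, sigma2_resid = 0.02,
    latitude_slope = 0.04, latitudes = seq(37, 44, length.out = 12),
    seed = 21)
  tab <- simulate_trial(cfg)
  m <- tapply(tab$y, tab$subrace, mean)
  lat <- subrace_latitudes(tab)
  fit <- regress_on_latitude(m, lat)
  expect_equal(fit$slope, 0.04, tolerance = 0.25) # ~3 sampling SEs
  expect_gt(fit$r_squared, 75)
})

test_that("cross-trait family correlations converge to the configured matrix", {
  rho <- 0.6
  cfg <- sim_config(n_subraces = 6, families_per_subrace = 60,
    trees_per_family = 5, n_replicates = 5, n_iblocks_per_replicate = 4,
    trait_names = c("a", "b"), grand_means = c(0, 0),
    sigma2_subrace = 1e-12, sigma2_family = 1, sigma2_iblock = 1e-12,
    sigma2_resid = 0.01, corr_family = matrix(c(1, rho, rho, 1), 2),
    replicate_effects = matrix(0, 5, 2), seed = 31)
  tab <- simulate_trial(cfg)
  fa <- tapply(tab$a, tab$family, mean)
  fb <- tapply(tab$b, tab$family, mean)
  expect_equal(unname(cor(fa, fb)), rho, tolerance = 0.1)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(trees_per_family = 6, n_replicates = 5),
    "one tree per")
  expect_error(sim_config(sigma2_resid = 0), "strictly positive")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  bad <- matrix(c(1, 2, 2, 1), 2) # not PSD as a correlation matrix
  cfg <- sim_config(trait_names = c("a", "b"), grand_means = c(0, 0),
    corr_family = bad, seed = 1)
  expect_error(simulate_trial(cfg), "family")
})

test_that("measurement-error overlay calibrates the reliability", {
  cfg <- sim_config(n_subraces = 8, families_per_subrace = 50,
    trees_per_family = 5, n_replicates = 5, n_iblocks_per_replicate = 6,
    trait_names = "y", grand_means = 3, sigma2_subrace = 0.05,
    sigma2_family = 0.2, sigma2_iblock = 0.01, sigma2_resid = 0.8,
    seed = 13)
  tab <- simulate_trial(cfg)

  # reliability 1: identical column
  t1 <- overlay_measurement_error(tab, "y", 1, seed = 2)
  expect_identical(t1$y_pred, t1$y)

  # reliability 0.5: empirical squared correlation ~ 0.5
  t2 <- overlay_measurement_error(tab, "y", 0.5, seed = 3)
  expect_equal(cor(t2$y, t2$y_pred)^2, 0.5, tolerance = 0.05)

  expect_error(overlay_measurement_error(tab, "y", 0, seed = 1),
    "reliability")
  expect_error(overlay_measurement_error(tab, "zz", 0.5, seed = 1),
    "not found")
})

test_that("missingness masks cells at the requested binomial rate", {
  cfg <- small_config(seed = 5)
  tab <- simulate_trial(cfg)
  expect_identical(apply_missingness(tab, 0, seed = 1), tab)

  big <- do.call(rbind, replicate(42, tab, simplify = FALSE)) # 10080 cells
  m <- apply_missingness(big, 0.1, seed = 8)
  n_missing <- sum(is.na(m$y))
  expect_lt(abs(n_missing - 0.1 * nrow(big)),
    4 * sqrt(nrow(big) * 0.1 * 0.9))
  # design columns untouched
  expect_false(anyNA(m$family))
  expect_error(apply_missingness(tab, 0.6, seed = 1), "rate")
})
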