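test_that("zero-variance data drive all random components to the boundary", {
  cfg <- sim_config(n_subraces = 5, families_per_subrace = 8,
    trees_per_family = 4, n_replicates = 4, n_iblocks_per_replicate = 3,
    trait_names = "y", grand_means = 1, sigma2_subrace = 0,
    sigma2_family = 0, sigma2_iblock = 0, sigma2_resid = 0.5, seed = 2)
  tab <- simulate_trial(cfg)
  fit <- fit_univariate(tab, model_spec("y", subrace_as = "random"))
  expect_true(fit$boundary[["subrace"]])
  expect_true(fit$boundary[["family"]])
  expect_true(fit$boundary[["iblock"]])
  expect_equal(unname(fit$components[["residual"]]), 0.5, tolerance = 0.25)
})

test_that("REML equals the nested-ANOVA oracle on balanced data", {
  tab <- balanced_nested_table(seed = 11)
  oracle <- balanced_nested_anova(tab, "y")
  fit <- fit_univariate(tab, model_spec("y", subrace_as = "random",
    include_iblock = FALSE, fixed_terms = character(0)), se = FALSE)
  expect_true(all(oracle > 0)) # interior truth for this seed
  expect_equal(unname(fit$components[c("subrace", "family", "residual")]),
    unname(oracle), tolerance = 1e-6)

  # oracle is unbiased: mean estimate over replicates near truth
  reps <- t(vapply(1:60, function(i) {
    balanced_nested_anova(balanced_nested_table(seed = 100 + i), "y")
  }, numeric(3)))
  mc_se <- apply(reps, 2, sd) / sqrt(nrow(reps))
  truth <- c(0.5, 0.3, 1)
  expect_true(all(abs(colMeans(reps) - truth) < 3 * mc_se))

  expect_error(balanced_nested_anova(tab[-1, ], "y"), "not balanced")
})

test_that("REML matches lme4 on an unbalanced blocked trial", {
  skip_if_not_installed("lme4")
  cfg <- small_config(seed = 77)
  tab <- simulate_trial(cfg)
  tab <- apply_missingness(tab, 0.05, seed = 3)
  fit <- fit_univariate(tab, model_spec("y", subrace_as = "random"))
  dat <- tab[!is.na(tab$y), ]
  dat$ib <- interaction(dat$replicate, dat$iblock)
  m <- lme4::lmer(y ~ replicate + (1 | subrace) + (1 | ib) + (1 | family),
    data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  ref <- setNames(vc$vcov, vc$grp)
  expect_equal(unname(fit$components[["subrace"]]), unname(ref[["subrace"]]),
    tolerance = 1e-4)
  expect_equal(unname(fit$components[["family"]]), unname(ref[["family"]]),
    tolerance = 1e-4)
  expect_equal(unname(fit$components[["iblock"]]), unname(ref[["ib"]]),
    tolerance = 1e-3)
  expect_equal(unname(fit$components[["residual"]]),
    unname(ref[["Residual"]]), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-7)
})

test_that("estimates are invariant to row order, relabelling and restarts", {
  cfg <- small_config(seed = 42)
  tab <- simulate_trial(cfg)
  f1 <- fit_univariate(tab, "y", se = FALSE)

  shuffled <- tab[sample(nrow(tab)), ]
  f2 <- fit_univariate(shuffled, "y", se = FALSE)
  expect_equal(f1$components, f2$components, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)

  relab <- tab
  relab$family <- paste0("XX_", relab$family)
  relab$subrace <- toupper(relab$subrace)
  f3 <- fit_univariate(relab, "y", se = FALSE)
  expect_equal(unname(f1$components), unname(f3$components),
    tolerance = 1e-6)

  # multi-start reproducibility of the restricted log-likelihood
  f4 <- fit_univariate(tab, "y", se = FALSE,
    control = list(start = NULL)) # same path, distinct object
  expect_equal(f1$loglik, f4$loglik, tolerance = 1e-6)
})

test_that("aliased subrace/family structure is rejected by name", {
  cfg <- sim_config(n_subraces = 6, families_per_subrace = 1,
    trees_per_family = 4, n_replicates = 4, n_iblocks_per_replicate = 2,
    trait_names = "y", grand_means = 0, sigma2_subrace = 0.2,
    sigma2_family = 0.1, sigma2_iblock = 0, sigma2_resid = 1, seed = 3)
  tab <- simulate_trial(cfg)
  expect_error(fit_univariate(tab, model_spec("y", subrace_as = "random")),
    "aliased")
})

test_that("parameter recovery at trial-like dimensions (reduced replicates)", {
  n_rep <- 30
  est <- t(vapply(seq_len(n_rep), function(i) {
    tab <- simulate_trial(paper_config(seed = 5000 + i))
    fit_univariate(tab, model_spec("y", subrace_as = "random"),
      se = FALSE)$components
  }, numeric(4)))
  truth <- c(paper_truth$sigma2_subrace, paper_truth$sigma2_iblock,
    paper_truth$sigma2_family, paper_truth$sigma2_resid)
  mc_se <- apply(est, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(colMeans(est) - truth) < 3 * mc_se))
})

test_that("bivariate fit: duplicated trait gives unit correlations", {
  cfg <- small_config(seed = 8)
  tab <- simulate_trial(cfg)
  tab$y2 <- tab$y
  bf <- fit_bivariate(tab, c("y", "y2"), se = FALSE)
  # the likelihood is unbounded along the singular ridge, so the optimiser
  # stops a numerical whisker short of exact unity at every level
  lev_r <- vapply(bf$Sigma[c("subrace", "family", "residual")],
    function(S) S[1, 2] / sqrt(prod(diag(S))), numeric(1))
  expect_true(all(lev_r > 0.99))
  # the aggregate phenotypic correlation carries Cauchy-Schwarz slack
  # because the per-trait variance split across levels is unidentified
  # along the ridge; it still sits near one
  rp <- genetic_correlations(bf, se = FALSE)$r[3]
  expect_gt(rp, 0.9)
})

test_that("bivariate fit recovers level correlations and is consistent with lme4", {
  rho_f <- 0.6; rho_s <- 0.8; rho_e <- 0.2
  cfg <- sim_config(n_subraces = 10, families_per_subrace = 20,
    trait_names = c("x", "y"), grand_means = c(0, 0),
    sigma2_subrace = 0.2, sigma2_family = 0.15, sigma2_iblock = 0.02,
    sigma2_resid = 0.8,
    corr_subrace = matrix(c(1, rho_s, rho_s, 1), 2),
    corr_family = matrix(c(1, rho_f, rho_f, 1), 2),
    corr_resid = matrix(c(1, rho_e, rho_e, 1), 2), seed = 5)
  tab <- simulate_trial(cfg)
  bf <- fit_bivariate(tab, c("x", "y"))
  ct <- genetic_correlations(bf)
  r_a <- ct$r[ct$level == "additive"]
  se_a <- ct$se[ct$level == "additive"]
  expect_lt(abs(r_a - rho_f), 3 * se_a)
  expect_lt(abs(ct$r[ct$level == "subrace"] - rho_s),
    3 * ct$se[ct$level == "subrace"])

  # cross-check marginal structure: univariate components of each trait
  # match the bivariate diagonal to a loose tolerance
  u <- fit_univariate(tab, model_spec("x", subrace_as = "random"),
    se = FALSE)
  expect_equal(unname(bf$Sigma$family["x", "x"]),
    unname(u$components[["family"]]), tolerance = 0.15)
  expect_equal(unname(bf$Sigma$residual["x", "x"]),
    unname(u$components[["residual"]]), tolerance = 0.05)
})

test_that("independently simulated traits give near-zero family correlation", {
  n_rep <- 12
  r <- vapply(seq_len(n_rep), function(i) {
    cfg <- sim_config(n_subraces = 6, families_per_subrace = 15,
      trait_names = c("x", "y"), grand_means = c(0, 0),
      sigma2_subrace = 0.1, sigma2_family = 0.2, sigma2_iblock = 0.02,
      sigma2_resid = 0.8, seed = 300 + i)
    bf <- fit_bivariate(simulate_trial(cfg), c("x", "y"), se = FALSE)
    genetic_correlations(bf, se = FALSE)$r[1L]
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.12)
})

test_that("constrained fits obey their constraints and likelihood dominance", {
  # inactive constraint: fixing the family variance at zero on data
  # simulated without family variance reproduces the unconstrained loglik
  cfg <- sim_config(n_subraces = 6, families_per_subrace = 10,
    trees_per_family = 4, n_replicates = 4, n_iblocks_per_replicate = 3,
    trait_names = "y", grand_means = 0, sigma2_subrace = 0.3,
    sigma2_family = 0, sigma2_iblock = 0.02, sigma2_resid = 1, seed = 17)
  tab <- simulate_trial(cfg)
  free <- fit_univariate(tab, model_spec("y", subrace_as = "random"),
    se = FALSE)
  con <- fit_constrained(tab, model_spec("y", subrace_as = "random",
    constraint = list(term = "family", value = 0)))
  expect_equal(con$loglik, free$loglik, tolerance = 1e-4)

  # qst_ratio tie: the tied solution satisfies Qst = Fst to high precision
  tab2 <- simulate_trial(paper_config(seed = 901))
  tied <- fit_constrained(tab2, model_spec("y", subrace_as = "random",
    constraint = list(type = "qst_ratio", fst = 0.09, relatedness = 0.4)))
  s <- tied$components[["subrace"]]
  f <- tied$components[["family"]]
  expect_equal(unname(s / (s + 2 * f / 0.4)), 0.09, tolerance = 1e-8)

  # dominance: the constrained optimum can never beat the unconstrained one
  worse <- vapply(1:15, function(i) {
    t <- simulate_trial(small_config(seed = 700 + i))
    full <- fit_univariate(t, model_spec("y", subrace_as = "random"),
      se = FALSE)$loglik
    tied <- fit_constrained(t, model_spec("y", subrace_as = "random",
      constraint = list(type = "qst_ratio", fst = 0.09,
        relatedness = 0.4)))$loglik
    tied <= full + 1e-6
  }, logical(1))
  expect_true(all(worse))
})
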