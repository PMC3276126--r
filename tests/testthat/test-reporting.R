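test_that("phenotype CSV round-trip preserves values and missingness", {
  tab <- simulate_trial(small_config(seed = 3))
  tab <- apply_missingness(tab, 0.1, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(tab, path)
  back <- read_phenotypes(path)
  expect_equal(back$y, tab$y)
  expect_identical(back$family, tab$family)
  expect_identical(which(is.na(back$y)), which(is.na(tab$y)))
})

test_that("malformed phenotype input is rejected", {
  tab <- simulate_trial(small_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")

  # missing required column
  write_phenotypes(tab[, setdiff(names(tab), "family")], path)
  expect_error(read_phenotypes(path), "family")

  # duplicate tree ids
  dup <- tab
  dup$tree_id[2] <- dup$tree_id[1]
  write_phenotypes(dup, path)
  expect_error(read_phenotypes(path), "duplicate")

  # a family mapped to two subraces
  bad <- tab
  bad$subrace[bad$family == bad$family[1]][1] <- "sXX"
  write_phenotypes(bad, path)
  expect_error(read_phenotypes(path), "more than one subrace")
})

test_that("a minimal hand-written fixture parses", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "tree_id,subrace,family,replicate,iblock,plot,y",
    "t1,A,A_f1,r1,b1,p1,1.0",
    "t2,A,A_f1,r2,b1,p1,1.2",
    "t3,A,A_f2,r1,b2,p1,0.9",
    "t4,A,A_f2,r2,b2,p1,",
    "t5,B,B_f1,r1,b1,p2,2.0",
    "t6,B,B_f1,r2,b1,p2,2.1",
    "t7,B,B_f2,r1,b2,p2,1.8",
    "t8,B,B_f2,r2,b2,p2,2.2"
  ), path)
  tab <- read_phenotypes(path)
  expect_equal(nrow(tab), 8L)
  expect_equal(length(unique(tab$subrace)), 2L)
  expect_true(is.na(tab$y[4]))
})

test_that("sim config YAML round trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_subraces: 4",
    "families_per_subrace: 6",
    "trees_per_family: 3",
    "n_replicates: 3",
    "n_iblocks_per_replicate: 2",
    "trait_names: tr",
    "grand_means: 5.0",
    "sigma2_subrace: 0.1",
    "sigma2_family: 0.1",
    "sigma2_iblock: 0.01",
    "sigma2_resid: 0.5",
    "seed: 12"
  ), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  tab <- simulate_trial(cfg)
  expect_equal(length(unique(tab$family)), 24L)

  writeLines("n_subraces: 4", path)
  expect_error(read_sim_config(path), "seed")
})

test_that("run_full_analysis produces a complete, deterministic bundle", {
  cfg <- sim_config(n_subraces = 6, families_per_subrace = 10,
    trees_per_family = 4, n_replicates = 4, n_iblocks_per_replicate = 4,
    trait_names = c("u", "v"), grand_means = c(2, 10),
    sigma2_subrace = c(0.1, 0.5), sigma2_family = c(0.08, 0.4),
    sigma2_iblock = 0.01, sigma2_resid = c(0.3, 1.5),
    corr_family = matrix(c(1, 0.5, 0.5, 1), 2),
    latitude_slope = c(0.05, 0), seed = 1)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  ac <- analysis_config(cfg, output_dir = out1, seed = 77)
  bundle <- run_full_analysis(ac)

  expect_false(bundle$partial)
  expect_equal(nrow(bundle$genetic_params), 2L)
  expect_setequal(unique(bundle$divergence_tests$test),
    c("family_variance", "qst_gt_fst"))
  expect_equal(sum(bundle$divergence_tests$test == "qst_gt_fst"), 4L)
  expect_equal(nrow(bundle$correlations), 3L) # one pair, three levels
  expect_equal(nrow(bundle$cline), 2L)
  expect_true(all(file.exists(file.path(out1,
    c("genetic_params.csv", "correlations.csv", "divergence_tests.csv",
      "cline.csv", "summary.json", "run_log.txt")))))

  # rerun with the same seed: byte-identical numeric outputs
  run_full_analysis(analysis_config(cfg, output_dir = out2, seed = 77))
  for (f in c("genetic_params.csv", "correlations.csv",
    "divergence_tests.csv", "cline.csv", "summary.json")) {
    expect_identical(readLines(file.path(out1, f)),
      readLines(file.path(out2, f)), label = f)
  }
})

test_that("single-trait config yields an empty correlation table", {
  cfg <- sim_config(n_subraces = 5, families_per_subrace = 8,
    trees_per_family = 4, n_replicates = 4, n_iblocks_per_replicate = 3,
    trait_names = "y", grand_means = 1, sigma2_subrace = 0.2,
    sigma2_family = 0.1, sigma2_iblock = 0.01, sigma2_resid = 0.6,
    seed = 2)
  bundle <- run_full_analysis(analysis_config(cfg, seed = 5))
  expect_null(bundle$correlations)
  expect_gt(nrow(bundle$genetic_params), 0L)
})
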