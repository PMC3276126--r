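# Shared simulation configurations for the test suite.
#
# small_config: a compact trial (few subraces/families) for fast unit tests.
# paper_config: the trial dimensions of the motivating study design
#   (17 subraces x 27 families x 5 trees over 5 replicates x 24 blocks)
#   with truth set to Qst = 0.35, h2_op = 0.44 at relatedness r = 0.4:
#   sigma2_family = 0.176, sigma2_resid = 0.824 (so family + resid = 1),
#   sigma2_add = 0.44, sigma2_subrace = 0.35/0.65 * 2 * 0.44.

small_config <- function(seed, ...) {
  sim_config(
    n_subraces = 6L, families_per_subrace = 10L, trees_per_family = 4L,
    n_replicates = 4L, n_iblocks_per_replicate = 6L,
    trait_names = "y", grand_means = 10,
    sigma2_subrace = 0.3, sigma2_family = 0.2, sigma2_iblock = 0.05,
    sigma2_resid = 1, seed = seed, ...
  )
}

paper_truth <- list(
  h2 = 0.44, qst = 0.35, r = 0.4,
  sigma2_family = 0.176,
  sigma2_resid = 0.824,
  sigma2_iblock = 0.02,
  sigma2_subrace = 0.35 / 0.65 * 2 * 0.44
)

paper_config <- function(seed, ...) {
  args <- list(
    n_subraces = 17L, families_per_subrace = 27L, trees_per_family = 5L,
    n_replicates = 5L, n_iblocks_per_replicate = 24L,
    trait_names = "y", grand_means = 2,
    sigma2_subrace = paper_truth$sigma2_subrace,
    sigma2_family = paper_truth$sigma2_family,
    sigma2_iblock = paper_truth$sigma2_iblock,
    sigma2_resid = paper_truth$sigma2_resid,
    seed = seed
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# balanced nested data with no block structure, for the ANOVA oracle
balanced_nested_table <- function(seed, n_sub = 8L, n_fam = 6L, n_tree = 5L,
                                  s2_s = 0.5, s2_f = 0.3, s2_e = 1) {
  set.seed(seed)
  sub <- rep(seq_len(n_sub), each = n_fam * n_tree)
  fam <- rep(seq_len(n_sub * n_fam), each = n_tree)
  y <- 5 +
    rnorm(n_sub, 0, sqrt(s2_s))[sub] +
    rnorm(n_sub * n_fam, 0, sqrt(s2_f))[fam] +
    rnorm(length(sub), 0, sqrt(s2_e))
  data.frame(
    tree_id = sprintf("t%04d", seq_along(sub)),
    subrace = sprintf("s%02d", sub),
    family = sprintf("s%02d_f%03d", sub, fam),
    replicate = "r1",
    iblock = "b1",
    plot = "p1",
    y = y,
    stringsAsFactors = FALSE
  )
}
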