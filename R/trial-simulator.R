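#' Configure a synthetic open-pollinated progeny trial
#'
#' Builds the true-parameter set for [simulate_trial()].  The defaults
#' emulate a range-wide base-population trial of open-pollinated families
#' laid out as a resolvable incomplete block design: 17 subraces, 27
#' families per subrace, 5 trees per family with one tree per replicate, 5
#' replicates each split into 24 incomplete blocks of two-tree family
#' plots.  The default single trait is a syringyl-to-guaiacyl-like lignin
#' ratio with grand mean 1.97 and variance components chosen so that the
#' open-pollinated narrow-sense heritability is 0.44 and Qst is 0.34 under
#' a relatedness coefficient of 0.4.
#'
#' Variances are per-trait vectors on the trait scale squared.
#' `sigma2_subrace` is the variance of subrace deviations *around* the
#' latitudinal cline, so with a nonzero `latitude_slope` the total
#' between-subrace variance is `sigma2_subrace + latitude_slope^2 *
#' var(latitudes)`.  Latitudes are decimal degrees South (positive
#' magnitudes increasing southward).
#'
#' @param n_subraces number of subraces.
#' @param families_per_subrace scalar or length-`n_subraces` vector of
#'   family counts.
#' @param trees_per_family trees sampled per family, each in a distinct
#'   replicate; must not exceed `n_replicates`.
#' @param n_replicates,n_iblocks_per_replicate field layout.
#' @param trait_names character vector of trait names.
#' @param grand_means,sigma2_subrace,sigma2_family,sigma2_iblock,sigma2_resid
#'   per-trait means and variance components (recycled to the number of
#'   traits).  All variances must be non-negative and `sigma2_resid`
#'   strictly positive.
#' @param corr_subrace,corr_family,corr_resid trait-by-trait correlation
#'   matrices for the multi-trait deviates at each level (incomplete-block
#'   deviates are drawn independently across traits).
#' @param latitude_slope per-trait cline slope, trait units per degree of
#'   latitude (applied to latitude centred on its mean).
#' @param latitudes per-subrace latitude of origin, degrees South.
#' @param replicate_effects optional `n_replicates` by traits matrix of
#'   fixed replicate offsets; the default is equally spaced offsets
#'   spanning +/- 0.5 residual standard deviations.
#' @param missing_rate completely-at-random per-cell missingness applied to
#'   trait columns, in `[0, 1)`.
#' @param seed integer seed making the draw reproducible.
#'
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(seed = 42)
#' str(cfg$trait_names)
#' @export
sim_config <- function(n_subraces = 17L,
                       families_per_subrace = 27L,
                       trees_per_family = 5L,
                       n_replicates = 5L,
                       n_iblocks_per_replicate = 24L,
                       trait_names = "SG",
                       grand_means = 1.97,
                       sigma2_subrace = 0.00206,
                       sigma2_family = 0.0008,
                       sigma2_iblock = 0.00023,
                       sigma2_resid = 0.003745,
                       corr_subrace = NULL,
                       corr_family = NULL,
                       corr_resid = NULL,
                       latitude_slope = 0,
                       latitudes = NULL,
                       replicate_effects = NULL,
                       missing_rate = 0,
                       seed = 1L) {
  nt <- length(trait_names)
  rec <- function(x) {
    if (length(x) == 1L) rep(x, nt) else x
  }
  grand_means <- rec(grand_means)
  sigma2_subrace <- rec(sigma2_subrace)
  sigma2_family <- rec(sigma2_family)
  sigma2_iblock <- rec(sigma2_iblock)
  sigma2_resid <- rec(sigma2_resid)
  latitude_slope <- rec(latitude_slope)
  lens <- lengths(list(grand_means, sigma2_subrace, sigma2_family,
    sigma2_iblock, sigma2_resid, latitude_slope))
  if (any(lens != nt)) {
    stop("per-trait parameter vectors must have length 1 or length(trait_names)",
      call. = FALSE)
  }
  if (any(c(sigma2_subrace, sigma2_family, sigma2_iblock) < 0) ||
      any(sigma2_resid <= 0)) {
    stop("variances must be non-negative and sigma2_resid strictly positive",
      call. = FALSE)
  }
  if (length(families_per_subrace) == 1L) {
    families_per_subrace <- rep(families_per_subrace, n_subraces)
  }
  stopifnot(length(families_per_subrace) == n_subraces,
    all(families_per_subrace >= 1L))
  if (trees_per_family > n_replicates) {
    stop("trees_per_family exceeds n_replicates: cannot place one tree per ",
      "family per replicate", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  ident <- diag(nt)
  dimnames(ident) <- list(trait_names, trait_names)
  if (is.null(corr_subrace)) corr_subrace <- ident
  if (is.null(corr_family)) corr_family <- ident
  if (is.null(corr_resid)) corr_resid <- ident
  for (nm in c("corr_subrace", "corr_family", "corr_resid")) {
    C <- get(nm)
    if (!is.matrix(C) || any(dim(C) != nt) || any(abs(diag(C) - 1) > 1e-8) ||
        any(abs(C - t(C)) > 1e-8)) {
      stop(nm, " must be a symmetric unit-diagonal ", nt, "x", nt, " matrix",
        call. = FALSE)
    }
  }
  if (is.null(latitudes)) {
    latitudes <- seq(38.5, 43.5, length.out = n_subraces)
  }
  if (any(latitude_slope != 0) && length(latitudes) != n_subraces) {
    stop("latitudes must have one entry per subrace when latitude_slope is ",
      "nonzero", call. = FALSE)
  }
  structure(
    list(
      n_subraces = as.integer(n_subraces),
      families_per_subrace = as.integer(families_per_subrace),
      trees_per_family = as.integer(trees_per_family),
      n_replicates = as.integer(n_replicates),
      n_iblocks_per_replicate = as.integer(n_iblocks_per_replicate),
      trait_names = trait_names,
      grand_means = grand_means,
      sigma2_subrace = sigma2_subrace,
      sigma2_family = sigma2_family,
      sigma2_iblock = sigma2_iblock,
      sigma2_resid = sigma2_resid,
      corr_subrace = corr_subrace,
      corr_family = corr_family,
      corr_resid = corr_resid,
      latitude_slope = latitude_slope,
      latitudes = latitudes,
      replicate_effects = replicate_effects,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# symmetric square root of a correlation matrix; rejects indefinite input
.corr_root <- function(C, level) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop("correlation matrix at the ", level,
      " level is not positive semi-definite", call. = FALSE)
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# n x traits matrix of correlated deviates with per-trait variances sig2
.mvn_deviates <- function(n, sig2, corr, level) {
  nt <- length(sig2)
  Z <- matrix(stats::rnorm(n * nt), n, nt)
  Z <- Z %*% .corr_root(corr, level)
  sweep(Z, 2L, sqrt(sig2), `*`)
}

#' Simulate an open-pollinated progeny trial
#'
#' Draws a phenotype table from the generative model
#' `phenotype = grand mean + cline + subrace deviate + family deviate +
#' replicate offset + incomplete-block deviate + residual`, with
#' multi-trait deviates at the subrace, family and residual levels drawn
#' from the configured correlation structures.  All random effects are
#' normal; replicate effects are fixed offsets; families are assigned to
#' incomplete blocks at random within each replicate; each family
#' contributes at most one tree per replicate.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with columns `tree_id`, `subrace`, `family`,
#'   `replicate`, `iblock`, `plot` and one column per trait.  The
#'   per-subrace latitudes are attached as attribute `"latitudes"` (a
#'   `data.frame` with columns `subrace`, `latitude_deg`) and the config as
#'   attribute `"sim_config"`.
#' @examples
#' tab <- simulate_trial(sim_config(n_subraces = 4, families_per_subrace = 6,
#'   seed = 7))
#' head(tab)
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- length(config$trait_names)
  S <- config$n_subraces
  fams <- config$families_per_subrace
  Ftot <- sum(fams)
  tpf <- config$trees_per_family
  R <- config$n_replicates
  B <- config$n_iblocks_per_replicate

  sub_ids <- sprintf("s%02d", seq_len(S))
  fam_sub <- rep(seq_len(S), fams)
  fam_ids <- sprintf("%s_f%03d", sub_ids[fam_sub], unlist(lapply(fams, seq_len)))

  # level deviates
  dev_sub <- .mvn_deviates(S, config$sigma2_subrace, config$corr_subrace,
    "subrace")
  dev_fam <- .mvn_deviates(Ftot, config$sigma2_family, config$corr_family,
    "family")
  dev_ib <- array(stats::rnorm(R * B * nt), c(R * B, nt))
  dev_ib <- sweep(dev_ib, 2L, sqrt(config$sigma2_iblock), `*`)

  rep_eff <- config$replicate_effects
  if (is.null(rep_eff)) {
    off <- if (R > 1L) seq(-0.5, 0.5, length.out = R) else 0
    rep_eff <- outer(off, sqrt(config$sigma2_resid))
  }
  rep_eff <- matrix(rep_eff, R, nt)

  lat <- config$latitudes
  cline <- outer(lat - mean(lat), config$latitude_slope)

  # replicate membership: which replicates carry a tree of each family
  fam_reps <- lapply(seq_len(Ftot), function(i) {
    if (tpf == R) seq_len(R) else sort(sample.int(R, tpf))
  })

  # random family-to-iblock assignment per replicate
  plots_per_block <- ceiling(Ftot / B)
  assign_rep <- lapply(seq_len(R), function(r) {
    ord <- sample.int(Ftot)
    blk <- integer(Ftot)
    plt <- integer(Ftot)
    blk[ord] <- ((seq_len(Ftot) - 1L) %/% plots_per_block) + 1L
    plt[ord] <- ((seq_len(Ftot) - 1L) %% plots_per_block) + 1L
    list(block = blk, plot = plt)
  })

  fam_idx <- rep(seq_len(Ftot), each = tpf)
  rep_idx <- unlist(fam_reps)
  sub_idx <- fam_sub[fam_idx]
  blk_idx <- mapply(function(f, r) assign_rep[[r]]$block[f], fam_idx, rep_idx)
  plt_idx <- mapply(function(f, r) assign_rep[[r]]$plot[f], fam_idx, rep_idx)
  n <- length(fam_idx)

  resid <- .mvn_deviates(n, config$sigma2_resid, config$corr_resid, "residual")

  pheno <- matrix(config$grand_means, n, nt, byrow = TRUE) +
    cline[sub_idx, , drop = FALSE] +
    dev_sub[sub_idx, , drop = FALSE] +
    dev_fam[fam_idx, , drop = FALSE] +
    rep_eff[rep_idx, , drop = FALSE] +
    dev_ib[(rep_idx - 1L) * B + blk_idx, , drop = FALSE] +
    resid
  colnames(pheno) <- config$trait_names

  tab <- data.frame(
    tree_id = sprintf("t%05d", seq_len(n)),
    subrace = sub_ids[sub_idx],
    family = fam_ids[fam_idx],
    replicate = sprintf("r%d", rep_idx),
    iblock = sprintf("b%02d", blk_idx),
    plot = sprintf("p%02d", plt_idx),
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(pheno))

  if (config$missing_rate > 0) {
    tab <- apply_missingness(tab, config$missing_rate,
      seed = config$seed + 1L)
  }

  attr(tab, "latitudes") <- data.frame(
    subrace = sub_ids, latitude_deg = lat, stringsAsFactors = FALSE)
  attr(tab, "sim_config") <- config
  tab
}

#' Overlay trait measurement error
#'
#' Emulates a spectroscopically predicted trait: adds to `trait` an
#' independent normal error sized so that the squared correlation between
#' the true and the predicted value equals `reliability`, and stores the
#' result as a new column `<trait>_pred`.  The noise variance is calibrated
#' against the observed phenotypic variance of the trait, so
#' `var(noise) = var(trait) * (1/reliability - 1)`.  Because the noise is
#' independent of all genetic effects, family means average it away: the
#' genetic-level correlation between trait and surrogate approaches 1 even
#' at moderate individual-level reliability, while the surrogate's
#' heritability is attenuated by the reliability factor.
#'
#' @param table phenotype table.
#' @param trait trait column to degrade.
#' @param reliability individual-level squared correlation in `(0, 1]`.
#' @param seed integer seed.
#' @return The table with an added `<trait>_pred` column.
#' @export
overlay_measurement_error <- function(table, trait, reliability, seed) {
  if (!trait %in% names(table)) stop("trait '", trait, "' not found")
  if (!is.numeric(reliability) || reliability <= 0 || reliability > 1) {
    stop("reliability must lie in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  x <- table[[trait]]
  noise_var <- stats::var(x, na.rm = TRUE) * (1 / reliability - 1)
  pred <- x + stats::rnorm(length(x), 0, sqrt(noise_var))
  table[[paste0(trait, "_pred")]] <- pred
  table
}

#' Mask trait values completely at random
#'
#' Each trait cell is independently set missing with probability `rate`;
#' design columns are untouched.
#'
#' @param table phenotype table.
#' @param rate per-cell missingness probability in `[0, 0.5]`.
#' @param seed integer seed.
#' @return The table with masked trait cells.
#' @export
apply_missingness <- function(table, rate, seed) {
  if (!is.numeric(rate) || rate < 0 || rate > 0.5) {
    stop("missingness rate must lie in [0, 0.5]", call. = FALSE)
  }
  if (rate == 0) return(table)
  set.seed(seed)
  trait_cols <- setdiff(names(table), .design_columns)
  for (cl in trait_cols) {
    mask <- stats::runif(nrow(table)) < rate
    table[[cl]][mask] <- NA_real_
  }
  table
}

#' Subrace latitudes of a simulated trial
#'
#' @param table a table produced by [simulate_trial()].
#' @return `data.frame` with columns `subrace` and `latitude_deg`.
#' @export
subrace_latitudes <- function(table) {
  lat <- attr(table, "latitudes")
  if (is.null(lat)) stop("table carries no latitude attribute; supply a ",
    "latitude table read with read_latitudes()", call. = FALSE)
  lat
}
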