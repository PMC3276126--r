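#' Univariate REML fit of the trial mixed model
#'
#' Fits, by restricted maximum likelihood, the individual-tree model
#' `trait = replicate (fixed) + subrace (fixed or random) +
#' iblock-within-replicate (random) + family-within-subrace (random) +
#' residual` to one trait of a phenotype table.  Variance components are
#' constrained to be non-negative; estimates that converge to the boundary
#' are reported as zero and flagged.  The asymptotic covariance of the
#' variance components (used by the delta-method standard errors of
#' heritability and Qst) is the inverse observed information of the
#' restricted likelihood at the optimum, and is unavailable when any
#' component is at the boundary.
#'
#' @param table a phenotype table (see [simulate_trial()] or
#'   [read_phenotypes()]).
#' @param spec a [model_spec()]; a bare trait name is accepted and expanded
#'   to the default specification.
#' @param se logical; compute the asymptotic covariance of the variance
#'   components (a small extra cost).
#' @param control optimiser control passed to [stats::nlminb()].
#'
#' @return An object of class `vc_fit` with elements `components` (named
#'   vector of variance estimates including `residual`), `boundary`,
#'   `vcov`, `loglik` (restricted log-likelihood including constants),
#'   `fixef`, `n_used`, `converged`, and the spec and model frame used.
#' @seealso [fit_constrained()], [fit_bivariate()], [genetic_params()]
#' @examples
#' cfg <- sim_config(n_subraces = 6, families_per_subrace = 8, seed = 1)
#' tab <- simulate_trial(cfg)
#' fit <- fit_univariate(tab, model_spec("SG", subrace_as = "random"))
#' fit$components
#' @export
fit_univariate <- function(table, spec, se = TRUE, control = list()) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"), length(spec$response) == 1L)
  trait <- spec$response
  .check_phenotypes(table, trait)

  keep <- !is.na(table[[trait]])
  dat <- table[keep, , drop = FALSE]
  if (nrow(dat) < 3L) stop("too few non-missing records for trait ", trait)
  dat$subrace <- factor(dat$subrace)
  dat$family <- factor(dat$family)
  dat$replicate <- factor(dat$replicate)

  if (length(unique(dat$subrace)) < 2L || length(unique(dat$family)) < 2L) {
    stop("need at least two subraces and two families with data", call. = FALSE)
  }

  fixed_terms <- spec$fixed_terms
  if (spec$subrace_as == "fixed") fixed_terms <- union(fixed_terms, "subrace")
  fixed_terms <- intersect(fixed_terms, names(dat))
  # a fixed term collapsing to one level carries no contrast
  fixed_terms <- fixed_terms[vapply(
    fixed_terms, function(v) length(unique(dat[[v]])) > 1L, logical(1L)
  )]

  Zlist <- list()
  if (spec$subrace_as == "random") Zlist$subrace <- .indicator(dat$subrace)
  if (spec$include_iblock && "iblock" %in% names(dat)) {
    ib <- .iblock_id(dat)
    if (nlevels(ib) > 1L) Zlist$iblock <- .indicator(ib)
  }
  if (spec$include_family) Zlist$family <- .indicator(dat$family)

  if (spec$subrace_as == "random" && spec$include_family) {
    fam_per_sub <- tapply(dat$family, dat$subrace,
      function(f) length(unique(f)))
    if (all(fam_per_sub == 1L)) {
      stop("subrace and family terms are aliased: every subrace contains a ",
        "single family, so subrace (random) and family-within-subrace ",
        "cannot be separated", call. = FALSE)
    }
  }

  tie <- NULL
  fixed_value <- NULL
  cns <- spec$constraint
  if (!is.null(cns)) {
    if (!is.null(cns$type) && cns$type == "qst_ratio") {
      if (!("subrace" %in% names(Zlist)) || !("family" %in% names(Zlist))) {
        stop("qst_ratio constraint needs subrace (random) and family terms",
          call. = FALSE)
      }
      k <- 2 * cns$fst / (1 - cns$fst) / cns$relatedness
      tie <- list(from = "subrace", to = "family", k = k)
    } else {
      if (!(cns$term %in% names(Zlist))) {
        stop("constraint term '", cns$term, "' is not a random term of the model",
          call. = FALSE)
      }
      fixed_value <- stats::setNames(cns$value, cns$term)
    }
  }

  X <- .fixed_design(dat, fixed_terms)
  res <- .reml_uni(dat[[trait]], X, Zlist,
    tie = tie, fixed_value = fixed_value, vcov = se, control = control)

  out <- c(res, list(
    trait = trait,
    spec = spec,
    model_frame = dat
  ))
  class(out) <- "vc_fit"
  out
}

#' Constrained univariate REML fit
#'
#' Thin wrapper around [fit_univariate()] for specifications that carry a
#' constraint: either one variance component held at a fixed value, or the
#' `qst_ratio` tie `sigma2_subrace = 2 Fst/(1 - Fst) * sigma2_family / r`,
#' under which Qst equals Fst exactly.  Used as the null model of the
#' one-tailed Qst-versus-Fst likelihood-ratio test.
#'
#' @inheritParams fit_univariate
#' @return A `vc_fit`, as for [fit_univariate()].
#' @export
fit_constrained <- function(table, spec, se = FALSE, control = list()) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(spec$constraint)) {
    stop("fit_constrained() requires a spec with a constraint; see model_spec()",
      call. = FALSE)
  }
  fit_univariate(table, spec, se = se, control = control)
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("REML variance components for trait '", x$trait, "' (n = ",
    x$n_used, ")\n", sep = "")
  comp <- x$components
  flag <- ifelse(x$boundary, " (boundary)", "")
  for (i in seq_along(comp)) {
    cat(sprintf("  %-10s %12.6g%s\n", names(comp)[i], comp[i], flag[i]))
  }
  cat("restricted log-likelihood:", format(x$loglik, digits = 8), "\n")
  if (!x$converged) cat("WARNING: optimiser did not report convergence\n")
  invisible(x)
}

#' Method-of-moments oracle for balanced nested data
#'
#' Closed-form variance-component estimators from the expected mean squares
#' of the balanced two-level nested random model (subraces / families /
#' trees), with no block structure.  On such data these ANOVA estimators
#' coincide with REML whenever all estimates are interior, which makes this
#' an independent check on the REML engine.
#'
#' @param table phenotype table with `subrace` and `family` columns; must be
#'   perfectly balanced (equal families per subrace, equal trees per
#'   family).
#' @param trait trait column name.
#' @return Named vector with `subrace`, `family` and `residual` variance
#'   estimates (method-of-moments; may be negative in small samples).
#' @export
balanced_nested_anova <- function(table, trait) {
  .check_phenotypes(table, trait)
  y <- table[[trait]]
  if (anyNA(y)) stop("balanced ANOVA oracle requires complete data")
  sub <- factor(table$subrace)
  fam <- factor(table$family)

  fam_n <- table(fam)
  fams_per_sub <- tapply(fam, sub, function(f) length(unique(f)))
  if (length(unique(fam_n)) != 1L || length(unique(fams_per_sub)) != 1L) {
    stop("design is not balanced; the nested-ANOVA oracle requires equal ",
      "family sizes and equal numbers of families per subrace", call. = FALSE)
  }
  n0 <- unname(fam_n[1L])
  f0 <- unname(fams_per_sub[1L])
  s0 <- nlevels(sub)

  fam_means <- tapply(y, fam, mean)
  sub_means <- tapply(y, sub, mean)
  grand <- mean(y)

  ss_e <- sum((y - fam_means[fam])^2)
  ms_e <- ss_e / (s0 * f0 * (n0 - 1))
  sub_of_fam <- tapply(as.character(sub), fam, `[`, 1L)
  ss_f <- n0 * sum((fam_means - sub_means[sub_of_fam])^2)
  ms_f <- ss_f / (s0 * (f0 - 1))
  ss_s <- n0 * f0 * sum((sub_means - grand)^2)
  ms_s <- ss_s / (s0 - 1)

  c(
    subrace = (ms_s - ms_f) / (n0 * f0),
    family = (ms_f - ms_e) / n0,
    residual = ms_e
  )
}
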