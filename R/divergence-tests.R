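#' Boundary-corrected p-value for a variance likelihood-ratio statistic
#'
#' A variance component tested against zero sits on the boundary of its
#' parameter space, so the likelihood-ratio statistic is referred to a
#' 50:50 mixture of a point mass at zero and a chi-square with one degree
#' of freedom: `p = 0.5 * P(chi2_1 >= statistic)` for a positive statistic
#' and `p = 1` at zero.
#'
#' @param statistic likelihood-ratio statistic (>= 0; small negative
#'   values from numerical error are clipped with a warning).
#' @return p-value in `[0, 1]`.
#' @examples
#' lrt_boundary_p(2.706) # 0.05
#' @export
lrt_boundary_p <- function(statistic) {
  if (any(statistic < -1e-6)) {
    stop("likelihood-ratio statistic is negative beyond numerical tolerance",
      call. = FALSE)
  }
  if (any(statistic < 0)) {
    warning("clipping slightly negative LRT statistic(s) to zero")
    statistic <- pmax(statistic, 0)
  }
  ifelse(statistic == 0, 1,
    0.5 * stats::pchisq(statistic, df = 1L, lower.tail = FALSE))
}

.lrt_result <- function(statistic, p_value, tail, reference,
                        full_loglik, constrained_loglik, extra = list()) {
  structure(
    c(list(
      statistic = statistic, p_value = p_value, tail = tail,
      reference = reference, full_loglik = full_loglik,
      constrained_loglik = constrained_loglik
    ), extra),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("Likelihood-ratio test (", x$tail, "-tailed, ", x$reference, ")\n",
    sep = "")
  cat(sprintf("  statistic = %.4f   p = %.4g %s\n", x$statistic, x$p_value,
    significance_stars(x$p_value)))
  invisible(x)
}

#' Significance stars
#'
#' Three-level convention: `*` P<0.05, `**` P<0.01, `***` P<0.001.
#' @param p p-value(s).
#' @return Character vector of stars (`"NS"` when not significant).
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "NS")))
}

#' Likelihood-ratio test of the family variance component
#'
#' Tests for additive genetic variation within subraces: compares the REML
#' log-likelihood of the full model against the model without the
#' family-within-subrace term.  The statistic is referred to the
#' boundary-corrected 0:1 chi-square mixture.  Both models share the same
#' fixed effects, so their restricted likelihoods are comparable.
#'
#' @param table phenotype table.
#' @param trait trait column name.
#' @param subrace_as subrace treatment in the two fits (`"fixed"` as in
#'   the standard univariate analysis).
#' @param include_iblock logical.
#' @return An `lrt_result`.
#' @export
test_family_variance <- function(table, trait, subrace_as = "fixed",
                                 include_iblock = TRUE) {
  full <- fit_univariate(table, model_spec(trait, subrace_as = subrace_as,
    include_iblock = include_iblock), se = FALSE)
  null <- fit_univariate(table, model_spec(trait, subrace_as = subrace_as,
    include_iblock = include_iblock, include_family = FALSE), se = FALSE)
  if (!full$converged || !null$converged) {
    stop("family-variance LRT: a component fit failed to converge",
      call. = FALSE)
  }
  stat <- max(2 * (full$loglik - null$loglik), 0)
  .lrt_result(stat, lrt_boundary_p(stat), "one", "chi2 mixture 0:1",
    full$loglik, null$loglik)
}

#' One-tailed likelihood-ratio test of Qst against Fst
#'
#' Tests whether the quantitative divergence Qst of a trait exceeds a
#' marker-based Fst.  The null model ties the subrace variance to the
#' family variance at `sigma2_subrace = 2 Fst/(1 - Fst) * sigma2_family /
#' r`, the unique value at which Qst equals Fst; the alternative is the
#' unconstrained subrace-random model.  One-sided direction-aware
#' convention: when the unconstrained estimate exceeds Fst,
#' `p = 0.5 * P(chi2_1 >= LRT)`; otherwise the evidence points the wrong
#' way and `p = 1 - 0.5 * P(chi2_1 >= LRT)` (so `p = 0.5` at a null-equal
#' fit, approaching 1 as Qst falls below Fst).
#'
#' @param table phenotype table.
#' @param trait trait column name.
#' @param fst marker-based fixation index in `(0, 1)`.
#' @param relatedness_r coefficient of relatedness in `(0, 1]`.
#' @return An `lrt_result` carrying also `qst_hat` and `fst`.
#' @export
test_qst_exceeds_fst <- function(table, trait, fst = 0.09,
                                 relatedness_r = 0.4) {
  if (!is.numeric(fst) || fst <= 0 || fst >= 1) {
    stop("fst must lie in (0, 1)", call. = FALSE)
  }
  full <- fit_univariate(table, model_spec(trait, subrace_as = "random"),
    se = FALSE)
  if (full$boundary[["subrace"]] && full$boundary[["family"]]) {
    stop("Qst undefined (subrace and family variances both at the ",
      "boundary); the Qst-Fst test is unavailable", call. = FALSE)
  }
  qhat <- qst(full$components[["subrace"]],
    additive_variance(full$components[["family"]], relatedness_r))
  tied <- fit_constrained(table, model_spec(trait, subrace_as = "random",
    constraint = list(type = "qst_ratio", fst = fst,
      relatedness = relatedness_r)))
  if (!full$converged || !tied$converged) {
    stop("Qst-Fst LRT: a component fit failed to converge", call. = FALSE)
  }
  stat <- max(2 * (full$loglik - tied$loglik), 0)
  half <- 0.5 * stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  p <- if (qhat > fst) half else min(1 - half, 1)
  .lrt_result(stat, p, "one", "chi2 mixture 0:1", full$loglik, tied$loglik,
    extra = list(qst_hat = qhat, fst = fst))
}

#' Two-tailed likelihood-ratio test of a genetic correlation
#'
#' Refits a bivariate model with the cross-trait covariance of the chosen
#' level (`additive` = family, `subrace`) fixed at zero and compares
#' restricted log-likelihoods.  The covariance is an interior parameter,
#' so the statistic is referred to a chi-square with one degree of
#' freedom.
#'
#' @param bifit a converged `vc_bifit` from [fit_bivariate()].
#' @param level `"additive"` or `"subrace"`.
#' @return An `lrt_result` carrying also the estimated correlation `r`.
#' @export
test_correlation_nonzero <- function(bifit, level = c("additive", "subrace")) {
  stopifnot(inherits(bifit, "vc_bifit"))
  level <- match.arg(level)
  lv <- if (level == "additive") "family" else "subrace"
  if (lv %in% bifit$constrain_zero) {
    stop("the fitted model already constrains this covariance to zero",
      call. = FALSE)
  }
  null <- fit_bivariate(bifit$model_frame, bifit$spec,
    constrain_zero = c(bifit$constrain_zero, lv),
    iblock_structure = bifit$iblock_structure, se = FALSE)
  if (!null$converged && !bifit$converged) {
    stop("correlation LRT: constrained refit failed to converge",
      call. = FALSE)
  }
  stat <- max(2 * (bifit$loglik - null$loglik), 0)
  S <- bifit$Sigma[[lv]]
  r <- if (all(diag(S) > 0)) S[1L, 2L] / sqrt(prod(diag(S))) else NA_real_
  .lrt_result(stat, stats::pchisq(stat, df = 1L, lower.tail = FALSE),
    "two", "chi2 df=1", bifit$loglik, null$loglik,
    extra = list(r = r, level = level))
}
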