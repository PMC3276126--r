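#' Additive genetic variance from the family variance component
#'
#' Open-pollinated families are more related than paternal half-sibs
#' because of mixed mating and biparental inbreeding, so the family
#' variance component is divided by a relatedness coefficient `r` larger
#' than the half-sib 0.25 — 0.4 by default throughout the package:
#' `sigma2_add = sigma2_family / r`.
#'
#' @param sigma2_family family-within-subrace variance component (>= 0).
#' @param relatedness_r coefficient of relatedness in `(0, 1]`.
#' @return Additive genetic variance.
#' @examples
#' additive_variance(0.2, 0.4) # 0.5
#' @export
additive_variance <- function(sigma2_family, relatedness_r = 0.4) {
  if (!is.numeric(relatedness_r) || any(relatedness_r <= 0) ||
      any(relatedness_r > 1)) {
    stop("relatedness_r must lie in (0, 1]", call. = FALSE)
  }
  if (any(sigma2_family < 0)) stop("sigma2_family must be non-negative")
  sigma2_family / relatedness_r
}

#' Quantitative divergence between populations (Qst)
#'
#' `Qst = sigma2_subrace / (sigma2_subrace + 2 * sigma2_add)`: the share of
#' the total additive genetic variance attributable to differentiation
#' between populations, the quantitative analogue of the marker-based Fst.
#'
#' @param sigma2_subrace between-subrace variance component (>= 0).
#' @param sigma2_add pooled within-subrace additive variance (>= 0).
#' @return Qst in `[0, 1]`.
#' @examples
#' qst(1, 1)   # 1/3
#' qst(2, 1)   # 0.5
#' @export
qst <- function(sigma2_subrace, sigma2_add) {
  if (any(sigma2_subrace < 0) || any(sigma2_add < 0)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  if (any(sigma2_subrace + sigma2_add == 0)) {
    stop("Qst is undefined when both variance components are zero",
      call. = FALSE)
  }
  sigma2_subrace / (sigma2_subrace + 2 * sigma2_add)
}

#' Open-pollinated narrow-sense heritability with its standard error
#'
#' `h2_op = (sigma2_family / r) / (sigma2_family + sigma2_resid)`.  The
#' denominator is the within-trial phenotypic variance excluding the
#' replicate and incomplete-block design variance (set
#' `include_iblock = TRUE` to add the block component).  The standard
#' error is the first-order delta method applied to the fit's asymptotic
#' component covariance.
#'
#' @param fit a `vc_fit` from [fit_univariate()].
#' @param relatedness_r coefficient of relatedness in `(0, 1]`.
#' @param include_iblock include the incomplete-block variance in the
#'   phenotypic denominator (default `FALSE`).
#' @return List with `h2`, `se` (NA when the family component is at the
#'   boundary or no covariance is available), and `boundary`.
#' @export
heritability_op <- function(fit, relatedness_r = 0.4, include_iblock = FALSE) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!fit$converged) stop("fit did not converge; heritability not derived")
  comp <- fit$components
  if (!"family" %in% names(comp)) {
    stop("fit has no family variance component", call. = FALSE)
  }
  f <- comp[["family"]]
  e <- comp[["residual"]]
  b <- if (include_iblock && "iblock" %in% names(comp)) {
    comp[["iblock"]]
  } else 0
  denom <- f + e + b
  if (fit$boundary[["family"]]) {
    return(list(h2 = 0, se = NA_real_, boundary = TRUE))
  }
  h2 <- additive_variance(f, relatedness_r) / denom
  se <- NA_real_
  V <- fit$vcov
  if (!is.null(V)) {
    g <- stats::setNames(numeric(nrow(V)), rownames(V))
    g["family"] <- (denom / relatedness_r - f / relatedness_r) / denom^2
    g["residual"] <- -(f / relatedness_r) / denom^2
    if (include_iblock && "iblock" %in% names(g)) {
      g["iblock"] <- -(f / relatedness_r) / denom^2
    }
    g[is.na(g)] <- 0
    se <- sqrt(max(drop(t(g) %*% V %*% g), 0))
  }
  list(h2 = unname(h2), se = unname(se), boundary = FALSE)
}

#' Coefficient of additive genetic variation (percent)
#'
#' `CV_a = 100 * sqrt(sigma2_add) / mean`: scale-free evolvability measure.
#'
#' @param sigma2_add additive genetic variance (>= 0).
#' @param mean trait grand mean (> 0).
#' @return Percent CV.
#' @examples
#' cv_additive(1.535, 17.3) # about 7.16
#' @export
cv_additive <- function(sigma2_add, mean) {
  if (any(mean <= 0)) stop("mean must be positive for a coefficient of variation")
  if (any(sigma2_add < 0)) stop("sigma2_add must be non-negative")
  100 * sqrt(sigma2_add) / mean
}

#' Coefficient of subrace genetic variation (percent)
#'
#' @param sigma2_subrace between-subrace variance component (>= 0).
#' @param mean trait grand mean (> 0).
#' @return Percent CV.
#' @export
cv_subrace <- function(sigma2_subrace, mean) {
  cv_additive(sigma2_subrace, mean)
}

#' Qst with a delta-method standard error
#'
#' Point estimate from the subrace-random fit's components via [qst()];
#' standard error by first-order Taylor propagation with gradient
#' `(2a/(s+2a)^2, -(2s/r)/(s+2a)^2)` with respect to the subrace and family
#' components, where `a = sigma2_family / r`.
#'
#' @param fit a `vc_fit` fitted with `subrace_as = "random"`.
#' @param relatedness_r coefficient of relatedness in `(0, 1]`.
#' @return List with `qst`, `se` (NA at the boundary), and `boundary`.
#' @export
qst_with_se <- function(fit, relatedness_r = 0.4) {
  stopifnot(inherits(fit, "vc_fit"))
  comp <- fit$components
  if (!all(c("subrace", "family") %in% names(comp))) {
    stop("Qst requires a fit with subrace (random) and family components",
      call. = FALSE)
  }
  s <- comp[["subrace"]]
  f <- comp[["family"]]
  if (s + f <= 0 || (fit$boundary[["subrace"]] && fit$boundary[["family"]])) {
    stop("Qst is undefined: both components at the boundary", call. = FALSE)
  }
  if (fit$boundary[["family"]]) {
    # family variance at zero: all additive variance is between subraces
    return(list(qst = 1, se = NA_real_, boundary = TRUE))
  }
  a <- additive_variance(f, relatedness_r)
  q <- qst(s, a)
  se <- NA_real_
  boundary <- fit$boundary[["subrace"]] || fit$boundary[["family"]]
  V <- fit$vcov
  if (!is.null(V) && !boundary &&
      all(c("subrace", "family") %in% rownames(V))) {
    g <- stats::setNames(numeric(nrow(V)), rownames(V))
    g["subrace"] <- 2 * a / (s + 2 * a)^2
    g["family"] <- -(2 * s / relatedness_r) / (s + 2 * a)^2
    se <- sqrt(max(drop(t(g) %*% V %*% g), 0))
  }
  list(qst = unname(q), se = unname(se), boundary = boundary)
}

#' Correlations at the additive, subrace and phenotypic levels
#'
#' From a bivariate fit: the additive genetic correlation is the
#' family-level correlation (the relatedness scaling cancels), the subrace
#' correlation comes from the subrace-level 2x2, and the phenotypic
#' correlation sums covariances over all random levels and divides by the
#' total standard deviations.  Standard errors are first-order delta-method
#' propagation of the fit's asymptotic parameter covariance.
#'
#' @param bifit a `vc_bifit` from [fit_bivariate()].
#' @param se logical; return delta-method standard errors (requires the
#'   fit to carry `vcov_th`).
#' @return `data.frame` with columns `level` (`additive`, `subrace`,
#'   `phenotypic`), `r`, `se`.
#' @export
genetic_correlations <- function(bifit, se = TRUE) {
  stopifnot(inherits(bifit, "vc_bifit"))
  S <- bifit$Sigma
  lev_r <- function(M) {
    if (any(diag(M) <= 0)) return(NA_real_)
    M[1L, 2L] / sqrt(prod(diag(M)))
  }
  # biological levels only: the incomplete-block level is design noise and
  # carries no cross-trait covariance under the default structure, so
  # including it would bias the phenotypic correlation towards zero
  tot <- S$subrace + S$family + S$residual
  r <- c(
    additive = lev_r(S$family),
    subrace = lev_r(S$subrace),
    phenotypic = lev_r(tot)
  )
  ses <- rep(NA_real_, 3L)
  if (se && !is.null(bifit$vcov_th)) {
    Vth <- bifit$vcov_th
    # correlation at a log-Cholesky-parameterised level depends only on the
    # off-diagonal b and log-sd c: r = b / sqrt(b^2 + exp(2c))
    lev_grad <- function(level) {
      if (bifit$levels_def[[level]] != "us") return(NULL)
      off <- bifit$offsets[[level]]
      idx <- off + 1:3
      b <- bifit$th[idx[2L]]; ec2 <- exp(2 * bifit$th[idx[3L]])
      den <- (b^2 + ec2)^1.5
      g <- numeric(length(bifit$th))
      g[idx[2L]] <- ec2 / den
      g[idx[3L]] <- -2 * b * ec2 / den
      g
    }
    for (i in seq_along(c("family", "subrace"))) {
      lv <- c("family", "subrace")[i]
      g <- lev_grad(lv)
      if (!is.null(g)) {
        ses[i] <- sqrt(max(drop(t(g) %*% Vth %*% g), 0))
      }
    }
    # phenotypic correlation: numerical gradient over all parameters
    rp_fun <- function(th) {
      Sl <- .bifit_unpack(bifit, th)
      lev_r(Sl$subrace + Sl$family + Sl$residual)
    }
    g <- .num_grad(rp_fun, bifit$th)
    ses[3L] <- sqrt(max(drop(t(g) %*% Vth %*% g), 0))
  }
  data.frame(
    level = c("additive", "subrace", "phenotypic"),
    r = unname(r),
    se = ses,
    stringsAsFactors = FALSE
  )
}

# rebuild per-level covariance matrices (standardised scale) from a
# parameter vector, following the fit's level structure
.bifit_unpack <- function(bifit, th) {
  defs <- bifit$levels_def
  offs <- bifit$offsets
  np <- bifit$npar_levels
  out <- list()
  pos <- 0L
  for (lv in names(defs)) {
    out[[lv]] <- .chol2cov(th[pos + seq_len(np[[lv]])], defs[[lv]])
    pos <- pos + np[[lv]]
  }
  out
}

.num_grad <- function(f, x, rel = 1e-5, floor = 1e-7) {
  h <- pmax(abs(x) * rel, floor)
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    (f(xp) - f(xm)) / (2 * h[i])
  }, numeric(1L))
}

#' Per-trait genetic parameter summary
#'
#' Fits the subrace-random univariate model to one trait and derives the
#' full parameter row: sample size, mean, additive variance (with SE),
#' coefficients of subrace and additive genetic variation, heritability
#' (with SE) and Qst (with SE).  All derived quantities come from the same
#' single REML fit.
#'
#' @param table phenotype table.
#' @param trait trait column name.
#' @param relatedness_r coefficient of relatedness in `(0, 1]`.
#' @param include_iblock include the block variance in the heritability
#'   denominator.
#' @return One-row `data.frame` with columns `trait`, `n`, `mean`, `V_a`,
#'   `se_Va`, `CV_s`, `CV_a`, `h2_op`, `se_h2`, `Qst`, `se_Qst`.
#' @export
genetic_params <- function(table, trait, relatedness_r = 0.4,
                           include_iblock = FALSE) {
  fit <- fit_univariate(table, model_spec(trait, subrace_as = "random"))
  comp <- fit$components
  mu <- mean(fit$model_frame[[trait]])
  va <- additive_variance(comp[["family"]], relatedness_r)
  se_va <- if (!is.null(fit$vcov) && "family" %in% rownames(fit$vcov)) {
    sqrt(fit$vcov["family", "family"]) / relatedness_r
  } else NA_real_
  h2 <- heritability_op(fit, relatedness_r, include_iblock)
  qq <- qst_with_se(fit, relatedness_r)
  data.frame(
    trait = trait,
    n = fit$n_used,
    mean = mu,
    V_a = va,
    se_Va = se_va,
    CV_s = cv_subrace(comp[["subrace"]], mu),
    CV_a = cv_additive(va, mu),
    h2_op = h2$h2,
    se_h2 = h2$se,
    Qst = qq$qst,
    se_Qst = qq$se,
    stringsAsFactors = FALSE
  )
}
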