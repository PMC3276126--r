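# Bivariate REML: unstructured 2x2 covariance at the subrace, family and
# residual levels (diagonal 2x2 for incomplete block by default), fitted by
# direct maximisation of the restricted likelihood over log-Cholesky
# parameters, which keeps every level matrix positive semi-definite and all
# implied correlations in [-1, 1].  Trees with only one of the two traits
# observed still contribute through their marginal likelihood.

# spread a group indicator into the (group-major, trait-minor) column layout
.spread_trait <- function(Z, trait, ntrait = 2L) {
  q <- ncol(Z)
  Tm <- Matrix::sparseMatrix(
    i = seq_len(q), j = ntrait * (seq_len(q) - 1L) + trait, x = 1,
    dims = c(q, ntrait * q)
  )
  Z %*% Tm
}

.chol2cov <- function(th, type) {
  if (type == "us") {
    L <- matrix(c(exp(th[1L]), th[2L], 0, exp(th[3L])), 2L, 2L)
    L %*% t(L)
  } else {
    diag(exp(2 * th), 2L)
  }
}

.cov2chol <- function(S, type) {
  if (type == "us") {
    L <- t(chol(S + diag(1e-10, 2L)))
    c(log(L[1L, 1L]), L[2L, 1L], log(L[2L, 2L]))
  } else {
    0.5 * log(pmax(diag(S), 1e-12))
  }
}

#' Bivariate REML fit of the trial mixed model
#'
#' Fits the two-trait individual-tree model with trait-specific replicate
#' fixed effects and unstructured 2x2 covariance matrices for the subrace,
#' family-within-subrace and residual levels.  Subrace is always random in
#' bivariate fits.  The incomplete-block level uses a diagonal 2x2
#' (no cross-trait block covariance) by default, which aids convergence;
#' set `iblock_structure = "us"` for an unstructured block covariance.
#' Rows missing one of the two responses contribute their marginal
#' likelihood; rows missing both are dropped.
#'
#' @param table phenotype table.
#' @param spec a [model_spec()] with two responses and
#'   `subrace_as = "random"`, or a length-2 character vector of trait
#'   names.
#' @param constrain_zero character vector of levels (`"subrace"`,
#'   `"family"`, `"residual"`) whose cross-trait covariance is fixed at
#'   zero; used by the correlation likelihood-ratio tests.
#' @param iblock_structure `"diag"` (default) or `"us"`.
#' @param se logical; compute the asymptotic covariance of the covariance
#'   parameters (needed for delta-method correlation standard errors).
#' @param control optimiser control passed to [stats::nlminb()].
#'
#' @return An object of class `vc_bifit`: per-level covariance matrices
#'   (`Sigma`), restricted log-likelihood, convergence flag, parameter
#'   vector and (optionally) its asymptotic covariance, plus the model
#'   frame for refits.
#' @seealso [genetic_correlations()], [test_correlation_nonzero()]
#' @examples
#' cfg <- sim_config(n_subraces = 5, families_per_subrace = 8,
#'   trait_names = c("a", "b"), grand_means = c(0, 0),
#'   sigma2_subrace = 0.1, sigma2_family = 0.1, sigma2_iblock = 0.01,
#'   sigma2_resid = 0.8,
#'   corr_family = matrix(c(1, .6, .6, 1), 2), seed = 3)
#' fit <- fit_bivariate(simulate_trial(cfg), c("a", "b"))
#' cov2cor(fit$Sigma$family)
#' @export
fit_bivariate <- function(table, spec, constrain_zero = character(0),
                          iblock_structure = c("diag", "us"),
                          se = TRUE, control = list()) {
  if (is.character(spec)) spec <- model_spec(spec, subrace_as = "random")
  stopifnot(inherits(spec, "model_spec"), length(spec$response) == 2L)
  if (spec$subrace_as != "random") {
    stop("bivariate fits require subrace_as = \"random\"", call. = FALSE)
  }
  iblock_structure <- match.arg(iblock_structure)
  traits <- spec$response
  .check_phenotypes(table, traits)

  obs1 <- !is.na(table[[traits[1L]]])
  obs2 <- !is.na(table[[traits[2L]]])
  keep <- obs1 | obs2
  if (!any(obs1 & obs2)) {
    stop("the two responses have no jointly observed rows", call. = FALSE)
  }
  dat <- table[keep, , drop = FALSE]
  dat$subrace <- factor(dat$subrace)
  dat$family <- factor(dat$family)
  dat$replicate <- factor(dat$replicate)
  obs1 <- obs1[keep]; obs2 <- obs2[keep]

  # internal standardisation keeps the optimiser scale-free
  sds <- vapply(traits, function(tr) stats::sd(dat[[tr]], na.rm = TRUE),
    numeric(1L))
  y1 <- dat[[traits[1L]]] / sds[1L]
  y2 <- dat[[traits[2L]]] / sds[2L]

  X0 <- .fixed_design(dat, intersect(spec$fixed_terms, names(dat)))
  p0 <- ncol(X0)
  Zs <- .indicator(dat$subrace)
  Zf <- .indicator(dat$family)
  levels_def <- list(subrace = "us", family = "us")
  Zl <- list(subrace = Zs, family = Zf)
  if (spec$include_iblock) {
    ib <- .iblock_id(dat)
    if (nlevels(ib) > 1L) {
      Zl$iblock <- .indicator(ib)
      levels_def$iblock <- iblock_structure
    }
  }
  for (lv in intersect(constrain_zero, names(levels_def))) {
    levels_def[[lv]] <- "diag"
  }
  resid_type <- if ("residual" %in% constrain_zero) "diag" else "us"

  Xz <- Matrix::Matrix(0, nrow(dat), p0, sparse = TRUE)
  W1 <- cbind(Matrix::Matrix(X0, sparse = TRUE), Xz)
  W2 <- cbind(Xz, Matrix::Matrix(X0, sparse = TRUE))
  for (lv in names(Zl)) {
    W1 <- cbind(W1, .spread_trait(Zl[[lv]], 1L))
    W2 <- cbind(W2, .spread_trait(Zl[[lv]], 2L))
  }
  p <- 2L * p0
  qs <- vapply(Zl, ncol, integer(1L))

  cc <- obs1 & obs2
  o1 <- obs1 & !obs2
  o2 <- obs2 & !obs1
  W1c <- W1[cc, , drop = FALSE]; W2c <- W2[cc, , drop = FALSE]
  pre <- list(
    A11 = Matrix::crossprod(W1c), A22 = Matrix::crossprod(W2c),
    A12 = Matrix::crossprod(W1c, W2c),
    B11 = Matrix::crossprod(W1[o1, , drop = FALSE]),
    B22 = Matrix::crossprod(W2[o2, , drop = FALSE]),
    v11 = as.numeric(Matrix::crossprod(W1c, y1[cc])),
    v12 = as.numeric(Matrix::crossprod(W1c, y2[cc])),
    v21 = as.numeric(Matrix::crossprod(W2c, y1[cc])),
    v22 = as.numeric(Matrix::crossprod(W2c, y2[cc])),
    w1 = as.numeric(Matrix::crossprod(W1[o1, , drop = FALSE], y1[o1])),
    w2 = as.numeric(Matrix::crossprod(W2[o2, , drop = FALSE], y2[o2])),
    yy11 = sum(y1[cc]^2), yy22 = sum(y2[cc]^2), yy12 = sum(y1[cc] * y2[cc]),
    yy1o = sum(y1[o1]^2), yy2o = sum(y2[o2]^2),
    nc = sum(cc), n1 = sum(o1), n2 = sum(o2)
  )
  N <- 2L * pre$nc + pre$n1 + pre$n2

  skel <- lapply(levels_def, function(tp) if (tp == "us") 1:3 else 1:2)
  npar_lv <- lengths(skel)
  offs <- cumsum(c(0L, npar_lv))
  names(offs) <- c(names(skel), "residual")
  npar <- sum(npar_lv) + (if (resid_type == "us") 3L else 2L)

  unpack <- function(th) {
    out <- vector("list", length(skel) + 1L)
    names(out) <- c(names(skel), "residual")
    for (i in seq_along(skel)) {
      out[[i]] <- .chol2cov(th[offs[i] + skel[[i]]], levels_def[[i]])
    }
    out$residual <- .chol2cov(
      th[(sum(npar_lv) + 1L):npar],
      resid_type)
    out
  }

  # ---- fixed-pattern assembly of the MME coefficient matrix ----
  # C(th) = W' R^-1 W + blockdiag(0, G^-1) is a linear combination of
  # matrices with a fixed union sparsity pattern, so each likelihood
  # evaluation only recomputes the numeric value vector and re-uses one
  # symbolic Cholesky factorisation.
  M <- p + 2L * sum(qs)
  col_off <- p + 2L * cumsum(c(0L, qs[-length(qs)]))
  names(col_off) <- names(qs)
  mats <- list(
    A11 = pre$A11, A22 = pre$A22,
    A12s = pre$A12 + Matrix::t(pre$A12)
  )
  if (pre$n1) mats$B11 <- pre$B11
  if (pre$n2) mats$B22 <- pre$B22
  for (lv in names(qs)) {
    i1 <- col_off[[lv]] + 2L * seq_len(qs[[lv]]) - 1L
    i2 <- i1 + 1L
    mats[[paste0("E11_", lv)]] <- Matrix::sparseMatrix(i = i1, j = i1,
      x = 1, dims = c(M, M), symmetric = TRUE)
    mats[[paste0("E22_", lv)]] <- Matrix::sparseMatrix(i = i2, j = i2,
      x = 1, dims = c(M, M), symmetric = TRUE)
    if (levels_def[[lv]] == "us") {
      mats[[paste0("E12_", lv)]] <- Matrix::sparseMatrix(i = i1, j = i2,
        x = 1, dims = c(M, M), symmetric = TRUE)
    }
  }
  mats <- lapply(mats, function(Mm) {
    as(as(Matrix::forceSymmetric(Mm), "CsparseMatrix"), "generalMatrix")
  })
  Ctmpl <- Matrix::forceSymmetric(Reduce(`+`, lapply(mats, function(Mm) {
    Mm@x[] <- 1
    Mm
  })))
  Ctri <- as(Ctmpl, "TsparseMatrix")
  ukey <- as.numeric(Ctri@j) * M + Ctri@i
  Vmat <- matrix(0, length(ukey), length(mats))
  colnames(Vmat) <- names(mats)
  for (k in seq_along(mats)) {
    Tk <- as(Matrix::forceSymmetric(mats[[k]]), "TsparseMatrix")
    Vmat[match(as.numeric(Tk@j) * M + Tk@i, ukey), k] <- Tk@x
  }

  coef_of <- function(S, Sinv_r) {
    cf <- stats::setNames(numeric(length(mats)), names(mats))
    cf["A11"] <- Sinv_r[1L, 1L]
    cf["A22"] <- Sinv_r[2L, 2L]
    cf["A12s"] <- Sinv_r[1L, 2L]
    if (pre$n1) cf["B11"] <- 1 / S$residual[1L, 1L]
    if (pre$n2) cf["B22"] <- 1 / S$residual[2L, 2L]
    for (lv in names(qs)) {
      Gi <- solve(S[[lv]])
      cf[paste0("E11_", lv)] <- Gi[1L, 1L]
      cf[paste0("E22_", lv)] <- Gi[2L, 2L]
      nm <- paste0("E12_", lv)
      if (nm %in% names(cf)) cf[nm] <- Gi[1L, 2L]
    }
    cf
  }

  ch0 <- NULL # symbolic factor, created at the first successful evaluation

  m2ll <- function(th) {
    S <- unpack(th)
    Sr <- S$residual
    detr <- Sr[1L, 1L] * Sr[2L, 2L] - Sr[1L, 2L]^2
    if (!is.finite(detr) || detr <= 1e-300) return(Inf)
    Si <- solve(Sr)
    Cm <- Ctmpl
    Cm@x <- as.numeric(Vmat %*% coef_of(S, Si))
    if (is.null(ch0)) {
      ch <- tryCatch(Matrix::Cholesky(Cm, LDL = FALSE, super = TRUE),
        error = function(e) NULL)
      if (!is.null(ch)) ch0 <<- ch
    } else {
      ch <- tryCatch(Matrix::update(ch0, Cm), error = function(e) NULL)
    }
    if (is.null(ch)) return(Inf)
    s11 <- Si[1L, 1L]; s22 <- Si[2L, 2L]; s12 <- Si[1L, 2L]
    WRy <- s11 * pre$v11 + s12 * (pre$v12 + pre$v21) + s22 * pre$v22 +
      pre$w1 / Sr[1L, 1L] + pre$w2 / Sr[2L, 2L]
    yRy <- s11 * pre$yy11 + s22 * pre$yy22 + 2 * s12 * pre$yy12 +
      pre$yy1o / Sr[1L, 1L] + pre$yy2o / Sr[2L, 2L]
    ldetC <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE,
      sqrt = TRUE)$modulus)
    b <- as.numeric(Matrix::solve(ch, WRy, system = "A"))
    ldetG <- sum(vapply(names(skel), function(lv) {
      qs[[lv]] * as.numeric(determinant(S[[lv]], logarithm = TRUE)$modulus)
    }, numeric(1L)))
    ldetR <- pre$nc * log(detr) + pre$n1 * log(Sr[1L, 1L]) +
      pre$n2 * log(Sr[2L, 2L])
    (N - p) * log(2 * pi) + ldetR + ldetG + ldetC + yRy - sum(b * WRy)
  }

  # starting values from univariate fits and raw cross-trait correlations
  th0 <- numeric(npar)
  uni <- lapply(traits, function(tr) {
    sp <- model_spec(tr, subrace_as = "random",
      include_iblock = spec$include_iblock)
    fit_univariate(dat, sp, se = FALSE)$components
  })
  rho0 <- suppressWarnings(stats::cor(y1[cc], y2[cc]))
  if (!is.finite(rho0)) rho0 <- 0
  # near-degenerate pairs (duplicated or noisy-surrogate traits) need a
  # start close to the ridge; otherwise shrink towards zero for stability
  rho0 <- if (abs(rho0) > 0.9) sign(rho0) * min(abs(rho0), 0.995) else
    0.7 * rho0
  start_level <- function(lv, type) {
    v1 <- max(uni[[1L]][lv] / sds[1L]^2, 1e-4)
    v2 <- max(uni[[2L]][lv] / sds[2L]^2, 1e-4)
    S <- matrix(c(v1, rho0 * sqrt(v1 * v2), rho0 * sqrt(v1 * v2), v2), 2L)
    if (type == "diag") S[1L, 2L] <- S[2L, 1L] <- 0
    .cov2chol(S, type)
  }
  for (i in seq_along(skel)) {
    lv <- names(skel)[i]
    key <- if (lv == "iblock") "iblock" else lv
    th0[offs[i] + skel[[i]]] <- start_level(key, levels_def[[i]])
  }
  th0[(sum(npar_lv) + 1L):npar] <- start_level("residual", resid_type)

  ctl <- utils::modifyList(
    list(iter.max = 400L, eval.max = 2000L, rel.tol = 1e-10),
    control
  )
  lb <- rep(-Inf, npar); ub <- rep(Inf, npar)
  is_logsd <- unlist(c(
    lapply(seq_along(skel), function(i) {
      if (levels_def[[i]] == "us") c(TRUE, FALSE, TRUE) else c(TRUE, TRUE)
    }),
    list(if (resid_type == "us") c(TRUE, FALSE, TRUE) else c(TRUE, TRUE))
  ))
  lb[is_logsd] <- -15; ub[is_logsd] <- 15
  opt <- .nlminb_checked(th0, m2ll, lower = lb, upper = ub,
    control = ctl[c("iter.max", "eval.max", "rel.tol")],
    nm_fallback = FALSE)

  Sigma_std <- unpack(opt$par)
  scale_mat <- tcrossprod(sds)
  Sigma <- lapply(Sigma_std, function(S) {
    S <- S * scale_mat
    dimnames(S) <- list(traits, traits)
    S
  })

  vcov_th <- NULL
  if (se) {
    at_bound <- opt$par <= lb + 1e-6 | opt$par >= ub - 1e-6
    if (!any(at_bound)) {
      H <- .num_hessian(m2ll, opt$par, rel = 1e-4, floor = 1e-5)
      vcov_th <- tryCatch(solve(H / 2), error = function(e) NULL)
    }
  }

  structure(list(
    traits = traits,
    Sigma = Sigma,
    levels_def = c(levels_def, residual = resid_type),
    th = opt$par,
    offsets = offs,
    npar_levels = c(npar_lv, residual = npar - sum(npar_lv)),
    vcov_th = vcov_th,
    # exact back-transform of the restricted likelihood from the internally
    # standardised scale: each trait contributes (n_t + p0) log(sd_t)
    loglik = -opt$objective / 2 -
      (sum(obs1) + p0) * log(sds[1L]) - (sum(obs2) + p0) * log(sds[2L]),
    loglik_std = -opt$objective / 2,
    converged = opt$convergence == 0,
    n_used = N,
    n_trees = nrow(dat),
    sds = sds,
    constrain_zero = constrain_zero,
    iblock_structure = iblock_structure,
    spec = spec,
    model_frame = dat
  ), class = "vc_bifit")
}

#' @export
print.vc_bifit <- function(x, ...) {
  cat("Bivariate REML fit:", paste(x$traits, collapse = " & "),
    " (", x$n_used, " observations)\n", sep = "")
  for (lv in names(x$Sigma)) {
    S <- x$Sigma[[lv]]
    r <- if (all(diag(S) > 0)) S[1L, 2L] / sqrt(prod(diag(S))) else NA_real_
    cat(sprintf("  %-9s var1 = %.4g  var2 = %.4g  corr = %.3f\n",
      lv, S[1L, 1L], S[2L, 2L], r))
  }
  cat("restricted log-likelihood:", format(x$loglik, digits = 8), "\n")
  invisible(x)
}
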