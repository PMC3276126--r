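# Internal REML machinery shared by the univariate and bivariate fitters.
#
# The mixed model is y = X b + sum_l Z_l u_l + e with u_l ~ N(0, s2_l I) and
# e ~ N(0, s2_e I).  The restricted likelihood is evaluated through the mixed
# model equations: with W = [X Z], D = diag(0_p, s2_e/s2_l) and
# b^ = (W'W + D)^{-1} W'y,
#
#   -2 l_R = (n-p) log 2pi + (n-p-q) log s2_e + sum_l q_l log s2_l
#            + log det(W'W + D) + (y'y - b^' W'y)/s2_e ,
#
# the classical identity log|V| + log|X'V^-1 X| = log|R| + log|G| + log|C|.
# All cross-products are sparse and precomputed once per data set; each
# likelihood evaluation is a sparse Cholesky factorisation of a (p+q)x(p+q)
# matrix, so fits remain fast at trial sizes of a few thousand trees.

.design_columns <- c("tree_id", "subrace", "family", "replicate", "iblock", "plot")

# sparse 0/1 indicator matrix for a grouping factor
.indicator <- function(f) {
  f <- factor(f)
  Matrix::sparseMatrix(
    i = seq_along(f), j = as.integer(f), x = 1,
    dims = c(length(f), nlevels(f)),
    dimnames = list(NULL, levels(f))
  )
}

# fixed-effect design matrix; drops aliased columns so W'W + D stays
# positive definite
.fixed_design <- function(data, fixed_terms) {
  if (length(fixed_terms) == 0L) {
    X <- matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    fml <- stats::as.formula(paste("~", paste(fixed_terms, collapse = " + ")))
    X <- stats::model.matrix(fml, data = data)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

# Precomputed pieces reused across likelihood evaluations.
# Zlist: named list of sparse indicator matrices (may be empty).
.uni_workspace <- function(y, X, Zlist) {
  W <- Matrix::Matrix(X, sparse = TRUE)
  if (length(Zlist)) W <- do.call(cbind, c(list(W), unname(Zlist)))
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  # symbolic factorisation reused (with updated values) by every
  # likelihood evaluation; the sparsity pattern never changes
  ch0 <- Matrix::Cholesky(
    WtW + Matrix::Diagonal(n = ncol(W)), LDL = FALSE, super = TRUE)
  list(
    WtW = WtW,
    ch0 = ch0,
    Wty = as.numeric(Matrix::crossprod(W, y)),
    yty = sum(y^2),
    n = length(y), p = ncol(X),
    q = vapply(Zlist, ncol, integer(1L)),
    col_names = colnames(X),
    levels = names(Zlist)
  )
}

# -2 * restricted log-likelihood at absolute variances
# sig2: named vector, components in ws$levels order then "residual"
.uni_m2ll <- function(sig2, ws) {
  s2e <- sig2[["residual"]]
  q <- ws$q
  dvec <- c(rep(0, ws$p), rep(s2e / pmax(sig2[ws$levels], 1e-300), times = q))
  C <- ws$WtW + Matrix::Diagonal(x = dvec)
  ch <- tryCatch(Matrix::update(ws$ch0, C), error = function(e) NULL)
  if (is.null(ch)) return(list(m2ll = Inf))
  ldet <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  b <- as.numeric(Matrix::solve(ch, ws$Wty, system = "A"))
  rss <- ws$yty - sum(b * ws$Wty)
  qtot <- sum(q)
  m2ll <- (ws$n - ws$p) * log(2 * pi) + (ws$n - ws$p - qtot) * log(s2e) +
    sum(q * log(pmax(sig2[ws$levels], 1e-300))) + ldet + rss / s2e
  list(m2ll = m2ll, b = b, rss = rss)
}

# Profiled objective in gamma_l = s2_l / s2_e; the residual variance has the
# closed-form optimum s2_e^ = rss/(n-p), so the optimiser works in one fewer
# dimension and is scale free.
.uni_profiled <- function(gamma, ws) {
  q <- ws$q
  dvec <- c(rep(0, ws$p), rep(1 / gamma, times = q))
  C <- ws$WtW + Matrix::Diagonal(x = dvec)
  ch <- tryCatch(Matrix::update(ws$ch0, C), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  ldet <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  b <- as.numeric(Matrix::solve(ch, ws$Wty, system = "A"))
  rss <- ws$yty - sum(b * ws$Wty)
  if (rss <= 0) return(Inf)
  np <- ws$n - ws$p
  np * (log(2 * pi) + 1 + log(rss / np)) + sum(q * log(gamma)) + ldet
}

# nlminb with an escalation ladder.  "False convergence" at tight
# tolerances is accepted when a restart from the solution cannot improve
# the objective beyond numerical noise; a genuinely stuck quasi-Newton
# path is polished by a derivative-free Nelder-Mead stage before the
# final nlminb verdict.
.nlminb_checked <- function(start, objective, lower = -Inf, upper = Inf,
                            control, nm_fallback = TRUE) {
  run <- function(st) {
    stats::nlminb(st, objective, lower = lower, upper = upper,
      control = control)
  }
  settle <- function(opt) {
    opt2 <- run(opt$par)
    if (opt2$objective <= opt$objective) {
      if (opt2$convergence != 0 &&
          opt$objective - opt2$objective < 1e-6) opt2$convergence <- 0L
      opt2
    } else {
      opt$convergence <- 0L # the restart cannot improve
      opt
    }
  }
  # a restart from the solution both verifies convergence and polishes
  # the last digits of flat-ridge optima
  opt <- settle(run(start))
  if (opt$convergence != 0 && nm_fallback) {
    # derivative-free rescue for quasi-Newton paths stuck short of the
    # optimum; not used for unbounded-ridge (degenerate) objectives where
    # a simplex can wander along the ridge
    clamp <- function(p) pmin(pmax(p, lower), upper)
    nm <- stats::optim(opt$par, function(p) objective(clamp(p)),
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-12))
    opt3 <- run(clamp(nm$par))
    if (opt3$objective <= opt$objective) opt <- opt3
    if (opt$convergence != 0) opt <- settle(opt)
  }
  opt
}

# A few damped Newton steps from a converged point, using numerical
# derivatives: nlminb's stopping rule leaves ~1e-5 relative error in the
# parameters on flat objectives, while downstream identities (REML =
# balanced ANOVA) are asserted to 1e-6.  Only applied strictly inside the
# bounds; boundary solutions do not need the extra digits.
.newton_polish <- function(objective, par, lower, upper, steps = 3L) {
  lo <- rep_len(lower, length(par)); up <- rep_len(upper, length(par))
  if (any(par <= 2 * lo) || any(par >= up / 2)) return(par)
  f0 <- objective(par)
  for (s in seq_len(steps)) {
    g <- .num_grad(objective, par, rel = 1e-6)
    H <- .num_hessian(objective, par, rel = 1e-4)
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) break
    moved <- FALSE
    for (damp in c(1, 0.5, 0.25)) {
      cand <- pmin(pmax(par - damp * delta, lo), up)
      fc <- objective(cand)
      if (is.finite(fc) && fc <= f0 + 1e-10) {
        par <- cand; f0 <- fc; moved <- TRUE
        break
      }
    }
    if (!moved || sqrt(sum(delta^2)) < 1e-10 * max(1, sqrt(sum(par^2)))) break
  }
  par
}

# Numerical Hessian by central differences with relative steps.
.num_hessian <- function(f, x, rel = 1e-4, floor = 1e-8) {
  k <- length(x)
  h <- pmax(abs(x) * rel, floor)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Low-level univariate REML driver.
#
# tie: optional list(from =, to =, k =) imposing s2_from = k * s2_to
# fixed_value: optional named scalar holding one component at an absolute value
# Returns components (absolute variances incl. residual), loglik, beta, flags.
.reml_uni <- function(y, X, Zlist, tie = NULL, fixed_value = NULL,
                      vcov = TRUE, control = list()) {
  ctl <- utils::modifyList(
    list(iter.max = 500L, eval.max = 2000L, rel.tol = 1e-12, x.tol = 1e-11),
    control
  )
  ws <- .uni_workspace(y, X, Zlist)
  lv <- ws$levels
  comp_names <- c(lv, "residual")
  lower_g <- 1e-10

  if (!is.null(fixed_value)) {
    # absolute constraint: optimise the remaining variances unprofiled
    fx_name <- names(fixed_value)
    stopifnot(fx_name %in% lv)
    free <- setdiff(comp_names, fx_name)
    vtot <- stats::var(y)
    start <- stats::setNames(rep(vtot / length(comp_names), length(free)), free)
    start["residual"] <- vtot / 2
    objf <- function(par) {
      sig2 <- stats::setNames(numeric(length(comp_names)), comp_names)
      sig2[free] <- par
      sig2[fx_name] <- fixed_value
      .uni_m2ll(sig2, ws)$m2ll
    }
    opt <- .nlminb_checked(start, objf,
      lower = c(rep(lower_g * vtot, length(free) - 1L), 1e-12 * vtot),
      control = ctl[c("iter.max", "eval.max", "rel.tol", "x.tol")]
    )
    sig2 <- stats::setNames(numeric(length(comp_names)), comp_names)
    sig2[free] <- opt$par
    sig2[fx_name] <- fixed_value
    conv <- opt$convergence == 0
  } else {
    # profiled optimisation over variance ratios
    if (!is.null(tie)) {
      stopifnot(tie$from %in% lv, tie$to %in% lv)
      free_g <- setdiff(lv, tie$from)
    } else {
      free_g <- lv
    }
    expand_gamma <- function(g) {
      gam <- stats::setNames(numeric(length(lv)), lv)
      gam[free_g] <- g
      if (!is.null(tie)) gam[tie$from] <- max(tie$k * gam[tie$to], lower_g)
      gam
    }
    if (length(free_g)) {
      start <- stats::setNames(rep(0.2, length(free_g)), free_g)
      if (!is.null(ctl$start)) start[] <- rep_len(ctl$start, length(free_g))
      objf <- function(g) .uni_profiled(expand_gamma(g)[lv], ws)
      opt <- .nlminb_checked(start, objf,
        lower = lower_g, upper = 1e8,
        control = ctl[c("iter.max", "eval.max", "rel.tol", "x.tol")]
      )
      polished <- .newton_polish(objf, opt$par, lower = lower_g,
        upper = 1e8)
      gam <- expand_gamma(polished)
      conv <- opt$convergence == 0
    } else {
      gam <- expand_gamma(numeric(0))
      conv <- TRUE
    }
    # recover the residual variance at the profiled optimum
    q <- ws$q
    dvec <- c(rep(0, ws$p), rep(1 / gam, times = q))
    C <- ws$WtW + Matrix::Diagonal(x = dvec)
    ch <- Matrix::Cholesky(C, LDL = FALSE)
    b <- as.numeric(Matrix::solve(ch, ws$Wty, system = "A"))
    rss <- ws$yty - sum(b * ws$Wty)
    s2e <- rss / (ws$n - ws$p)
    sig2 <- stats::setNames(c(gam * s2e, s2e), comp_names)
  }

  ev <- .uni_m2ll(sig2, ws)
  beta <- stats::setNames(ev$b[seq_len(ws$p)], ws$col_names)

  vtot <- sum(sig2)
  boundary <- stats::setNames(sig2 < 1e-6 * vtot, comp_names)
  boundary["residual"] <- FALSE

  V <- NULL
  if (vcov && !any(boundary)) {
    # asymptotic covariance of the free variance components from the
    # observed information of the restricted likelihood
    free <- if (!is.null(fixed_value)) {
      setdiff(comp_names, names(fixed_value))
    } else if (!is.null(tie)) setdiff(comp_names, tie$from) else comp_names
    hfun <- function(par) {
      s <- sig2
      s[free] <- par
      if (!is.null(tie)) s[tie$from] <- tie$k * s[tie$to]
      .uni_m2ll(s, ws)$m2ll
    }
    H <- .num_hessian(hfun, sig2[free])
    V <- tryCatch(solve(H / 2), error = function(e) NULL)
    if (!is.null(V)) dimnames(V) <- list(free, free)
  }

  opt_info <- if (exists("opt", inherits = FALSE)) {
    list(iterations = opt$iterations, evaluations = opt$evaluations,
      message = opt$message)
  } else NULL

  list(
    components = sig2,
    boundary = boundary,
    loglik = -ev$m2ll / 2,
    fixef = beta,
    vcov = V,
    n_used = ws$n,
    p = ws$p,
    converged = conv,
    optim_info = opt_info
  )
}
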