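#' Subrace means of a trait
#'
#' Least-squares means from the subrace-fixed mixed model (adjusted for
#' replicate fixed effects, with incomplete block and family as random
#' effects), or raw arithmetic means.  LS means are the default because
#' the trial is unbalanced across replicates and blocks; a subrace's LS
#' mean is its fixed-effect estimate plus the average replicate effect.
#'
#' @param table phenotype table.
#' @param trait trait column name.
#' @param method `"lsmeans"` (default) or `"raw"`.
#' @return Named numeric vector of per-subrace means.  Subraces without
#'   data are omitted with a warning.
#' @export
subrace_means <- function(table, trait, method = c("lsmeans", "raw")) {
  method <- match.arg(method)
  .check_phenotypes(table, trait)
  keep <- !is.na(table[[trait]])
  empty <- setdiff(unique(table$subrace), unique(table$subrace[keep]))
  if (length(empty)) {
    warning("omitting subrace(s) with no data for ", trait, ": ",
      paste(empty, collapse = ", "))
  }
  dat <- table[keep, , drop = FALSE]
  if (length(unique(dat$subrace)) < 3L) {
    stop("need data in at least three subraces", call. = FALSE)
  }
  if (method == "raw") {
    return(tapply(dat[[trait]], dat$subrace, mean))
  }
  fit <- fit_univariate(dat, model_spec(trait, subrace_as = "fixed"),
    se = FALSE)
  beta <- fit$fixef
  mf <- fit$model_frame
  subs <- levels(factor(mf$subrace))
  # treatment contrasts: intercept + subrace effect + mean replicate effect
  rep_cols <- grep("^replicate", names(beta), value = TRUE)
  n_rep <- length(unique(mf$replicate))
  rep_adj <- if (n_rep > 1L) sum(beta[rep_cols]) / n_rep else 0
  mu <- beta[["(Intercept)"]] + rep_adj
  out <- vapply(subs, function(s) {
    cl <- paste0("subrace", s)
    mu + if (cl %in% names(beta)) beta[[cl]] else 0
  }, numeric(1L))
  stats::setNames(out, subs)
}

#' Regress subrace means on latitude of origin
#'
#' Ordinary least squares of per-subrace trait means on their latitude of
#' origin (signed decimal degrees; here degrees South as positive
#' magnitudes, so a positive slope means the trait increases southward).
#'
#' @param means named per-subrace means, as from [subrace_means()].
#' @param latitudes either a named numeric vector of latitudes or a
#'   `data.frame` with columns `subrace` and `latitude_deg`.
#' @param weights optional per-subrace weights (e.g. family counts);
#'   unweighted by default.
#' @return A `cline_fit` list: `slope`, `intercept`, `r_squared`
#'   (percent), `p_value` (two-sided, `n_subraces - 2` df), `n_subraces`.
#' @examples
#' lat <- c(a = 38, b = 40, c = 42, d = 43)
#' m <- 1.9 + 0.04 * lat + c(a = 0.01, b = -0.01, c = 0, d = 0.005)
#' regress_on_latitude(m, lat)
#' @export
regress_on_latitude <- function(means, latitudes, weights = NULL) {
  if (is.data.frame(latitudes)) {
    latitudes <- stats::setNames(latitudes$latitude_deg, latitudes$subrace)
  }
  orphans <- c(setdiff(names(means), names(latitudes)),
    setdiff(names(latitudes), names(means)))
  common <- intersect(names(means), names(latitudes))
  if (length(common) < 3L) {
    stop("need at least three subraces shared between means and latitudes",
      if (length(orphans)) paste0("; unmatched: ",
        paste(orphans, collapse = ", ")) else "", call. = FALSE)
  }
  if (length(orphans)) {
    warning("dropping unmatched subrace(s): ", paste(orphans, collapse = ", "))
  }
  df <- data.frame(m = as.numeric(means[common]),
    lat = as.numeric(latitudes[common]))
  if (stats::var(df$m) == 0) {
    return(structure(list(slope = 0, intercept = df$m[1L], r_squared = 0,
      p_value = 1, n_subraces = length(common)), class = "cline_fit"))
  }
  fit <- stats::lm(m ~ lat, data = df, weights = weights)
  sm <- suppressWarnings(summary(fit)) # perfect fits warn harmlessly
  p <- if (nrow(sm$coefficients) > 1L) sm$coefficients["lat", 4L] else NA_real_
  if (sm$sigma == 0) p <- 0  # exactly collinear means
  structure(list(
    slope = unname(stats::coef(fit)[["lat"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = 100 * sm$r.squared,
    p_value = p,
    n_subraces = length(common)
  ), class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf(
    "Latitudinal cline over %d subraces: slope = %.4g per degree (p = %.3g %s), R2 = %.1f%%\n",
    x$n_subraces, x$slope, x$p_value, significance_stars(x$p_value),
    x$r_squared))
  invisible(x)
}
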