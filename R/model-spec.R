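#' Specify a trial mixed model
#'
#' Builds the model specification used by [fit_univariate()],
#' [fit_bivariate()] and [fit_constrained()].  The default model is the one
#' used throughout: replicate as a fixed effect, incomplete block within
#' replicate and family within subrace as random effects, and subrace fixed
#' in univariate analyses but random whenever the subrace variance component
#' itself is of interest (Qst) or a bivariate fit is requested.
#'
#' @param response character; one trait name (univariate) or two (bivariate).
#' @param subrace_as `"fixed"` or `"random"`.  Bivariate fits require
#'   `"random"`.
#' @param include_iblock logical; fit the incomplete-block variance
#'   component.  Set to `FALSE` for data without block structure.
#' @param include_family logical; fit the family-within-subrace component.
#'   Dropping it gives the null model of the family-variance test.
#' @param fixed_terms character vector of fixed-effect columns in addition
#'   to the intercept; `"replicate"` by default (and `"subrace"` is appended
#'   automatically when `subrace_as = "fixed"`).
#' @param constraint optional constraint for [fit_constrained()]: either
#'   `list(term =, value =)` holding one variance component at an absolute
#'   value, or `list(type = "qst_ratio", fst =, relatedness =)` tying the
#'   subrace variance to the family variance at the value where Qst equals
#'   Fst, i.e. `sigma2_subrace = 2 * fst / (1 - fst) * sigma2_family /
#'   relatedness`.
#'
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("SG")
#' model_spec("SG", subrace_as = "random",
#'   constraint = list(type = "qst_ratio", fst = 0.09, relatedness = 0.4))
#' @export
model_spec <- function(response, subrace_as = c("fixed", "random"),
                       include_iblock = TRUE, include_family = TRUE,
                       fixed_terms = "replicate", constraint = NULL) {
  subrace_as <- match.arg(subrace_as)
  stopifnot(is.character(response), length(response) %in% 1:2)
  if (length(response) == 2L && subrace_as != "random") {
    stop("bivariate models require subrace_as = \"random\"", call. = FALSE)
  }
  if (!is.null(constraint)) {
    if (!is.null(constraint$type) && constraint$type == "qst_ratio") {
      fst <- constraint$fst
      r <- constraint$relatedness
      if (!is.numeric(fst) || fst <= 0 || fst >= 1) {
        stop("qst_ratio constraint needs fst in (0, 1)", call. = FALSE)
      }
      if (!is.numeric(r) || r <= 0 || r > 1) {
        stop("qst_ratio constraint needs relatedness in (0, 1]", call. = FALSE)
      }
      if (subrace_as != "random") {
        stop("the qst_ratio constraint requires subrace_as = \"random\"",
          call. = FALSE)
      }
    } else {
      if (is.null(constraint$term) || is.null(constraint$value)) {
        stop("constraint must be list(term=, value=) or list(type=\"qst_ratio\", ...)",
          call. = FALSE)
      }
      if (constraint$value < 0) {
        stop("constrained variance value must be non-negative", call. = FALSE)
      }
    }
  }
  structure(
    list(
      response = response,
      subrace_as = subrace_as,
      include_iblock = include_iblock,
      include_family = include_family,
      fixed_terms = fixed_terms,
      constraint = constraint
    ),
    class = "model_spec"
  )
}

# required design columns present, family nested in subrace
.check_phenotypes <- function(table, traits = character(0)) {
  need <- c("subrace", "family", "replicate", "iblock", traits)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE)
  }
  map <- unique(table[, c("family", "subrace")])
  dup <- map$family[duplicated(map$family)]
  if (length(dup)) {
    stop("family identifier(s) mapped to more than one subrace: ",
      paste(utils::head(unique(dup), 5L), collapse = ", "), call. = FALSE)
  }
  invisible(table)
}

# unique incomplete-block grouping (iblock labels may repeat across replicates)
.iblock_id <- function(table) {
  interaction(table$replicate, table$iblock, drop = TRUE, sep = ":")
}
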