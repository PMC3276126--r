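#' Read a phenotype table from CSV
#'
#' Expects the header `tree_id,subrace,family,replicate,iblock,plot,
#' <trait1>,...` (the `plot` column is optional).  Empty fields become
#' missing values; identifier columns are kept as character labels.
#'
#' @param path CSV file path.
#' @return A validated phenotype `data.frame`.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
    na.strings = c("", "NA"))
  need <- c("tree_id", "subrace", "family", "replicate", "iblock")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("phenotype CSV is missing required column(s): ",
      paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$tree_id)) {
    stop("duplicate tree_id values in ", path, call. = FALSE)
  }
  for (cl in intersect(.design_columns, names(tab))) {
    tab[[cl]] <- as.character(tab[[cl]])
  }
  trait_cols <- setdiff(names(tab), .design_columns)
  for (cl in trait_cols) {
    tab[[cl]] <- as.numeric(tab[[cl]])
    if (all(is.na(tab[[cl]]))) {
      stop("trait column '", cl, "' is entirely missing", call. = FALSE)
    }
  }
  .check_phenotypes(tab, trait_cols)
}

#' Write a phenotype table to CSV
#'
#' Missing trait values are written as empty fields, the format
#' [read_phenotypes()] reads back.
#'
#' @param table phenotype table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a subrace latitude table from CSV
#'
#' @param path CSV with columns `subrace,latitude_deg` (degrees South as
#'   positive magnitudes).
#' @return `data.frame` with those two columns.
#' @export
read_latitudes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subrace", "latitude_deg") %in% names(tab))) {
    stop("latitude CSV needs columns subrace,latitude_deg", call. = FALSE)
  }
  tab$subrace <- as.character(tab$subrace)
  tab$latitude_deg <- as.numeric(tab$latitude_deg)
  tab
}

#' Read a simulation configuration from YAML
#'
#' Flat-key YAML mapping of [sim_config()] arguments; correlation matrices
#' may be given as nested lists of rows.  A `seed` key is mandatory.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("sim config YAML must set a seed", call. = FALSE)
  for (nm in grep("^corr_", names(raw), value = TRUE)) {
    raw[[nm]] <- do.call(rbind, lapply(raw[[nm]], as.numeric))
  }
  known <- names(formals(sim_config))
  do.call(sim_config, raw[intersect(names(raw), known)])
}

#' Analysis configuration
#'
#' Bundles the inputs of [run_full_analysis()].
#'
#' @param phenotypes a phenotype table, or a path to a phenotype CSV, or a
#'   [sim_config()] to simulate from.
#' @param traits trait columns to analyse (default: all trait columns).
#' @param trait_pairs list of length-2 character vectors for the bivariate
#'   correlation analyses; defaults to all pairs of `traits` (empty when
#'   only one trait).
#' @param latitudes optional latitude table (`data.frame` or CSV path);
#'   simulated tables carry their own.
#' @param fst Fst value(s) against which Qst is tested; the default tests
#'   against 0.09 with a 0.158 sensitivity value.
#' @param relatedness_r coefficient of relatedness in `(0, 1]`.
#' @param output_dir directory for report files, or `NULL` to skip
#'   writing.
#' @param seed integer seed used for any simulation step.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(phenotypes, traits = NULL, trait_pairs = NULL,
                            latitudes = NULL, fst = c(0.09, 0.158),
                            relatedness_r = 0.4, output_dir = NULL,
                            seed = 1L) {
  if (any(fst <= 0) || any(fst >= 1)) stop("fst values must lie in (0, 1)")
  if (relatedness_r <= 0 || relatedness_r > 1) {
    stop("relatedness_r must lie in (0, 1]")
  }
  structure(list(
    phenotypes = phenotypes, traits = traits, trait_pairs = trait_pairs,
    latitudes = latitudes, fst = fst, relatedness_r = relatedness_r,
    output_dir = output_dir, seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Run the full trial analysis
#'
#' Orchestrates the whole pipeline on a phenotype table (read, supplied,
#' or simulated): per-trait genetic parameters with the family-variance
#' and Qst-versus-Fst likelihood-ratio tests, bivariate correlations with
#' their two-tailed tests, and latitudinal cline regressions.  When
#' `output_dir` is set, writes `genetic_params.csv`, `correlations.csv`,
#' `divergence_tests.csv`, `cline.csv`, a `summary.json` and a plain-text
#' run log.
#'
#' @param config an [analysis_config()].
#' @return A report bundle (list) with elements `genetic_params`,
#'   `correlations`, `divergence_tests`, `cline`, `status` and `seed`,
#'   invisibly when written to disk.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  ph <- config$phenotypes
  if (inherits(ph, "sim_config")) {
    ph$seed <- config$seed
    tab <- simulate_trial(ph)
  } else if (is.character(ph)) {
    tab <- read_phenotypes(ph)
  } else {
    tab <- ph
  }
  traits <- config$traits
  if (is.null(traits)) traits <- setdiff(names(tab), .design_columns)
  pairs <- config$trait_pairs
  if (is.null(pairs)) {
    pairs <- if (length(traits) > 1L) {
      utils::combn(traits, 2L, simplify = FALSE)
    } else list()
  }
  lat <- config$latitudes
  if (is.character(lat)) lat <- read_latitudes(lat)
  if (is.null(lat)) lat <- attr(tab, "latitudes")

  status <- character(0)
  note <- function(...) {
    status <<- c(status, paste0(...))
  }

  params <- NULL
  tests <- NULL
  for (tr in traits) {
    row <- tryCatch(
      genetic_params(tab, tr, config$relatedness_r),
      error = function(e) {
        note("genetic_params failed for ", tr, ": ", conditionMessage(e))
        NULL
      })
    params <- rbind(params, row)
    fv <- tryCatch(test_family_variance(tab, tr), error = function(e) {
      note("family-variance LRT failed for ", tr, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(fv)) {
      tests <- rbind(tests, data.frame(trait = tr, test = "family_variance",
        fst = NA_real_, statistic = fv$statistic, p = fv$p_value,
        signif = significance_stars(fv$p_value), stringsAsFactors = FALSE))
    }
    for (f in config$fst) {
      qt <- tryCatch(
        test_qst_exceeds_fst(tab, tr, f, config$relatedness_r),
        error = function(e) {
          note("Qst-Fst LRT failed for ", tr, " at Fst=", f, ": ",
            conditionMessage(e))
          NULL
        })
      if (!is.null(qt)) {
        tests <- rbind(tests, data.frame(trait = tr, test = "qst_gt_fst",
          fst = f, statistic = qt$statistic, p = qt$p_value,
          signif = significance_stars(qt$p_value), stringsAsFactors = FALSE))
      }
    }
  }

  cors <- NULL
  for (pr in pairs) {
    res <- tryCatch({
      bf <- fit_bivariate(tab, model_spec(pr, subrace_as = "random"))
      ct <- genetic_correlations(bf)
      pa <- test_correlation_nonzero(bf, "additive")
      ps <- test_correlation_nonzero(bf, "subrace")
      # phenotypic-level p from a normal approximation on the delta SE
      rp <- ct$r[ct$level == "phenotypic"]
      sp <- ct$se[ct$level == "phenotypic"]
      pp <- if (is.finite(sp) && sp > 0) {
        2 * stats::pnorm(-abs(rp) / sp)
      } else NA_real_
      data.frame(
        trait1 = pr[1L], trait2 = pr[2L],
        level = ct$level, r = ct$r, se = ct$se,
        p = c(pa$p_value, ps$p_value, pp),
        signif = significance_stars(c(pa$p_value, ps$p_value, pp)),
        stringsAsFactors = FALSE)
    }, error = function(e) {
      note("bivariate analysis failed for ", paste(pr, collapse = "/"),
        ": ", conditionMessage(e))
      NULL
    })
    cors <- rbind(cors, res)
  }

  clines <- NULL
  if (!is.null(lat)) {
    for (tr in traits) {
      cf <- tryCatch({
        m <- subrace_means(tab, tr)
        regress_on_latitude(m, lat)
      }, error = function(e) {
        note("cline regression failed for ", tr, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(cf)) {
        clines <- rbind(clines, data.frame(trait = tr, slope = cf$slope,
          p = cf$p_value, signif = significance_stars(cf$p_value),
          r_squared = cf$r_squared, n_subraces = cf$n_subraces,
          stringsAsFactors = FALSE))
      }
    }
  } else {
    note("no latitude table available; cline analysis skipped")
  }

  bundle <- list(
    genetic_params = params,
    correlations = cors,
    divergence_tests = tests,
    cline = clines,
    status = if (length(status)) status else "complete",
    partial = length(status) > 0L,
    seed = config$seed
  )

  out <- config$output_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      if (!is.null(df)) utils::write.csv(df, file.path(out, name),
        row.names = FALSE)
    }
    wr(params, "genetic_params.csv")
    wr(cors, "correlations.csv")
    wr(tests, "divergence_tests.csv")
    wr(clines, "cline.csv")
    jsonlite::write_json(bundle[c("genetic_params", "correlations",
      "divergence_tests", "cline", "status", "seed")],
      file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    writeLines(c(
      paste("seed:", config$seed),
      paste("R version:", R.version.string),
      paste("status:", paste(bundle$status, collapse = "; "))
    ), file.path(out, "run_log.txt"))
    return(invisible(bundle))
  }
  bundle
}
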