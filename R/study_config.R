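#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with the defaults used
#' throughout: the uninformative-unit variance cutoff (sigma^2 < 0.01), the
#' 10-fold / 100-lambda cross-validated Lasso, the significance level
#' alpha = 0.01 for Welch comparisons, the face-selectivity cutoff 0.33,
#' the 62-stimulus held-out split, and the neuron-subset sampling design
#' (5 sizes drawn from [10, 50], 10 subsets per size).
#'
#' @param master_seed integer master seed; stage seeds are derived from it.
#' @param var_threshold variance cutoff below which a scaled unit counts as
#'   uninformative.
#' @param cv_folds number of cross-validation folds for the Lasso.
#' @param n_lambda number of points on the geometric lambda grid.
#' @param lambda_min_ratio ratio of the smallest to the largest lambda.
#' @param alpha two-sided significance level for Welch tests.
#' @param fsi_cutoff face-selectivity index cutoff for neuron selection.
#' @param n_heldout number of held-out stimuli.
#' @param subset_size_range integer length-2 vector, inclusive range of
#'   neuron-subset sizes.
#' @param n_subset_sizes number of distinct subset sizes to draw.
#' @param subsets_per_size number of subsets drawn at each size.
#'
#' @return an object of class `study_config` (a validated named list).
#' @export
study_config <- function(master_seed = 1L,
                         var_threshold = 0.01,
                         cv_folds = 10L,
                         n_lambda = 100L,
                         lambda_min_ratio = 1e-4,
                         alpha = 0.01,
                         fsi_cutoff = 0.33,
                         n_heldout = 62L,
                         subset_size_range = c(10L, 50L),
                         n_subset_sizes = 5L,
                         subsets_per_size = 10L) {
  cfg <- list(master_seed = as.integer(master_seed),
              var_threshold = var_threshold,
              cv_folds = as.integer(cv_folds),
              n_lambda = as.integer(n_lambda),
              lambda_min_ratio = lambda_min_ratio,
              alpha = alpha,
              fsi_cutoff = fsi_cutoff,
              n_heldout = as.integer(n_heldout),
              subset_size_range = as.integer(subset_size_range),
              n_subset_sizes = as.integer(n_subset_sizes),
              subsets_per_size = as.integer(subsets_per_size))
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  counts <- c("cv_folds", "n_lambda", "n_heldout", "n_subset_sizes",
              "subsets_per_size")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L) {
      stop("`", f, "` must be a positive integer")
    }
  }
  if (cfg$var_threshold <= 0) stop("`var_threshold` must be > 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (cfg$lambda_min_ratio <= 0 || cfg$lambda_min_ratio >= 1) {
    stop("`lambda_min_ratio` must lie in (0, 1)")
  }
  if (length(cfg$subset_size_range) != 2L ||
      cfg$subset_size_range[1L] > cfg$subset_size_range[2L]) {
    stop("`subset_size_range` must be an increasing integer pair")
  }
  invisible(cfg)
}

#' Read a configuration file
#'
#' Accepts YAML or JSON whose keys mirror the [study_config()] arguments;
#' unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(study_config))
  bad <- setdiff(names(fields), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(study_config, fields)
}
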