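#' Alignment (completeness) score from a weight matrix
#'
#' Given the nonnegative relative-importance matrix `R` (rows = model
#' units, columns = neurons) from sparse encoding fits, each neuron's
#' weight profile is normalized to a distribution
#' `p_dj = R_dj / sum_d R_dj`, its entropy is taken in base `D` (the total
#' number of model units, with `0 log 0 = 0`), and the neuron's
#' completeness is `C_j = rho_j (1 - H(p_j))` where
#' `rho_j = sum_d R_dj / sum_dj R_dj` is the neuron's share of total
#' weight. The overall score is `C = sum_j C_j`. The score is 1 exactly
#' when every explained neuron is explained by a single model unit, and 0
#' when explanation is spread uniformly; neurons with an all-zero column
#' (not explained at all) contribute nothing and do not hurt the score.
#'
#' @param R nonnegative numeric matrix, model units x neurons, with at
#'   least 2 rows (the base-`D` logarithm is undefined for `D = 1`).
#' @return an object of class `alignment_result`: list with `per_neuron`
#'   (data frame: neuron, rho, entropy, completeness), `total` (the score
#'   `C`), and `n_units` (`D`).
#' @export
alignment_from_weights <- function(R) {
  R <- as.matrix(R)
  if (any(R < 0) || any(!is.finite(R))) stop("`R` must be nonnegative and finite")
  D <- nrow(R)
  if (D < 2L) stop("alignment score undefined for a single model unit (log base 1)")
  if (ncol(R) < 1L) stop("`R` must have at least one neuron column")
  col_tot <- colSums(R)
  grand <- sum(col_tot)
  rho <- if (grand > 0) col_tot / grand else rep(0, ncol(R))
  H <- vapply(seq_len(ncol(R)), function(j) {
    if (col_tot[j] == 0) return(0)
    p <- R[, j] / col_tot[j]
    p <- p[p > 0]
    -sum(p * log(p) / log(D))
  }, numeric(1L))
  Cj <- rho * (1 - H)
  neurons <- colnames(R) %||% paste0("n", seq_len(ncol(R)))
  structure(list(per_neuron = data.frame(neuron = neurons, rho = rho,
                                         entropy = H, completeness = Cj,
                                         row.names = NULL),
                 total = sum(Cj), n_units = D),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> C = %.4f over %d neurons, D = %d model units\n",
              x$total, nrow(x$per_neuron), x$n_units))
  invisible(x)
}

#' Full alignment pipeline: model units -> sparse encoding -> score
#'
#' Composes [zero_uninformative()], [encode_population()] and
#' [alignment_from_weights()] over shared stimuli. For the recombined
#' (artificial) control the original analysis skips the uninformative-unit
#' zeroing and drops to 3 CV folds; `zero_units` and `cv_folds` expose
#' those switches.
#'
#' @inheritParams encode_population
#' @param zero_units logical; zero out uninformative model units first.
#' @param cv_folds optional override of `cfg$cv_folds`.
#' @return an `alignment_result` with extra fields `weights`, `ve`
#'   (held-out VE per neuron), and `informative` (model-unit mask).
#' @export
alignment_pipeline <- function(neural, model, cfg = study_config(), seed = 1L,
                               split = NULL, zero_units = TRUE,
                               cv_folds = NULL) {
  if (!is.null(cv_folds)) cfg$cv_folds <- as.integer(cv_folds)
  if (zero_units) {
    zu <- zero_uninformative(model, cfg)
    model_used <- zu$matrix
    informative <- zu$informative
  } else {
    model_used <- model
    informative <- stats::setNames(rep(TRUE, ncol(model$values)), model$unit_ids)
  }
  enc <- encode_population(neural, model_used, cfg, seed, split = split)
  res <- alignment_from_weights(enc$weights)
  res$weights <- enc$weights
  res$ve <- enc$ve
  res$informative <- informative
  res
}

#' Correlation-ratio and unit-proportion statistics
#'
#' A direct, regression-free view of one-to-one coding. For each neuron,
#' the absolute Pearson correlation with every informative model unit is
#' computed; the neuron's ratio is the maximum correlation divided by the
#' sum of all correlations (1 when a single unit carries all the
#' correlation). The `average_ratio` aggregates over the set of unique
#' best-matching units: neurons are grouped by best unit and, by default,
#' the maximum ratio within each group is averaged across groups
#' (`group_stat = "mean"` averages within groups instead). The
#' `unit_proportion` is the number of unique best-matching units divided by
#' the number of informative units -- a diversity measure.
#'
#' @param neural a neural-kind [response_matrix()].
#' @param model a model-kind [response_matrix()] over the same stimuli.
#' @param informative logical mask over model units (e.g. from
#'   [zero_uninformative()]); `NULL` keeps all units.
#' @param group_stat `"max"` (default) or `"mean"`: statistic taken within
#'   each best-unit group before averaging across groups.
#' @return an object of class `correlation_summary`: list with
#'   `per_neuron` (data frame: neuron, ratio, best_unit), `average_ratio`,
#'   `unit_proportion`, `n_informative`.
#' @export
correlation_summary <- function(neural, model, informative = NULL,
                                group_stat = c("max", "mean")) {
  group_stat <- match.arg(group_stat)
  stopifnot(inherits(neural, "response_matrix"), inherits(model, "response_matrix"))
  if (!identical(neural$stimulus_ids, model$stimulus_ids)) {
    shared <- intersect(neural$stimulus_ids, model$stimulus_ids)
    if (length(shared) < 3L) stop("matrices share fewer than 3 stimuli")
    neural <- select_stimuli(neural, shared)
    model <- select_stimuli(model, shared)
  }
  if (is.null(informative)) informative <- rep(TRUE, ncol(model$values))
  if (!any(informative)) stop("no informative model units")
  Z <- model$values[, informative, drop = FALSE]
  unit_ids <- model$unit_ids[informative]
  # Constant units or neurons get correlation 0 rather than NA.
  const_z <- col_sds(Z) == 0
  const_n <- col_sds(neural$values) == 0
  if (any(const_z) || any(const_n)) {
    message("constant columns present: their correlations are defined as 0")
  }
  cors <- suppressWarnings(abs(stats::cor(neural$values, Z)))
  cors[!is.finite(cors)] <- 0
  ratio <- numeric(nrow(cors))
  best <- integer(nrow(cors))
  for (j in seq_len(nrow(cors))) {
    s <- sum(cors[j, ])
    ratio[j] <- if (s > 0) max(cors[j, ]) / s else 0
    best[j] <- which.max(cors[j, ]) # ties -> lowest unit index
  }
  groups <- split(ratio, best)
  per_group <- vapply(groups, if (group_stat == "max") max else mean, numeric(1L))
  structure(list(per_neuron = data.frame(neuron = neural$unit_ids,
                                         ratio = ratio,
                                         best_unit = unit_ids[best],
                                         row.names = NULL),
                 average_ratio = mean(per_group),
                 unit_proportion = length(groups) / length(unit_ids),
                 n_informative = length(unit_ids)),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf(
    "<correlation_summary> average ratio = %.4f, unit proportion = %.4f (%d informative units)\n",
    x$average_ratio, x$unit_proportion, x$n_informative))
  invisible(x)
}
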