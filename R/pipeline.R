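#' Alignment ceiling from neuron subsets
#'
#' How well can the neural population explain itself, one subset at a
#' time? Each sampled neuron subset is treated as a "model" and scored
#' with the full [alignment_pipeline()] against the whole population. In a
#' population with redundant coding (several neurons per factor) the
#' subsets cannot reach the maximal score of 1 -- they provide the
#' empirical ceiling that genuine models are compared against.
#'
#' @param neural a neural-kind [response_matrix()].
#' @param cfg a [study_config()].
#' @param seed integer seed for subset sampling and fits.
#' @param max_subsets optional cap on the number of subsets scored (the
#'   sampler's full design is 5 sizes x 10 subsets = 50).
#' @param split optional precomputed train/held-out stimulus split.
#' @return numeric vector of alignment scores, one per subset, with the
#'   subset sizes in `attr(, "sizes")`.
#' @export
ceiling_from_subsets <- function(neural, cfg = study_config(), seed = 1L,
                                 max_subsets = NULL, split = NULL) {
  subsets <- sample_neuron_subsets(neural, cfg, seed)
  if (!is.null(max_subsets)) subsets <- subsets[seq_len(min(max_subsets, length(subsets)))]
  scores <- vapply(seq_along(subsets), function(i) {
    sub <- subsets[[i]]
    sub$kind <- "model"
    alignment_pipeline(neural, sub, cfg, derive_seed(seed, 50L + i),
                       split = split)$total
  }, numeric(1L))
  names(scores) <- names(subsets)
  attr(scores, "sizes") <- vapply(subsets, attr, integer(1L), "subset_size")
  scores
}

#' Run the full synthetic comparison
#'
#' One seeded end-to-end run over a generated world: realizes the neural
#' population and every model recipe, fits encoding and decoding models,
#' computes alignment, correlation-ratio/unit-proportion and UDR scores,
#' decodes held-out stimuli from one-to-one matched neurons, and adds the
#' two controls -- alignment against linearly recombined (artificial)
#' responses and the neuron-subset ceiling. All quantities are
#' recomputable from `cfg` plus the world parameters alone.
#'
#' @param cfg a [study_config()]; `cfg$master_seed` drives every stage.
#' @param recipes named list of [model_recipe()]s (>= 1; UDR needs >= 2).
#' @param S,K,J,noise_sd world parameters (see [generate_world()]).
#' @param n_ceiling_subsets number of neuron subsets scored for the
#'   ceiling; 0 skips the ceiling stage.
#' @param artificial_control logical; also score every model against
#'   recombined responses (3 CV folds, no unit zeroing, as in the original
#'   control).
#' @return an object of class `run_report`: list with `config`, `world`,
#'   `models` (data frame of per-model scores), `per_model` (stage
#'   objects), `udr`, `ceiling`, `welch` (pairwise comparisons of
#'   per-neuron completeness), `seeds`.
#' @export
run_full_comparison <- function(cfg = study_config(),
                                recipes = default_recipes(),
                                S = 500L, K = 8L, J = 60L, noise_sd = 0.5,
                                n_ceiling_subsets = 20L,
                                artificial_control = TRUE) {
  if (length(recipes) < 1L) stop("need at least one model recipe")
  if (is.null(names(recipes))) {
    names(recipes) <- vapply(recipes, function(r) r$family, character(1L))
  }
  seed <- cfg$master_seed
  world <- generate_world(S = S, K = K, J = J, noise_sd = noise_sd, seed = seed)
  neural <- realize_neural(world)
  parts <- split_heldout(neural, cfg$n_heldout, derive_seed(seed, 60L))
  split <- list(train = parts$train$stimulus_ids,
                heldout = parts$heldout$stimulus_ids)
  artificial <- if (artificial_control) {
    make_artificial_neural(neural, derive_seed(seed, 61L))
  } else NULL

  models <- list()
  rows <- list()
  for (nm in names(recipes)) {
    model <- realize_model(world, recipes[[nm]])
    zu <- zero_uninformative(model, cfg)
    align <- alignment_pipeline(neural, model, cfg,
                                derive_seed(seed, 62L), split = split)
    corr <- correlation_summary(neural, model, zu$informative)
    dec <- decode_population(model, neural, cfg, derive_seed(seed, 63L),
                             split = split, informative = zu$informative)
    asg <- match_units(model, neural, zu$informative)
    fit <- decode_from_matched(asg,
                               neural_train = select_stimuli(neural, split$train),
                               model_train = select_stimuli(model, split$train),
                               neural_heldout = select_stimuli(neural, split$heldout),
                               model_heldout = select_stimuli(model, split$heldout))
    cosine <- cosine_distance_score(fit$truth, fit$predicted)
    recon <- if (!is.null(model$factor_map)) {
      reconstruction_error(world, fit$predicted_raw, model, split$heldout)
    } else NA_real_
    art_align <- if (artificial_control) {
      alignment_pipeline(artificial$responses, model, cfg,
                         derive_seed(seed, 64L), split = split,
                         zero_units = FALSE, cv_folds = 3L)$total
    } else NA_real_
    models[[nm]] <- list(model = model, alignment = align, corr = corr,
                         assignment = asg)
    rows[[nm]] <- data.frame(
      model = nm, family = recipes[[nm]]$family,
      n_units = ncol(model$values), n_informative = sum(zu$informative),
      alignment = align$total,
      average_ratio = corr$average_ratio,
      unit_proportion = corr$unit_proportion,
      median_encode_ve = stats::median(align$ve, na.rm = TRUE),
      median_decode_ve = stats::median(dec$ve, na.rm = TRUE),
      mean_cosine_distance = as.numeric(cosine),
      reconstruction_error = recon,
      alignment_vs_artificial = art_align,
      row.names = NULL)
  }
  table <- do.call(rbind, rows)

  udr <- if (length(models) >= 2L) {
    udr_family(lapply(models, `[[`, "model"), cfg)
  } else {
    message("single model: UDR stage skipped")
    NULL
  }
  ceiling <- if (n_ceiling_subsets > 0L) {
    ceiling_from_subsets(neural, cfg, derive_seed(seed, 65L),
                         max_subsets = n_ceiling_subsets, split = split)
  } else NULL
  if (!is.null(udr)) table$udr <- udr$per_model[table$model]

  welch <- list()
  nms <- names(models)
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j <= i) next
      key <- paste(nms[i], "vs", nms[j])
      welch[[key]] <- welch_test(
        models[[nms[i]]]$alignment$per_neuron$completeness,
        models[[nms[j]]]$alignment$per_neuron$completeness,
        alpha = cfg$alpha)
    }
  }

  structure(list(config = cfg,
                 world = list(S = S, K = K, J = J, noise_sd = noise_sd,
                              seed = seed),
                 models = table, per_model = models, udr = udr,
                 ceiling = ceiling, welch = welch,
                 seeds = list(master = seed)),
            class = "run_report")
}

#' Default model zoo
#'
#' The four-recipe zoo used throughout: a disentangled reference, its
#' rotated (entangled) sibling on the same factors, a sparseness-matched
#' random baseline and a PCA-like dense baseline.
#'
#' @param K number of world factors the recipes should span.
#' @param noise_sd unit noise for the factor-based recipes.
#' @param seed integer seed shared by the recipes.
#' @return named list of [model_recipe()]s.
#' @export
default_recipes <- function(K = 8L, noise_sd = 0.1, seed = 1L) {
  list(disentangled = model_recipe("disentangled", n_units = K,
                                   noise_sd = noise_sd, seed = seed),
       rotated = model_recipe("rotated", n_units = K, noise_sd = noise_sd,
                              seed = seed),
       sparse_random = model_recipe("sparse_random", n_units = K, seed = seed),
       pca_like = model_recipe("pca_like", n_units = K, seed = seed))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> world S=%d K=%d J=%d (seed %d)\n",
              x$world$S, x$world$K, x$world$J, x$world$seed))
  print(x$models[, c("model", "alignment", "average_ratio", "unit_proportion",
                     "median_encode_ve", "mean_cosine_distance")], digits = 3)
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `report.json` (full scores and provenance), `models.tsv` (the
#' per-model score table) and, when present, `udr_pairwise.tsv` and
#' `ceiling.tsv`.
#'
#' @param report a [run_full_comparison()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$models, file.path(dir, "models.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$udr)) {
    utils::write.table(report$udr$pairwise, file.path(dir, "udr_pairwise.tsv"),
                       sep = "\t", quote = FALSE)
  }
  if (!is.null(report$ceiling)) {
    utils::write.table(
      data.frame(subset = names(report$ceiling),
                 size = attr(report$ceiling, "sizes"),
                 alignment = as.numeric(report$ceiling)),
      file.path(dir, "ceiling.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  payload <- list(
    config = unclass(report$config),
    world = report$world,
    models = report$models,
    welch = lapply(report$welch, unclass),
    ceiling = if (!is.null(report$ceiling)) {
      list(scores = as.numeric(report$ceiling),
           sizes = attr(report$ceiling, "sizes"))
    } else NULL,
    udr_per_model = if (!is.null(report$udr)) report$udr$per_model else NULL)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
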