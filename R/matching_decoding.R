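#' One-to-one matching of model units to neurons
#'
#' Computes the Pearson correlation matrix `D_ij` between every informative
#' model unit and every neuron over the shared (training) stimuli, then
#' solves the minimum-cost assignment over `1 - D_ij` with the
#' Kuhn-Munkres algorithm so that every informative unit is paired with a
#' distinct neuron. Signed (not absolute) correlation is used, as in the
#' original procedure: an anti-correlated unit is a poor match by
#' construction; a diagnostic warning fires when some unit's best absolute
#' correlation greatly exceeds its best signed one.
#'
#' @param model a model-kind [response_matrix()].
#' @param neural a neural-kind [response_matrix()] over the same stimuli,
#'   with at least as many neurons as there are informative units.
#' @param informative logical mask over model units; `NULL` keeps all.
#' @return an object of class `unit_assignment`: list with `pairs` (data
#'   frame: unit, neuron, correlation), `correlation_matrix` (informative
#'   units x neurons), `total_cost` (`sum(1 - D)` over the pairs).
#' @export
match_units <- function(model, neural, informative = NULL) {
  stopifnot(inherits(model, "response_matrix"), inherits(neural, "response_matrix"))
  if (!identical(model$stimulus_ids, neural$stimulus_ids)) {
    shared <- intersect(model$stimulus_ids, neural$stimulus_ids)
    if (length(shared) < 3L) stop("matrices share fewer than 3 stimuli")
    model <- select_stimuli(model, shared)
    neural <- select_stimuli(neural, shared)
  }
  if (is.null(informative)) informative <- rep(TRUE, ncol(model$values))
  Z <- model$values[, informative, drop = FALSE]
  unit_ids <- model$unit_ids[informative]
  if (ncol(Z) > ncol(neural$values)) {
    stop("more informative units (", ncol(Z), ") than neurons (",
         ncol(neural$values), "): one-to-one matching impossible")
  }
  D <- suppressWarnings(stats::cor(Z, neural$values))
  D[!is.finite(D)] <- 0
  if (any(apply(abs(D), 1L, max) > apply(D, 1L, max) + 0.5)) {
    warning("some unit is strongly anti-correlated with every neuron; ",
            "signed matching will pair it weakly")
  }
  sol <- lap_solve(1 - D)
  pairs <- data.frame(unit = unit_ids,
                      neuron = neural$unit_ids[sol$assignment],
                      correlation = D[cbind(seq_len(nrow(D)), sol$assignment)],
                      row.names = NULL)
  structure(list(pairs = pairs, correlation_matrix = D, total_cost = sol$cost),
            class = "unit_assignment")
}

#' @export
print.unit_assignment <- function(x, ...) {
  cat(sprintf("<unit_assignment> %d pairs, total cost = %.4f, mean r = %.4f\n",
              nrow(x$pairs), x$total_cost, mean(x$pairs$correlation)))
  invisible(x)
}

#' Decode model units on held-out stimuli from matched single neurons
#'
#' For every matched (unit, neuron) pair, a univariate least-squares
#' regression of the unit on its neuron is fitted on the training stimuli
#' (both sides standardized with training-set statistics only) and applied
#' to the neuron's held-out responses. With standardized variables the
#' slope equals the training Pearson correlation.
#'
#' @param assignment a [match_units()] result.
#' @param neural_train,model_train training-stimulus matrices.
#' @param neural_heldout held-out neural responses (training and held-out
#'   stimulus ids must be disjoint).
#' @param model_heldout optional held-out model responses; when supplied,
#'   their standardized values are returned alongside for scoring.
#' @return list with `predicted` (held-out stimuli x matched units,
#'   standardized scale), `predicted_raw` (mapped back through the model
#'   units' training mean/SD), `truth` (standardized held-out model
#'   responses, if `model_heldout` given), `train_stats`.
#' @export
decode_from_matched <- function(assignment, neural_train, model_train,
                                neural_heldout, model_heldout = NULL) {
  stopifnot(inherits(assignment, "unit_assignment"),
            inherits(neural_train, "response_matrix"),
            inherits(model_train, "response_matrix"),
            inherits(neural_heldout, "response_matrix"))
  if (length(intersect(neural_train$stimulus_ids,
                       neural_heldout$stimulus_ids)) > 0L) {
    stop("training and held-out stimuli must be disjoint")
  }
  pairs <- assignment$pairs
  n_mu <- colMeans(neural_train$values)
  n_sd <- col_sds(neural_train$values)
  z_mu <- colMeans(model_train$values)
  z_sd <- col_sds(model_train$values)
  pred <- matrix(0, nrow(neural_heldout$values), nrow(pairs),
                 dimnames = list(neural_heldout$stimulus_ids, pairs$unit))
  for (k in seq_len(nrow(pairs))) {
    u <- pairs$unit[k]
    nj <- pairs$neuron[k]
    if (n_sd[nj] == 0 || z_sd[u] == 0) {
      warning("constant matched neuron or unit for pair (", u, ", ", nj,
              "): prediction set to 0")
      next
    }
    x_tr <- (neural_train$values[, nj] - n_mu[nj]) / n_sd[nj]
    y_tr <- (model_train$values[, u] - z_mu[u]) / z_sd[u]
    slope <- sum(x_tr * y_tr) / sum(x_tr^2)
    intercept <- mean(y_tr) - slope * mean(x_tr)
    x_te <- (neural_heldout$values[, nj] - n_mu[nj]) / n_sd[nj]
    pred[, k] <- intercept + slope * x_te
  }
  truth <- NULL
  if (!is.null(model_heldout)) {
    stopifnot(inherits(model_heldout, "response_matrix"))
    tv <- model_heldout$values[, pairs$unit, drop = FALSE]
    sdv <- z_sd[pairs$unit]
    sdv[sdv == 0] <- 1
    truth <- sweep(sweep(tv, 2L, z_mu[pairs$unit]), 2L, sdv, `/`)
  }
  pred_raw <- sweep(sweep(pred, 2L, z_sd[pairs$unit], `*`), 2L,
                    z_mu[pairs$unit], `+`)
  list(predicted = pred, predicted_raw = pred_raw, truth = truth,
       train_stats = list(neuron_mean = n_mu, neuron_sd = n_sd,
                          unit_mean = z_mu, unit_sd = z_sd))
}

#' Mean cosine distance between predicted and true latent responses
#'
#' For each held-out stimulus, `1 - cos(u, v)` between the true and
#' predicted latent vectors restricted to informative units; the mean over
#' stimuli is returned. Stimuli where either vector has zero norm are
#' excluded with a warning (the count is reported in an attribute).
#'
#' @param true_latents,predicted_latents numeric matrices of equal shape,
#'   held-out stimuli x units (standardized scale).
#' @param informative logical mask over units; `NULL` keeps all.
#' @return mean cosine distance (in [0, 2]); `attr(, "n_excluded")` counts
#'   dropped stimuli.
#' @export
cosine_distance_score <- function(true_latents, predicted_latents,
                                  informative = NULL) {
  true_latents <- as.matrix(true_latents)
  predicted_latents <- as.matrix(predicted_latents)
  if (!all(dim(true_latents) == dim(predicted_latents))) stop("shape mismatch")
  if (is.null(informative)) informative <- rep(TRUE, ncol(true_latents))
  if (!any(informative)) stop("no informative units")
  U <- true_latents[, informative, drop = FALSE]
  V <- predicted_latents[, informative, drop = FALSE]
  nu <- sqrt(rowSums(U^2))
  nv <- sqrt(rowSums(V^2))
  ok <- nu > 0 & nv > 0
  if (!all(ok)) {
    warning(sum(!ok), " stimulus/stimuli with a zero-norm vector excluded")
  }
  if (!any(ok)) stop("every stimulus has a zero-norm vector")
  d <- 1 - rowSums(U[ok, , drop = FALSE] * V[ok, , drop = FALSE]) /
    (nu[ok] * nv[ok])
  structure(mean(d), n_excluded = sum(!ok))
}

#' Feature-space reconstruction error of decoded latents
#'
#' Maps predicted unit responses back to factor space through the model's
#' ground-truth factor map (available for disentangled and rotated
#' recipes), renders both true and predicted factors through the world's
#' linear decoder, and returns the mean squared error per feature averaged
#' over held-out stimuli -- the synthetic stand-in for reconstructing
#' held-out stimuli through a pre-trained decoder.
#'
#' @param world a [generate_world()] result.
#' @param predicted_latents held-out stimuli x matched units, on the raw
#'   model-unit scale (`predicted_raw` of [decode_from_matched()]).
#' @param model the realized model carrying `$factor_map` ([realize_model()]).
#' @param heldout_ids stimulus ids of the held-out rows.
#' @return mean squared reconstruction error (a single number).
#' @export
reconstruction_error <- function(world, predicted_latents, model, heldout_ids) {
  stopifnot(inherits(world, "synthetic_world"), inherits(model, "response_matrix"))
  if (is.null(model$factor_map)) {
    stop("reconstruction is defined only for recipes with a ground-truth ",
         "factor map (disentangled or rotated)")
  }
  predicted_latents <- as.matrix(predicted_latents)
  W <- model$factor_map # K x n_units, orthonormal columns
  idx <- match(colnames(predicted_latents), model$unit_ids)
  if (anyNA(idx)) stop("predicted latent columns do not match model units")
  W <- W[, idx, drop = FALSE]
  f_hat <- predicted_latents %*% t(W) # least-squares factor estimate
  f_true <- select_stimuli(world$factors, heldout_ids)$values
  if (nrow(f_true) != nrow(f_hat)) stop("held-out stimulus mismatch")
  err <- decode_features(world, f_hat) - decode_features(world, f_true)
  mean(rowMeans(err^2))
}
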