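#' Zero out uninformative units
#'
#' Units whose responses carry essentially no stimulus information are set
#' to all-zero columns before any regression, both to speed up the fits and
#' so that collapsed latent units cannot attract spurious weight. A unit is
#' uninformative when the variance of its scaled responses falls below
#' `cfg$var_threshold` (default 0.01). Scaling divides the whole matrix by
#' its mean per-unit standard deviation, so collapsed units remain
#' detectable (strict per-unit standardization would force every variance
#' to 1 and make the threshold vacuous).
#'
#' @param m a model-kind [response_matrix()].
#' @param cfg a [study_config()].
#' @return list with `matrix` (the input with uninformative columns zeroed)
#'   and `informative` (logical mask over units, `TRUE` = kept).
#' @export
zero_uninformative <- function(m, cfg = study_config()) {
  stopifnot(inherits(m, "response_matrix"))
  sds <- col_sds(m$values)
  scale_const <- mean(sds)
  if (scale_const == 0) stop("all units are constant: no predictors remain")
  scaled_var <- (sds / scale_const)^2
  informative <- scaled_var >= cfg$var_threshold
  if (!any(informative)) stop("all units are uninformative: no predictors remain")
  values <- m$values
  values[, !informative] <- 0
  out <- response_matrix(values, kind = m$kind, standardized = m$standardized)
  out$constant_units <- m$unit_ids[!informative]
  names(informative) <- m$unit_ids
  list(matrix = out, informative = informative)
}

#' Held-out variance explained
#'
#' `VE = 1 - sum((yhat - y)^2) / sum((y - ybar)^2)`, with `ybar` the mean
#' of the true responses over the evaluation stimuli. Equals 1 for a
#' perfect prediction, 0 for the mean predictor, and can be negative for
#' predictions worse than the mean.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return a single real number.
#' @export
variance_explained <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least 2 evaluation stimuli")
  denom <- sum((y_true - mean(y_true))^2)
  if (denom == 0) stop("variance explained undefined: constant `y_true`")
  1 - sum((y_pred - y_true)^2) / denom
}

# Seeded fold assignment: a stimulus permutation cut into contiguous blocks.
make_foldid <- function(S, k, seed) {
  ord <- with_seed(seed, sample.int(S))
  foldid <- integer(S)
  foldid[ord] <- cut(seq_len(S), breaks = k, labels = FALSE)
  foldid
}

# Geometric lambda grid from lambda_max (smallest lambda with an all-zero
# solution under the 1/(2S) least-squares objective on standardized
# predictors) down to lambda_max * lambda_min_ratio.
lambda_grid <- function(X, y, n_lambda, lambda_min_ratio) {
  S <- nrow(X)
  mu <- colMeans(X)
  sd_n <- sqrt(colSums(sweep(X, 2L, mu)^2) / S) # n divisor, glmnet convention
  keep <- sd_n > 0
  if (!any(keep)) stop("all predictors are constant")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L, sd_n[keep], `/`)
  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / S
  if (lambda_max <= 0) lambda_max <- .Machine$double.eps
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = n_lambda))
}

#' L1-penalized regression of one response on a unit population
#'
#' Solves `min ||y - Xb||^2 / (2S) + lambda ||b||_1` over a 100-point
#' geometric lambda grid, scores each lambda by `cfg$cv_folds`-fold
#' cross-validated MSE (standardization constants computed within each
#' training fold), selects lambda by the one-standard-error rule -- the
#' largest (sparsest) lambda whose CV MSE is within one standard error of
#' the minimum -- and refits on all training stimuli at the chosen lambda.
#'
#' @param y numeric response vector (one neuron or one latent unit).
#' @param X a [response_matrix()] of predictor units over the same stimuli.
#' @param cfg a [study_config()].
#' @param seed integer seed controlling fold assignment.
#' @return an object of class `lasso_fit`: list with `coefficients` (named,
#'   no intercept, original predictor scale), `intercept`, `lambda_grid`,
#'   `chosen_lambda`, `cv_mse`, `cv_se`, `glmnet_fit`.
#' @export
fit_lasso <- function(y, X, cfg = study_config(), seed = 1L) {
  stopifnot(inherits(X, "response_matrix"))
  Xv <- X$values
  S <- nrow(Xv)
  if (length(y) != S) stop("response length does not match predictor stimuli")
  if (S < cfg$cv_folds) stop("fewer stimuli (", S, ") than folds (", cfg$cv_folds, ")")
  if (stats::sd(y) == 0) {
    warning("zero-variance response: returning all-zero fit")
    co <- stats::setNames(numeric(ncol(Xv)), X$unit_ids)
    return(structure(list(coefficients = co, intercept = mean(y),
                          lambda_grid = NULL, chosen_lambda = NA_real_,
                          cv_mse = NULL, cv_se = NULL, glmnet_fit = NULL),
                     class = "lasso_fit"))
  }
  grid <- lambda_grid(Xv, y, cfg$n_lambda, cfg$lambda_min_ratio)
  foldid <- make_foldid(S, cfg$cv_folds, derive_seed(seed, 20L))
  cv <- glmnet::cv.glmnet(Xv, y, lambda = grid, foldid = foldid,
                          family = "gaussian", standardize = TRUE,
                          thresh = 1e-10)
  chosen <- cv$lambda.1se
  # The chosen lambda is a grid point: read the path solution at its index
  # rather than interpolating (interpolation leaves ~1e-17 dust on exact
  # zeros, which would corrupt the support of the weight matrix).
  idx <- which.min(abs(cv$glmnet.fit$lambda - chosen))
  co <- as.numeric(cv$glmnet.fit$beta[, idx])
  # Coordinate-descent warm starts leave ~1e-17 residue on structural
  # zeros; a coefficient whose standardized effect (|b_d| sd(x_d) / sd(y))
  # is below 1e-8 is numerically zero and must not enter the support.
  sd_x <- col_sds(Xv)
  co[abs(co) * sd_x < 1e-8 * stats::sd(y)] <- 0
  structure(list(coefficients = stats::setNames(co, X$unit_ids),
                 intercept = cv$glmnet.fit$a0[idx],
                 lambda_grid = cv$lambda, chosen_lambda = chosen,
                 cv_mse = cv$cvm, cv_se = cv$cvsd, glmnet_fit = cv$glmnet.fit),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<lasso_fit> %d/%d nonzero coefficients, lambda = %s\n",
              nz, length(x$coefficients), format(x$chosen_lambda, digits = 4)))
  invisible(x)
}

predict_lasso <- function(fit, newX) {
  drop(newX %*% fit$coefficients) + fit$intercept
}

#' Encoding models: predict every neuron from model units
#'
#' Fits one sparse regression per neuron on the training stimuli and scores
#' held-out variance explained ([variance_explained()]) on the held-out
#' stimuli. The relative-importance matrix `R` collects the absolute values
#' of the refit coefficients (rows = predictor units, columns = neurons)
#' and is the input to [alignment_from_weights()].
#'
#' @param neural a neural-kind [response_matrix()] (prediction targets).
#' @param model a model-kind [response_matrix()] (predictors); pass it
#'   through [zero_uninformative()] first for the standard pipeline.
#' @param cfg a [study_config()].
#' @param seed integer seed (held-out split and fold assignment).
#' @param split optional precomputed list with `train`/`heldout` stimulus
#'   ids; when `NULL` a split of `cfg$n_heldout` stimuli is drawn.
#' @return list with `weights` (nonnegative units x neurons matrix),
#'   `ve` (named numeric, held-out VE per neuron; `NA` if a neuron is
#'   constant on the held-out set), `lambda` (chosen lambda per neuron),
#'   and `split` (the stimulus ids used).
#' @export
encode_population <- function(neural, model, cfg = study_config(), seed = 1L,
                              split = NULL) {
  stopifnot(inherits(neural, "response_matrix"), inherits(model, "response_matrix"))
  if (!identical(neural$stimulus_ids, model$stimulus_ids)) {
    shared <- intersect(neural$stimulus_ids, model$stimulus_ids)
    if (length(shared) < 2L) stop("matrices share fewer than 2 stimuli")
    neural <- select_stimuli(neural, shared)
    model <- select_stimuli(model, shared)
  }
  if (is.null(split)) {
    parts <- split_heldout(neural, cfg$n_heldout, derive_seed(seed, 21L))
    split <- list(train = parts$train$stimulus_ids,
                  heldout = parts$heldout$stimulus_ids)
  }
  X_tr <- select_stimuli(model, split$train)
  X_te <- select_stimuli(model, split$heldout)
  N_tr <- select_stimuli(neural, split$train)
  N_te <- select_stimuli(neural, split$heldout)
  J <- ncol(neural$values)
  D <- ncol(model$values)
  weights <- matrix(0, D, J, dimnames = list(model$unit_ids, neural$unit_ids))
  ve <- stats::setNames(rep(NA_real_, J), neural$unit_ids)
  lambda <- stats::setNames(rep(NA_real_, J), neural$unit_ids)
  for (j in seq_len(J)) {
    fit <- fit_lasso(N_tr$values[, j], X_tr, cfg, derive_seed(seed, 22L + j))
    weights[, j] <- abs(fit$coefficients)
    lambda[j] <- fit$chosen_lambda
    y_te <- N_te$values[, j]
    if (stats::sd(y_te) > 0) {
      ve[j] <- variance_explained(y_te, predict_lasso(fit, X_te$values))
    }
  }
  list(weights = weights, ve = ve, lambda = lambda, split = split)
}

#' Decoding models: predict every informative model unit from neurons
#'
#' Mirror of [encode_population()] with the roles swapped: each informative
#' model unit is regressed on the neural population and scored by held-out
#' variance explained.
#'
#' @inheritParams encode_population
#' @param informative optional logical mask over model units (from
#'   [zero_uninformative()]); uninformative units are skipped (VE `NA`).
#' @return list with `ve` (named numeric per model unit) and `split`.
#' @export
decode_population <- function(model, neural, cfg = study_config(), seed = 1L,
                              split = NULL, informative = NULL) {
  stopifnot(inherits(neural, "response_matrix"), inherits(model, "response_matrix"))
  if (is.null(informative)) informative <- rep(TRUE, ncol(model$values))
  enc <- encode_population(
    neural = select_units(model, which(informative)),
    model = neural, cfg = cfg, seed = derive_seed(seed, 30L), split = split)
  ve <- stats::setNames(rep(NA_real_, ncol(model$values)), model$unit_ids)
  ve[names(enc$ve)] <- enc$ve
  list(ve = ve, split = enc$split)
}

#' Exclude models that share no information with the neural data
#'
#' A model is filtered out when its mean variance explained falls more than
#' one standard deviation below the across-model mean:
#' `VE_m < mean(VE) - SD(VE)` (sample SD, n-1 divisor).
#'
#' @param ve_by_model named numeric vector of per-model mean VE (>= 2
#'   models; a single model is kept trivially with a warning).
#' @return list with `kept`, `excluded` (names or indices) and `threshold`.
#' @export
filter_models <- function(ve_by_model) {
  if (length(ve_by_model) < 2L) {
    warning("single model: kept trivially")
    return(list(kept = names(ve_by_model) %||% 1L, excluded = character(0),
                threshold = -Inf))
  }
  if (is.null(names(ve_by_model))) {
    names(ve_by_model) <- paste0("model", seq_along(ve_by_model))
  }
  threshold <- mean(ve_by_model) - stats::sd(ve_by_model)
  excluded <- names(ve_by_model)[ve_by_model < threshold]
  list(kept = setdiff(names(ve_by_model), excluded), excluded = excluded,
       threshold = threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
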