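#' Recipe for a synthetic model representation
#'
#' Describes one member of the model zoo used to exercise the pipeline:
#' \describe{
#'   \item{disentangled}{a random subset of the ground-truth factors, under
#'     random permutation and sign flip, plus Gaussian noise; `mixing > 0`
#'     smoothly rotates the axis-aligned basis toward a fully entangled one.}
#'   \item{rotated}{a random orthogonal mixture of a factor subset -- the
#'     same information as a disentangled model but spread across units.}
#'   \item{sparse_random}{factor-independent noise whose per-unit sparseness
#'     is matched to a reference disentangled model.}
#'   \item{pca_like}{dense mixtures given by the leading principal
#'     directions of the neural population.}
#' }
#'
#' @param family one of `"disentangled"`, `"rotated"`, `"sparse_random"`,
#'   `"pca_like"`.
#' @param n_units number of latent units (for disentangled/rotated, at most
#'   the world's `K`: subset semantics).
#' @param noise_sd standard deviation of additive unit noise (>= 0).
#' @param mixing rotation amount in [0, 1]; 0 is a pure axis code. Only
#'   meaningful for the disentangled family.
#' @param seed integer seed for the recipe's random choices.
#' @return an object of class `model_recipe`.
#' @export
model_recipe <- function(family = c("disentangled", "rotated", "sparse_random",
                                    "pca_like"),
                         n_units, noise_sd = 0, mixing = 0, seed = 1L) {
  family <- match.arg(family)
  if (n_units < 1L) stop("`n_units` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (mixing < 0 || mixing > 1) stop("`mixing` must lie in [0, 1]")
  structure(list(family = family, n_units = as.integer(n_units),
                 noise_sd = noise_sd, mixing = mixing,
                 seed = as.integer(seed)),
            class = "model_recipe")
}

# Orthonormalize the columns of a K x n matrix (QR with sign fix).
orthonormalize <- function(W) {
  qrd <- qr(W)
  q <- qr.Q(qrd)
  q %*% diag(sign(diag(qr.R(qrd))), ncol(W), ncol(W))
}

#' Realize a model representation over a synthetic world
#'
#' Produces the latent responses of one zoo member on the world's stimuli.
#' Disentangled and rotated models carry their ground-truth linear map from
#' factors to units (`$factor_map`, a K x n_units matrix with orthonormal
#' columns) so that predicted unit responses can later be mapped back to
#' factor space; pure axis codes additionally record the planted
#' factor/sign per unit in `$axis`.
#'
#' @param world a [generate_world()] result.
#' @param recipe a [model_recipe()].
#' @return a model-kind [response_matrix()] with extra fields `recipe`,
#'   `factor_map` (or `NULL`) and `axis` (or `NULL`).
#' @export
realize_model <- function(world, recipe) {
  stopifnot(inherits(world, "synthetic_world"), inherits(recipe, "model_recipe"))
  K <- world$K
  S <- world$S
  out <- switch(
    recipe$family,
    disentangled = ,
    rotated = {
      if (recipe$n_units > K) {
        stop("disentangled/rotated recipe with n_units > K (", K,
             "): subset semantics require n_units <= K")
      }
      with_seed(derive_seed(recipe$seed, 10L), {
        subset <- sort(sample.int(K, recipe$n_units))
        perm <- sample.int(recipe$n_units)
        signs <- sample(c(-1, 1), recipe$n_units, replace = TRUE)
        # Axis-aligned orthonormal map: unit u reads factor subset[perm[u]]
        W0 <- matrix(0, K, recipe$n_units)
        W0[cbind(subset[perm], seq_len(recipe$n_units))] <- signs
        mix <- if (recipe$family == "rotated") 1 else recipe$mixing
        W <- W0
        axis <- data.frame(unit = paste0("z", seq_len(recipe$n_units)),
                           factor = subset[perm], sign = signs)
        if (mix > 0) {
          Q <- random_orthogonal(recipe$n_units)
          R0 <- matrix(0, K, recipe$n_units)
          R0[subset, ] <- Q
          W <- orthonormalize((1 - mix) * W0 + mix * R0)
          if (mix == 1) W <- R0
          axis <- NULL
        }
        vals <- world$factors$values %*% W
        if (recipe$noise_sd > 0) {
          vals <- vals + matrix(stats::rnorm(length(vals), sd = recipe$noise_sd),
                                S, recipe$n_units)
        }
        list(values = vals, factor_map = W, axis = axis)
      })
    },
    pca_like = {
      neural <- realize_neural(world)
      n_units <- min(recipe$n_units, ncol(neural$values))
      pc <- stats::prcomp(neural$values, center = TRUE, scale. = FALSE)
      vals <- pc$x[, seq_len(n_units), drop = FALSE]
      if (recipe$noise_sd > 0) {
        vals <- vals + with_seed(derive_seed(recipe$seed, 11L),
                                 matrix(stats::rnorm(length(vals),
                                                     sd = recipe$noise_sd),
                                        nrow(vals), ncol(vals)))
      }
      list(values = vals, factor_map = NULL, axis = NULL)
    },
    sparse_random = {
      # Reference disentangled sibling fixes the per-unit sparseness target:
      # the fraction of stimuli whose standardized response lies within
      # +/- 0.1 of zero. Gaussian draws are soft-thresholded to hit that
      # fraction, then rescaled to unit variance.
      ref_recipe <- model_recipe("disentangled",
                                 n_units = min(recipe$n_units, K),
                                 noise_sd = recipe$noise_sd,
                                 seed = derive_seed(recipe$seed, 12L))
      ref <- realize_model(world, ref_recipe)
      ref_std <- standardize_units(ref)
      target <- colMeans(abs(ref_std$values) < 0.1)
      with_seed(derive_seed(recipe$seed, 13L), {
        vals <- matrix(0, S, recipe$n_units)
        soft <- function(g, t) sign(g) * pmax(abs(g) - t, 0)
        for (u in seq_len(recipe$n_units)) {
          q <- target[((u - 1L) %% length(target)) + 1L]
          g <- stats::rnorm(S)
          # fraction of near-zero standardized responses after thresholding
          # at t (rescaling to unit SD included); monotone in t
          frac_at <- function(t) {
            z <- soft(g, t)
            s <- stats::sd(z)
            if (s == 0) return(1)
            mean(abs(z / s) < 0.1)
          }
          thr <- if (frac_at(0) >= q) 0 else {
            stats::uniroot(function(t) frac_at(t) - q,
                           c(0, max(abs(g)) * 0.99))$root
          }
          z <- soft(g, thr)
          s <- stats::sd(z)
          vals[, u] <- if (s > 0) z / s else z
        }
        list(values = vals, factor_map = NULL, axis = NULL)
      })
    }
  )
  dimnames(out$values) <- list(world$factors$stimulus_ids,
                               paste0("z", seq_len(ncol(out$values))))
  m <- response_matrix(out$values, kind = "model")
  m$recipe <- recipe
  m$factor_map <- out$factor_map
  m$axis <- out$axis
  m
}
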