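#' Generate a synthetic world with planted axis-coded structure
#'
#' Builds the ground truth every downstream stage is tested against: `K`
#' independent standard-normal latent factors over `S` stimuli, a neural
#' population of `J` neurons in which each neuron codes one dominant factor
#' (axis code) with several neurons per factor (redundancy), additive
#' Gaussian response noise, and a linear decoder mapping factors to `P`
#' observable stimulus features (the stand-in for pixels).
#'
#' Dominant loadings have magnitude 1 and random sign (real neurons are
#' tuned in either direction along an axis), so with noise standard
#' deviation `noise_sd` the fraction of each neuron's variance carried by
#' its factor is `1 / (1 + noise_sd^2)` -- e.g. `noise_sd = 0.5` plants a
#' signal fraction of 0.8.
#'
#' @param S number of stimuli (>= 20).
#' @param K number of ground-truth factors (>= 2).
#' @param J number of neurons (>= K so every factor can be axis-coded).
#' @param redundancy expected neurons per factor; must be consistent with
#'   `J / K` (checked loosely; the factor assignment cycles 1..K through a
#'   random permutation of neurons, giving each factor ~ J/K neurons).
#' @param noise_sd standard deviation of additive neural noise (>= 0).
#' @param seed integer seed; the world is a pure function of its arguments.
#' @param mixing optional off-axis contamination in [0, 1]; 0 plants a pure
#'   axis code, larger values add small random off-axis loadings.
#' @param n_features number of observable features `P` produced by the
#'   decoder.
#'
#' @return an object of class `synthetic_world`: list with `factors` (a
#'   factor-kind [response_matrix()]), `loadings` (K x J), `dominant`
#'   (factor index per neuron), `noise_sd`, `decoder` (K x P), `seed`, and
#'   the generating parameters.
#' @export
generate_world <- function(S, K, J, redundancy = max(1, round(J / K)),
                           noise_sd = 0.5, seed = 1L, mixing = 0,
                           n_features = 2L * K) {
  if (S < 20L) stop("`S` must be at least 20")
  if (K < 2L) stop("`K` must be at least 2")
  if (J < K) stop("`J` < `K`: cannot axis-code all factors")
  if (redundancy < 1) stop("`redundancy` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (mixing < 0 || mixing > 1) stop("`mixing` must lie in [0, 1]")
  with_seed(derive_seed(seed, 1L), {
    factors <- matrix(stats::rnorm(S * K), S, K,
                      dimnames = list(paste0("s", seq_len(S)),
                                      paste0("f", seq_len(K))))
    dominant <- rep_len(seq_len(K), J)[sample.int(J)]
    loadings <- matrix(0, K, J,
                       dimnames = list(paste0("f", seq_len(K)),
                                       paste0("n", seq_len(J))))
    loadings[cbind(dominant, seq_len(J))] <- sample(c(-1, 1), J, replace = TRUE)
    if (mixing > 0) {
      off <- matrix(stats::rnorm(K * J, sd = 0.3 * mixing), K, J)
      off[cbind(dominant, seq_len(J))] <- 0
      loadings <- loadings + off
    }
    decoder <- matrix(stats::rnorm(K * n_features), K, n_features,
                      dimnames = list(paste0("f", seq_len(K)),
                                      paste0("p", seq_len(n_features))))
    structure(
      list(factors = response_matrix(factors, kind = "factor"),
           loadings = loadings, dominant = dominant, noise_sd = noise_sd,
           decoder = decoder, seed = as.integer(seed),
           S = as.integer(S), K = as.integer(K), J = as.integer(J),
           redundancy = redundancy, mixing = mixing),
      class = "synthetic_world"
    )
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> S=%d stimuli, K=%d factors, J=%d neurons, noise_sd=%g, seed=%d\n",
    x$S, x$K, x$J, x$noise_sd, x$seed))
  invisible(x)
}

#' Realize the neural population of a synthetic world
#'
#' Neural responses are the linear read-out of the factors through the
#' planted loading matrix plus i.i.d. Gaussian noise:
#' `N = F loadings + E`, `E ~ N(0, noise_sd^2)`. Deterministic given the
#' world (the noise seed is derived from `world$seed`).
#'
#' @param world a [generate_world()] result.
#' @return a neural-kind [response_matrix()], `S x J`.
#' @export
realize_neural <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  signal <- world$factors$values %*% world$loadings
  noise <- if (world$noise_sd > 0) {
    with_seed(derive_seed(world$seed, 2L),
              matrix(stats::rnorm(length(signal), sd = world$noise_sd),
                     nrow(signal), ncol(signal)))
  } else 0
  response_matrix(signal + noise, kind = "neural")
}

#' Map factor values through the world's linear decoder
#'
#' Stand-in for rendering stimuli from latent factors: returns
#' `factor_values %*% decoder`, used to score reconstruction error of
#' predicted against true factors in feature space.
#'
#' @param world a [generate_world()] result.
#' @param factor_values a factor-kind [response_matrix()] or numeric matrix
#'   whose columns align with the decoder's rows.
#' @return numeric matrix, stimuli x features.
#' @export
decode_features <- function(world, factor_values) {
  stopifnot(inherits(world, "synthetic_world"))
  vals <- if (inherits(factor_values, "response_matrix")) {
    factor_values$values
  } else {
    as.matrix(factor_values)
  }
  if (ncol(vals) != nrow(world$decoder)) {
    stop("dimension mismatch: ", ncol(vals), " factor columns vs decoder with ",
         nrow(world$decoder), " rows")
  }
  vals %*% world$decoder
}

#' Linearly recombine neural responses into artificial data
#'
#' Control analysis probing whether model units merely encode linear
#' combinations of neurons: the neural responses are standardized, and
#' multiplied by a random square projection matrix `A` whose entries are
#' absolute values of unit-Gaussian draws with every column normalized to
#' sum to 1. Alignment against such recombined responses should drop for a
#' genuinely one-to-one code.
#'
#' @param neural a neural-kind [response_matrix()] with >= 2 neurons.
#' @param seed integer seed for the projection draw.
#' @param projection optional pre-made `J x J` matrix (test hook); when
#'   supplied it is used as-is and `seed` is ignored.
#' @return list with `responses` (a neural-kind `response_matrix` of the
#'   recombined units) and `projection` (the matrix `A` actually used).
#' @export
make_artificial_neural <- function(neural, seed = 1L, projection = NULL) {
  stopifnot(inherits(neural, "response_matrix"))
  J <- ncol(neural$values)
  if (J < 2L) stop("need at least 2 neurons to recombine")
  std <- standardize_units(neural)
  if (is.null(projection)) {
    projection <- with_seed(derive_seed(seed, 3L), {
      A <- abs(matrix(stats::rnorm(J * J), J, J))
      sweep(A, 2L, colSums(A), `/`)
    })
  } else {
    projection <- as.matrix(projection)
    if (!all(dim(projection) == c(J, J))) {
      stop("`projection` must be a ", J, " x ", J, " matrix")
    }
  }
  out <- std$values %*% projection
  colnames(out) <- paste0("a", seq_len(ncol(projection)))
  list(responses = response_matrix(out, kind = "neural"),
       projection = projection)
}

#' Sample random neuron subsets
#'
#' Draws `n_subset_sizes` distinct subset sizes uniformly without
#' replacement from `subset_size_range`, then for each size draws
#' `subsets_per_size` distinct neuron subsets uniformly without replacement
#' (no repeated subset within a size). Under the defaults this yields the
#' study's 5 x 10 = 50 subsets with sizes in [10, 50].
#'
#' @param neural a neural-kind [response_matrix()] with at least as many
#'   neurons as the upper end of the size range.
#' @param cfg a [study_config()].
#' @param seed integer seed.
#' @return list of neural-kind `response_matrix` subsets; each carries its
#'   size in `attr(, "subset_size")` and member ids in `attr(, "members")`.
#' @export
sample_neuron_subsets <- function(neural, cfg = study_config(), seed = 1L) {
  stopifnot(inherits(neural, "response_matrix"), inherits(cfg, "study_config"))
  J <- ncol(neural$values)
  lo <- cfg$subset_size_range[1L]
  hi <- cfg$subset_size_range[2L]
  if (J < hi) {
    stop("population of ", J, " neurons is smaller than the maximum subset size ", hi)
  }
  if (hi - lo + 1L < cfg$n_subset_sizes) {
    stop("size range too narrow for ", cfg$n_subset_sizes, " distinct sizes")
  }
  with_seed(derive_seed(seed, 4L), {
    sizes <- sample(seq.int(lo, hi), cfg$n_subset_sizes)
    out <- list()
    for (size in sizes) {
      seen <- character(0)
      for (r in seq_len(cfg$subsets_per_size)) {
        for (attempt in 1:1000) {
          members <- sort(sample.int(J, size))
          key <- paste(members, collapse = ",")
          if (!key %in% seen) break
          if (attempt == 1000L) stop("could not draw a fresh subset of size ", size)
        }
        seen <- c(seen, key)
        sub <- select_units(neural, members)
        attr(sub, "subset_size") <- size
        attr(sub, "members") <- neural$unit_ids[members]
        out[[sprintf("size%d_rep%d", size, r)]] <- sub
      }
    }
    out
  })
}
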