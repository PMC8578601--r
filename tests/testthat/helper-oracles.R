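# Independent brute-force oracles, written directly from the defining
# formulas with explicit loops. They deliberately share no code with the
# package implementations they check.

# Completeness: p_dj = R_dj / sum_d R_dj; H base D with 0 log 0 = 0;
# rho_j = column share of total weight; C = sum_j rho_j (1 - H_j).
oracle_alignment <- function(R) {
  D <- nrow(R)
  total <- 0
  grand <- sum(R)
  for (j in seq_len(ncol(R))) {
    colsum <- sum(R[, j])
    if (colsum == 0) next
    rho <- colsum / grand
    H <- 0
    for (d in seq_len(D)) {
      p <- R[d, j] / colsum
      if (p > 0) H <- H - p * log(p) / log(D)
    }
    total <- total + rho * (1 - H)
  }
  total
}

# Pairwise UDR from an absolute-similarity matrix and informative masks.
oracle_udr <- function(R, mask_a, mask_b) {
  d_a <- sum(mask_a)
  d_b <- sum(mask_b)
  acc <- 0
  for (b in seq_len(ncol(R))) {
    denom <- sum(R[, b])
    if (denom > 0) acc <- acc + max(R[, b])^2 * mask_b[b] / denom
  }
  for (a in seq_len(nrow(R))) {
    denom <- sum(R[a, ])
    if (denom > 0) acc <- acc + max(R[a, ])^2 * mask_a[a] / denom
  }
  acc / (d_a + d_b)
}

# Exhaustive minimum-cost one-to-one assignment (rows <= cols).
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  best <- Inf
  recurse <- function(i, used, acc) {
    if (i > n) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, acc + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0)
  best
}

# Draw data whose *sample* correlation matrix equals Sigma exactly:
# empirically whiten Gaussian draws, then colour with chol(Sigma).
make_data_with_cor <- function(n, Sigma, seed = 1L) {
  set.seed(seed)
  p <- ncol(Sigma)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- X %*% solve(chol(crossprod(X) / (n - 1)))
  X %*% chol(Sigma)
}

# Small, fast study configuration for unit tests (full defaults are used
# where a test checks the stated procedure counts).
tiny_config <- function(...) {
  study_config(n_heldout = 20L, subset_size_range = c(3L, 8L),
               n_subset_sizes = 2L, subsets_per_size = 3L, ...)
}

tiny_world <- function(S = 150L, K = 4L, J = 12L, noise_sd = 0.5, seed = 11L,
                       ...) {
  generate_world(S = S, K = K, J = J, noise_sd = noise_sd, seed = seed, ...)
}
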