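# Internal helpers shared across stages.

# Derive a stage seed from a master seed. Deterministic LCG step keeps the
# result a valid 32-bit R integer whatever the (small) master seed is.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(salt))
  as.integer((abs(seed) * 69069 + salt * 1013 + 1) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Column means / sds (n-1 divisor) without repeated apply() overhead.
col_means <- function(x) colMeans(x)
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to compute a standard deviation")
  mu <- colMeans(x)
  sqrt(colSums(sweep(x, 2L, mu)^2) / (n - 1L))
}

# Random orthogonal matrix via QR of a Gaussian draw, sign-fixed so the
# decomposition is unique (positive diagonal of R).
random_orthogonal <- function(d) {
  qrd <- qr(matrix(stats::rnorm(d * d), d, d))
  q <- qr.Q(qrd)
  q %*% diag(sign(diag(qr.R(qrd))), d, d)
}
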