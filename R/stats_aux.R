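#' Welch's two-sample t-test (unequal variances)
#'
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Satterthwaite degrees of freedom and a two-sided p-value from the
#' t-distribution. Used for all pairwise model comparisons at
#' `alpha = 0.01`.
#'
#' @param a,b numeric samples of length >= 2.
#' @param alpha significance level for the `significant` flag.
#' @return an object of class `welch_result`: list with `t`, `df`,
#'   `p_two_sided`, `significant`.
#' @export
welch_test <- function(a, b, alpha = 0.01) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 observations")
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(t = 0, df = length(a) + length(b) - 2,
                            p_two_sided = 1, significant = FALSE),
                       class = "welch_result"))
    }
    stop("both samples constant but unequal: t statistic undefined")
  }
  na <- length(a)
  nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p_two_sided = p, significant = p < alpha),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t = %.4f, df = %.2f, p = %.4g%s\n",
              x$t, x$df, x$p_two_sided,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Face-selectivity index
#'
#' Normalized contrast between a cell's mean response to face and non-face
#' stimuli: `(face - nonface) / (face + nonface)`, in [-1, 1] for
#' nonnegative rates. Cells with FSI above the cutoff (0.33 by default)
#' count as face-selective.
#'
#' @param face_mean,nonface_mean nonnegative mean responses; their sum must
#'   be positive.
#' @return the index, a single number in [-1, 1].
#' @export
face_selectivity_index <- function(face_mean, nonface_mean) {
  if (face_mean < 0 || nonface_mean < 0) stop("mean rates must be nonnegative")
  if (face_mean + nonface_mean == 0) stop("FSI undefined: both means are zero")
  (face_mean - nonface_mean) / (face_mean + nonface_mean)
}

#' Rater-consensus statistics for categorical labels
#'
#' Given the counts of raters choosing each label for one item, reports the
#' maximum agreement proportion and the natural-log entropy of the label
#' distribution, plus a Monte-Carlo null in which each rater picks
#' uniformly among the K labels: the chance level is the null's mean
#' maximum proportion and the p-value the fraction of null draws whose
#' maximum proportion reaches the observed one.
#'
#' @param label_counts integer vector (>= 2 labels, total >= 1).
#' @param n_mc number of Monte-Carlo draws (>= 100).
#' @param seed integer seed.
#' @return an object of class `consensus_result`: list with `label_counts`,
#'   `max_agreement`, `entropy`, `mc_chance_level`, `mc_p_agreement`.
#' @export
rater_consensus <- function(label_counts, n_mc = 10000L, seed = 1L) {
  label_counts <- as.integer(label_counts)
  K <- length(label_counts)
  if (K < 2L) stop("need at least 2 labels")
  if (any(label_counts < 0) || sum(label_counts) < 1L) {
    stop("counts must be nonnegative with positive total")
  }
  if (n_mc < 100L) stop("`n_mc` < 100 gives an unstable null")
  total <- sum(label_counts)
  p <- label_counts / total
  pp <- p[p > 0]
  entropy <- -sum(pp * log(pp))
  max_agreement <- max(p)
  null_max <- with_seed(derive_seed(seed, 40L), {
    draws <- stats::rmultinom(n_mc, total, rep(1 / K, K))
    apply(draws, 2L, max) / total
  })
  structure(list(label_counts = label_counts,
                 max_agreement = max_agreement,
                 entropy = entropy,
                 mc_chance_level = mean(null_max),
                 mc_p_agreement = mean(null_max >= max_agreement)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> max agreement = %.3f (chance %.3f, p = %.4g), entropy = %.4f nats\n",
    x$max_agreement, x$mc_chance_level, x$mc_p_agreement, x$entropy))
  invisible(x)
}
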