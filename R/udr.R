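#' Pairwise UDR score from an absolute-correlation matrix
#'
#' Scores how well two latent spaces match up to permutation, subsetting
#' and sign flip. With `R_ab` the absolute similarity matrix between the
#' latents of models a (rows) and b (columns), the score is
#' \deqn{\frac{1}{d_a + d_b}\Big[\sum_b \frac{r_a(b)^2 I(b)}{\sum_a R(a,b)}
#'   + \sum_a \frac{r_b(a)^2 I(a)}{\sum_b R(a,b)}\Big]}
#' where `r_a(b)` is the maximum of column `b`, `r_b(a)` the maximum of
#' row `a`, `I(.)` marks informative latents and `d_a`, `d_b` count them.
#' A permutation matrix scores 1; an all-zero matrix scores 0. Columns or
#' rows with a zero denominator contribute 0.
#'
#' @param R_ab numeric matrix with entries in [0, 1], latents of model a
#'   x latents of model b.
#' @param mask_a,mask_b logical masks of informative latents (default all).
#' @return a single score in [0, 1].
#' @export
udr_pair <- function(R_ab, mask_a = NULL, mask_b = NULL) {
  R_ab <- as.matrix(R_ab)
  if (any(R_ab < 0) || any(R_ab > 1 + 1e-12)) stop("`R_ab` entries must lie in [0, 1]")
  if (is.null(mask_a)) mask_a <- rep(TRUE, nrow(R_ab))
  if (is.null(mask_b)) mask_b <- rep(TRUE, ncol(R_ab))
  d_a <- sum(mask_a)
  d_b <- sum(mask_b)
  if (d_a < 1L || d_b < 1L) stop("each model needs at least one informative latent")
  col_sum <- colSums(R_ab)
  row_sum <- rowSums(R_ab)
  col_max <- apply(R_ab, 2L, max)
  row_max <- apply(R_ab, 1L, max)
  term_b <- ifelse(col_sum > 0, col_max^2 * mask_b / col_sum, 0)
  term_a <- ifelse(row_sum > 0, row_max^2 * mask_a / row_sum, 0)
  (sum(term_b) + sum(term_a)) / (d_a + d_b)
}

#' UDR over a family of model representations
#'
#' For every model pair the absolute Spearman correlation matrix between
#' their latents is computed over shared stimuli (average-tie ranks;
#' constant latents give correlation 0), masked by each model's
#' informative units (variance criterion of [zero_uninformative()]), and
#' scored with [udr_pair()]. Each model's score is the median of its
#' pairwise scores. When `groups` is supplied, pairs are only formed
#' within a group (mirroring comparisons among models trained with the
#' same hyperparameter value).
#'
#' @param models list of >= 2 model-kind [response_matrix()] objects over
#'   shared stimuli.
#' @param cfg a [study_config()] (supplies the informativeness threshold).
#' @param groups optional vector of group tags, one per model.
#' @return an object of class `udr_result`: list with `pairwise` (square
#'   matrix, `NA` diagonal and cross-group entries), `per_model` (median
#'   over each row's available entries), `informative_counts`.
#' @export
udr_family <- function(models, cfg = study_config(), groups = NULL) {
  M <- length(models)
  if (M < 2L) stop("need at least 2 models")
  for (m in models) stopifnot(inherits(m, "response_matrix"))
  if (is.null(groups)) groups <- rep(1L, M)
  if (length(groups) != M) stop("`groups` must tag every model")
  ids <- names(models) %||% paste0("model", seq_len(M))
  masks <- lapply(models, function(m) zero_uninformative(m, cfg)$informative)
  pairwise <- matrix(NA_real_, M, M, dimnames = list(ids, ids))
  for (i in seq_len(M - 1L)) {
    for (j in seq.int(i + 1L, M)) {
      if (groups[i] != groups[j]) next
      R <- abs(suppressWarnings(
        stats::cor(models[[i]]$values, models[[j]]$values, method = "spearman")))
      R[!is.finite(R)] <- 0
      s <- udr_pair(R, masks[[i]], masks[[j]])
      pairwise[i, j] <- s
      pairwise[j, i] <- s
    }
  }
  per_model <- apply(pairwise, 1L, function(row) {
    vals <- row[!is.na(row)]
    if (length(vals) == 0L) NA_real_ else stats::median(vals)
  })
  structure(list(pairwise = pairwise,
                 per_model = stats::setNames(per_model, ids),
                 informative_counts = vapply(masks, sum, integer(1L))),
            class = "udr_result")
}

#' @export
print.udr_result <- function(x, ...) {
  cat(sprintf("<udr_result> %d models, median pairwise UDR = %.4f\n",
              length(x$per_model),
              stats::median(x$pairwise[upper.tri(x$pairwise)], na.rm = TRUE)))
  invisible(x)
}

#' Keep the top fraction of models by UDR score
#'
#' Models whose score reaches the `(1 - fraction)` quantile (linear
#' interpolation, ties kept) are retained, mirroring selection of the
#' top-15% most disentangled instances.
#'
#' @param per_model named numeric vector of per-model scores.
#' @param fraction fraction to keep, in (0, 1].
#' @return character vector of kept model ids (names of `per_model`).
#' @export
select_top_udr <- function(per_model, fraction = 0.15) {
  if (length(per_model) == 0L) stop("empty score vector")
  if (fraction <= 0 || fraction > 1) stop("`fraction` must lie in (0, 1]")
  if (is.null(names(per_model))) {
    names(per_model) <- paste0("model", seq_along(per_model))
  }
  cutoff <- stats::quantile(per_model, 1 - fraction, names = FALSE, na.rm = TRUE)
  names(per_model)[!is.na(per_model) & per_model >= cutoff]
}
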