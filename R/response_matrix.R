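#' Stimulus-by-unit response matrix
#'
#' The universal currency of the pipeline: a real matrix of responses with
#' rows indexed by stimuli and columns by units (neurons, model latent units,
#' or ground-truth factors). All downstream stages -- encoding models,
#' alignment scores, UDR, matching -- consume and produce this container.
#'
#' @param values numeric matrix, rows = stimuli, columns = units. Row and
#'   column names, when present, seed the stimulus / unit ids.
#' @param kind one of `"neural"`, `"model"`, `"factor"`.
#' @param stimulus_ids,unit_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @param standardized logical; `TRUE` only when every non-constant column
#'   has zero mean and unit variance (see [standardize_units()]).
#'
#' @return An object of class `response_matrix`: a list with fields
#'   `values`, `stimulus_ids`, `unit_ids`, `kind`, `standardized`,
#'   `constant_units` (character vector of flagged constant columns).
#' @export
response_matrix <- function(values, kind = c("neural", "model", "factor"),
                            stimulus_ids = NULL, unit_ids = NULL,
                            standardized = FALSE) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("empty response matrix refused: need at least one stimulus and one unit")
  }
  if (any(!is.finite(values))) stop("response matrix contains non-finite entries")
  if (is.null(stimulus_ids)) {
    stimulus_ids <- rownames(values)
    if (is.null(stimulus_ids)) stimulus_ids <- paste0("s", seq_len(nrow(values)))
  }
  if (is.null(unit_ids)) {
    unit_ids <- colnames(values)
    if (is.null(unit_ids)) unit_ids <- paste0("u", seq_len(ncol(values)))
  }
  stimulus_ids <- as.character(stimulus_ids)
  unit_ids <- as.character(unit_ids)
  if (length(stimulus_ids) != nrow(values)) {
    stop("length of `stimulus_ids` does not match the number of rows")
  }
  if (length(unit_ids) != ncol(values)) {
    stop("length of `unit_ids` does not match the number of columns")
  }
  if (anyDuplicated(stimulus_ids)) {
    stop("duplicate stimulus id: ", stimulus_ids[duplicated(stimulus_ids)][1L])
  }
  if (anyDuplicated(unit_ids)) {
    stop("duplicate unit id: ", unit_ids[duplicated(unit_ids)][1L])
  }
  dimnames(values) <- list(stimulus_ids, unit_ids)
  structure(
    list(values = values, stimulus_ids = stimulus_ids, unit_ids = unit_ids,
         kind = kind, standardized = isTRUE(standardized),
         constant_units = character(0)),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix [%s]> %d stimuli x %d units%s\n",
              x$kind, nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' @export
as.matrix.response_matrix <- function(x, ...) x$values

#' Number of stimuli / units
#' @param m a [response_matrix()]
#' @return integer count.
#' @export
n_stimuli <- function(m) nrow(m$values)

#' @rdname n_stimuli
#' @export
n_units <- function(m) ncol(m$values)

#' Subset a response matrix by unit ids or indices
#'
#' @param m a [response_matrix()]
#' @param units character ids or integer/logical indices of columns to keep.
#' @return a `response_matrix` of the selected units, same kind.
#' @export
select_units <- function(m, units) {
  stopifnot(inherits(m, "response_matrix"))
  if (is.character(units)) {
    idx <- match(units, m$unit_ids)
    if (anyNA(idx)) stop("unknown unit id: ", units[is.na(idx)][1L])
  } else {
    idx <- seq_len(ncol(m$values))[units]
  }
  out <- response_matrix(m$values[, idx, drop = FALSE], kind = m$kind,
                         standardized = m$standardized)
  out$constant_units <- intersect(m$constant_units, out$unit_ids)
  out
}

#' Subset a response matrix by stimulus ids
#'
#' @param m a [response_matrix()]
#' @param stimuli character ids or indices of rows to keep.
#' @return a `response_matrix` over the selected stimuli. The
#'   `standardized` flag is dropped because column moments change under row
#'   subsetting.
#' @export
select_stimuli <- function(m, stimuli) {
  stopifnot(inherits(m, "response_matrix"))
  if (is.character(stimuli)) {
    idx <- match(stimuli, m$stimulus_ids)
    if (anyNA(idx)) stop("unknown stimulus id: ", stimuli[is.na(idx)][1L])
  } else {
    idx <- seq_len(nrow(m$values))[stimuli]
  }
  response_matrix(m$values[idx, , drop = FALSE], kind = m$kind)
}

#' Standardize every unit to zero mean and unit variance
#'
#' Each column is centred and scaled by its sample standard deviation
#' (n-1 divisor). Constant columns cannot be scaled; they are mapped to
#' all-zero columns and recorded in `constant_units` -- a collapsed latent
#' unit is an expected, meaningful outcome, not an error.
#'
#' @param m a [response_matrix()] with at least two stimuli.
#' @return a standardized `response_matrix` (flag set, constants flagged).
#' @export
standardize_units <- function(m) {
  stopifnot(inherits(m, "response_matrix"))
  if (nrow(m$values) < 2L) stop("standardization needs at least 2 stimuli")
  mu <- colMeans(m$values)
  sd <- col_sds(m$values)
  const <- sd == 0
  sd[const] <- 1 # avoid 0/0; constant columns centred to exact zeros below
  values <- sweep(sweep(m$values, 2L, mu), 2L, sd, `/`)
  values[, const] <- 0
  out <- response_matrix(values, kind = m$kind, standardized = TRUE)
  out$constant_units <- m$unit_ids[const]
  out
}

#' Split stimuli into train and held-out sets
#'
#' Reproducible random partition of the stimuli, mimicking the held-out
#' stimulus design of the original study (2100 training faces, 62 held out).
#'
#' @param m a [response_matrix()]
#' @param n_heldout number of stimuli to hold out, `0 < n_heldout < S`.
#' @param seed integer seed controlling the draw.
#' @return list with components `train` and `heldout`, both `response_matrix`
#'   objects; their stimulus ids are disjoint and their union is the input's.
#' @export
split_heldout <- function(m, n_heldout, seed) {
  stopifnot(inherits(m, "response_matrix"))
  S <- nrow(m$values)
  if (n_heldout <= 0L || n_heldout >= S) {
    stop("`n_heldout` must satisfy 0 < n_heldout < number of stimuli (", S, ")")
  }
  held_idx <- sort(with_seed(seed, sample.int(S, n_heldout)))
  list(train = select_stimuli(m, setdiff(seq_len(S), held_idx)),
       heldout = select_stimuli(m, held_idx))
}
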