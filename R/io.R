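#' Read a response matrix from delimited text
#'
#' The on-disk format is a plain table: first row holds unit ids, first
#' column holds stimulus ids, every body cell is numeric. Tab is the
#' preferred delimiter; comma is accepted. Decimal points only, no quoting.
#'
#' @param path path to a `.tsv`/`.csv` file.
#' @param kind the caller's declaration of what the units are
#'   (`"neural"`, `"model"` or `"factor"`).
#' @return a [response_matrix()] preserving the file's row/column order.
#' @export
read_response_matrix <- function(path, kind = c("neural", "model", "factor")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("parse error: need a header row and at least one data row")
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1L])) {
    stop("parse error: ragged row ", which(widths != widths[1L])[1L])
  }
  header <- cells[[1L]]
  unit_ids <- header[-1L]
  if (length(unit_ids) == 0L) stop("parse error: header declares no units")
  if (anyDuplicated(unit_ids)) {
    stop("parse error: duplicate unit id '", unit_ids[duplicated(unit_ids)][1L], "'")
  }
  body <- cells[-1L]
  stimulus_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(stimulus_ids)) {
    stop("parse error: duplicate stimulus id '",
         stimulus_ids[duplicated(stimulus_ids)][1L], "'")
  }
  values <- matrix(NA_real_, length(body), length(unit_ids))
  for (i in seq_along(body)) {
    row <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(row)) {
      j <- which(is.na(row))[1L]
      stop("parse error: non-numeric cell at row ", i, ", column ", j,
           " ('", body[[i]][j + 1L], "')")
    }
    values[i, ] <- row
  }
  response_matrix(values, kind = kind, stimulus_ids = stimulus_ids,
                  unit_ids = unit_ids)
}

#' Write a response matrix to delimited text
#'
#' Full-precision (`%.17g`) tab-separated output so that
#' `read_response_matrix(write_response_matrix(m))` reproduces ids exactly
#' and values to 1e-12.
#'
#' @param m a [response_matrix()]
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(m, path) {
  stopifnot(inherits(m, "response_matrix"))
  header <- paste(c("stimulus", m$unit_ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(m$values)), function(i) {
    paste(c(m$stimulus_ids[i], sprintf("%.17g", m$values[i, ])), collapse = "\t")
  }, character(1L))
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write to ", path)
  invisible(path)
}
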