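#' Expression matrix with missing entries
#'
#' Container pairing a genes-by-samples matrix whose missing cells are `NA`
#' with the boolean missing mask and, in simulation contexts, the stashed
#' true values at the masked positions so imputations can be scored.
#'
#' @param values Numeric matrix; `NA` marks a missing cell; observed entries
#'   must be strictly positive on the expression scale.
#' @param truth Optional complete numeric matrix of the same shape holding
#'   the true values (used by the error measures).
#' @param check_positive If `TRUE` (default), require observed entries > 0.
#' @return Object of class `masked_matrix`: list with `values`, `mask`,
#'   `truth`, `row_ids`, `col_ids`.
#' @export
masked_matrix <- function(values, truth = NULL, check_positive = TRUE) {
  stopifnot(is.matrix(values), is.numeric(values))
  mask <- is.na(values)
  if (all(mask)) stop("all entries missing", call. = FALSE)
  if (check_positive && any(values[!mask] <= 0))
    stop("observed entries must be strictly positive", call. = FALSE)
  if (!is.null(truth)) {
    stopifnot(is.matrix(truth), all(dim(truth) == dim(values)))
  }
  structure(
    list(values = values, mask = mask, truth = truth,
         row_ids = rownames(values) %||% sprintf("g%d", seq_len(nrow(values))),
         col_ids = colnames(values) %||% sprintf("s%d", seq_len(ncol(values)))),
    class = "masked_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.masked_matrix <- function(x, ...) {
  cat(sprintf("<masked_matrix> %d x %d, %d missing (%.1f%%)%s\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              100 * mean(x$mask),
              if (is.null(x$truth)) "" else ", truth stashed"))
  invisible(x)
}

as_masked_matrix <- function(m) {
  if (inherits(m, "masked_matrix")) m else masked_matrix(m)
}

#' Tidy a masked or imputed matrix into long format
#'
#' @param x A `masked_matrix` or `imputed_matrix`.
#' @param ... Unused.
#' @return Tibble `probe_set_id, sample_id, value, missing` (plus `truth`
#'   when stashed).
#' @export
tidy.masked_matrix <- function(x, ...) {
  out <- tibble::tibble(
    probe_set_id = rep(x$row_ids, times = ncol(x$values)),
    sample_id = rep(x$col_ids, each = nrow(x$values)),
    value = as.vector(x$values),
    missing = as.vector(x$mask)
  )
  if (!is.null(x$truth)) out$truth <- as.vector(x$truth)
  out
}
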