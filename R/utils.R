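#' @importFrom rlang abort warn := .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# classed abort helpers so callers can condition on failure modes
stop_invalid_parameter <- function(msg) abort(msg, class = "evodfnc_invalid_parameter")
stop_invalid_input <- function(msg) abort(msg, class = "evodfnc_invalid_input")
stop_not_found <- function(msg) abort(msg, class = "evodfnc_not_found")
stop_degenerate <- function(msg, class) abort(msg, class = c(class, "evodfnc_degenerate"))

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}

#' Vectorize the upper triangle of a correlation matrix
#'
#' Flattens a symmetric matrix with unit diagonal into the row-major upper
#' triangle (pairs ordered (1,2), (1,3), ..., (2,3), ...). This fixed feature
#' order is shared by every downstream stage, and [devectorize_upper()] is its
#' exact inverse.
#'
#' @param corr Symmetric numeric matrix with unit diagonal.
#' @param tol Maximum tolerated absolute asymmetry (default `1e-10`).
#' @return Numeric vector of length `N * (N - 1) / 2`.
#' @seealso [devectorize_upper()]
#' @export
#' @examples
#' vectorize_upper(diag(4))
vectorize_upper <- function(corr, tol = 1e-10) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop_invalid_input("`corr` must be a square matrix.")
  }
  if (max(abs(corr - t(corr))) > tol) {
    stop_invalid_input(sprintf(
      "`corr` is asymmetric beyond tolerance %g (max deviation %g).",
      tol, max(abs(corr - t(corr)))
    ))
  }
  # t(corr)[lower.tri] walks the upper triangle in row-major order
  tc <- t(corr)
  tc[lower.tri(tc)]
}

#' Rebuild a correlation matrix from its upper-triangle vector
#'
#' @param v Numeric vector of length `N * (N - 1) / 2` in the order produced
#'   by [vectorize_upper()].
#' @param diag_value Value placed on the diagonal (default 1).
#' @return Symmetric `N x N` matrix.
#' @export
devectorize_upper <- function(v, diag_value = 1) {
  d <- length(v)
  n <- (1 + sqrt(1 + 8 * d)) / 2
  if (abs(n - round(n)) > 1e-8) {
    stop_invalid_input("Length of `v` is not a triangular number N*(N-1)/2.")
  }
  n <- as.integer(round(n))
  tc <- matrix(0, n, n)
  tc[lower.tri(tc)] <- v
  m <- t(tc) + tc
  diag(m) <- diag_value
  m
}

# write/read numeric matrices as TSV with full double precision (%.17g
# round-trips IEEE doubles exactly through text)
write_matrix_tsv <- function(x, path, col_names = colnames(x)) {
  stopifnot(is.matrix(x))
  txt <- apply(x, 1L, function(r) paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  if (!is.null(col_names)) txt <- c(paste(col_names, collapse = "\t"), txt)
  writeLines(txt, path)
  invisible(path)
}

read_matrix_tsv <- function(path, header = TRUE) {
  as.matrix(utils::read.delim(path, header = header, check.names = FALSE))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_json_file <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
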