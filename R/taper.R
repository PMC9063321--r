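#' Build a tapered rectangular window
#'
#' Constructs the observation weights used for windowed connectivity: a
#' rectangle of `window_len` TRs convolved with a Gaussian kernel of standard
#' deviation `sigma` TRs, truncated back to `window_len` samples and
#' renormalized to sum to one. `sigma = Inf` gives the pure rectangle.
#'
#' @param window_len Window length in TRs (>= 3).
#' @param sigma Gaussian taper width in TRs; `Inf` for an untapered rectangle.
#'   Default 3.
#' @return Numeric weight vector of length `window_len`; nonnegative,
#'   symmetric, summing to 1.
#' @export
#' @examples
#' build_taper(22, 3)
#' build_taper(22, Inf) # flat 1/22 weights
build_taper <- function(window_len, sigma = 3) {
  if (!is_count(window_len, min = 3L)) {
    stop_invalid_parameter("`window_len` must be an integer >= 3.")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop_invalid_parameter("`sigma` must be a positive number (Inf for a pure rectangle).")
  }
  window_len <- as.integer(window_len)
  if (is.infinite(sigma)) {
    return(rep(1 / window_len, window_len))
  }
  half <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  rect <- rep(1, window_len)
  # full discrete convolution, length window_len + 2 * half
  full <- stats::convolve(rect, rev(kern), type = "open")
  w <- full[(half + 1L):(half + window_len)]
  w <- (w + rev(w)) / 2 # enforce exact symmetry against fft round-off
  w / sum(w)
}
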