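#' Discrete Hilbert transform and instantaneous phase
#'
#' Computes the discrete Hilbert transform `H[x]` and the instantaneous
#' phase of the analytic signal `x + i H[x]`, wrapped to `(-pi, pi]`.
#'
#' Two evaluation methods are provided:
#' \describe{
#'   \item{`"fft"` (default)}{The standard analytic-signal construction:
#'     zero out negative frequencies of the DFT and invert. Exact (to
#'     machine precision) for periodic tones; the method used by the RIP
#'     pipeline.}
#'   \item{`"direct"`}{A fast (FFT linear-convolution) evaluation of the
#'     literal odd-index kernel sum
#'     `H[x](n) = (2/pi) * sum_{n - t odd} x(t) / (n - t)` over the finite
#'     sequence. This agrees with the naive O(N^2) double sum to machine
#'     precision and is useful as a transparent, summation-defined
#'     reference; its truncation error near finite-window edges makes the
#'     `"fft"` method preferable for phase extraction.}
#' }
#'
#' @param x Numeric vector (length >= 4).
#' @param method `"fft"` or `"direct"`.
#' @return An object of class `analytic_phase`: a list with `hilbert` (the
#'   transform), `phase` (radians in `(-pi, pi]`), and the input `x`.
#' @export
#' @examples
#' n <- 0:255
#' ap <- discrete_hilbert(cos(2 * pi * 8 * n / 256))
#' max(abs(ap$hilbert - sin(2 * pi * 8 * n / 256)))  # ~1e-15
discrete_hilbert <- function(x, method = c("fft", "direct")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (length(x) < 4L) {
    rlang::abort("Need at least 4 samples for a Hilbert transform.",
                 class = "ripsync_validation_error")
  }
  h <- switch(method, fft = hilbert_fft(x), direct = hilbert_kernel_fast(x))
  structure(list(x = x, hilbert = h, phase = atan2(h, x)),
            class = "analytic_phase")
}

#' @export
print.analytic_phase <- function(x, ...) {
  cat(sprintf("<analytic_phase> %d samples, phase in (-pi, pi]\n", length(x$x)))
  invisible(x)
}

# Analytic-signal Hilbert transform via the DFT (one-sided spectrum).
hilbert_fft <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  Im(stats::fft(X * w, inverse = TRUE) / n)
}

# Fast evaluation of the finite odd-index kernel sum: linear convolution of x
# with k(m) = (2/pi)/m for odd m, 0 otherwise, m = -(N-1)..(N-1).
hilbert_kernel_fast <- function(x) {
  n <- length(x)
  m <- (-(n - 1)):(n - 1)
  ker <- ifelse(m %% 2 != 0, (2 / pi) / m, 0)
  L <- stats::nextn(2 * n - 1, 2)
  # circularly place the kernel so lag 0 sits at index 1
  kbuf <- c(ker[n:(2 * n - 1)], rep(0, L - (2 * n - 1)), ker[1:(n - 1)])
  X <- stats::fft(c(x, rep(0, L - n)))
  K <- stats::fft(kbuf)
  Re(stats::fft(X * K, inverse = TRUE) / L)[1:n]
}

#' Instantaneous phase synchrony between two phase series
#'
#' Per-sample synchrony `phi(n) = 1 - sin(|wrap(da(n))| / 2)` where
#' `da = phase_a - phase_b` is wrapped to `(-pi, pi]`. The statistic lives in
#' `[0, 1]`: 1 means the two signals are perfectly in phase, 0 means
#' antiphase (one compartment moving opposite to the other). It is invariant
#' to adding a common constant to both phase series.
#'
#' @param phase_a,phase_b Phase series in radians, equal lengths.
#' @return Numeric vector of synchrony values in `[0, 1]`.
#' @export
#' @examples
#' phase_synchrony(c(0, 1, 2), c(0, 1, 2))        # all 1
#' phase_synchrony(c(0, 1), c(pi, 1 + pi))        # all 0
phase_synchrony <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) {
    rlang::abort("Phase series must have equal lengths.",
                 class = "ripsync_validation_error")
  }
  d <- wrap_phase(phase_a - phase_b)
  1 - sin(abs(d) / 2)
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param theta Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_phase <- function(theta) {
  out <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  # the interval is half-open at -pi: map the -pi endpoint to +pi
  out[out == -pi] <- pi
  out
}
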