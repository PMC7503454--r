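#' Mixed Gaussian/mono-exponential spatial autocorrelation parameters
#'
#' Spatial noise smoothness is summarized by the mixed autocorrelation
#' function `ACF(r) = a exp(-r^2 / (2 b^2)) + (1 - a) exp(-r / c)`, with
#' `r` in voxel units. This heavy-tailed form (rather than a pure Gaussian)
#' is what whole-brain residual smoothness estimates follow.
#'
#' @param a Mixing fraction of the Gaussian component, in `[0, 1]`.
#' @param b Gaussian width, voxels; positive.
#' @param c Exponential decay length, voxels; positive.
#' @return Object of class `acf_params`.
#' @examples
#' acf_value(acf_params(0.97, 1.10, 9.01), r = c(0, 1, 2))
#' @export
acf_params <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            a >= 0, a <= 1, b > 0, c > 0)
  structure(list(a = a, b = b, c = c), class = "acf_params")
}

#' Evaluate the mixed spatial ACF
#' @param params An [acf_params()] object.
#' @param r Nonnegative voxel distances.
#' @return Correlation values; `acf_value(params, 0)` is 1.
#' @export
acf_value <- function(params, r) {
  stopifnot(inherits(params, "acf_params"))
  if (any(r < 0)) stop("r must be nonnegative")
  params$a * exp(-r^2 / (2 * params$b^2)) +
    (1 - params$a) * exp(-r / params$c)
}

#' Spectral filter for ACF-matched noise synthesis
#'
#' Square root of the (clipped, nonnegative) power spectrum of the target ACF
#' evaluated on the torus of the given grid, for FFT filtering of white noise.
#' Precompute once when simulating many fields on the same grid.
#'
#' @param params An [acf_params()] object.
#' @param dim Integer grid dimensions (length 3).
#' @return Numeric array of spectral amplitudes with a `norm` attribute such
#'   that filtered fields have unit variance.
#' @export
acf_spectrum <- function(params, dim) {
  stopifnot(length(dim) == 3, all(dim >= 2))
  ax <- lapply(dim, function(n) {
    d <- 0:(n - 1)
    pmin(d, n - d)
  })
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  rho <- acf_value(params, sqrt(r2))
  spec <- pmax(Re(stats::fft(rho)), 0)
  S <- array(sqrt(spec), dim = dim)
  attr(S, "norm") <- sqrt(mean(S^2))
  S
}

#' Simulate a spatially autocorrelated Gaussian noise field
#'
#' Draws a zero-mean, unit-variance 3D Gaussian field whose isotropic spatial
#' autocorrelation matches the target mixed ACF, by filtering white noise in
#' the Fourier domain with the square-root power spectrum of the ACF.
#'
#' @param params An [acf_params()] object.
#' @param dim Integer grid dimensions (length 3).
#' @param seed Optional integer seed.
#' @param spectrum Optional precomputed [acf_spectrum()] for this grid.
#' @return 3D numeric array.
#' @export
simulate_noise_field <- function(params, dim, seed = NULL, spectrum = NULL) {
  if (is.null(spectrum)) spectrum <- acf_spectrum(params, dim)
  with_seed(seed, {
    w <- array(stats::rnorm(prod(dim)), dim = dim)
    noise_filter(w, spectrum)
  })
}

# Filter an existing white-noise array (consumes no RNG itself).
noise_filter <- function(w, spectrum) {
  n <- length(w)
  f <- stats::fft(w) * spectrum
  Re(stats::fft(f, inverse = TRUE)) / n / attr(spectrum, "norm")
}
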