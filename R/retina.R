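#' Frequency response of the photoreceptor (OPL) low-pass filter
#'
#' Returns the complex gain grid of the outer-plexiform-layer filter on the
#' standard (unshifted) DFT grid: entry `[1, 1]` is DC, and the frequency of
#' entry `[i, j]` is `fy = (i-1)/height`, `fx = (j-1)/width` cycles/pixel,
#' wrapped to `[-0.5, 0.5)`. The 1-D photoreceptor response
#' `1 / (1 + beta_ph + 2 alpha_ph (1 - cos 2 pi fs) + j 2 pi tau_ph ft)`
#' is extended to two spatial dimensions with the separable-cosine
#' (discrete-Laplacian) coupling `2 alpha_ph (2 - cos 2 pi fx - cos 2 pi fy)`,
#' the standard choice in OPL retina models; it keeps an exact circular
#' spatial-convolution counterpart. The DC gain is exactly `1/(1 + beta_ph)`
#' and the gain magnitude is maximal there (low-pass).
#'
#' @param shape Integer vector `c(height, width)`.
#' @param params [photoreceptor_params()].
#' @param ft Scalar temporal frequency (cycles/frame); 0 for static images,
#'   which drops the imaginary temporal term.
#' @return A `height x width` complex matrix of gains.
#' @examples
#' H <- opl_frequency_response(c(8, 8), photoreceptor_params())
#' H[1, 1]  # DC gain 1/(1 + beta_ph) = 1
#' @export
opl_frequency_response <- function(shape, params = photoreceptor_params(), ft = 0) {
  stopifnot(inherits(params, "photoreceptor_params"))
  if (length(shape) != 2L || any(shape < 1) || any(shape != floor(shape))) {
    stop("`shape` must be two positive integers c(height, width)", call. = FALSE)
  }
  if (!is.numeric(ft) || length(ft) != 1L || !is.finite(ft)) {
    stop("`ft` must be a single finite number", call. = FALSE)
  }
  h <- shape[1L]; w <- shape[2L]
  # cos(2*pi*k/n) is periodic, so the unwrapped DFT index frequencies k/n
  # give identical values to the wrapped [-0.5, 0.5) convention.
  cy <- cos(2 * pi * (seq_len(h) - 1L) / h)
  cx <- cos(2 * pi * (seq_len(w) - 1L) / w)
  spatial <- 2 * params$alpha_ph * outer(2 - cy, cx, function(a, b) a - b)
  denom <- 1 + params$beta_ph + spatial + (0 + 2i) * pi * params$tau_ph * ft
  1 / denom
}

#' Apply the photoreceptor low-pass filter to an image
#'
#' Multiplies the image's 2-D DFT by the OPL frequency response and inverts
#' the transform, i.e. circular (periodic-boundary) convolution with the
#' filter's impulse response. The real part is returned; the imaginary
#' residue of a Hermitian response is numerical noise. The result is the
#' local-luminance map used by light adaptation and is *not* clipped: it may
#' slightly exceed the input range near strong edges.
#'
#' @param image Numeric matrix (grayscale intensities).
#' @param params [photoreceptor_params()].
#' @return Filtered matrix, same shape as `image`.
#' @examples
#' img <- matrix(runif(64, 0, 255), 8, 8)
#' L <- apply_photoreceptor_filter(img, photoreceptor_params())
#' all.equal(mean(L), mean(img))  # DC preserved when beta_ph = 0
#' @export
apply_photoreceptor_filter <- function(image, params = photoreceptor_params()) {
  if (!is.matrix(image)) stop("`image` must be a numeric matrix", call. = FALSE)
  assert_image(image)
  H <- opl_frequency_response(dim(image), params, ft = 0)
  Re(stats::fft(stats::fft(image) * H, inverse = TRUE)) / length(image)
}

#' One step of the recursive temporal photoreceptor filter
#'
#' Discrete realization of the temporal term `1/(1 + j 2 pi tau_ph ft)` as
#' the first-order exponential-smoothing recursion
#' `y[t] = (x[t] + tau_ph * y[t-1]) / (1 + tau_ph)`, which has unity DC gain.
#' With no previous output the filter initializes to the current frame.
#'
#' @param current Current frame (numeric matrix).
#' @param previous_output Previous filtered frame, or `NULL` on the first step.
#' @param params [photoreceptor_params()].
#' @return Filtered frame, same shape as `current`.
#' @export
temporal_filter_step <- function(current, previous_output = NULL,
                                 params = photoreceptor_params()) {
  if (!is.matrix(current)) stop("`current` must be a numeric matrix", call. = FALSE)
  assert_image(current, "current")
  if (is.null(previous_output)) return(current)
  if (!is.matrix(previous_output) || !all(dim(previous_output) == dim(current))) {
    stop("`previous_output` must match the shape of `current`", call. = FALSE)
  }
  (current + params$tau_ph * previous_output) / (1 + params$tau_ph)
}
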