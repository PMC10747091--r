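#' Per-pixel compression parameter from local luminance
#'
#' The Michaelis-Menten operating point of each photoreceptor is tied to the
#' light in its vicinity: `R0(m,n) = v0 * L(m,n) + vmax * (1 - v0)`, where
#' `L` is the OPL-filtered local-luminance map. With `v0 = 0` the operating
#' point is `vmax` everywhere (no surround influence); with `v0 = 1` it
#' equals `L` exactly.
#'
#' @param L Local-luminance matrix (output of [apply_photoreceptor_filter()]).
#' @param params [adaptation_params()].
#' @return Matrix `R0`, same shape as `L`.
#' @examples
#' compression_parameter(matrix(100, 2, 2), adaptation_params())  # 146.5
#' @export
compression_parameter <- function(L, params = adaptation_params()) {
  stopifnot(inherits(params, "adaptation_params"))
  if (!is.matrix(L)) stop("`L` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(L))) stop("`L` contains non-finite values", call. = FALSE)
  params$v0 * L + params$vmax * (1 - params$v0)
}

#' Michaelis-Menten light adaptation of an intensity map
#'
#' Saturating photoreceptor response
#' `C(m,n) = R(m,n) * (vmax + R0(m,n)) / (R(m,n) + R0(m,n))`,
#' clipped to `[0, vmax]`; pixels where `R + R0 = 0` map to 0 (the continuous
#' limit as `R -> 0`). Dark pixels are amplified (`C >= R` whenever
#' `R0 <= vmax`), while `R = vmax` under a bright surround (`R0 = vmax`)
#' is a fixed point, so bright regions are preserved.
#'
#' @param R Input intensity matrix, values >= 0.
#' @param R0 Compression map from [compression_parameter()], same shape.
#' @param params [adaptation_params()].
#' @return Adapted intensity matrix on `[0, vmax]`.
#' @examples
#' adapt_response(matrix(50, 1, 1), matrix(146.5, 1, 1))  # ~102.16
#' @export
adapt_response <- function(R, R0, params = adaptation_params()) {
  stopifnot(inherits(params, "adaptation_params"))
  if (!is.matrix(R) || !is.matrix(R0) || !all(dim(R) == dim(R0))) {
    stop("`R` and `R0` must be matrices of the same shape", call. = FALSE)
  }
  if (any(!is.finite(R)) || any(!is.finite(R0))) {
    stop("non-finite values in `R` or `R0`", call. = FALSE)
  }
  if (any(R < 0)) stop("`R` must be non-negative", call. = FALSE)
  denom <- R + R0
  C <- R * (params$vmax + R0)
  out <- ifelse(denom == 0, 0, C / ifelse(denom == 0, 1, denom))
  matrix(clip(out, 0, params$vmax), nrow(R), ncol(R))
}

#' Retina-inspired contrast enhancement of an image
#'
#' Full light-regulation chain: the OPL low-pass filter of the luminance
#' channel gives the local-luminance map `L`; `L` sets the per-pixel
#' Michaelis-Menten operating point `R0`; every channel is then adapted
#' against the shared `R0` map (preserving hue relations in RGB images).
#' Dark regions of a scene are amplified while bright regions stay close to
#' their value, balancing the histogram of under-exposed images. Output is
#' floating point on `[0, vmax]`; quantization to integers happens only on
#' file write.
#'
#' @param image Gray matrix or H x W x 3 RGB array on `[0, vmax]`.
#' @param ph [photoreceptor_params()].
#' @param ad [adaptation_params()].
#' @param per_channel_luminance If `TRUE`, compute a separate `L`/`R0` per
#'   RGB channel instead of a shared luminance-derived map. Default `FALSE`.
#' @return Enhanced image of the same kind and shape.
#' @examples
#' dark <- matrix(runif(100, 0, 30), 10, 10)
#' bright <- enhance(dark)
#' mean(bright) > mean(dark)
#' @export
enhance <- function(image, ph = photoreceptor_params(), ad = adaptation_params(),
                    per_channel_luminance = FALSE) {
  assert_image(image)
  if (any(image < 0) || any(image > ad$vmax)) {
    stop(sprintf("`image` values must lie in [0, %g]", ad$vmax), call. = FALSE)
  }
  adapt_channel <- function(R, L) {
    adapt_response(R, compression_parameter(L, ad), ad)
  }
  if (is.matrix(image)) {
    return(adapt_channel(image, apply_photoreceptor_filter(image, ph)))
  }
  out <- image
  if (per_channel_luminance) {
    for (k in 1:3) {
      out[, , k] <- adapt_channel(image[, , k],
                                  apply_photoreceptor_filter(image[, , k], ph))
    }
  } else {
    L <- apply_photoreceptor_filter(luminance(image), ph)
    R0 <- compression_parameter(L, ad)
    for (k in 1:3) out[, , k] <- adapt_response(image[, , k], R0, ad)
  }
  out
}

#' Photoreceptor response curve under a uniform surround
#'
#' Tabulates the adapted response `C(R)` for inputs `R` on `[0, vmax]` when
#' the local luminance is uniformly `L_level`. Used to visualize how the
#' compression parameter `v0` shifts the response family: larger `v0`
#' (darker effective operating point) lifts the curve for dark inputs.
#'
#' @param params [adaptation_params()].
#' @param L_level Uniform surround luminance (scalar intensity).
#' @param n Number of tabulation points. Default 256.
#' @return A `data.frame` with columns `R` and `C`.
#' @examples
#' head(response_curve(adaptation_params(v0 = 0.7), L_level = 50))
#' @export
response_curve <- function(params = adaptation_params(), L_level = 50, n = 256) {
  stopifnot(inherits(params, "adaptation_params"))
  if (!is.numeric(L_level) || length(L_level) != 1L || !is.finite(L_level)) {
    stop("`L_level` must be a single finite number", call. = FALSE)
  }
  R <- seq(0, params$vmax, length.out = n)
  R0 <- params$v0 * L_level + params$vmax * (1 - params$v0)
  C <- as.numeric(adapt_response(matrix(R, 1), matrix(R0, 1, n), params))
  data.frame(R = R, C = C)
}
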