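#' Photoreceptor (OPL) filter parameters
#'
#' Constants of the outer-plexiform-layer low-pass filter that models the
#' spatio-temporal response of retinal photoreceptors. `beta_ph` is the gain
#' control (DC gain is `1/(1 + beta_ph)`), `alpha_ph` sets the spatial
#' cut-off (larger values suppress high spatial frequencies more strongly),
#' and `tau_ph` is the temporal smoothing constant in frame-time units.
#' Defaults are the reference operating point for static images.
#'
#' @param beta_ph Dimensionless gain-control constant, >= 0. Default 0.
#' @param alpha_ph Dimensionless spatial filtering constant, >= 0. Default 1.
#' @param tau_ph Temporal filtering constant (frames), >= 0. Default 1.
#' @return An object of class `photoreceptor_params`.
#' @examples
#' photoreceptor_params()
#' photoreceptor_params(beta_ph = 1)
#' @export
photoreceptor_params <- function(beta_ph = 0, alpha_ph = 1, tau_ph = 1) {
  for (nm in c("beta_ph", "alpha_ph", "tau_ph")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single finite non-negative number", nm), call. = FALSE)
    }
  }
  structure(list(beta_ph = beta_ph, alpha_ph = alpha_ph, tau_ph = tau_ph),
            class = "photoreceptor_params")
}

#' @export
print.photoreceptor_params <- function(x, ...) {
  cat(sprintf("OPL photoreceptor filter: beta_ph = %g, alpha_ph = %g, tau_ph = %g\n",
              x$beta_ph, x$alpha_ph, x$tau_ph))
  invisible(x)
}

#' Light-adaptation (Michaelis-Menten) parameters
#'
#' `v0` is the compression parameter on `[0, 1]` controlling how strongly the
#' local luminance shifts the adaptation operating point (0: no adaptation to
#' the surround; 1: operating point equals the local luminance). `vmax` is
#' the maximum representable pixel value (255 for 8-bit images).
#'
#' @param v0 Compression parameter in `[0, 1]`. Default 0.7.
#' @param vmax Maximum pixel value, > 0. Default 255.
#' @return An object of class `adaptation_params`.
#' @examples
#' adaptation_params()
#' adaptation_params(v0 = 0.3)
#' @export
adaptation_params <- function(v0 = 0.7, vmax = 255) {
  if (!is.numeric(v0) || length(v0) != 1L || !is.finite(v0) || v0 < 0 || v0 > 1) {
    stop("`v0` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(vmax) || length(vmax) != 1L || !is.finite(vmax) || vmax <= 0) {
    stop("`vmax` must be a single positive number", call. = FALSE)
  }
  structure(list(v0 = v0, vmax = vmax), class = "adaptation_params")
}

#' @export
print.adaptation_params <- function(x, ...) {
  cat(sprintf("Light adaptation: v0 = %g, vmax = %g\n", x$v0, x$vmax))
  invisible(x)
}
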