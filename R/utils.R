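#' Evaluate an expression with a fixed, restorable RNG state
#'
#' All stochastic code in the package funnels through this helper so that
#' fixtures and training runs are reproducible across machines: the RNG kind
#' is pinned to Mersenne-Twister with inversion sampling, and the caller's
#' `.Random.seed` is restored afterwards.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  old_kind <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Shannon entropy of an image histogram
#'
#' Quantizes intensities to integer bins 0..vmax (round half up, as on 8-bit
#' write) and returns the entropy of the resulting histogram in bits.
#'
#' @param image Numeric matrix or array of intensities on `[0, vmax]`.
#' @param vmax Maximum representable intensity (default 255).
#' @return Entropy in bits (scalar).
#' @export
shannon_entropy <- function(image, vmax = 255) {
  v <- floor(clip(as.numeric(image), 0, vmax) + 0.5)
  p <- tabulate(v + 1L, nbins = vmax + 1L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

is_image <- function(x) {
  is.numeric(x) && (is.matrix(x) || (is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L))
}

assert_image <- function(x, name = "image") {
  if (!is_image(x)) {
    stop(sprintf("`%s` must be a numeric matrix (gray) or H x W x 3 array (RGB)", name),
         call. = FALSE)
  }
  if (any(!is.finite(x))) stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L) stop(sprintf("`%s` is empty", name), call. = FALSE)
  invisible(x)
}

#' Collapse an RGB array to a single luminance channel
#'
#' @param image Gray matrix (returned unchanged) or H x W x 3 array; luminance
#'   is the unweighted channel mean, which preserves hue relations when the
#'   same adaptation map is later applied to every channel.
#' @return Numeric matrix.
#' @export
luminance <- function(image) {
  assert_image(image)
  if (is.matrix(image)) return(image)
  (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
}
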