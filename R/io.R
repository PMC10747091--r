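#' Read an 8-bit image from PNG or JPEG
#'
#' Returns intensities on `[0, 255]` as a matrix (grayscale files) or an
#' H x W x 3 array (color files; any alpha channel is dropped). Rows index
#' the vertical axis top to bottom, columns the horizontal axis.
#'
#' @param path File path (.png, .jpg/.jpeg, .tif).
#' @return Numeric matrix or H x W x 3 array on `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: '%s'", path), call. = FALSE)
  img <- EBImage::imageData(EBImage::readImage(path))
  # EBImage stores [x, y, channel]; transpose to matrix [row=y, col=x]
  if (length(dim(img)) == 2L) return(t(img) * 255)
  nc <- dim(img)[3L]
  if (nc == 1L) return(t(img[, , 1L]) * 255)
  out <- array(0, c(dim(img)[2L], dim(img)[1L], 3L))
  for (k in 1:3) out[, , k] <- t(img[, , k]) * 255
  out * 1  # drop alpha if present (channels beyond 3 ignored)
}

#' Write an image as 8-bit PNG or JPEG
#'
#' Values are clipped to `[0, vmax]`, rescaled, and quantized round-half-up
#' to 8 bits. The format is chosen from the file extension.
#'
#' @param image Numeric matrix or H x W x 3 array on `[0, vmax]`.
#' @param path Output path (.png or .jpg/.jpeg).
#' @param vmax Maximum intensity of the input scale. Default 255.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, vmax = 255) {
  assert_image(image)
  q <- floor(clip(image / vmax, 0, 1) * 255 + 0.5) / 255
  dat <- if (is.matrix(q)) t(q) else {
    a <- array(0, c(ncol(q), nrow(q), 3L))
    for (k in 1:3) a[, , k] <- t(q[, , k])
    a
  }
  obj <- EBImage::Image(dat, colormode = if (is.matrix(q)) "Grayscale" else "Color")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  EBImage::writeImage(obj, path)
  invisible(path)
}

#' Area-averaging image resize
#'
#' Exact box (pixel-area overlap) downsampling, applied separably: each
#' target pixel is the average of the source area it covers. This is the
#' appropriate anti-aliasing resampler for the large downscale (e.g.
#' 200 x 200 to 50 x 50) used when standardizing classifier inputs; it is
#' also defined (as linear interpolation of box overlaps) for upscaling.
#'
#' @param image Gray matrix or H x W x 3 array.
#' @param size Target `c(height, width)`.
#' @return Resized image of the same kind.
#' @export
resize_area <- function(image, size) {
  assert_image(image)
  if (length(size) != 2L || any(size < 1)) stop("`size` must be c(height, width) >= 1", call. = FALSE)
  wy <- box_weights(nrow(image), size[1L])
  wx <- box_weights(ncol(image), size[2L])
  if (is.matrix(image)) return(wy %*% image %*% t(wx))
  out <- array(0, c(size[1L], size[2L], 3L))
  for (k in 1:3) out[, , k] <- wy %*% image[, , k] %*% t(wx)
  out
}

# dst x src row matrix of normalized interval-overlap weights
box_weights <- function(src, dst) {
  s <- src / dst
  W <- matrix(0, dst, src)
  for (i in seq_len(dst)) {
    a <- (i - 1) * s; b <- i * s
    j0 <- floor(a) + 1; j1 <- ceiling(b)
    for (j in j0:min(j1, src)) {
      W[i, j] <- max(0, min(b, j) - max(a, j - 1))
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

#' Convert an image to grayscale via the channel mean
#'
#' @param image Gray matrix (returned unchanged) or H x W x 3 array.
#' @return Numeric matrix.
#' @export
to_grayscale <- function(image) luminance(image)
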