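#' Deterministic bright-blob stub hand detector
#'
#' A synthetic stand-in for a real hand-landmark detector, for tests and
#' fixtures only: it looks for a high-contrast bright blob and, if one
#' exists, anchors a 21-point hand template at the blob centroid, scaled to
#' the blob extent. The foreground criterion is contrast-based (intensity
#' dispersion and the upper mid-range), not an absolute threshold, so the
#' decision is stable whether the image is raw or enhancement-brightened;
#' blank scenes (e.g. a NOTHING class) yield a miss (`NULL`). The function
#' is pure and deterministic, so dataset builds are reproducible.
#'
#' A detector, for this package, is any `function(image)` returning a
#' [hand_landmarks()] object or `NULL` on a miss; adapters for real
#' detectors can be plugged into [build_variant()] the same way.
#'
#' @param contrast Minimum intensity standard deviation for the scene to
#'   contain anything detectable. Default 25.
#' @param min_pixels Minimum foreground (above mid-range) pixel count for a
#'   detection. Default 40.
#' @return A detector function.
#' @export
stub_detector <- function(contrast = 25, min_pixels = 40) {
  force(contrast); force(min_pixels)
  function(image) {
    g <- luminance(image)
    if (stats::sd(g) < contrast) return(NULL)
    mid <- (min(g) + max(g)) / 2
    fg <- which(g > mid, arr.ind = TRUE)
    if (nrow(fg) < min_pixels) return(NULL)
    cy <- mean(fg[, 1L]) / nrow(g)
    cx <- mean(fg[, 2L]) / ncol(g)
    spread <- 2.5 * (stats::sd(fg[, 1L]) / nrow(g) + stats::sd(fg[, 2L]) / ncol(g))
    scale <- clip(spread, 0.25, 0.9)
    base <- unclass(gen_landmarks(seed = 0, jitter = 0))  # fixed template
    pts <- base[, 1:2, drop = FALSE]
    center <- colMeans(pts)
    pts <- sweep(pts, 2L, center) * scale
    pts <- sweep(pts, 2L, c(cx, cy), "+")
    hand_landmarks(cbind(pts, base[, 3L]))
  }
}

#' Build one dataset variant from a directory-per-class image tree
#'
#' Produces the three training-set variants of the pipeline, standardized to
#' the classifier's input raster:
#' \describe{
#'   \item{V1}{raw images, grayscaled and area-resized to `size`;}
#'   \item{V2}{photoreceptor-enhanced ([enhance()]) first, then grayscale
#'     and resize;}
#'   \item{V3}{enhanced, passed to the landmark `detector`, and the detected
#'     21-point skeleton rendered white-on-black at the source resolution
#'     ([rasterize_landmarks()]) before resizing. Images where the detector
#'     returns no hand are dropped (and counted), so a class with no
#'     detectable hands — typically NOTHING — can be absent from V3.}
#' }
#'
#' @param src_root Directory containing `<CLASS>/<image>.(png|jpg)` subtrees.
#' @param tag One of `"V1"`, `"V2"`, `"V3"`.
#' @param detector Detector function (see [stub_detector()]); required for V3.
#' @param ph,ad Filter and adaptation parameters for the enhancement stage.
#' @param size Output raster, default `c(50, 50)` grayscale.
#' @param radius,thickness V3 rasterization geometry at the source
#'   resolution; defaults 2 px discs and 1 px bones at 200 x 200 scale with
#'   the rescaling handled by drawing before the resize.
#' @param out_dir Optional: write the variant as a mirrored PNG tree plus a
#'   `manifest.csv` (path, class, variant, kept/dropped).
#' @return A `gesture_dataset` with attributes `variant`, `dropped` (named
#'   integer drop counts per class) and `manifest` (data.frame).
#' @export
build_variant <- function(src_root, tag = c("V1", "V2", "V3"), detector = NULL,
                          ph = photoreceptor_params(), ad = adaptation_params(),
                          size = c(50, 50), radius = 2, thickness = 1,
                          out_dir = NULL) {
  tag <- match.arg(tag)
  if (!dir.exists(src_root)) stop(sprintf("no such directory: '%s'", src_root), call. = FALSE)
  classes <- sort(basename(list.dirs(src_root, recursive = FALSE)))
  if (length(classes) == 0L) stop("`src_root` has no class directories", call. = FALSE)
  if (tag == "V3" && is.null(detector)) stop("V3 requires a `detector`", call. = FALSE)

  images <- list(); labels <- character(0)
  man <- list()
  dropped <- integer(length(classes)); names(dropped) <- classes
  for (cls in classes) {
    files <- sort(list.files(file.path(src_root, cls),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    for (f in files) {
      img <- tryCatch(read_image(f), error = function(e) NULL)
      if (is.null(img)) {
        warning(sprintf("skipping unreadable image '%s'", f), call. = FALSE)
        man[[length(man) + 1L]] <- data.frame(path = f, class = cls, variant = tag,
                                              status = "unreadable")
        next
      }
      out <- switch(tag,
        V1 = resize_area(to_grayscale(img), size),
        V2 = resize_area(to_grayscale(enhance(img, ph, ad)), size),
        V3 = {
          lm <- detector(enhance(img, ph, ad))
          if (is.null(lm)) NULL else {
            resize_area(rasterize_landmarks(lm, dim(to_grayscale(img)),
                                            radius = radius, thickness = thickness,
                                            vmax = ad$vmax), size)
          }
        })
      if (is.null(out)) {
        dropped[cls] <- dropped[cls] + 1L
        man[[length(man) + 1L]] <- data.frame(path = f, class = cls, variant = tag,
                                              status = "dropped")
        next
      }
      images[[length(images) + 1L]] <- clip(out, 0, ad$vmax)
      labels <- c(labels, cls)
      man[[length(man) + 1L]] <- data.frame(path = f, class = cls, variant = tag,
                                            status = "kept")
    }
  }
  kept_classes <- classes[classes %in% unique(labels)]
  empty <- setdiff(classes, kept_classes)
  if (length(empty) > 0) {
    warning(sprintf("classes with no kept images in %s: %s",
                    tag, paste(empty, collapse = ", ")), call. = FALSE)
  }
  manifest <- do.call(rbind, man)
  ds <- structure(list(images = images, labels = labels, classes = kept_classes),
                  class = "gesture_dataset")
  attr(ds, "variant") <- tag
  attr(ds, "dropped") <- dropped
  attr(ds, "manifest") <- manifest
  if (!is.null(out_dir)) {
    write_gesture_dataset(ds, out_dir)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  ds
}

#' Split a gesture dataset into training and held-out parts
#'
#' Stratified per class: a seeded shuffle within each class, then the first
#' `1 - test_fraction` of each class goes to training.
#'
#' @param ds A `gesture_dataset`.
#' @param test_fraction Held-out fraction per class. Default 0.2.
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` datasets.
#' @export
split_dataset <- function(ds, test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(ds, "gesture_dataset"))
  pick <- with_seed(seed, {
    test_idx <- unlist(lapply(ds$classes, function(cls) {
      idx <- which(ds$labels == cls)
      n_test <- max(1L, round(test_fraction * length(idx)))
      sample(idx, n_test)
    }))
    test_idx
  })
  subset_ds <- function(idx) {
    structure(list(images = ds$images[idx], labels = ds$labels[idx],
                   classes = ds$classes), class = "gesture_dataset")
  }
  list(train = subset_ds(setdiff(seq_along(ds$images), pick)),
       test = subset_ds(sort(pick)))
}
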