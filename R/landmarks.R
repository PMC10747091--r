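#' Construct a 21-point hand-landmark set
#'
#' The standard articulated-hand topology: point 1 is the wrist, then four
#' joints per finger in the order thumb, index, middle, ring, pinky
#' (0-based indices 0; 1-4; 5-8; 9-12; 13-16; 17-20 in detector
#' conventions). Coordinates are normalized image coordinates: `x` rightward
#' and `y` downward in `[0, 1]` (clamped), `z` an unconstrained relative
#' depth.
#'
#' @param points A 21 x 2 or 21 x 3 numeric matrix of `(x, y[, z])` rows.
#' @return An object of class `hand_landmarks`: a 21 x 3 matrix with columns
#'   `x`, `y`, `z`.
#' @export
hand_landmarks <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 21L || !(ncol(points) %in% c(2L, 3L))) {
    stop("a hand landmark set must have exactly 21 (x, y[, z]) points", call. = FALSE)
  }
  if (any(!is.finite(points))) stop("landmark coordinates must be finite", call. = FALSE)
  if (ncol(points) == 2L) points <- cbind(points, 0)
  points[, 1:2] <- clip(points[, 1:2], 0, 1)
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(points, class = "hand_landmarks")
}

# the 20 bones: wrist -> proximal joint of each finger, then each
# four-joint chain (0-based endpoint pairs)
hand_bones <- function() {
  chains <- lapply(c(1L, 5L, 9L, 13L, 17L), function(b) {
    cbind(c(0L, b, b + 1L, b + 2L), c(b, b + 1L, b + 2L, b + 3L))
  })
  do.call(rbind, chains)
}

# squared distance from pixel centers (px, py vectors) to segment (x1,y1)-(x2,y2)
dist2_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- clip(((px - x1) * dx + (py - y1) * dy) / len2, 0, 1)
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

# paint value onto canvas where pixel centers fall within `radius` of any
# disc center or within `thickness/2` of any segment; coordinates are
# 0-based pixel centers, x rightward, y downward
draw_shapes <- function(canvas, discs = NULL, segments = NULL,
                        radius = 2, thickness = 1, value = 255) {
  h <- nrow(canvas); w <- ncol(canvas)
  px <- rep(0:(w - 1L), each = h)
  py <- rep(0:(h - 1L), times = w)
  hit <- rep(FALSE, h * w)
  if (!is.null(discs) && nrow(discs) > 0) {
    r2 <- radius^2
    for (i in seq_len(nrow(discs))) {
      hit <- hit | ((px - discs[i, 1])^2 + (py - discs[i, 2])^2 <= r2)
    }
  }
  if (!is.null(segments) && nrow(segments) > 0) {
    t2 <- (thickness / 2)^2
    for (i in seq_len(nrow(segments))) {
      hit <- hit | (dist2_segment(px, py, segments[i, 1], segments[i, 2],
                                  segments[i, 3], segments[i, 4]) <= t2)
    }
  }
  canvas[matrix(hit, h, w)] <- value
  canvas
}

#' Render a hand-landmark set as a white skeleton on black
#'
#' Joints are drawn as filled discs and the 20 bone segments of the standard
#' hand topology as thick lines, white (`vmax`) on a black (0) canvas. A
#' pixel is painted when its center lies within `radius` of a joint or
#' within `thickness/2` of a bone segment; coordinates are 0-based pixel
#' centers, x rightward, y downward, with normalized landmark coordinates
#' scaled by `(width-1, height-1)`. Deterministic for fixed inputs.
#'
#' @param lm A [hand_landmarks()] object, or `NULL` (detector miss), which
#'   yields an all-zero canvas.
#' @param size Canvas `c(height, width)`.
#' @param radius Joint disc radius in pixels. Default 2 (at 200 x 200).
#' @param thickness Bone line thickness in pixels. Default 1.
#' @param vmax Foreground intensity. Default 255.
#' @return Numeric matrix of 0s and `vmax`s.
#' @examples
#' img <- rasterize_landmarks(gen_landmarks(1), c(50, 50), radius = 1)
#' @export
rasterize_landmarks <- function(lm, size, radius = 2, thickness = 1, vmax = 255) {
  if (length(size) != 2L || any(size < 1)) stop("`size` must be c(height, width)", call. = FALSE)
  canvas <- matrix(0, size[1L], size[2L])
  if (is.null(lm)) return(canvas)
  if (!inherits(lm, "hand_landmarks")) lm <- hand_landmarks(lm)
  sx <- size[2L] - 1L; sy <- size[1L] - 1L
  pts <- cbind(lm[, "x"] * sx, lm[, "y"] * sy)
  bones <- hand_bones() + 1L
  segs <- cbind(pts[bones[, 1L], , drop = FALSE], pts[bones[, 2L], , drop = FALSE])
  draw_shapes(canvas, discs = pts, segments = segs,
              radius = radius, thickness = thickness, value = vmax)
}
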