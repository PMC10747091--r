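# shared helpers: small in-memory fixtures and independent oracles

# circular spatial convolution oracle: shift-and-accumulate, no FFT on the
# application path (the kernel is the inverse-DFT of the frequency response)
circ_conv_oracle <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (a in 0:(h - 1)) {
    rows <- ((0:(h - 1) - a) %% h) + 1
    for (b in 0:(w - 1)) {
      kv <- kernel[a + 1, b + 1]
      if (kv == 0) next
      cols <- ((0:(w - 1) - b) %% w) + 1
      out <- out + kv * img[rows, cols]
    }
  }
  out
}

# brute-force pixel-enumeration rasterization oracle
raster_oracle <- function(lm, size, radius, thickness, vmax = 255) {
  h <- size[1]; w <- size[2]
  pts <- cbind(lm[, "x"] * (w - 1), lm[, "y"] * (h - 1))
  bones <- retinasign:::hand_bones() + 1
  seg_d <- function(px, py, p, q) {
    d <- q - p
    len2 <- sum(d^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((c(px, py) - p) * d) / len2))
    sqrt(sum((c(px, py) - (p + t * d))^2))
  }
  canvas <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      px <- j - 1; py <- i - 1
      hit <- any(sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2) <= radius)
      if (!hit) {
        for (s in seq_len(nrow(bones))) {
          if (seg_d(px, py, pts[bones[s, 1], ], pts[bones[s, 2], ]) <= thickness / 2) {
            hit <- TRUE; break
          }
        }
      }
      if (hit) canvas[i, j] <- vmax
    }
  }
  canvas
}

# brute-force classification metrics by pairwise enumeration
report_oracle <- function(truth, pred, classes) {
  k <- length(classes)
  cm <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cm[i, j] <- sum(truth == classes[i] & pred == classes[j])
  }
  per <- data.frame(class = classes, precision = 0, recall = 0, f1 = 0,
                    support = rowSums(cm))
  for (i in seq_len(k)) {
    tp <- cm[i, i]; fp <- sum(cm[, i]) - tp; fn <- sum(cm[i, ]) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    per$precision[i] <- p; per$recall[i] <- r
    per$f1[i] <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  list(per_class = per, accuracy = sum(diag(cm)) / sum(cm))
}

# small in-memory gesture dataset already at the classifier's input raster
small_gesture_dataset <- function(n_classes = 6, per_class = 10, seed = 11) {
  ds <- gen_gesture_dataset(fixture_spec(seed = seed, n_classes = n_classes,
                                         samples_per_class = per_class,
                                         size = c(100, 100)))
  ds$images <- lapply(ds$images, resize_area, size = c(50, 50))
  ds
}
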