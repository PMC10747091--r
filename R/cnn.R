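#' @name gesture_net
#' @title Small convolutional network for 50 x 50 static-gesture images
#'
#' @description
#' Fixed architecture over 50 x 50 x 1 inputs:
#' conv 16 filters 2 x 2 (same padding) -> max-pool 2 x 2 / stride 2
#' (25 x 25 x 16) -> conv 32 filters 3 x 3 -> max-pool 3 x 3 / stride 3
#' (8 x 8 x 32) -> conv 64 filters 5 x 5 -> max-pool 8 x 8 / stride 8
#' (1 x 1 x 64) -> fully connected 128 (ReLU) -> fully connected `n_classes`
#' with SoftMax. With 29 classes this is 68,045 trainable parameters
#' (80 + 4,640 + 51,264 convolutional; 8,320 + 3,741 fully connected).
#' The shape chain and parameter count are asserted at construction.
#'
#' Forward, backward and Adam training are implemented in vectorized R:
#' convolutions are computed as sums over kernel offsets of sliced-input
#' matrix products, with mini-batches stacked vertically so every product is
#' a single BLAS call. All randomness (initialization, shuffling) is seeded.
NULL

# geometry of one stride-1 "same" convolution: index vectors into the
# zero-padded plane for each kernel offset, plus the interior (unpadded)
# indices. TF-style asymmetric padding for even kernels (pad end only).
conv_geom <- function(H, W, k) {
  pad_beg <- (k - 1L) %/% 2L
  pad_end <- k - 1L - pad_beg
  Hp <- H + pad_beg + pad_end
  Wp <- W + pad_beg + pad_end
  idx <- vector("list", k * k)
  m <- 0L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    m <- m + 1L
    idx[[m]] <- as.vector(outer(dy + seq_len(H), (dx + seq_len(W) - 1L) * Hp, "+"))
  }
  int_idx <- as.vector(outer(pad_beg + seq_len(H), (pad_beg + seq_len(W) - 1L) * Hp, "+"))
  list(H = H, W = W, k = k, Hp = Hp, Wp = Wp, idx = idx, int_idx = int_idx)
}

# geometry of a k x k / stride k max-pool (valid: trailing remainder dropped)
pool_geom <- function(H, W, k) {
  Ho <- H %/% k; Wo <- W %/% k
  cell <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * H, "+"))  # offsets within plane
  base <- as.vector(outer(k * (seq_len(Ho) - 1L) + 1L,
                          (k * (seq_len(Wo) - 1L)) * H, "+"))
  PIDX <- outer(base, cell, "+")  # (Ho*Wo) x k^2 linear indices into H x W plane
  list(H = H, W = W, k = k, Ho = Ho, Wo = Wo, PIDX = PIDX)
}

# replicate single-image index structures across a batch (image-major rows)
batch_rows <- function(idx, plane, B) {
  rep(idx, times = B) + rep((0:(B - 1L)) * plane, each = length(idx))
}
batch_pool <- function(PIDX, plane, B) {
  PIDX[rep(seq_len(nrow(PIDX)), times = B), , drop = FALSE] +
    rep((0:(B - 1L)) * plane, each = nrow(PIDX))
}

net_architecture <- function(input = c(50L, 50L), n_classes = 29L) {
  g1 <- conv_geom(input[1L], input[2L], 2L)
  p1 <- pool_geom(input[1L], input[2L], 2L)
  g2 <- conv_geom(p1$Ho, p1$Wo, 3L)
  p2 <- pool_geom(p1$Ho, p1$Wo, 3L)
  g3 <- conv_geom(p2$Ho, p2$Wo, 5L)
  p3 <- pool_geom(p2$Ho, p2$Wo, 8L)
  list(g1 = g1, p1 = p1, g2 = g2, p2 = p2, g3 = g3, p3 = p3,
       channels = c(1L, 16L, 32L, 64L),
       fc1 = 128L, n_classes = as.integer(n_classes),
       flat = p3$Ho * p3$Wo * 64L)
}

#' Build the gesture-classification network
#'
#' Constructs the fixed convolutional architecture described in
#' [gesture_net], verifying the intermediate shape chain
#' (50 -> 25 x 25 x 16 -> 8 x 8 x 32 -> 1 x 1 x 64) and, for 29 classes,
#' the 68,045-parameter total.
#'
#' @param n_classes Number of output classes (>= 2). Default 29.
#' @param classes Optional class labels, length `n_classes`; defaults to the
#'   29 sign-alphabet labels when `n_classes` <= 29.
#' @param seed Seed for He-normal weight initialization. Default 7.
#' @param init `"he"` (default) or `"zero"` (all weights and biases zero;
#'   yields uniform output probabilities).
#' @return An object of class `gesture_net`.
#' @examples
#' net <- build_network()
#' count_parameters(net)  # 68045
#' @export
build_network <- function(n_classes = 29, classes = NULL, seed = 7,
                          init = c("he", "zero")) {
  init <- match.arg(init)
  if (n_classes < 2) stop("`n_classes` must be >= 2", call. = FALSE)
  n_classes <- as.integer(n_classes)
  if (is.null(classes)) {
    classes <- if (n_classes <= 29L) gesture_classes(n_classes) else
      sprintf("class_%02d", seq_len(n_classes))
  }
  if (length(classes) != n_classes) stop("`classes` must have length `n_classes`", call. = FALSE)
  arch <- net_architecture(n_classes = n_classes)
  stopifnot(arch$p1$Ho == 25L, arch$p1$Wo == 25L,
            arch$p2$Ho == 8L, arch$p2$Wo == 8L,
            arch$p3$Ho == 1L, arch$p3$Wo == 1L, arch$flat == 64L)
  ch <- arch$channels
  shapes <- list(
    W1 = c(2L, 2L, ch[1L], ch[2L]), b1 = ch[2L],
    W2 = c(3L, 3L, ch[2L], ch[3L]), b2 = ch[3L],
    W3 = c(5L, 5L, ch[3L], ch[4L]), b3 = ch[4L],
    Wf1 = c(arch$flat, arch$fc1), bf1 = arch$fc1,
    Wf2 = c(arch$fc1, n_classes), bf2 = n_classes)
  params <- with_seed(seed, {
    lapply(shapes, function(s) {
      n <- prod(s)
      if (init == "zero") return(array(0, s))
      fan_in <- if (length(s) == 4L) prod(s[1:3]) else if (length(s) == 2L) s[1L] else NA
      if (is.na(fan_in)) array(0, s)  # biases start at zero
      else array(stats::rnorm(n, 0, sqrt(2 / fan_in)), s)
    })
  })
  net <- structure(list(arch = arch, params = params, classes = classes,
                        n_classes = n_classes, idx_cache = new.env(parent = emptyenv())),
                   class = "gesture_net")
  stopifnot(count_parameters(net) ==
              sum(vapply(shapes, prod, numeric(1))))
  if (n_classes == 29L) stopifnot(count_parameters(net) == 68045L)
  net
}

#' Trainable-parameter bookkeeping
#'
#' @param net A `gesture_net`.
#' @return `count_parameters()`: total number of trainable scalars.
#'   `layer_parameter_counts()`: named vector of per-layer counts
#'   (weights + biases per layer).
#' @examples
#' layer_parameter_counts(build_network())
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "gesture_net"))
  sum(vapply(net$params, length, numeric(1)))
}

#' @rdname count_parameters
#' @export
layer_parameter_counts <- function(net) {
  stopifnot(inherits(net, "gesture_net"))
  p <- net$params
  c(conv1 = length(p$W1) + length(p$b1),
    conv2 = length(p$W2) + length(p$b2),
    conv3 = length(p$W3) + length(p$b3),
    fc1 = length(p$Wf1) + length(p$bf1),
    fc2 = length(p$Wf2) + length(p$bf2))
}

#' @export
print.gesture_net <- function(x, ...) {
  cat(sprintf("gesture_net: 50x50x1 -> 25x25x16 -> 8x8x32 -> 1x1x64 -> 128 -> %d\n",
              x$n_classes))
  cat(sprintf("  trainable parameters: %d\n", count_parameters(x)))
  invisible(x)
}

# cached batch-replicated index structures for batch size B
net_indices <- function(net, B) {
  key <- paste0("B", B)
  cache <- net$idx_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  a <- net$arch
  ix <- list(
    c1 = lapply(a$g1$idx, batch_rows, plane = a$g1$Hp * a$g1$Wp, B = B),
    c1int = batch_rows(a$g1$int_idx, a$g1$Hp * a$g1$Wp, B),
    p1 = batch_pool(a$p1$PIDX, a$p1$H * a$p1$W, B),
    c2 = lapply(a$g2$idx, batch_rows, plane = a$g2$Hp * a$g2$Wp, B = B),
    c2int = batch_rows(a$g2$int_idx, a$g2$Hp * a$g2$Wp, B),
    p2 = batch_pool(a$p2$PIDX, a$p2$H * a$p2$W, B),
    c3 = lapply(a$g3$idx, batch_rows, plane = a$g3$Hp * a$g3$Wp, B = B),
    c3int = batch_rows(a$g3$int_idx, a$g3$Hp * a$g3$Wp, B),
    p3 = batch_pool(a$p3$PIDX, a$p3$H * a$p3$W, B))
  cache[[key]] <- ix
  ix
}

weight_slices <- function(W) {
  k <- dim(W)[1L]; Cin <- dim(W)[3L]; Cout <- dim(W)[4L]
  out <- vector("list", k * k)
  m <- 0L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    m <- m + 1L
    out[[m]] <- matrix(W[dy + 1L, dx + 1L, , ], Cin, Cout)
  }
  out
}

conv_forward <- function(X, g, fidx, int_idx, Wm, b, B) {
  Cin <- ncol(X)
  Xpad <- matrix(0, g$Hp * g$Wp * B, Cin)
  Xpad[int_idx, ] <- X
  n <- g$H * g$W * B
  Y <- matrix(0, n, length(b))
  Xs <- vector("list", length(fidx))
  for (m in seq_along(fidx)) {
    Xs[[m]] <- Xpad[fidx[[m]], , drop = FALSE]
    Y <- Y + Xs[[m]] %*% Wm[[m]]
  }
  Y <- Y + rep(b, each = n)
  list(Y = Y, Xs = Xs)
}

conv_backward <- function(dY, g, fidx, int_idx, Wm, Xs, B, Cin, need_dx = TRUE) {
  k2 <- length(fidx)
  dWm <- vector("list", k2)
  dXpad <- if (need_dx) matrix(0, g$Hp * g$Wp * B, Cin) else NULL
  for (m in seq_len(k2)) {
    dWm[[m]] <- crossprod(Xs[[m]], dY)
    if (need_dx) {
      ii <- fidx[[m]]
      dXpad[ii, ] <- dXpad[ii, , drop = FALSE] + dY %*% t(Wm[[m]])
    }
  }
  list(dWm = dWm, db = colSums(dY),
       dX = if (need_dx) dXpad[int_idx, , drop = FALSE] else NULL)
}

pool_forward <- function(X, PIDXB) {
  n <- nrow(PIDXB); C <- ncol(X)
  out <- matrix(0, n, C)
  aidx <- matrix(0L, n, C)
  sel <- cbind(seq_len(n), 0L)
  for (c in seq_len(C)) {
    xc <- X[, c]
    M <- xc[PIDXB]; dim(M) <- dim(PIDXB)
    j <- max.col(M, ties.method = "first")
    sel[, 2L] <- j
    out[, c] <- M[sel[, 1L] + (j - 1L) * n]
    aidx[, c] <- PIDXB[sel[, 1L] + (j - 1L) * n]
  }
  list(Y = out, aidx = aidx)
}

pool_backward <- function(dY, aidx, in_rows) {
  C <- ncol(dY)
  dX <- matrix(0, in_rows, C)
  for (c in seq_len(C)) dX[aidx[, c], c] <- dY[, c]
  dX
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# full forward pass on a batch; X is (2500*B) x 1, inputs scaled to [0, 1]
net_forward <- function(net, X, B, training = FALSE) {
  a <- net$arch; p <- net$params
  ix <- net_indices(net, B)
  W1m <- weight_slices(p$W1); W2m <- weight_slices(p$W2); W3m <- weight_slices(p$W3)
  c1 <- conv_forward(X, a$g1, ix$c1, ix$c1int, W1m, p$b1, B)
  A1 <- c1$Y * (c1$Y > 0)
  q1 <- pool_forward(A1, ix$p1)
  c2 <- conv_forward(q1$Y, a$g2, ix$c2, ix$c2int, W2m, p$b2, B)
  A2 <- c2$Y * (c2$Y > 0)
  q2 <- pool_forward(A2, ix$p2)
  c3 <- conv_forward(q2$Y, a$g3, ix$c3, ix$c3int, W3m, p$b3, B)
  A3 <- c3$Y * (c3$Y > 0)
  q3 <- pool_forward(A3, ix$p3)
  FL <- q3$Y  # B x 64 (1 x 1 spatial)
  Z1 <- FL %*% p$Wf1 + rep(p$bf1, each = B)
  H1 <- Z1 * (Z1 > 0)
  Z2 <- H1 %*% p$Wf2 + rep(p$bf2, each = B)
  P <- softmax_rows(Z2)
  if (!training) return(list(P = P))
  list(P = P, c1 = c1, c2 = c2, c3 = c3, q1 = q1, q2 = q2, q3 = q3,
       A1m = c1$Y > 0, A2m = c2$Y > 0, A3m = c3$Y > 0,
       FL = FL, H1 = H1, Z1m = Z1 > 0,
       W1m = W1m, W2m = W2m, W3m = W3m)
}

# gradients of mean cross-entropy; y integer labels in 1..n_classes
net_backward <- function(net, fwd, y, B) {
  a <- net$arch; p <- net$params
  ix <- net_indices(net, B)
  dZ2 <- fwd$P
  dZ2[cbind(seq_len(B), y)] <- dZ2[cbind(seq_len(B), y)] - 1
  dZ2 <- dZ2 / B
  g <- list()
  g$Wf2 <- crossprod(fwd$H1, dZ2); g$bf2 <- colSums(dZ2)
  dH1 <- (dZ2 %*% t(p$Wf2)) * fwd$Z1m
  g$Wf1 <- crossprod(fwd$FL, dH1); g$bf1 <- colSums(dH1)
  dFL <- dH1 %*% t(p$Wf1)
  dA3 <- pool_backward(dFL, fwd$q3$aidx, nrow(fwd$c3$Y))
  dY3 <- dA3 * fwd$A3m
  b3 <- conv_backward(dY3, a$g3, ix$c3, ix$c3int, fwd$W3m, fwd$c3$Xs, B,
                      Cin = a$channels[3L])
  g$W3 <- b3$dWm; g$b3 <- b3$db
  dA2 <- pool_backward(b3$dX, fwd$q2$aidx, nrow(fwd$c2$Y))
  dY2 <- dA2 * fwd$A2m
  b2 <- conv_backward(dY2, a$g2, ix$c2, ix$c2int, fwd$W2m, fwd$c2$Xs, B,
                      Cin = a$channels[2L])
  g$W2 <- b2$dWm; g$b2 <- b2$db
  dA1 <- pool_backward(b2$dX, fwd$q1$aidx, nrow(fwd$c1$Y))
  dY1 <- dA1 * fwd$A1m
  b1 <- conv_backward(dY1, a$g1, ix$c1, ix$c1int, fwd$W1m, fwd$c1$Xs, B,
                      Cin = a$channels[1L], need_dx = FALSE)
  g$W1 <- b1$dWm; g$b1 <- b1$db
  g
}

# fold per-offset weight-gradient slices back into a (k,k,Cin,Cout) array
fold_dW <- function(dWm, shape) {
  dW <- array(0, shape)
  k <- shape[1L]
  m <- 0L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    m <- m + 1L
    dW[dy + 1L, dx + 1L, , ] <- dWm[[m]]
  }
  dW
}

#' Training configuration
#'
#' Hyperparameters of the training harness. The architecture itself is
#' fixed; these defaults (Adam, learning rate 1e-3, batch 32, 20 epochs) are
#' conventional choices for a network of this size.
#'
#' @param epochs Number of passes over the training set (>= 1). Default 20.
#' @param batch_size Mini-batch size. Default 32.
#' @param lr Adam learning rate. Default 1e-3.
#' @param optimizer Only `"adam"` is implemented.
#' @param seed Seed controlling epoch shuffles. Default 7.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 20, batch_size = 32, lr = 1e-3,
                         optimizer = "adam", seed = 7) {
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (!identical(optimizer, "adam")) stop("only the 'adam' optimizer is implemented", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, optimizer = optimizer, seed = as.integer(seed)),
            class = "train_config")
}

dataset_tensors <- function(ds, classes, vmax = 255) {
  bad <- setdiff(unique(ds$labels), classes)
  if (length(bad) > 0) {
    stop(sprintf("labels outside the model's class set: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  list(x = lapply(ds$images, function(img) as.numeric(img) / vmax),
       y = match(ds$labels, classes))
}

#' Train the gesture network
#'
#' Mini-batch Adam on the mean cross-entropy, deterministic for a fixed
#' configuration seed (initialization is fixed at [build_network()] time;
#' epoch shuffles derive from `cfg$seed`). Inputs are scaled from
#' `[0, vmax]` to `[0, 1]`.
#'
#' @param net A `gesture_net`.
#' @param dataset A `gesture_dataset` with labels inside the net's class set.
#' @param cfg A [train_config()].
#' @param validation Optional held-out `gesture_dataset`; its accuracy is
#'   recorded per epoch.
#' @param vmax Input intensity scale. Default 255.
#' @param verbose Print a line per epoch. Default `FALSE`.
#' @return The trained `gesture_net`, with a `history` data.frame attribute
#'   (`epoch`, `loss`, `val_accuracy`).
#' @export
train_network <- function(net, dataset, cfg = train_config(), validation = NULL,
                          vmax = 255, verbose = FALSE) {
  stopifnot(inherits(net, "gesture_net"), inherits(dataset, "gesture_dataset"),
            inherits(cfg, "train_config"))
  if (length(dataset$images) == 0L) stop("`dataset` is empty", call. = FALSE)
  tens <- dataset_tensors(dataset, net$classes, vmax)
  N <- length(tens$x)
  # Adam state
  mstate <- lapply(net$params, function(p) array(0, dim(p) %||% length(p)))
  vstate <- lapply(net$params, function(p) array(0, dim(p) %||% length(p)))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  tstep <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0), val_accuracy = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed * 1000L + epoch, sample.int(N))
    epoch_loss <- 0; seen <- 0L
    for (start in seq(1L, N, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, N)]
      B <- length(idx)
      X <- matrix(unlist(tens$x[idx], use.names = FALSE), ncol = 1L)
      y <- tens$y[idx]
      fwd <- net_forward(net, X, B, training = TRUE)
      pj <- fwd$P[cbind(seq_len(B), y)]
      epoch_loss <- epoch_loss - sum(log(pmax(pj, 1e-12)))
      seen <- seen + B
      g <- net_backward(net, fwd, y, B)
      grads <- list(W1 = fold_dW(g$W1, dim(net$params$W1)), b1 = g$b1,
                    W2 = fold_dW(g$W2, dim(net$params$W2)), b2 = g$b2,
                    W3 = fold_dW(g$W3, dim(net$params$W3)), b3 = g$b3,
                    Wf1 = g$Wf1, bf1 = g$bf1, Wf2 = g$Wf2, bf2 = g$bf2)
      tstep <- tstep + 1L
      for (nm in names(net$params)) {
        gr <- grads[[nm]]
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * gr
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * gr * gr
        mhat <- mstate[[nm]] / (1 - beta1^tstep)
        vhat <- vstate[[nm]] / (1 - beta2^tstep)
        net$params[[nm]] <- net$params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_acc <- NA_real_
    if (!is.null(validation)) {
      pred <- predict_dataset(net, validation, vmax = vmax)
      val_acc <- mean(pred == validation$labels)
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss / seen,
                                         val_accuracy = val_acc))
    if (verbose) {
      cat(sprintf("epoch %2d  loss %.4f  val_acc %s\n", epoch, epoch_loss / seen,
                  ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
  }
  attr(net, "history") <- history
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify one 50 x 50 grayscale image
#'
#' @param object A `gesture_net`.
#' @param image Numeric 50 x 50 matrix on `[0, vmax]`.
#' @param vmax Input intensity scale. Default 255.
#' @param ... Unused.
#' @return List with `label` (argmax class; ties resolved to the lowest
#'   class index) and `prob` (named probability vector summing to 1).
#' @export
predict.gesture_net <- function(object, image, vmax = 255, ...) {
  if (!is.matrix(image) || !all(dim(image) == c(object$arch$g1$H, object$arch$g1$W))) {
    stop(sprintf("`image` must be a %d x %d matrix",
                 object$arch$g1$H, object$arch$g1$W), call. = FALSE)
  }
  X <- matrix(as.numeric(image) / vmax, ncol = 1L)
  P <- net_forward(object, X, 1L)$P[1L, ]
  names(P) <- object$classes
  list(label = object$classes[which.max(P)], prob = P)
}

#' Predict labels for every image of a dataset
#'
#' @param net A `gesture_net`.
#' @param ds A `gesture_dataset`.
#' @param batch_size Images per forward batch. Default 64.
#' @param vmax Input intensity scale. Default 255.
#' @return Character vector of predicted labels.
#' @export
predict_dataset <- function(net, ds, batch_size = 64, vmax = 255) {
  stopifnot(inherits(net, "gesture_net"), inherits(ds, "gesture_dataset"))
  N <- length(ds$images)
  out <- character(N)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    B <- length(idx)
    X <- matrix(unlist(lapply(ds$images[idx], function(m) as.numeric(m) / vmax),
                       use.names = FALSE), ncol = 1L)
    P <- net_forward(net, X, B)$P
    out[idx] <- net$classes[max.col(P, ties.method = "first")]
  }
  out
}

#' Save / load network weights
#'
#' Checkpoints are the package's native serialized parameter list (weights,
#' classes, training history), written with R's serialization.
#'
#' @param net A `gesture_net`.
#' @param path Checkpoint file path.
#' @return `save_network()`: `path` invisibly; `load_network()`: the network.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "gesture_net"))
  obj <- list(params = net$params, classes = net$classes,
              n_classes = net$n_classes, history = attr(net, "history"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  net <- build_network(n_classes = obj$n_classes, classes = obj$classes,
                       init = "zero")
  net$params <- obj$params
  attr(net, "history") <- obj$history
  net
}
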