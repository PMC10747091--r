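test_that("network construction reproduces the printed shape chain and counts", {
  net <- build_network(n_classes = 29)
  expect_equal(count_parameters(net), 68045)
  expect_equal(layer_parameter_counts(net),
               c(conv1 = 80, conv2 = 4640, conv3 = 51264, fc1 = 8320, fc2 = 3741))
  a <- net$arch
  expect_equal(c(a$p1$Ho, a$p1$Wo), c(25L, 25L))
  expect_equal(c(a$p2$Ho, a$p2$Wo), c(8L, 8L))
  expect_equal(c(a$p3$Ho, a$p3$Wo), c(1L, 1L))
  expect_equal(a$flat, 64L)
})

test_that("forward pass yields a probability vector; zero weights are uniform", {
  net <- build_network(seed = 3)
  img <- matrix(runif(2500, 0, 255), 50, 50)
  res <- predict(net, img)
  expect_equal(sum(res$prob), 1, tolerance = 1e-6)
  expect_true(all(res$prob >= 0))
  expect_equal(res$label, names(which.max(res$prob)))
  zero <- build_network(init = "zero")
  expect_equal(unname(predict(zero, img)$prob), rep(1 / 29, 29))
  expect_error(predict(net, matrix(0, 40, 40)), "50 x 50")
})

test_that("training is deterministic and reduces the loss on separable data", {
  ds <- small_gesture_dataset(n_classes = 4, per_class = 8, seed = 5)
  cfg <- train_config(epochs = 3, batch_size = 16, seed = 9)
  net1 <- train_network(build_network(n_classes = 4, classes = ds$classes, seed = 9),
                        ds, cfg)
  net2 <- train_network(build_network(n_classes = 4, classes = ds$classes, seed = 9),
                        ds, cfg)
  h1 <- attr(net1, "history"); h2 <- attr(net2, "history")
  expect_identical(h1$loss, h2$loss)  # same seed, same trajectory
  expect_lt(h1$loss[3], h1$loss[1])  # cross-entropy decreases
  # a training exemplar is recalled after fitting
  ex <- ds$images[[1]]
  expect_equal(predict(net1, ex)$label, ds$labels[1])
})

test_that("one-sample one-epoch training records a finite loss", {
  ds <- small_gesture_dataset(n_classes = 2, per_class = 1, seed = 2)
  net <- train_network(build_network(n_classes = 2, classes = ds$classes, seed = 1),
                       ds, train_config(epochs = 1, batch_size = 1, seed = 1))
  h <- attr(net, "history")
  expect_equal(nrow(h), 1L)
  expect_true(is.finite(h$loss))
})

test_that("labels outside the class set are rejected", {
  ds <- small_gesture_dataset(n_classes = 3, per_class = 2)
  net <- build_network(n_classes = 2, classes = ds$classes[1:2])
  expect_error(train_network(net, ds, train_config(epochs = 1)), "outside")
})

test_that("a moderately sized separable fixture is learned to high accuracy", {
  ds <- small_gesture_dataset(n_classes = 8, per_class = 20, seed = 17)
  sp <- split_dataset(ds, 0.25, seed = 17)
  net <- build_network(n_classes = 8, classes = ds$classes, seed = 17)
  net <- train_network(net, sp$train, train_config(epochs = 8, seed = 17))
  acc <- mean(predict_dataset(net, sp$test) == sp$test$labels)
  expect_gte(acc, 0.95)
})

test_that("checkpoints round-trip through save/load", {
  ds <- small_gesture_dataset(n_classes = 2, per_class = 3, seed = 8)
  net <- train_network(build_network(n_classes = 2, classes = ds$classes, seed = 8),
                       ds, train_config(epochs = 1, seed = 8))
  path <- file.path(tempdir(), "net.ckpt")
  save_network(net, path)
  back <- load_network(path)
  img <- ds$images[[1]]
  expect_equal(predict(back, img)$prob, predict(net, img)$prob)
})
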