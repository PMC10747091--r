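test_that("frequency response matches the closed form at key frequencies", {
  # DC gain 1/(1+beta)
  expect_equal(Re(opl_frequency_response(c(8, 8), photoreceptor_params())[1, 1]), 1)
  expect_equal(Re(opl_frequency_response(c(8, 8), photoreceptor_params(beta_ph = 1))[1, 1]), 0.5)
  # 1-D Nyquist slice (fx = 0.5, fy = 0): 1 / (1 + 2*1*(1 - cos(pi))) = 0.2
  H <- opl_frequency_response(c(16, 16), photoreceptor_params(beta_ph = 0, alpha_ph = 1))
  expect_equal(Re(H[1, 9]), 0.2)
  expect_equal(Im(H[1, 9]), 0)
})

test_that("response is a Hermitian low-pass with maximum gain at DC", {
  p <- photoreceptor_params(beta_ph = 0.5, alpha_ph = 2)
  H <- opl_frequency_response(c(12, 16), p)
  g <- Mod(H)
  expect_true(all(g <= 1 / (1 + p$beta_ph) + 1e-12))
  expect_equal(g[1, 1], 1 / (1 + p$beta_ph))
  # Hermitian symmetry at ft = 0: H(-f) = Conj(H(f))
  h <- nrow(H); w <- ncol(H)
  neg <- function(k, n) ((n - (k - 1)) %% n) + 1
  for (i in 1:h) for (j in 1:w) {
    expect_equal(H[neg(i, h), neg(j, w)], Conj(H[i, j]))
  }
  # monotone non-increasing along the fx and fy axes up to Nyquist
  expect_true(all(diff(g[1, 1:(w %/% 2 + 1)]) <= 1e-12))
  expect_true(all(diff(g[1:(h %/% 2 + 1), 1]) <= 1e-12))
})

test_that("filter application equals circular spatial convolution (oracle)", {
  set.seed(42)
  for (rep in 1:12) {
    h <- sample(4:32, 1); w <- sample(4:32, 1)
    p <- photoreceptor_params(beta_ph = runif(1, 0, 2), alpha_ph = runif(1, 0, 3))
    img <- matrix(runif(h * w, 0, 255), h, w)
    H <- opl_frequency_response(c(h, w), p)
    kernel <- Re(stats::fft(H, inverse = TRUE)) / (h * w)
    expect_lt(max(abs(apply_photoreceptor_filter(img, p) -
                      circ_conv_oracle(img, kernel))), 1e-8)
  }
})

test_that("filtering is linear and preserves the scaled mean", {
  set.seed(5)
  p <- photoreceptor_params(beta_ph = 0.3, alpha_ph = 1.5)
  a <- matrix(runif(64, 0, 255), 8, 8)
  b <- matrix(runif(64, 0, 255), 8, 8)
  lin <- apply_photoreceptor_filter(2 * a - 3 * b, p)
  sep <- 2 * apply_photoreceptor_filter(a, p) - 3 * apply_photoreceptor_filter(b, p)
  expect_lt(max(abs(lin - sep)), 1e-8)
  expect_equal(mean(apply_photoreceptor_filter(a, p)), mean(a) / (1 + p$beta_ph))
})

test_that("uniform images and impulses behave like the DC/impulse analysis", {
  u <- matrix(120, 10, 10)
  expect_equal(apply_photoreceptor_filter(u, photoreceptor_params()), u)
  imp <- matrix(0, 16, 16); imp[8, 8] <- 1
  for (beta in c(0, 1)) {
    out <- apply_photoreceptor_filter(imp, photoreceptor_params(beta_ph = beta))
    expect_equal(sum(out), 1 / (1 + beta))
  }
})

test_that("temporal recursion smooths with unity DC gain", {
  x <- matrix(runif(16, 0, 255), 4, 4)
  expect_equal(temporal_filter_step(x, x * 0, photoreceptor_params(tau_ph = 0)), x)
  # one step from zero state with tau = 1 halves the input
  expect_equal(temporal_filter_step(matrix(100, 3, 3), matrix(0, 3, 3),
                                    photoreceptor_params(tau_ph = 1)),
               matrix(50, 3, 3))
  # constant input converges to the constant; exact after initialization at c
  y <- NULL
  for (t in 1:30) y <- temporal_filter_step(matrix(80, 2, 2), y, photoreceptor_params(tau_ph = 2))
  expect_equal(y, matrix(80, 2, 2), tolerance = 1e-3)
  expect_equal(temporal_filter_step(matrix(80, 2, 2), matrix(80, 2, 2),
                                    photoreceptor_params(tau_ph = 5)),
               matrix(80, 2, 2))
  expect_error(temporal_filter_step(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("invalid parameters and empty images are rejected", {
  expect_error(photoreceptor_params(beta_ph = -1), "non-negative")
  expect_error(photoreceptor_params(alpha_ph = Inf), "finite")
  expect_error(apply_photoreceptor_filter(matrix(NA_real_, 2, 2)), "non-finite")
  expect_error(opl_frequency_response(c(0, 4), photoreceptor_params()), "positive")
})
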