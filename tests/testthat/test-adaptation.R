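test_that("compression parameter follows its affine form and endpoints", {
  L <- matrix(c(0, 50, 100, 255), 2, 2)
  expect_equal(compression_parameter(L, adaptation_params(v0 = 0)),
               matrix(255, 2, 2))
  expect_equal(compression_parameter(L, adaptation_params(v0 = 1)), L)
  expect_equal(compression_parameter(matrix(100, 1, 1), adaptation_params())[1, 1],
               0.7 * 100 + 255 * 0.3)  # 146.5
  # range bound for in-range luminance: vmax(1 - v0) <= R0 <= vmax
  for (v0 in c(0.2, 0.7, 1)) {
    R0 <- compression_parameter(L, adaptation_params(v0 = v0))
    expect_true(all(R0 >= 255 * (1 - v0) - 1e-12) && all(R0 <= 255 + 1e-12))
  }
  expect_error(adaptation_params(v0 = 1.2), "\\[0, 1\\]")
})

test_that("adapted response amplifies dark pixels and fixes bright ones", {
  ad <- adaptation_params()
  expect_equal(adapt_response(matrix(0, 2, 2), matrix(100, 2, 2), ad), matrix(0, 2, 2))
  # uniform bright scene: R = R0 = vmax is a fixed point
  expect_equal(adapt_response(matrix(255, 2, 2), matrix(255, 2, 2), ad), matrix(255, 2, 2))
  expect_equal(adapt_response(matrix(50, 1, 1), matrix(146.5, 1, 1), ad)[1, 1],
               50 * (255 + 146.5) / (50 + 146.5))  # ~102.16, dark pixel ~doubled
  # degenerate pixel R + R0 = 0 maps to 0
  expect_equal(adapt_response(matrix(0, 1, 1), matrix(0, 1, 1), ad)[1, 1], 0)
  expect_error(adapt_response(matrix(-1, 1, 1), matrix(10, 1, 1), ad), "non-negative")
})

test_that("response is bounded, monotone in R, and dominates the identity", {
  ad <- adaptation_params()
  R <- seq(0, 255, by = 5)
  for (R0v in c(76.5, 146.5, 255)) {
    C <- adapt_response(matrix(R, 1), matrix(R0v, 1, length(R)), ad)
    expect_true(all(C >= 0 & C <= 255))
    expect_true(all(diff(as.numeric(C)) > 0))  # strictly increasing, no inversion
    expect_true(all(C >= matrix(R, 1) - 1e-9))  # C >= R whenever R0 <= vmax
  }
})

test_that("response curves shift upward with v0 under a dark surround", {
  # Fig-5-style family: for L < vmax, larger v0 lowers R0 and lifts C
  for (L in c(20, 80, 150)) {
    c_lo <- response_curve(adaptation_params(v0 = 0.3), L_level = L)
    c_hi <- response_curve(adaptation_params(v0 = 0.7), L_level = L)
    inner <- c_lo$R < 255
    expect_true(all(c_hi$C[inner] >= c_lo$C[inner] - 1e-9))
    expect_true(all(diff(c_hi$C[-1]) > 0))
  }
})

test_that("enhance balances dark-biased scenes and preserves uniform ones", {
  # spatially constant input stays spatially constant
  u <- matrix(128, 16, 16)
  out <- enhance(u)
  expect_lt(max(out) - min(out), 1e-9)
  # all-vmax image is a fixed point
  expect_equal(enhance(matrix(255, 8, 8)), matrix(255, 8, 8))
  # dark-biased scene: mean and entropy strictly increase
  sc <- gen_dark_scene(fixture_spec(seed = 21, size = c(120, 120), dark_bias = 0.9))
  en <- enhance(sc)
  expect_gt(mean(en), mean(sc))
  expect_gte(shannon_entropy(en), shannon_entropy(sc))
  expect_true(all(en >= 0 & en <= 255))
  # enhancement is deliberately not idempotent: enhancing again brightens more
  g <- luminance(sc)
  once <- enhance(g); twice <- enhance(once)
  expect_gt(mean(twice), mean(once))
})

test_that("RGB enhancement shares one adaptation map across channels", {
  sc <- gen_dark_scene(fixture_spec(seed = 3, size = c(40, 40)))
  en <- enhance(sc)
  expect_equal(dim(en), dim(sc))
  # channel ordering is preserved where the input channels are ordered
  brighter <- sc[, , 3] > sc[, , 1]
  expect_true(all(en[, , 3][brighter] >= en[, , 1][brighter] - 1e-9))
})
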