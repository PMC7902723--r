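test_that("pH grid and response validation enforce the invariants", {
  expect_s3_class(ph_grid(), "ph_grid")
  expect_length(ph_grid(), 9)
  expect_error(ph_grid(c(5.1)), "at least 2")
  expect_error(ph_grid(c(5.4, 5.1)), "increasing")
  expect_error(ph_grid(c(-1, 7)), "within")
  g <- ph_grid(c(5.1, 5.4))
  expect_error(ph_response(g, r = c(-0.1, 0.2), K = c(0.1, 0.1)), ">= 0")
  expect_error(ph_response(g, r = c(0.1, 0.2), K = c(0, 0.1)), "> 0")
  expect_error(ph_response(g, r = c(0.1), K = c(0.1, 0.1)), "per pH grid")
})

test_that("interp_response is exact at nodes, linear between, clamped outside", {
  resp <- ph_response(ph_grid(c(5.1, 5.4)), r = c(0.2, 0.4), K = c(0.1, 0.3))
  expect_equal(interp_response(resp, 5.25)$rate, 0.3)
  expect_equal(interp_response(resp, 5.1)$rate, 0.2)
  expect_equal(interp_response(resp, 5.4)$capacity, 0.3)
  # clamping rule below/above the grid
  expect_equal(interp_response(resp, 4.8)$rate, 0.2)
  expect_equal(interp_response(resp, 9)$rate, 0.4)
  expect_error(interp_response(resp, NaN), "finite")
  # continuity on a dense sweep (no jumps larger than the local slope allows)
  full <- ph_response(ph_grid(), r = runif(9, 0.1, 1), K = runif(9, 0.1, 1))
  p <- seq(4.5, 8.1, by = 1e-3)
  y <- interp_response(full, p)$rate
  max_slope <- max(abs(diff(full$r))) / 0.3
  expect_lt(max(abs(diff(y))), max_slope * 1e-3 * 1.01)
})

test_that("infer_interaction matches the supernatant formula and errors", {
  expect_equal(infer_interaction(0, 0.2, 0.2), -1)   # self-effect
  expect_equal(infer_interaction(0.2, 0.2, 0.5), 0)  # no effect
  expect_equal(infer_interaction(0.3, 0.2, 0.1), 1)
  expect_error(infer_interaction(0.3, 0.2, 0), "> 0")
  expect_error(infer_interaction(-0.1, 0.2, 0.1), ">= 0")
})

test_that("first-order error propagation matches a Monte-Carlo oracle", {
  # oracle: empirical SD of (K_ij - K_i)/K_j under independent Gaussian
  # measurement noise, tiny relative SDs so the linearization is exact
  set.seed(42)
  K_ij <- 0.35; K_i <- 0.2; K_j <- 0.25
  sds <- c(0.002, 0.003, 0.004)
  draws <- (rnorm(2e5, K_ij, sds[1]) - rnorm(2e5, K_i, sds[2])) /
    rnorm(2e5, K_j, sds[3])
  est <- infer_interaction(K_ij, K_i, K_j, sd_K_ij = sds[1],
                           sd_K_i = sds[2], sd_K_j = sds[3])
  expect_equal(as.numeric(est), (K_ij - K_i) / K_j)
  expect_equal(attr(est, "sd"), sd(draws), tolerance = 0.02)
})

test_that("predict/infer round-trip is the identity to machine precision", {
  expect_equal(predict_supernatant_capacity(0.2, 0, 0.1), 0.2)
  expect_equal(predict_supernatant_capacity(0.2, -1, 0.2), 0)
  expect_equal(predict_supernatant_capacity(0.2, 0.5, 0.1), 0.25)
  set.seed(7)
  for (i in 1:200) {
    K_i <- runif(1, 0.05, 1); K_j <- runif(1, 0.05, 1)
    c_ij <- runif(1, -1.5, 0.3)
    K_ij <- predict_supernatant_capacity(K_i, c_ij, K_j)
    if (K_ij < 0) next  # forward model can leave the assay's domain
    expect_equal(infer_interaction(K_ij, K_i, K_j), c_ij,
                 tolerance = 1e-12)
  }
})

test_that("screen_instability flags exactly strong mutual facilitation", {
  C <- matrix(c(-1, 1.1, 1.2, -1), 2, 2)
  hits <- screen_instability(interaction_matrix(C))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$product, 1.32)
  C2 <- matrix(c(-1, 0.5, 1.2, -1), 2, 2)
  expect_equal(nrow(screen_instability(interaction_matrix(C2))), 0)
  C3 <- matrix(c(-1, 2.0, -0.5, -1), 2, 2)  # one-way only
  expect_equal(nrow(screen_instability(interaction_matrix(C3))), 0)
})

test_that("interaction matrices validate and evaluate pH dependence", {
  expect_error(interaction_matrix(matrix(0, 2, 2)), "diagonal")
  expect_error(interaction_matrix(matrix(-1, 2, 3)), "square")
  C <- matrix(c(-1, -0.2, -0.5, -1), 2, 2)
  m <- matrix(0.2, 2, 2)
  im <- interaction_matrix(C, slopes = m, p0 = 7.2)
  expect_equal(interaction_at_ph(im, 7.2), C)
  eff <- interaction_at_ph(im, 8.2)  # p - p0 = 1
  expect_equal(eff[1, 2], -0.3)
  expect_equal(diag(eff), c(-1, -1))  # diagonal pinned
  im0 <- interaction_matrix(C, slopes = matrix(0, 2, 2))
  expect_equal(interaction_at_ph(im0, 5.5), C)
  # no slopes: returned unchanged at any pH
  expect_equal(interaction_at_ph(interaction_matrix(C), 5.0), C)
})
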