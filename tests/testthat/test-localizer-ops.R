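# Layer operations of the localizer against independent scalar-loop oracles
# and their analytic special cases.

test_that("depthwise-separable conv: identity case and parameter count", {
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  # centered delta depthwise kernels + identity pointwise = identity
  dw <- array(0, c(3, 3, 3)); dw[2, 2, ] <- 1
  pw <- diag(3)
  expect_equal(depthwise_separable_conv(x, dw, pw), x, tolerance = 1e-12)
  # closed-form parameter count: depthwise + pointwise < full convolution
  c_in <- 4; c_out <- 8; k <- 3
  expect_equal(c_in * k^2 + c_in * c_out, 68)
  expect_lt(c_in * k^2 + c_in * c_out, c_in * c_out * k^2)
  # shape error on kernel/channel mismatch
  expect_error(depthwise_separable_conv(x, array(0, c(3, 3, 2)), diag(3)),
               class = "svpnet_contract_error")
})

test_that("depthwise-separable conv matches the nested-loop oracle", {
  set.seed(101)
  for (rep in 1:25) {
    C <- sample(1:4, 1); Cout <- sample(1:4, 1)
    H <- sample(4:8, 1); W <- sample(4:8, 1)
    x <- array(rnorm(H * W * C), c(H, W, C))
    dw <- array(rnorm(9 * C), c(3, 3, C))
    pw <- matrix(rnorm(C * Cout), C, Cout)
    got <- depthwise_separable_conv(x, dw, pw)
    expect_lt(max(abs(got - oracle_dsconv(x, dw, pw))), 1e-6)
  }
})

test_that("attention gate: forced values and saturation", {
  u <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  g <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  zero <- list(W_u = matrix(0, 3, 2), W_g = matrix(0, 2, 2), b_g = c(0, 0),
               psi = c(0, 0), b_psi = 0)
  r <- attention_gate(u, g, zero)
  expect_equal(r$alpha, array(0.5, c(5, 5, 1)))
  expect_equal(r$output, 0.5 * u)
  # large positive psi bias saturates the sigmoid: output ~= u
  sat <- zero; sat$b_psi <- 100
  expect_lt(max(abs(attention_gate(u, g, sat)$output - u)), 1e-6)
})

test_that("attention gate matches the scalar-loop oracle and stays bounded", {
  set.seed(102)
  for (rep in 1:25) {
    Cu <- sample(1:4, 1); Cg <- sample(1:4, 1); Ci <- sample(1:3, 1)
    H <- sample(3:8, 1); W <- sample(3:8, 1)
    u <- array(rnorm(H * W * Cu), c(H, W, Cu))
    g <- array(rnorm(H * W * Cg), c(H, W, Cg))
    par <- list(W_u = matrix(rnorm(Cu * Ci), Cu, Ci),
                W_g = matrix(rnorm(Cg * Ci), Cg, Ci),
                b_g = rnorm(Ci), psi = rnorm(Ci), b_psi = rnorm(1))
    got <- attention_gate(u, g, par)
    want <- oracle_attention(u, g, par$W_u, par$W_g, par$b_g, par$psi, par$b_psi)
    expect_lt(max(abs(got$output - want$output)), 1e-6)
    expect_lt(max(abs(got$alpha[, , 1] - want$alpha)), 1e-6)
    expect_true(all(got$alpha >= 0 & got$alpha <= 1))
    expect_true(all(abs(got$output) <= abs(u) + 1e-12))
  }
})

test_that("attention gate upsamples a coarser gating signal", {
  u <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  g <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  par <- list(W_u = matrix(rnorm(4), 2, 2), W_g = matrix(rnorm(4), 2, 2),
              b_g = rnorm(2), psi = rnorm(2), b_psi = 0)
  expect_identical(dim(attention_gate(u, g, par)$output), dim(u))
  gbad <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  expect_error(attention_gate(u, gbad, par), class = "svpnet_contract_error")
})

test_that("recurrent-residual block: passthrough, t = 0, and unrolled oracle", {
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  zero_par <- list(dw = array(0, c(3, 3, 2)), pw = matrix(0, 2, 2))
  # all conv weights zero, identity residual: output equals x
  expect_equal(recurrent_residual_block(x, zero_par, t = 1), x)

  set.seed(103)
  par <- list(dw = array(rnorm(9 * 2, sd = 0.5), c(3, 3, 2)),
              dw_b = rnorm(2), pw = matrix(rnorm(4, sd = 0.5), 2, 2),
              pw_b = rnorm(2))
  g_fn <- function(z) {
    h <- depthwise_separable_conv(z, par$dw, par$pw, par$dw_b, par$pw_b)
    pmax(h, 0)
  }
  # t = 0 reduces to plain conv + residual
  expect_equal(recurrent_residual_block(x, par, t = 0), x + g_fn(x),
               tolerance = 1e-10)
  # t = 1 equals the hand-unrolled g(x + g(x)) + x
  expect_lt(max(abs(recurrent_residual_block(x, par, t = 1) -
                      (x + g_fn(x + g_fn(x))))), 1e-6)
  # t = 2 equals g(x + g(x + g(x))) + x
  expect_lt(max(abs(recurrent_residual_block(x, par, t = 2) -
                      (x + g_fn(x + g_fn(x + g_fn(x)))))), 1e-6)
})

test_that("recurrent-residual block projects when channel widths change", {
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  par <- list(dw = array(rnorm(9 * 3, sd = 0.3), c(3, 3, 3)),
              pw = matrix(rnorm(9, sd = 0.3), 3, 3),
              proj = list(w = matrix(rnorm(6, sd = 0.3), 2, 3), b = rnorm(3)))
  out <- recurrent_residual_block(x, par, t = 1)
  expect_identical(dim(out), c(4L, 4L, 3L))
})

test_that("dice loss: analytic examples, symmetry, bounds", {
  m <- random_mask(8, 8)
  expect_lt(dice_loss(m, m), 1e-6)
  a <- matrix(0, 4, 4); a[1:2, ] <- 1
  b <- matrix(0, 4, 4); b[3:4, ] <- 1
  expect_gt(dice_loss(a, b), 1 - 1e-6)
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5, tolerance = 1e-6)
  set.seed(104)
  for (rep in 1:20) {
    p <- matrix(runif(36), 6, 6); t <- random_mask(6, 6)
    expect_equal(dice_loss(p, t), dice_loss(t, p))
    expect_gte(dice_loss(p, t), 0)
    expect_lte(dice_loss(p, t), 1)
  }
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "svpnet_contract_error")
})
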