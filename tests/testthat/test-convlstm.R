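# ConvLSTM cell: analytic zero-weight behavior, the dense-LSTM reduction on
# a 1x1 grid, gate boundedness, and the output-gate peephole variants.

zero_convlstm_weights <- function(cin, chid, hs, ws, k = 3L) {
  z <- function(...) array(0, c(...))
  list(W_Xf = z(k, k, cin, chid), W_Hf = z(k, k, chid, chid),
       W_Xi = z(k, k, cin, chid), W_Hi = z(k, k, chid, chid),
       W_Xg = z(k, k, cin, chid), W_Hg = z(k, k, chid, chid),
       W_Xo = z(k, k, cin, chid), W_Ho = z(k, k, chid, chid),
       W_cf = z(hs, ws, chid), W_ci = z(hs, ws, chid), W_Co = z(hs, ws, chid),
       b_f = numeric(chid), b_Hi = numeric(chid), b_hg = numeric(chid),
       b_ho = numeric(chid))
}

random_convlstm_weights <- function(cin, chid, hs, ws, k = 1L) {
  r <- function(...) array(rnorm(prod(c(...)), sd = 0.5), c(...))
  list(W_Xf = r(k, k, cin, chid), W_Hf = r(k, k, chid, chid),
       W_Xi = r(k, k, cin, chid), W_Hi = r(k, k, chid, chid),
       W_Xg = r(k, k, cin, chid), W_Hg = r(k, k, chid, chid),
       W_Xo = r(k, k, cin, chid), W_Ho = r(k, k, chid, chid),
       W_cf = r(hs, ws, chid), W_ci = r(hs, ws, chid), W_Co = r(hs, ws, chid),
       b_f = rnorm(chid), b_Hi = rnorm(chid), b_hg = rnorm(chid),
       b_ho = rnorm(chid))
}

test_that("all-zero parameters force the analytic gate values", {
  set.seed(110)
  w <- zero_convlstm_weights(2, 3, 4, 4)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  C0 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  H0 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  st <- convlstm_step(x, list(H = H0, C = C0), w)
  # f = i = O = sigmoid(0) = 0.5, g = 0 => C_t = 0.5 C_{t-1},
  # H_t = 0.5 tanh(0.5 C_{t-1})
  expect_equal(st$C, 0.5 * C0, tolerance = 1e-12)
  expect_equal(st$H, 0.5 * tanh(0.5 * C0), tolerance = 1e-12)
})

test_that("zero input, state, and biases give the zero fixed point", {
  w <- zero_convlstm_weights(1, 2, 3, 3)
  z <- array(0, c(3, 3, 2))
  st <- convlstm_step(array(0, c(3, 3, 1)), list(H = z, C = z), w)
  expect_equal(st$H, z)
  expect_equal(st$C, z)
})

test_that("1x1 grid with 1x1 kernels reduces to a dense peephole LSTM", {
  set.seed(111)
  for (rep in 1:30) {
    cin <- sample(1:3, 1); chid <- sample(1:3, 1)
    w <- random_convlstm_weights(cin, chid, 1, 1, k = 1L)
    x <- array(rnorm(cin), c(1, 1, cin))
    H0 <- array(rnorm(chid), c(1, 1, chid))
    C0 <- array(rnorm(chid), c(1, 1, chid))
    st <- convlstm_step(x, list(H = H0, C = C0), w)
    dw <- list(W_Xf = matrix(w$W_Xf, chid, cin, byrow = TRUE),
               W_Hf = matrix(w$W_Hf, chid, chid, byrow = TRUE),
               W_Xi = matrix(w$W_Xi, chid, cin, byrow = TRUE),
               W_Hi = matrix(w$W_Hi, chid, chid, byrow = TRUE),
               W_Xg = matrix(w$W_Xg, chid, cin, byrow = TRUE),
               W_Hg = matrix(w$W_Hg, chid, chid, byrow = TRUE),
               W_Xo = matrix(w$W_Xo, chid, cin, byrow = TRUE),
               W_Ho = matrix(w$W_Ho, chid, chid, byrow = TRUE),
               W_cf = as.vector(w$W_cf), W_ci = as.vector(w$W_ci),
               W_Co = as.vector(w$W_Co), b_f = w$b_f, b_Hi = w$b_Hi,
               b_hg = w$b_hg, b_ho = w$b_ho)
    want <- oracle_dense_lstm_step(as.vector(x), as.vector(H0), as.vector(C0), dw)
    expect_lt(max(abs(as.vector(st$H) - want$H)), 1e-6)
    expect_lt(max(abs(as.vector(st$C) - want$C)), 1e-6)
  }
})

test_that("the conventional peephole variant peeks at C_{t-1}", {
  set.seed(112)
  cin <- 2; chid <- 2
  w <- random_convlstm_weights(cin, chid, 1, 1, k = 1L)
  x <- array(rnorm(cin), c(1, 1, cin))
  H0 <- array(rnorm(chid), c(1, 1, chid))
  C0 <- array(rnorm(chid), c(1, 1, chid))
  st_prev <- convlstm_step(x, list(H = H0, C = C0), w,
                           peephole_on_previous = TRUE)
  st_cur <- convlstm_step(x, list(H = H0, C = C0), w)
  expect_equal(st_prev$C, st_cur$C)  # C_t does not involve the output gate
  expect_false(isTRUE(all.equal(st_prev$H, st_cur$H)))
  dw <- list(W_Xf = matrix(w$W_Xf, chid, cin, byrow = TRUE),
             W_Hf = matrix(w$W_Hf, chid, chid, byrow = TRUE),
             W_Xi = matrix(w$W_Xi, chid, cin, byrow = TRUE),
             W_Hi = matrix(w$W_Hi, chid, chid, byrow = TRUE),
             W_Xg = matrix(w$W_Xg, chid, cin, byrow = TRUE),
             W_Hg = matrix(w$W_Hg, chid, chid, byrow = TRUE),
             W_Xo = matrix(w$W_Xo, chid, cin, byrow = TRUE),
             W_Ho = matrix(w$W_Ho, chid, chid, byrow = TRUE),
             W_cf = as.vector(w$W_cf), W_ci = as.vector(w$W_ci),
             W_Co = as.vector(w$W_Co), b_f = w$b_f, b_Hi = w$b_Hi,
             b_hg = w$b_hg, b_ho = w$b_ho)
  want <- oracle_dense_lstm_step(as.vector(x), as.vector(H0), as.vector(C0),
                                 dw, peephole_on_previous = TRUE)
  expect_lt(max(abs(as.vector(st_prev$H) - want$H)), 1e-6)
})

test_that("hidden state is tanh-bounded after any step", {
  set.seed(113)
  for (rep in 1:10) {
    w <- random_convlstm_weights(2, 4, 4, 4, k = 3L)
    st <- list(H = array(rnorm(4 * 4 * 4), c(4, 4, 4)),
               C = array(rnorm(4 * 4 * 4), c(4, 4, 4)))
    for (t in 1:5)
      st <- convlstm_step(array(rnorm(4 * 4 * 2, sd = 2), c(4, 4, 2)), st, w)
    expect_true(all(abs(st$H) < 1))
  }
})
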