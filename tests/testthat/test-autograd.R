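test_that("elementwise and matrix primitives match numeric gradients", {
  set.seed(101)
  A <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(8), 4, 2)
  r <- matrix(rnorm(4), 1, 4)

  a <- pf_tensor(A, requires_grad = TRUE)
  b <- pf_tensor(B, requires_grad = TRUE)
  rv <- pf_tensor(r, requires_grad = TRUE)
  out <- pf_mean(pf_sigmoid(pf_matmul(pf_tanh(pf_mul(pf_add(a, rv), a)), b)))
  pf_backward(out)

  f_of <- function(Am, Bm, rm) {
    mean(1 / (1 + exp(-tanh((Am + matrix(rm, 3, 4, byrow = TRUE)) * Am) %*% Bm)))
  }
  expect_lt(max(abs(a$grad - num_grad(function(x) f_of(matrix(x, 3, 4), B, r), A))), 1e-7)
  expect_lt(max(abs(b$grad - num_grad(function(x) f_of(A, matrix(x, 4, 2), r), B))), 1e-7)
  expect_lt(max(abs(rv$grad - num_grad(function(x) f_of(A, B, x), r))), 1e-7)
})

test_that("reduction, power, clip and division primitives differentiate correctly", {
  set.seed(102)
  X <- matrix(runif(10, 0.2, 0.9), 2, 5)
  x <- pf_tensor(X, requires_grad = TRUE)
  out <- pf_sum(pf_div(pf_pow(pf_pmin_const(pf_addc(x, 0.05), 0.8), 2),
                       pf_addc(pf_exp(pf_scale(x, -1)), 1)))
  pf_backward(out)
  f <- function(v) {
    m <- matrix(v, 2, 5)
    sum(pmin(m + 0.05, 0.8)^2 / (exp(-m) + 1))
  }
  expect_lt(max(abs(x$grad - num_grad(f, X))), 1e-6)
})

test_that("row gather scatters gradients back additively", {
  E <- pf_tensor(matrix(1:6, 3, 2), requires_grad = TRUE)
  idx <- c(2L, 0L, 2L, 1L)
  out <- pf_rows(E, idx)
  expect_equal(out$value[2, ], c(0, 0))      # index 0 is the implicit zero row
  expect_equal(out$value[1, ], c(2, 5))
  pf_backward(pf_sum(out))
  # row 2 gathered twice, row 1 once, row 3 never
  expect_equal(E$grad, matrix(c(1, 2, 0, 1, 2, 0), 3, 2))
})

test_that("layernorm matches numeric gradients for inputs, gain and bias", {
  set.seed(103)
  X <- matrix(rnorm(12), 3, 4)
  g0 <- matrix(runif(4, 0.5, 1.5), 1, 4)
  b0 <- matrix(rnorm(4), 1, 4)
  x <- pf_tensor(X, TRUE); gn <- pf_tensor(g0, TRUE); bs <- pf_tensor(b0, TRUE)
  out <- pf_mean(pf_layernorm(x, gn, bs))
  pf_backward(out)
  ln_ref <- function(Xm, gv, bv) {
    mu <- rowMeans(Xm); xc <- Xm - mu
    s <- sqrt(rowMeans(xc^2) + 1e-5)
    mean(sweep(sweep(xc / s, 2, gv, "*"), 2, bv, "+"))
  }
  expect_lt(max(abs(x$grad - num_grad(function(v) ln_ref(matrix(v, 3, 4), g0, b0), X))), 1e-6)
  expect_lt(max(abs(gn$grad - num_grad(function(v) ln_ref(X, v, b0), g0))), 1e-6)
  expect_lt(max(abs(bs$grad - num_grad(function(v) ln_ref(X, g0, v), b0))), 1e-6)
})

test_that("fused attention, BiLSTM, conv and maxpool match numeric gradients", {
  set.seed(104)
  B <- 2L; L <- 5L; d <- 4L
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
  X <- matrix(rnorm(B * L * d), B * L, d) * mask

  # attention
  q <- pf_tensor(X, TRUE); k <- pf_tensor(X + 0.1, TRUE); v <- pf_tensor(X - 0.2, TRUE)
  out <- pf_mean(pf_attention(q, k, v, B, L, 2L, mask))
  pf_backward(out)
  att_ref <- function(Qm) {
    as.numeric(pf_attention(pf_tensor(matrix(Qm, B * L, d)), pf_tensor(X + 0.1),
                            pf_tensor(X - 0.2), B, L, 2L, mask)$value) |> mean()
  }
  expect_lt(max(abs(q$grad - num_grad(att_ref, X))), 1e-6)

  # BiLSTM
  h <- 3L
  Wxf <- matrix(rnorm(d * 4 * h, sd = 0.4), d, 4 * h)
  Whf <- matrix(rnorm(h * 4 * h, sd = 0.4), h, 4 * h)
  bf <- matrix(0, 1, 4 * h)
  Wxb <- matrix(rnorm(d * 4 * h, sd = 0.4), d, 4 * h)
  Whb <- matrix(rnorm(h * 4 * h, sd = 0.4), h, 4 * h)
  bb <- matrix(0.1, 1, 4 * h)
  xs <- pf_tensor(X, TRUE)
  wh <- pf_tensor(Whf, TRUE)
  out <- pf_mean(pf_bilstm(xs, mask, wh_x <- pf_tensor(Wxf, TRUE), wh,
                           pf_tensor(bf, TRUE), pf_tensor(Wxb, TRUE),
                           pf_tensor(Whb, TRUE), pf_tensor(bb, TRUE), B, L))
  pf_backward(out)
  lstm_ref <- function(Xm, Whm) {
    mean(pf_bilstm(pf_tensor(matrix(Xm, B * L, d)), mask, pf_tensor(Wxf),
                   pf_tensor(matrix(Whm, h, 4 * h)), pf_tensor(bf),
                   pf_tensor(Wxb), pf_tensor(Whb), pf_tensor(bb), B, L)$value)
  }
  expect_lt(max(abs(xs$grad - num_grad(function(v) lstm_ref(v, Whf), X))), 1e-6)
  expect_lt(max(abs(wh$grad - num_grad(function(v) lstm_ref(X, v), Whf))), 1e-6)

  # conv + maxpool
  Wc <- matrix(rnorm(3 * d * 2, sd = 0.5), 3 * d, 2)
  xc <- pf_tensor(X, TRUE); wc <- pf_tensor(Wc, TRUE)
  out <- pf_mean(pf_maxpool_seq(pf_relu(pf_conv1d(xc, wc, pf_tensor(matrix(0.05, 1, 2)),
                                                  3L, B, L, mask)), B, L, mask))
  pf_backward(out)
  conv_ref <- function(Xm, Wm) {
    cv <- pf_conv1d(pf_tensor(matrix(Xm, B * L, d)), pf_tensor(matrix(Wm, 3 * d, 2)),
                    pf_tensor(matrix(0.05, 1, 2)), 3L, B, L, mask)
    mean(pf_maxpool_seq(pf_relu(cv), B, L, mask)$value)
  }
  expect_lt(max(abs(xc$grad - num_grad(function(v) conv_ref(v, Wc), X))), 1e-6)
  expect_lt(max(abs(wc$grad - num_grad(function(v) conv_ref(X, v), Wc))), 1e-6)
})

test_that("attention rows are convex combinations and masked rows stay zero", {
  set.seed(105)
  B <- 1L; L <- 6L; d <- 4L
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  X <- matrix(rnorm(L * d), L, d) * mask
  V <- matrix(1, L, d) * mask  # constant values over valid positions
  out <- pf_attention(pf_tensor(X), pf_tensor(X), pf_tensor(V), B, L, 2L, mask)
  # softmax weights sum to 1, so attending over constant values returns 1
  expect_equal(out$value[1:4, ], matrix(1, 4, d), tolerance = 1e-12)
  expect_equal(out$value[5:6, ], matrix(0, 2, d))
})
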