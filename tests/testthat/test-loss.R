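test_that("class weights follow inverse-sqrt counts scaled by the maximum", {
  Y <- matrix(0L, 101, 2)
  Y[1:100, 1] <- 1L
  Y[101, 2] <- 1L
  cfg <- mfdl_config(m_max = 0.5)
  st <- compute_class_stats(Y, cfg)
  expect_equal(st$w_c, c(0.5 * sqrt(1 / 100), 0.5), tolerance = 1e-12)
  # uniform weights when disabled
  st0 <- compute_class_stats(Y, mfdl_config(use_class_weights = FALSE))
  expect_equal(st0$w_c, c(1, 1))
  # equal counts give equal weights
  Yb <- cbind(rep(c(1L, 0L), 5), rep(c(0L, 1L), 5))
  stb <- compute_class_stats(Yb, cfg)
  expect_equal(stb$w_c[1], stb$w_c[2])
  # minority side receives the larger margin
  expect_equal(st$margin_pos[2], 0.5)       # 1 positive vs 100 negatives
  expect_lt(st$margin_neg[2], 0.5)
  expect_true(all(st$margin_pos <= cfg$m_max + 1e-12))
  expect_warning(compute_class_stats(cbind(Y[, 1], 0L), cfg), "smoothing")
})

test_that("MFDL reproduces the hand-computed worked example", {
  z <- matrix(c(0, 0), 1, 2)
  Y <- matrix(c(1, 0), 1, 2)
  cfg <- mfdl_config(alpha = 0.5, m_max = 0, p_pos = 1, p_neg = 1,
                     clip_pos = 0, clip_neg = 0, use_class_weights = FALSE)
  st <- suppressWarnings(compute_class_stats(Y, cfg))
  expect_equal(mfdl_loss(z, Y, st, cfg), 0.3, tolerance = 1e-7)
})

test_that("vectorized MFDL equals the scalar reference loop on random instances", {
  set.seed(60)
  for (rep in 1:100) {
    n <- sample(1:8, 1); m <- sample(2:5, 1)
    Y <- random_label_matrix(n, m)
    if (sum(Y) == 0) Y[1, 1] <- 1L
    z <- matrix(rnorm(n * m, sd = 2), n, m)
    cfg <- mfdl_config(alpha = runif(1), m_max = runif(1, 0, 1),
                       p_pos = sample(1:3, 1), p_neg = sample(1:3, 1),
                       clip_pos = runif(1, 0, 0.2), clip_neg = runif(1, 0, 0.2),
                       use_class_weights = sample(c(TRUE, FALSE), 1),
                       reduction = sample(c("mean", "sum", "none"), 1))
    st <- suppressWarnings(compute_class_stats(Y, cfg))
    got <- mfdl_loss(z, Y, st, cfg)
    want <- mfdl_oracle(z, Y, st, cfg)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("MFDL limits: perfect predictions drive the loss to zero, inverted to one", {
  set.seed(61)
  Y <- random_label_matrix(6, 4)
  Y[1, ] <- c(1L, 0L, 1L, 0L)   # ensure both sides exist somewhere
  Y[2, ] <- c(0L, 1L, 0L, 1L)
  cfg <- mfdl_config(m_max = 0, p_pos = 1, p_neg = 1, clip_pos = 0,
                     clip_neg = 0, use_class_weights = FALSE, reduction = "none")
  st <- suppressWarnings(compute_class_stats(Y, cfg))
  perfect <- (2 * Y - 1) * 60
  expect_lt(max(abs(mfdl_loss(perfect, Y, st, cfg))), 1e-8)
  inverted <- (1 - 2 * Y) * 60
  per_class <- mfdl_loss(inverted, Y, st, cfg)
  # each active dice component saturates at 1; both sides active gives 1
  expect_equal(per_class, rep(1, 4), tolerance = 1e-8)
})

test_that("monotonicity: raising a positive-label logit never increases the loss", {
  set.seed(62)
  Y <- random_label_matrix(5, 3)
  Y[1, 1] <- 1L
  cfg <- mfdl_config()
  st <- suppressWarnings(compute_class_stats(Y, cfg))
  z <- matrix(rnorm(15), 5, 3)
  pos <- which(Y == 1)
  for (j in pos[1:min(3, length(pos))]) {
    vals <- vapply(seq(-3, 3, by = 0.5), function(delta) {
      zz <- z; zz[j] <- zz[j] + delta
      mfdl_loss(zz, Y, st, cfg)
    }, numeric(1))
    expect_true(all(diff(vals) <= 1e-10))
  }
})

test_that("margin-free uniform MFDL equals the MLFDL comparator", {
  set.seed(63)
  for (rep in 1:20) {
    n <- sample(2:8, 1); m <- sample(2:5, 1)
    Y <- random_label_matrix(n, m)
    if (sum(Y) == 0) Y[1, 1] <- 1L
    z <- matrix(rnorm(n * m), n, m)
    cfg <- mfdl_config(m_max = 0, use_class_weights = FALSE)
    st <- suppressWarnings(compute_class_stats(Y, cfg))
    expect_equal(mfdl_loss(z, Y, st, cfg),
                 reference_losses(z, Y, "mlfdl", config = cfg),
                 tolerance = 1e-10)
  }
})

test_that("reference losses hit their closed forms", {
  expect_equal(reference_losses(matrix(0), matrix(1), "bce"), log(2),
               tolerance = 1e-9)
  # focal factor with exponent 0 reduces to plain cross-entropy
  set.seed(64)
  z <- matrix(rnorm(12), 3, 4)
  Y <- random_label_matrix(3, 4)
  node_b <- pepfusion:::bce_graph(pf_tensor(z), Y)
  node_f <- pepfusion:::focal_graph(pf_tensor(z), Y, gamma = 0)
  expect_equal(as.numeric(node_f$value), as.numeric(node_b$value),
               tolerance = 1e-9)
  expect_error(reference_losses(z, Y, "nope"), "arg")
})

test_that("MFDL gradients match finite differences on micro instances", {
  set.seed(65)
  for (rep in 1:5) {
    n <- sample(2:4, 1); m <- sample(2:3, 1)
    Y <- random_label_matrix(n, m)
    if (sum(Y) == 0) Y[1, 1] <- 1L
    z <- matrix(rnorm(n * m), n, m)
    cfg <- mfdl_config()
    st <- suppressWarnings(compute_class_stats(Y, cfg))
    ag <- mfdl_grad(z, Y, st, cfg)
    ng <- num_grad(function(v) mfdl_loss(matrix(v, n, m), Y, st, cfg), z)
    expect_lt(max(abs(ag - ng)), 1e-4)
  }
})

test_that("reduction modes are mutually consistent", {
  set.seed(66)
  Y <- random_label_matrix(6, 4)
  if (sum(Y) == 0) Y[1, 1] <- 1L
  z <- matrix(rnorm(24), 6, 4)
  mk <- function(red) mfdl_config(reduction = red)
  st <- suppressWarnings(compute_class_stats(Y, mk("mean")))
  lmean <- mfdl_loss(z, Y, st, mk("mean"))
  lsum <- mfdl_loss(z, Y, st, mk("sum"))
  lnone <- mfdl_loss(z, Y, st, mk("none"))
  expect_length(lnone, 4L)
  expect_equal(lsum, 4 * lmean, tolerance = 1e-12)
  expect_equal(mean(lnone), lmean, tolerance = 1e-12)
})
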