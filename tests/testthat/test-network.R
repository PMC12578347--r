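test_that("model building is deterministic and validates its config", {
  m1 <- tiny_model(seed = 9)
  m2 <- tiny_model(seed = 9)
  for (nm in names(m1$params)) {
    expect_identical(m1$params[[nm]]$value, m2$params[[nm]]$value)
  }
  m3 <- tiny_model(seed = 10)
  expect_false(identical(m1$params$E$value, m3$params$E$value))
  expect_equal(ncol(m1$params$cls_W2$value), 3L)
  expect_error(model_config(conv_kernels = integer(0)), "non-empty")
  expect_error(model_config(d_model = 9), "even")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(ablate_modules = "warp"), "unknown module")
})

test_that("forward produces finite logits of the right shape, batch independent", {
  m <- tiny_model()
  tk <- tokenize_batch(c("ACDEFGH", "KWKLF", "YYYYYYYYYY"), max_len = 12)
  lg <- forward(m, tk$tokens, tk$mask)
  expect_equal(dim(lg), c(3L, 3L))
  expect_true(all(is.finite(lg)))
  # permuting batch order permutes logits rows identically
  perm <- c(3L, 1L, 2L)
  lg2 <- forward(m, tk$tokens[perm, ], tk$mask[perm, ])
  expect_equal(lg2, lg[perm, ], tolerance = 1e-10)
  # evaluation mode is deterministic
  expect_identical(forward(m, tk$tokens, tk$mask), lg)
})

test_that("logits are invariant to values stored at masked positions", {
  m <- tiny_model()
  tk <- tokenize_batch(c("ACDEFGH", "KWKLF"), max_len = 12)
  bt <- make_batch(tk$tokens, tk$mask, m)
  base <- forward_batch(m, bt, training = FALSE)$value
  bt2 <- bt
  bt2$bio <- lapply(bt$bio, function(x) { x[!bt$mask, ] <- 77; x })
  bt2$aac[!bt$mask, ] <- -5
  pert <- forward_batch(m, bt2, training = FALSE)$value
  expect_lt(max(abs(base - pert)), 1e-6)
})

test_that("end-to-end gradients match finite differences on a micro-batch", {
  m <- tiny_model(seed = 3)
  tk <- tokenize_batch(c("ACDEFGH", "KWKLF"), max_len = 12)
  bt <- make_batch(tk$tokens, tk$mask, m)
  Y <- matrix(c(1, 0, 0, 0, 1, 1), 2, 3, byrow = TRUE)
  cfg <- mfdl_config()
  st <- suppressWarnings(compute_class_stats(Y, cfg))
  lossfun <- function() {
    pepfusion:::mfdl_graph(forward_batch(m, bt, FALSE), Y, st, cfg)
  }
  pf_backward(lossfun())
  set.seed(77)
  for (nm in c("E", "Wq", "gat_asrc", "fz_c_PC6", "gate_AAC", "lstm1_Wx_f",
               "conv_W_3", "ffn_W1", "ln_gain", "cls_W2")) {
    p <- m$params[[nm]]
    ag <- p$grad
    for (i in sample(length(p$value), min(3, length(p$value)))) {
      v0 <- p$value[i]; eps <- 1e-5
      p$value[i] <- v0 + eps; lp <- as.numeric(lossfun()$value)
      p$value[i] <- v0 - eps; lm <- as.numeric(lossfun()$value)
      p$value[i] <- v0
      expect_lt(abs((lp - lm) / (2 * eps) - ag[i]), 1e-3)
    }
  }
})

test_that("graph attention normalizes neighbourhoods and respects symmetry", {
  m <- tiny_model(max_len = 6)
  g <- build_chain_graph(tokenize("ACD", max_len = 6))
  feats <- matrix(rep(1, 3 * 8), 3, 8)  # identical features on all nodes
  gs <- graph_stream(m, g, feats)
  # coefficients over each node's {prev, self, next} neighbourhood sum to 1
  asum <- gs$alphas[[1]] + gs$alphas[[2]] + gs$alphas[[3]]
  expect_equal(asum[1:3, ], matrix(1, 3, 2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(asum[4:6, ], matrix(0, 3, 2), ignore_attr = TRUE)
  # identical node features: the end nodes see symmetric attention patterns
  expect_equal(gs$alphas[[2]][1, ], gs$alphas[[2]][3, ], tolerance = 1e-9)
  expect_equal(gs$alphas[[3]][1, ], gs$alphas[[1]][3, ], tolerance = 1e-9)
  # rows beyond the graph are zero-padded
  expect_equal(gs$values[4:6, ], matrix(0, 3, 8))

  # single-node graph depends only on that node's own transformed features
  g1 <- build_chain_graph(list(tokens = c(5L, rep(0L, 5)),
                               mask = c(TRUE, rep(FALSE, 5))))
  gs1 <- graph_stream(m, g1, matrix(rnorm(8), 1, 8))
  expect_equal(gs1$alphas[[2]][1, ], c(1, 1), tolerance = 1e-9)
  expect_error(graph_stream(m, list(n_nodes = 0L), matrix(0, 0, 8)), "empty")
})

test_that("thresholding assigns labels by strict probability comparison", {
  lg <- matrix(c(2, -1, 0), 1, 3)
  expect_equal(predict_labels(lg, 0.5)[[1]], 1L)    # strict at logit 0
  expect_equal(predict_labels(matrix(-Inf, 1, 3), 0.5)[[1]], integer(0))
  # sigmoid(2) ~ 0.881 < 0.9
  expect_equal(predict_labels(matrix(2, 1, 1), 0.9)[[1]], integer(0))
  expect_equal(predict_labels(matrix(2, 1, 1), 0.8)[[1]], 1L)
  ls <- label_space(c("A", "B", "C"))
  expect_equal(predict_labels(lg, 0.5, ls)[[1]], "A")
  expect_error(predict_labels(lg, 1.5), "config error")
})

test_that("stream and module ablations run with unchanged shapes", {
  tk <- tokenize_batch(c("ACDEFGH", "KWKLF"), max_len = 12)
  base <- tiny_model(seed = 5)
  lg0 <- forward(base, tk$tokens, tk$mask)
  for (ab in list(list(ablate_streams = "AAC"),
                  list(ablate_streams = c("attention", "BLOSUM62")),
                  list(ablate_modules = "gat"),
                  list(ablate_modules = "bilstm"),
                  list(ablate_modules = "gate_fusion"),
                  list(ablate_modules = "cnn"),
                  list(ablate_modules = "ffn"),
                  list(ablate_modules = "fuzzifier"))) {
    m <- do.call(tiny_model, c(list(seed = 5), ab))
    lg <- forward(m, tk$tokens, tk$mask)
    expect_equal(dim(lg), dim(lg0))
    expect_true(all(is.finite(lg)))
  }
})
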