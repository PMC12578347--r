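# Shared helpers: numeric differentiation, scalar reference losses and
# brute-force metric oracles. These stay independent of the package's own
# vectorized implementations.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# scalar per-entry/per-class reference implementation of the marginal focal
# dice loss, written as explicit loops over samples and classes
mfdl_oracle <- function(logits, labels, stats, cfg, use_margins = TRUE) {
  N <- nrow(logits); C <- ncol(logits)
  eps <- 1e-8
  per_class <- numeric(C)
  for (cc in seq_len(C)) {
    num_p <- den_p <- num_n <- den_n <- 0
    npos <- nneg <- 0
    for (i in seq_len(N)) {
      y <- labels[i, cc]
      m <- if (use_margins && cfg$m_max > 0) {
        if (y == 1) stats$margin_pos[cc] else stats$margin_neg[cc]
      } else 0
      p <- 1 / (1 + exp(-(logits[i, cc] - m)))
      if (y == 1) {
        pp <- min(p + cfg$clip_pos, 1) * p
        num_p <- num_p + pp * y
        den_p <- den_p + pp^cfg$p_pos + y^cfg$p_pos
        npos <- npos + 1
      } else {
        pn <- min((1 - p) + cfg$clip_neg, 1) * (1 - p)
        num_n <- num_n + pn * (1 - y)
        den_n <- den_n + pn^cfg$p_neg + (1 - y)^cfg$p_neg
        nneg <- nneg + 1
      }
    }
    lp <- if (npos > 0) 1 - 2 * num_p / (den_p + eps) else 0
    ln <- if (nneg > 0) 1 - 2 * num_n / (den_n + eps) else 0
    per_class[cc] <- stats$w_c[cc] * (cfg$alpha * lp + (1 - cfg$alpha) * ln)
  }
  switch(cfg$reduction, mean = mean(per_class), sum = sum(per_class),
         none = per_class)
}

# brute-force multi-label metrics by direct enumeration over samples
metrics_oracle <- function(Yt, Yp, M) {
  n <- nrow(Yt)
  pr <- cv <- ac <- at <- af <- numeric(n)
  for (i in seq_len(n)) {
    L <- which(Yt[i, ] == 1); P <- which(Yp[i, ] == 1)
    it <- length(intersect(L, P)); un <- length(union(L, P))
    pr[i] <- if (length(P)) it / length(P) else 0
    cv[i] <- if (length(L)) it / length(L) else 0
    ac[i] <- if (un) it / un else 1
    at[i] <- as.numeric(setequal(L, P))
    af[i] <- (un - it) / M
  }
  c(precision = mean(pr), coverage = mean(cv), accuracy = mean(ac),
    absolute_true = mean(at), absolute_false = mean(af))
}

auc_oracle <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  tot / (length(pos) * length(neg))
}

random_label_matrix <- function(n, m, p = 0.4) {
  matrix(as.integer(stats::runif(n * m) < p), n, m)
}

tiny_model <- function(n_classes = 3L, max_len = 12L, seed = 7L, ...) {
  build_model(model_config(d_model = 8L, attn_heads = 2L, lstm_hidden = 5L,
                           conv_kernels = c(3L, 5L), conv_channels = 6L,
                           ffn_dim = 10L, cls_hidden = 8L, gat_heads = 2L,
                           dropout = 0, n_classes = n_classes,
                           max_len = max_len, seed = seed, ...))
}
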