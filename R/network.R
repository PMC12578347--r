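# The trainable predictor: eight feature streams -> gated fusion -> BiLSTM
# -> parallel multi-width convolutions -> residual FFN -> sigmoid classifier.

STREAM_NAMES <- c("embedding", "attention", "graph", "AAIndex", "PAAC",
                  "PC6", "BLOSUM62", "AAC")
MODULE_NAMES <- c("gat", "bilstm", "fuzzifier", "gate_fusion", "cnn", "ffn")

#' Model architecture configuration
#'
#' @param d_model Shared fusion/embedding dimension (even, for the
#'   sinusoidal positions).
#' @param attn_heads Self-attention heads (must divide `d_model`).
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param lstm_layers Stacked BiLSTM layers.
#' @param conv_kernels Odd kernel widths of the parallel convolutions.
#' @param conv_channels Output channels per kernel.
#' @param ffn_dim Hidden width of the feed-forward block.
#' @param cls_hidden Hidden width of the classifier MLP.
#' @param gat_heads Graph-attention heads (must divide `d_model`).
#' @param dropout Dropout rate in \[0, 1), applied in training mode only.
#' @param n_classes Number of functional categories.
#' @param max_len Padded sequence length.
#' @param seed Integer seed for parameter initialization.
#' @param ablate_modules Character subset of
#'   `c("gat","bilstm","fuzzifier","gate_fusion","cnn","ffn")`; listed
#'   modules are removed (gate fusion is replaced by plain summation of the
#'   aligned streams).
#' @param ablate_streams Character subset of the eight stream names; listed
#'   streams are zeroed in every batch.
#' @export
model_config <- function(d_model = 64L, attn_heads = 4L, lstm_hidden = 64L,
                         lstm_layers = 1L, conv_kernels = c(3L, 5L, 7L),
                         conv_channels = 64L, ffn_dim = 256L,
                         cls_hidden = 128L, gat_heads = 2L, dropout = 0.1,
                         n_classes = 21L, max_len = 50L, seed = 1L,
                         ablate_modules = character(0),
                         ablate_streams = character(0)) {
  if (!length(conv_kernels)) stop("build error: conv_kernels must be non-empty")
  if (any(conv_kernels %% 2L != 1L)) stop("build error: kernels must be odd")
  if (d_model %% 2L != 0L) stop("build error: d_model must be even")
  if (d_model %% attn_heads != 0L) stop("build error: attn_heads must divide d_model")
  if (d_model %% gat_heads != 0L) stop("build error: gat_heads must divide d_model")
  if (dropout < 0 || dropout >= 1) stop("build error: dropout must be in [0,1)")
  stopifnot(d_model >= 2L, lstm_hidden >= 1L, lstm_layers >= 1L,
            conv_channels >= 1L, ffn_dim >= 1L, n_classes >= 1L, max_len >= 1L)
  bad <- setdiff(ablate_modules, MODULE_NAMES)
  if (length(bad)) stop("config error: unknown module(s) ", paste(bad, collapse = ","))
  bad <- setdiff(ablate_streams, STREAM_NAMES)
  if (length(bad)) stop("config error: unknown stream(s) ", paste(bad, collapse = ","))
  structure(list(d_model = as.integer(d_model), attn_heads = as.integer(attn_heads),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 conv_kernels = as.integer(conv_kernels),
                 conv_channels = as.integer(conv_channels),
                 ffn_dim = as.integer(ffn_dim), cls_hidden = as.integer(cls_hidden),
                 gat_heads = as.integer(gat_heads), dropout = dropout,
                 n_classes = as.integer(n_classes), max_len = as.integer(max_len),
                 seed = as.integer(seed), ablate_modules = ablate_modules,
                 ablate_streams = ablate_streams), class = "pf_model_config")
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

param <- function(value) pf_tensor(value, requires_grad = TRUE)

#' Build a model with deterministic initialization
#'
#' @param config A [model_config()].
#' @return A `pf_model`: environment holding the parameter list `params`
#'   (autodiff leaves), the property tables, the positional-encoding matrix
#'   and the config.
#' @export
build_model <- function(config = model_config()) {
  d <- config$d_model
  h <- config$lstm_hidden
  tables <- list(AAIndex = load_property_table("AAIndex"),
                 PAAC = load_property_table("PAAC"),
                 PC6 = load_property_table("PC6"),
                 BLOSUM62 = load_property_table("BLOSUM62"))
  native <- c(embedding = d, attention = d, graph = d,
              AAIndex = tables$AAIndex$dim, PAAC = tables$PAAC$dim,
              PC6 = tables$PC6$dim, BLOSUM62 = tables$BLOSUM62$dim, AAC = 20L)
  p <- local_seed(config$seed, {
    p <- list()
    p$E <- param(glorot(20L, d))
    p$Wq <- param(glorot(d, d)); p$Wk <- param(glorot(d, d))
    p$Wv <- param(glorot(d, d)); p$Wo <- param(glorot(d, d))
    p$bo <- param(matrix(0, 1L, d))
    p$gat_W <- param(glorot(d, d))
    p$gat_asrc <- param(matrix(stats::runif(d, -0.1, 0.1), 1L))
    p$gat_adst <- param(matrix(stats::runif(d, -0.1, 0.1), 1L))
    for (s in c("AAIndex", "PAAC", "PC6", "BLOSUM62", "AAC")) {
      p[[paste0("fz_c_", s)]] <- param(matrix(0, 1L, native[[s]]))
      p[[paste0("fz_s_", s)]] <- param(matrix(1, 1L, native[[s]]))
    }
    for (s in STREAM_NAMES) {
      p[[paste0("proj_W_", s)]] <- param(glorot(native[[s]], d))
      p[[paste0("proj_b_", s)]] <- param(matrix(0, 1L, d))
      p[[paste0("gate_", s)]] <- param(matrix(stats::runif(d, -0.1, 0.1), 1L))
    }
    din <- d
    for (l in seq_len(config$lstm_layers)) {
      fb <- matrix(0, 1L, 4L * h)
      fb[, (h + 1L):(2L * h)] <- 1  # forget-gate bias
      for (dir in c("f", "b")) {
        p[[sprintf("lstm%d_Wx_%s", l, dir)]] <- param(glorot(din, 4L * h))
        p[[sprintf("lstm%d_Wh_%s", l, dir)]] <- param(glorot(h, 4L * h))
        p[[sprintf("lstm%d_b_%s", l, dir)]] <- param(fb)
      }
      din <- 2L * h
    }
    seq_dim <- if ("bilstm" %in% config$ablate_modules) d else 2L * h
    for (k in config$conv_kernels) {
      p[[paste0("conv_W_", k)]] <- param(glorot(k * seq_dim, config$conv_channels))
      p[[paste0("conv_b_", k)]] <- param(matrix(0, 1L, config$conv_channels))
    }
    pooled_dim <- if ("cnn" %in% config$ablate_modules) seq_dim else
      length(config$conv_kernels) * config$conv_channels
    p$ffn_W1 <- param(glorot(pooled_dim, config$ffn_dim))
    p$ffn_b1 <- param(matrix(0, 1L, config$ffn_dim))
    p$ffn_W2 <- param(glorot(config$ffn_dim, pooled_dim))
    p$ffn_b2 <- param(matrix(0, 1L, pooled_dim))
    p$ln_gain <- param(matrix(1, 1L, pooled_dim))
    p$ln_bias <- param(matrix(0, 1L, pooled_dim))
    p$cls_W1 <- param(glorot(pooled_dim, config$cls_hidden))
    p$cls_b1 <- param(matrix(0, 1L, config$cls_hidden))
    p$cls_W2 <- param(glorot(config$cls_hidden, config$n_classes))
    p$cls_b2 <- param(matrix(0, 1L, config$n_classes))
    p
  })
  model <- new.env(parent = emptyenv())
  model$params <- p
  model$config <- config
  model$tables <- tables
  model$native <- native
  model$pe <- positional_encoding(config$max_len, d)
  class(model) <- "pf_model"
  model
}

#' @export
print.pf_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("<pf_model d=%d classes=%d params=%d>\n",
              x$config$d_model, x$config$n_classes, np))
  invisible(x)
}

n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' Prepare a batch from tokenized matrices
#'
#' Precomputes the flattened token/mask vectors and the constant
#' physicochemical lookup matrices used by [forward_batch()].
#'
#' @param tokens,mask Integer and logical (B x L) matrices from
#'   [tokenize_batch()].
#' @param model A `pf_model`.
#' @return A batch list.
#' @export
make_batch <- function(tokens, mask, model) {
  B <- nrow(tokens); L <- ncol(tokens)
  flat_tok <- as.vector(t(tokens))
  flat_mask <- as.vector(t(mask))
  valid <- which(flat_tok > 0L)
  bio <- lapply(model$tables, function(tb) {
    m <- matrix(0, B * L, tb$dim)
    m[valid, ] <- tb$rows[flat_tok[valid], , drop = FALSE]
    m
  })
  # per-sequence composition broadcast over that sequence's valid positions
  aac <- matrix(0, B * L, 20L)
  for (b in seq_len(B)) {
    tk <- tokens[b, ][mask[b, ]]
    if (!length(tk)) next
    freq <- tabulate(tk, nbins = 20L) / length(tk)
    rows <- ((b - 1L) * L) + which(mask[b, ])
    aac[rows, ] <- matrix(freq, length(rows), 20L, byrow = TRUE)
  }
  list(B = B, L = L, tokens = flat_tok, mask = flat_mask, bio = bio, aac = aac)
}

fuzzify_node <- function(x_node, c_par, s_par, mask) {
  d2 <- pf_pow(pf_sub(x_node, c_par), 2)
  den <- pf_addc(pf_scale(pf_pow(s_par, 2), 2), 2e-6)  # 2*(s^2 + eps)
  pf_mask_rows(pf_exp(pf_scale(pf_div(d2, den), -1)), mask)
}

# one multi-head graph-attention layer over the residue chain graphs of a
# flattened batch; neighbourhoods are {i-1, i, i+1} within each sequence
gat_node <- function(model, feats, B, L, mask, return_alpha = FALSE) {
  p <- model$params
  d <- model$config$d_model
  heads <- model$config$gat_heads
  dh <- d %/% heads
  Hw <- pf_matmul(feats, p$gat_W)
  # per-head attention logit contributions of source and destination nodes
  group <- matrix(0, d, heads)
  for (hh in seq_len(heads)) group[((hh - 1L) * dh + 1L):(hh * dh), hh] <- 1
  Gc <- pf_const(group)
  s_src <- pf_matmul(pf_mul(Hw, p$gat_asrc), Gc)  # (B*L x heads)
  s_dst <- pf_matmul(pf_mul(Hw, p$gat_adst), Gc)
  offs <- c(-1L, 0L, 1L)
  es <- list(); valid <- list(); gathers <- list()
  for (k in seq_along(offs)) {
    idx <- shift_index(B, L, offs[k], mask)
    valid[[k]] <- (idx > 0L) & mask
    t_shift <- pf_rows(s_dst, idx)
    es[[k]] <- pf_lrelu(pf_add(s_src, t_shift), 0.2)
    gathers[[k]] <- pf_rows(Hw, idx)
  }
  # exact softmax stabilization: subtract the (detached) per-entry maximum
  # over the neighbourhood before exponentiating
  masked_e <- lapply(seq_along(offs), function(k) {
    v <- es[[k]]$value
    v[!valid[[k]], ] <- -Inf
    v
  })
  emax <- pmax(masked_e[[1]], masked_e[[2]], masked_e[[3]])
  emax[!is.finite(emax)] <- 0
  enums <- lapply(seq_along(offs), function(k) {
    pf_mask_rows(pf_exp(pf_sub(es[[k]], pf_const(emax))), valid[[k]])
  })
  denom <- pf_addc(pf_add(pf_add(enums[[1]], enums[[2]]), enums[[3]]), 1e-12)
  out <- NULL
  alphas <- list()
  for (k in seq_along(offs)) {
    alpha <- pf_div(enums[[k]], denom)
    alphas[[k]] <- alpha
    term <- pf_mul(gathers[[k]], pf_rep_cols(alpha, dh))
    out <- if (is.null(out)) term else pf_add(out, term)
  }
  out <- pf_mask_rows(pf_relu(out), mask)
  if (return_alpha) list(node = out, alphas = alphas) else out
}

#' Forward pass on a prepared batch
#'
#' Builds the full differentiable graph: eight streams, fuzzification, gated
#' fusion, BiLSTM, parallel convolutions with masked max-pooling, residual
#' FFN with layer normalization and the sigmoid classifier head.
#'
#' @param model A `pf_model`.
#' @param batch A [make_batch()] result.
#' @param training Apply dropout (stochastic; seeded by the caller's RNG)?
#' @return `pf_tensor` of logits (B x n_classes).
#' @export
forward_batch <- function(model, batch, training = FALSE) {
  p <- model$params
  cfg <- model$config
  B <- batch$B; L <- batch$L
  mask <- batch$mask
  d <- cfg$d_model
  drop <- function(x) if (training && cfg$dropout > 0) pf_dropout(x, cfg$dropout) else x

  emb <- pf_embedding(p$E, batch$tokens)
  pe_tiled <- model$pe[rep(seq_len(L), B), , drop = FALSE] * as.numeric(mask)
  ax <- pf_add(emb, pf_const(pe_tiled))
  att <- pf_attention(pf_matmul(ax, p$Wq), pf_matmul(ax, p$Wk),
                      pf_matmul(ax, p$Wv), B, L, cfg$attn_heads, mask)
  att <- pf_mask_rows(pf_add(pf_matmul(att, p$Wo), p$bo), mask)

  streams <- list(embedding = emb, attention = att)
  if (!("gat" %in% cfg$ablate_modules)) {
    streams$graph <- gat_node(model, emb, B, L, mask)
  }
  fuzz_on <- !("fuzzifier" %in% cfg$ablate_modules)
  bio_in <- c(batch$bio, list(AAC = batch$aac))
  for (s in names(bio_in)) {
    xc <- pf_const(bio_in[[s]])
    streams[[s]] <- if (fuzz_on) {
      fuzzify_node(xc, p[[paste0("fz_c_", s)]], p[[paste0("fz_s_", s)]], mask)
    } else xc
  }
  aligned <- list()
  for (s in names(streams)) {
    if (s %in% cfg$ablate_streams) {
      aligned[[s]] <- pf_const(matrix(0, B * L, d))
      next
    }
    proj <- pf_add(pf_matmul(streams[[s]], p[[paste0("proj_W_", s)]]),
                   p[[paste0("proj_b_", s)]])
    aligned[[s]] <- pf_mask_rows(proj, mask)
  }
  N <- length(aligned)
  fused <- NULL
  if ("gate_fusion" %in% cfg$ablate_modules) {
    for (s in names(aligned)) {
      fused <- if (is.null(fused)) aligned[[s]] else pf_add(fused, aligned[[s]])
    }
  } else {
    for (s in names(aligned)) {
      gated <- pf_mul(aligned[[s]], pf_sigmoid(p[[paste0("gate_", s)]]))
      fused <- if (is.null(fused)) gated else pf_add(fused, gated)
    }
    fused <- pf_scale(fused, 1 / N)
  }
  fused <- drop(fused)

  seqrep <- fused
  if (!("bilstm" %in% cfg$ablate_modules)) {
    for (l in seq_len(cfg$lstm_layers)) {
      seqrep <- pf_bilstm(seqrep, mask,
                          p[[sprintf("lstm%d_Wx_f", l)]],
                          p[[sprintf("lstm%d_Wh_f", l)]],
                          p[[sprintf("lstm%d_b_f", l)]],
                          p[[sprintf("lstm%d_Wx_b", l)]],
                          p[[sprintf("lstm%d_Wh_b", l)]],
                          p[[sprintf("lstm%d_b_b", l)]], B, L)
    }
  }
  if ("cnn" %in% cfg$ablate_modules) {
    pooled <- pf_maxpool_seq(seqrep, B, L, mask)
  } else {
    pools <- lapply(cfg$conv_kernels, function(k) {
      cv <- pf_relu(pf_conv1d(seqrep, p[[paste0("conv_W_", k)]],
                              p[[paste0("conv_b_", k)]], k, B, L, mask))
      pf_maxpool_seq(cv, B, L, mask)
    })
    pooled <- pf_cbind(pools)
  }
  pooled <- drop(pooled)
  if (!("ffn" %in% cfg$ablate_modules)) {
    hidden <- pf_relu(pf_add(pf_matmul(pooled, p$ffn_W1), p$ffn_b1))
    hidden <- drop(hidden)
    ffn_out <- pf_add(pf_matmul(hidden, p$ffn_W2), p$ffn_b2)
    pooled <- pf_layernorm(pf_add(pooled, ffn_out), p$ln_gain, p$ln_bias)
  }
  chid <- pf_relu(pf_add(pf_matmul(pooled, p$cls_W1), p$cls_b1))
  chid <- drop(chid)
  pf_add(pf_matmul(chid, p$cls_W2), p$cls_b2)
}

#' Forward pass returning numeric logits
#'
#' Deterministic evaluation-mode pass (no dropout).
#'
#' @param model A `pf_model`.
#' @param tokens,mask (B x L) matrices from [tokenize_batch()].
#' @return Numeric logits matrix (B x n_classes).
#' @export
forward <- function(model, tokens, mask) {
  batch <- make_batch(tokens, mask, model)
  forward_batch(model, batch, training = FALSE)$value
}

#' Graph-attention stream over an explicit chain graph
#'
#' Runs the model's graph-attention layer on one residue chain graph with
#' caller-supplied node features; rows beyond the graph are zero-padded.
#'
#' @param model A `pf_model`.
#' @param graph A [build_chain_graph()] result.
#' @param node_features Matrix (n_nodes x d_model).
#' @return List with `values` (max_len x d_model) and the per-offset
#'   attention coefficient matrices `alphas` (columns = heads; rows beyond
#'   `n_nodes`, or pointing outside the chain, are zero).
#' @export
graph_stream <- function(model, graph, node_features) {
  if (graph$n_nodes < 1L) stop("stream error: empty graph")
  stopifnot(ncol(node_features) == model$config$d_model)
  L <- model$config$max_len
  mask <- c(rep(TRUE, graph$n_nodes), rep(FALSE, L - graph$n_nodes))
  feats <- matrix(0, L, model$config$d_model)
  feats[seq_len(graph$n_nodes), ] <- node_features
  res <- gat_node(model, pf_const(feats), 1L, L, mask, return_alpha = TRUE)
  list(values = res$node$value,
       alphas = lapply(res$alphas, function(a) a$value))
}

#' Probability predictions for peptide records
#'
#' @param model A `pf_model`.
#' @param records `pf_records` data.frame (or character sequences).
#' @param batch_size Sequences per forward pass.
#' @return Matrix (n x n_classes) of sigmoid probabilities.
#' @export
predict_proba <- function(model, records, batch_size = 64L) {
  tk <- tokenize_batch(records, max_len = model$config$max_len)
  n <- nrow(tk$tokens)
  out <- matrix(NA_real_, n, model$config$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- 1 / (1 + exp(-forward(model, tk$tokens[idx, , drop = FALSE],
                                        tk$mask[idx, , drop = FALSE])))
  }
  out
}

#' Threshold logits into label subsets
#'
#' Label c is assigned iff `sigmoid(logit_c) > threshold` (strict).
#'
#' @param logits Numeric matrix (n x n_classes).
#' @param threshold Probability threshold in (0, 1); default 0.5.
#' @param labels Optional [label_space()] for named subsets.
#' @return List of label subsets (integer indices, or names when `labels`
#'   is given).
#' @export
predict_labels <- function(logits, threshold = 0.5, labels = NULL) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("config error: threshold must lie in (0, 1)")
  cut <- stats::qlogis(threshold)
  apply(logits, 1L, function(z) {
    idx <- which(z > cut)
    if (is.null(labels)) idx else labels$names[idx]
  }, simplify = FALSE)
}
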