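# Fused network layers with hand-derived backward passes.
#
# Batches of B sequences padded to length L are stored flattened as
# (B*L) x d matrices, rows ordered position-major within each sequence
# (row (b-1)*L + t holds position t of sequence b), together with a logical
# validity mask of length B*L.

seq_rows <- function(B, L, t) (seq_len(B) - 1L) * L + t

#' Masked multi-head scaled dot-product self-attention
#'
#' @param Q,K,V `pf_tensor`s of shape (B*L x d) with d divisible by `heads`.
#' @param B,L Batch size and padded length.
#' @param heads Number of attention heads.
#' @param mask Logical vector of length B*L; masked positions neither attend
#'   nor are attended to, and their output rows are zero.
#' @return `pf_tensor` of shape (B*L x d).
#' @export
pf_attention <- function(Q, K, V, B, L, heads, mask) {
  Q <- as_pf(Q); K <- as_pf(K); V <- as_pf(V)
  d <- ncol(Q$value)
  stopifnot(d %% heads == 0L)
  dh <- d %/% heads
  scale <- 1 / sqrt(dh)
  out <- matrix(0, B * L, d)
  attn <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    valid <- which(mask[rows])
    if (!length(valid)) next
    attn[[b]] <- vector("list", heads)
    vrows <- rows[valid]
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qb <- Q$value[vrows, cols, drop = FALSE]
      Kb <- K$value[vrows, cols, drop = FALSE]
      Vb <- V$value[vrows, cols, drop = FALSE]
      S <- tcrossprod(Qb, Kb) * scale
      S <- S - apply(S, 1L, max)
      A <- exp(S)
      A <- A / rowSums(A)
      out[vrows, cols] <- A %*% Vb
      attn[[b]][[h]] <- A
    }
  }
  pf_node(out, list(Q, K, V), function(g) {
    dQ <- matrix(0, B * L, d); dK <- dQ; dV <- dQ
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      valid <- which(mask[rows])
      if (!length(valid)) next
      vrows <- rows[valid]
      for (h in seq_len(heads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- attn[[b]][[h]]
        gO <- g[vrows, cols, drop = FALSE]
        Qb <- Q$value[vrows, cols, drop = FALSE]
        Kb <- K$value[vrows, cols, drop = FALSE]
        Vb <- V$value[vrows, cols, drop = FALSE]
        dV[vrows, cols] <- dV[vrows, cols] + crossprod(A, gO)
        dA <- tcrossprod(gO, Vb)
        dS <- A * (dA - rowSums(dA * A))
        dQ[vrows, cols] <- dQ[vrows, cols] + (dS %*% Kb) * scale
        dK[vrows, cols] <- dK[vrows, cols] + crossprod(dS, Qb) * scale
      }
    }
    list(dQ, dK, dV)
  })
}

# one LSTM direction; returns list(H = (B*L x h) matrix, caches).
# The input projection X %*% Wx + b is hoisted out of the time loop.
lstm_forward_dir <- function(X, mask, Wx, Wh, b, B, L, reverse) {
  hdim <- ncol(Wh) %/% 4L
  H <- matrix(0, B * L, hdim)
  hp <- matrix(0, B, hdim)
  cp <- matrix(0, B, hdim)
  steps <- if (reverse) rev(seq_len(L)) else seq_len(L)
  cache <- vector("list", L)
  XWx <- X %*% Wx
  XWx <- sweep(XWx, 2L, as.numeric(b), "+")
  for (t in steps) {
    rows <- seq_rows(B, L, t)
    m <- as.numeric(mask[rows])
    a <- XWx[rows, , drop = FALSE] + hp %*% Wh
    ii <- 1 / (1 + exp(-a[, 1:hdim, drop = FALSE]))
    ff <- 1 / (1 + exp(-a[, (hdim + 1):(2 * hdim), drop = FALSE]))
    gg <- tanh(a[, (2 * hdim + 1):(3 * hdim), drop = FALSE])
    oo <- 1 / (1 + exp(-a[, (3 * hdim + 1):(4 * hdim), drop = FALSE]))
    cn <- ff * cp + ii * gg
    tc <- tanh(cn)
    hn <- oo * tc
    # carry previous state through padded positions
    hcur <- hn * m + hp * (1 - m)
    ccur <- cn * m + cp * (1 - m)
    H[rows, ] <- hcur * m  # padded rows emit zeros
    cache[[t]] <- list(hp = hp, cp = cp, ii = ii, ff = ff, gg = gg,
                       oo = oo, cn = cn, tc = tc, m = m)
    hp <- hcur
    cp <- ccur
  }
  list(H = H, cache = cache, steps = steps)
}

lstm_backward_dir <- function(gH, X, mask, Wx, Wh, b, B, L, fwd) {
  hdim <- ncol(Wh) %/% 4L
  dA <- matrix(0, B * L, 4L * hdim)  # gradient at the pre-activation gates
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  dh_carry <- matrix(0, B, hdim)
  dc_carry <- matrix(0, B, hdim)
  for (t in rev(fwd$steps)) {
    cc <- fwd$cache[[t]]
    rows <- seq_rows(B, L, t)
    m <- cc$m
    dh_total <- gH[rows, , drop = FALSE] * m + dh_carry
    # undo the mask carry: hcur = hn*m + hp*(1-m)
    dhn <- dh_total * m
    dh_prev <- dh_total * (1 - m)
    dcn <- dc_carry * m
    dc_prev <- dc_carry * (1 - m)
    # LSTM cell backward
    doo <- dhn * cc$tc
    dtc <- dhn * cc$oo
    dcn <- dcn + dtc * (1 - cc$tc^2)
    dff <- dcn * cc$cp
    dii <- dcn * cc$gg
    dgg <- dcn * cc$ii
    dc_prev <- dc_prev + dcn * cc$ff
    da <- cbind(dii * cc$ii * (1 - cc$ii),
                dff * cc$ff * (1 - cc$ff),
                dgg * (1 - cc$gg^2),
                doo * cc$oo * (1 - cc$oo))
    dA[rows, ] <- da
    dWh <- dWh + crossprod(cc$hp, da)
    dh_prev <- dh_prev + tcrossprod(da, Wh)
    dh_carry <- dh_prev
    dc_carry <- dc_prev
  }
  list(dX = tcrossprod(dA, Wx), dWx = crossprod(X, dA),
       dWh = dWh, db = matrix(colSums(dA), 1L))
}

#' Bidirectional LSTM over flattened padded batches
#'
#' Runs one forward and one reverse LSTM over each sequence and concatenates
#' their per-position hidden states. Padded positions carry state through
#' unchanged and emit zero rows.
#'
#' @param X `pf_tensor` (B*L x d_in).
#' @param mask Logical vector of length B*L.
#' @param Wx_f,Wh_f,b_f Forward-direction weights: (d_in x 4h), (h x 4h), (1 x 4h)
#'   with gate order input, forget, cell, output.
#' @param Wx_b,Wh_b,b_b Reverse-direction weights, same shapes.
#' @param B,L Batch size and padded length.
#' @return `pf_tensor` (B*L x 2h).
#' @export
pf_bilstm <- function(X, mask, Wx_f, Wh_f, b_f, Wx_b, Wh_b, b_b, B, L) {
  X <- as_pf(X)
  Wx_f <- as_pf(Wx_f); Wh_f <- as_pf(Wh_f); b_f <- as_pf(b_f)
  Wx_b <- as_pf(Wx_b); Wh_b <- as_pf(Wh_b); b_b <- as_pf(b_b)
  fwd <- lstm_forward_dir(X$value, mask, Wx_f$value, Wh_f$value, b_f$value,
                          B, L, reverse = FALSE)
  bwd <- lstm_forward_dir(X$value, mask, Wx_b$value, Wh_b$value, b_b$value,
                          B, L, reverse = TRUE)
  v <- cbind(fwd$H, bwd$H)
  hdim <- ncol(fwd$H)
  pf_node(v, list(X, Wx_f, Wh_f, b_f, Wx_b, Wh_b, b_b), function(g) {
    gF <- g[, seq_len(hdim), drop = FALSE]
    gB <- g[, hdim + seq_len(hdim), drop = FALSE]
    bf <- lstm_backward_dir(gF, X$value, mask, Wx_f$value, Wh_f$value,
                            b_f$value, B, L, fwd)
    bb <- lstm_backward_dir(gB, X$value, mask, Wx_b$value, Wh_b$value,
                            b_b$value, B, L, bwd)
    list(bf$dX + bb$dX, bf$dWx, bf$dWh, bf$db, bb$dWx, bb$dWh, bb$db)
  })
}

#' Masked max-pooling over sequence positions
#'
#' @param x `pf_tensor` (B*L x d).
#' @param B,L Batch size and padded length.
#' @param mask Logical vector of length B*L; sequences with no valid position
#'   pool to zero.
#' @return `pf_tensor` (B x d).
#' @export
pf_maxpool_seq <- function(x, B, L, mask) {
  x <- as_pf(x)
  d <- ncol(x$value)
  out <- matrix(0, B, d)
  argmax <- matrix(NA_integer_, B, d)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    vrows <- rows[mask[rows]]
    if (!length(vrows)) next
    sub <- x$value[vrows, , drop = FALSE]
    am <- max.col(t(sub), ties.method = "first")
    out[b, ] <- sub[cbind(am, seq_len(d))]
    argmax[b, ] <- vrows[am]
  }
  pf_node(out, list(x), function(g) {
    dx <- matrix(0, nrow(x$value), d)
    for (b in seq_len(B)) {
      if (is.na(argmax[b, 1L])) next
      idx <- cbind(argmax[b, ], seq_len(d))
      dx[idx] <- dx[idx] + g[b, ]
    }
    list(dx)
  })
}

# index vector for gathering positions shifted by `off` within each sequence;
# out-of-range or masked sources map to 0 (the implicit zero row of pf_rows)
shift_index <- function(B, L, off, mask) {
  t_src <- rep(seq_len(L), B) + off
  base <- rep((seq_len(B) - 1L) * L, each = L)
  ok <- t_src >= 1L & t_src <= L
  idx <- integer(B * L)
  idx[ok] <- base[ok] + t_src[ok]
  idx[idx > 0L & !mask[pmax(idx, 1L)]] <- 0L
  idx
}

#' Multi-width 1-D convolution over flattened padded batches
#'
#' Same-padded convolution implemented as shifted row gathers plus one matrix
#' product per kernel width. Masked positions contribute zeros and emit zeros.
#'
#' @param x `pf_tensor` (B*L x d_in).
#' @param W `pf_tensor` (kernel*d_in x channels), offset-major rows.
#' @param b `pf_tensor` (1 x channels).
#' @param kernel Odd kernel width.
#' @param B,L,mask Batch geometry as elsewhere.
#' @return `pf_tensor` (B*L x channels).
#' @export
pf_conv1d <- function(x, W, b, kernel, B, L, mask) {
  stopifnot(kernel %% 2L == 1L)
  half <- (kernel - 1L) %/% 2L
  cols <- lapply(-half:half, function(off) pf_rows(x, shift_index(B, L, off, mask)))
  im2col <- pf_cbind(cols)
  out <- pf_add(pf_matmul(im2col, W), b)
  pf_mask_rows(out, mask)
}
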