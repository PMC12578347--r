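# Marginal focal dice loss (MFDL) and reference losses for the
# loss-comparison harness.
#
# MFDL pipeline per label-instance entry (i, c): subtract a
# label-distribution-aware margin from the logit, map through a sigmoid,
# form clipped focal-scaled probabilities for the positive and negative
# sides, aggregate each side into a per-class dice component over the batch,
# mix the sides with alpha, weight classes by inverse-sqrt-count weights and
# reduce.  All losses are built as autodiff graphs so the same code yields
# values for evaluation and gradients for training.

#' MFDL hyperparameters
#'
#' @param alpha Mixing weight of the positive dice component in \[0, 1\].
#' @param m_max Maximum margin (and class-weight scale) >= 0.
#' @param p_pos,p_neg Focal exponents (> 0) of the positive/negative dice
#'   denominators.
#' @param clip_pos,clip_neg Clipping increments (>= 0) of the focal
#'   probabilities.
#' @param use_class_weights Apply inverse-sqrt-count class weights?
#' @param reduction `"mean"`, `"sum"` or `"none"` over per-class losses.
#' @export
mfdl_config <- function(alpha = 0.5, m_max = 0.5, p_pos = 2, p_neg = 2,
                        clip_pos = 0.5, clip_neg = 0.5,
                        use_class_weights = TRUE,
                        reduction = c("mean", "sum", "none")) {
  reduction <- match.arg(reduction)
  stopifnot(alpha >= 0, alpha <= 1, m_max >= 0, p_pos > 0, p_neg > 0,
            clip_pos >= 0, clip_neg >= 0)
  structure(list(alpha = alpha, m_max = m_max, p_pos = p_pos, p_neg = p_neg,
                 clip_pos = clip_pos, clip_neg = clip_neg,
                 use_class_weights = isTRUE(use_class_weights),
                 reduction = reduction), class = "pf_mfdl_config")
}

#' Per-class counts, weights and margins
#'
#' Class weights follow the inverse square root of the per-class positive
#' count, normalized by the largest such weight and scaled by `m_max`; with
#' `use_class_weights = FALSE` every class weight is 1. Margins treat each
#' class as a binary sub-problem: the minority side (usually the positives)
#' receives the full margin `m_max` and the majority side the proportionally
#' smaller `m_max * w_majside / w_minside`, shifting the decision boundary
#' in favor of the minority side.
#'
#' A class with no positives (or no negatives) gets its side count smoothed
#' to 1 with a warning.
#'
#' @param label_matrix Binary N x C matrix of training labels.
#' @param config A [mfdl_config()].
#' @return A `pf_class_stats` with `n_pos`, `n_neg`, `w_pos`, `w_neg`,
#'   `w_c`, `margin_pos`, `margin_neg`.
#' @export
compute_class_stats <- function(label_matrix, config = mfdl_config()) {
  if (!all(label_matrix %in% c(0, 1)))
    stop("validation error: labels must be binary")
  n <- nrow(label_matrix)
  n_pos <- colSums(label_matrix)
  n_neg <- n - n_pos
  if (sum(n_pos) == 0) stop("at least one class needs a positive sample")
  if (any(n_pos == 0 | n_neg == 0)) {
    warning("class(es) with an empty side; smoothing count to 1: ",
            paste(which(n_pos == 0 | n_neg == 0), collapse = ","))
  }
  sp <- pmax(n_pos, 1)
  sn <- pmax(n_neg, 1)
  w_pos <- sp^(-0.5)
  w_neg <- sn^(-0.5)
  w_c <- if (config$use_class_weights) {
    config$m_max * w_pos / max(w_pos)
  } else rep(1, length(n_pos))
  w_side_max <- pmax(w_pos, w_neg)
  margin_pos <- config$m_max * w_pos / w_side_max
  margin_neg <- config$m_max * w_neg / w_side_max
  structure(list(n = n, n_pos = n_pos, n_neg = n_neg, w_pos = w_pos,
                 w_neg = w_neg, w_c = w_c, margin_pos = margin_pos,
                 margin_neg = margin_neg), class = "pf_class_stats")
}

# margin matrix: entry (i,c) is margin_pos[c] where y=1, margin_neg[c] where y=0
margin_matrix <- function(Y, stats) {
  Mp <- matrix(stats$margin_pos, nrow(Y), ncol(Y), byrow = TRUE)
  Mn <- matrix(stats$margin_neg, nrow(Y), ncol(Y), byrow = TRUE)
  Mp * Y + Mn * (1 - Y)
}

# build the MFDL graph on a logits node; returns a 1 x C node of per-class
# weighted losses before reduction
mfdl_class_graph <- function(z, Y, stats, config, use_margins = TRUE) {
  eps <- 1e-8
  Yc <- pf_const(Y)
  Yn <- pf_const(1 - Y)
  zm <- if (use_margins && config$m_max > 0) {
    pf_sub(z, pf_const(margin_matrix(Y, stats)))
  } else z
  p <- pf_sigmoid(zm)
  # positive side
  ppos <- pf_mul(pf_mul(pf_pmin_const(pf_addc(p, config$clip_pos), 1), p), Yc)
  num_pos <- pf_colsums(ppos)
  den_pos <- pf_addc(pf_colsums(pf_pow(ppos, config$p_pos)),
                     colSums(Y) + eps)
  has_pos <- matrix(as.numeric(colSums(Y) > 0), 1L)
  L_pos <- pf_mul(pf_sub(pf_const(matrix(1, 1L, ncol(Y))),
                         pf_scale(pf_div(num_pos, den_pos), 2)),
                  pf_const(has_pos))
  # negative side
  q <- pf_addc(pf_scale(p, -1), 1)
  pneg <- pf_mul(pf_mul(pf_pmin_const(pf_addc(q, config$clip_neg), 1), q), Yn)
  num_neg <- pf_colsums(pneg)
  den_neg <- pf_addc(pf_colsums(pf_pow(pneg, config$p_neg)),
                     colSums(1 - Y) + eps)
  has_neg <- matrix(as.numeric(colSums(1 - Y) > 0), 1L)
  L_neg <- pf_mul(pf_sub(pf_const(matrix(1, 1L, ncol(Y))),
                         pf_scale(pf_div(num_neg, den_neg), 2)),
                  pf_const(has_neg))
  mix <- pf_add(pf_scale(L_pos, config$alpha), pf_scale(L_neg, 1 - config$alpha))
  pf_mul(mix, pf_const(matrix(stats$w_c, 1L)))
}

mfdl_graph <- function(z, Y, stats, config, use_margins = TRUE) {
  cls <- mfdl_class_graph(z, Y, stats, config, use_margins)
  switch(config$reduction,
         mean = pf_mean(cls),
         sum = pf_sum(cls),
         none = cls)
}

#' Marginal focal dice loss
#'
#' @param logits Numeric N x C matrix of raw scores.
#' @param labels Binary N x C matrix.
#' @param stats A [compute_class_stats()] result (computed on the training
#'   labels).
#' @param config A [mfdl_config()].
#' @param use_margins Apply the margin adjustment (training-time behaviour;
#'   evaluation typically uses raw logits).
#' @return Scalar loss for reductions `"mean"`/`"sum"`; per-class numeric
#'   vector for `"none"`.
#' @export
mfdl_loss <- function(logits, labels, stats, config = mfdl_config(),
                      use_margins = TRUE) {
  check_loss_inputs(logits, labels)
  node <- mfdl_graph(pf_const(logits), labels, stats, config, use_margins)
  as.numeric(node$value)
}

#' Gradient of the MFDL with respect to the logits
#'
#' @inheritParams mfdl_loss
#' @return Numeric N x C gradient matrix (of the reduced scalar loss; for
#'   reduction `"none"` the per-class losses are summed first).
#' @export
mfdl_grad <- function(logits, labels, stats, config = mfdl_config(),
                      use_margins = TRUE) {
  check_loss_inputs(logits, labels)
  z <- pf_tensor(logits, requires_grad = TRUE)
  node <- mfdl_graph(z, labels, stats, config, use_margins)
  if (config$reduction == "none") node <- pf_sum(node)
  pf_backward(node)
  z$grad
}

check_loss_inputs <- function(logits, labels) {
  if (!all(dim(logits) == dim(labels)))
    stop("shape mismatch between logits and labels")
  if (!all(labels %in% c(0, 1)))
    stop("validation error: labels must be binary")
  invisible(TRUE)
}

# graph builders for the comparator losses ---------------------------------

bce_graph <- function(z, Y, eps = 1e-12) {
  p <- pf_sigmoid(z)
  q <- pf_addc(pf_scale(p, -1), 1)
  ll <- pf_add(pf_mul(pf_log(pf_addc(p, eps)), pf_const(Y)),
               pf_mul(pf_log(pf_addc(q, eps)), pf_const(1 - Y)))
  pf_scale(pf_mean(ll), -1)
}

focal_graph <- function(z, Y, gamma = 2, eps = 1e-12) {
  p <- pf_sigmoid(z)
  q <- pf_addc(pf_scale(p, -1), 1)
  # pt = p where y=1, 1-p where y=0
  pt <- pf_add(pf_mul(p, pf_const(Y)), pf_mul(q, pf_const(1 - Y)))
  onemt <- pf_addc(pf_scale(pt, -1), 1)
  term <- pf_mul(pf_pow(onemt, gamma), pf_log(pf_addc(pt, eps)))
  pf_scale(pf_mean(term), -1)
}

ldam_graph <- function(z, Y, stats, config) {
  zm <- pf_sub(z, pf_const(margin_matrix(Y, stats)))
  bce_graph(zm, Y)
}

asymmetric_graph <- function(z, Y, gamma_pos = 0, gamma_neg = 4,
                             clip = 0.05, eps = 1e-12) {
  p <- pf_sigmoid(z)
  q <- pf_addc(pf_scale(p, -1), 1)
  # shifted negative probability pm = max(p - clip, 0)
  pm <- pf_scale(pf_pmin_const(pf_scale(pf_addc(p, -clip), -1), 0), -1)
  pos <- pf_mul(pf_mul(pf_pow(q, gamma_pos), pf_log(pf_addc(p, eps))),
                pf_const(Y))
  qn <- pf_addc(pf_scale(pm, -1), 1)
  neg <- pf_mul(pf_mul(pf_pow(pm, gamma_neg), pf_log(pf_addc(qn, eps))),
                pf_const(1 - Y))
  pf_scale(pf_mean(pf_add(pos, neg)), -1)
}

loss_graph <- function(variant, z, Y, stats = NULL, config = mfdl_config(),
                       use_margins = TRUE) {
  switch(variant,
    mfdl = mfdl_graph(z, Y, stats, config, use_margins),
    bce = bce_graph(z, Y),
    focal = focal_graph(z, Y),
    mlfdl = {
      cfg <- config
      cfg$m_max <- 0
      cfg$use_class_weights <- FALSE
      # margin-free comparator needs no side counts; silence the
      # empty-side smoothing note its stats computation would emit
      st0 <- suppressWarnings(compute_class_stats(Y, cfg))
      mfdl_graph(z, Y, st0, cfg, use_margins = FALSE)
    },
    ldam_margin = ldam_graph(z, Y, stats, config),
    asymmetric = asymmetric_graph(z, Y),
    stop("config error: unknown loss variant '", variant, "'"))
}

#' Reference losses for the comparison harness
#'
#' `bce` is binary cross-entropy with logits; `focal` the binary focal loss
#' (exponent 2); `mlfdl` the margin-free focal dice loss (MFDL with zero
#' margin and uniform class weights); `ldam_margin` binary cross-entropy on
#' margin-adjusted logits; `asymmetric` the asymmetric loss with negative
#' focusing exponent 4 and probability shift 0.05.
#'
#' @param logits,labels Numeric / binary N x C matrices.
#' @param variant One of `"bce"`, `"focal"`, `"mlfdl"`, `"ldam_margin"`,
#'   `"asymmetric"`.
#' @param stats Class statistics (needed for `ldam_margin`).
#' @param config An [mfdl_config()] (exponents/clips for `mlfdl`).
#' @return Scalar loss value.
#' @export
reference_losses <- function(logits, labels,
                             variant = c("bce", "focal", "mlfdl",
                                         "ldam_margin", "asymmetric"),
                             stats = NULL, config = mfdl_config()) {
  variant <- match.arg(variant)
  check_loss_inputs(logits, labels)
  if (variant == "ldam_margin" && is.null(stats))
    stop("ldam_margin requires class stats")
  node <- loss_graph(variant, pf_const(logits), labels, stats, config)
  val <- as.numeric(node$value)
  if (length(val) > 1L) mean(val) else val
}
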