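# Learnable sigmoid-gated fusion of aligned feature streams.
#
# Each stream i carries one gate vector g_i in R^d shared across positions
# and batch. The effective gate sigma(g_i) lies in (0,1); gated streams are
# averaged, so fusion shrinks but never amplifies its inputs.

#' Initialize gate parameters
#'
#' Gates start uniform in \[-0.1, 0.1\]: every effective gate
#' `sigmoid(g)` is near the neutral value 0.5 while symmetry between
#' streams is broken.
#'
#' @param n_streams Number of feature streams (rows of the gate matrix).
#' @param d Shared fusion dimension.
#' @param seed Integer seed; identical seeds give identical gates.
#' @param stream_order Optional character vector of stream names.
#' @return A `pf_gate_state` with matrix `G` (n_streams x d) and
#'   `stream_order`.
#' @export
init_gates <- function(n_streams, d, seed = 1L, stream_order = NULL) {
  if (n_streams < 1L || d < 1L)
    stop("config error: n_streams and d must be positive")
  G <- local_seed(seed, matrix(stats::runif(n_streams * d, -0.1, 0.1),
                               n_streams, d))
  if (is.null(stream_order)) stream_order <- paste0("stream_", seq_len(n_streams))
  rownames(G) <- stream_order
  structure(list(G = G, stream_order = stream_order), class = "pf_gate_state")
}

#' Initialize per-stream affine projections to the fusion dimension
#'
#' @param native_dims Named integer vector of stream widths.
#' @param d Target dimension.
#' @param seed Integer seed.
#' @return Named list of `list(W, b)` per stream; W uses uniform
#'   Glorot-style initialization.
#' @export
init_projections <- function(native_dims, d, seed = 1L) {
  local_seed(seed, lapply(native_dims, function(nd) {
    r <- sqrt(6 / (nd + d))
    list(W = matrix(stats::runif(nd * d, -r, r), nd, d),
         b = matrix(0, 1L, d))
  }))
}

#' Align feature streams to a common dimension
#'
#' Applies each stream's affine projection `X %*% W + b` and re-applies the
#' shared mask, yielding equal-width streams ready for gated fusion.
#'
#' @param streams List of `pf_feature_stream`s sharing one mask.
#' @param projections List from [init_projections()], same order.
#' @return A `pf_aligned_streams`: list of (max_len x d) matrices plus the
#'   shared `mask`.
#' @export
align_streams <- function(streams, projections) {
  stopifnot(length(streams) == length(projections))
  mask <- streams[[1]]$mask
  for (s in streams) {
    if (!identical(s$mask, mask))
      stop("alignment error: streams carry inconsistent masks")
  }
  aligned <- lapply(seq_along(streams), function(i) {
    p <- projections[[i]]
    v <- streams[[i]]$values %*% p$W
    v <- sweep(v, 2L, as.numeric(p$b), "+")
    v[!mask, ] <- 0
    v
  })
  names(aligned) <- vapply(streams, `[[`, "", "name")
  structure(list(streams = aligned, mask = mask), class = "pf_aligned_streams")
}

#' Sigmoid-gated fusion of aligned streams
#'
#' Each aligned stream is multiplied elementwise by its effective gate
#' `sigmoid(g_i)` (broadcast over positions) and the gated streams are
#' averaged.
#'
#' @param aligned A `pf_aligned_streams` (or plain list of equal-width
#'   matrices).
#' @param gates A [init_gates()] state with one row per stream.
#' @return Fused matrix (max_len x d).
#' @export
gate_fuse <- function(aligned, gates) {
  mats <- if (inherits(aligned, "pf_aligned_streams")) aligned$streams else aligned
  N <- length(mats)
  if (nrow(gates$G) != N)
    stop("fusion error: ", nrow(gates$G), " gate rows for ", N, " streams")
  d <- ncol(mats[[1]])
  if (ncol(gates$G) != d)
    stop("fusion error: gate width ", ncol(gates$G), " != stream width ", d)
  sg <- 1 / (1 + exp(-gates$G))
  out <- matrix(0, nrow(mats[[1]]), d)
  for (i in seq_len(N)) out <- out + sweep(mats[[i]], 2L, sg[i, ], "*")
  out / N
}

#' Export learned gate values for inspection
#'
#' @param gates A `pf_gate_state`.
#' @return data.frame with stream, dimension and effective (sigmoid) gate.
#' @export
gate_table <- function(gates) {
  sg <- 1 / (1 + exp(-gates$G))
  data.frame(stream = rep(gates$stream_order, each = ncol(sg)),
             dimension = rep(seq_len(ncol(sg)), nrow(sg)),
             gate = as.vector(t(sg)))
}
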