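# The eight per-sequence feature streams: sinusoidal positions, five
# physicochemical property encodings with Gaussian-membership fuzzification,
# and the residue chain graph. (The embedding and self-attention streams are
# learned inside the network; their inputs are built here.)

#' Load a per-residue property table
#'
#' Tables ship as plain TSV fixtures (one row per standard residue). The
#' AAindex, PAAC and PC6 tables are column-standardized at load so that all
#' property scales are comparable before fuzzification; the BLOSUM62 matrix
#' is kept verbatim (its log-odds scores are already on a common scale).
#'
#' @param name One of `"AAIndex"`, `"PAAC"`, `"PC6"`, `"BLOSUM62"`.
#' @param path Optional path to a custom table of the same layout (first
#'   column `residue`, remaining columns numeric); the declared dimension
#'   follows the loaded table.
#' @param standardize Override the default standardization choice.
#' @return A `pf_property_table` with fields `name`, `dim` and `rows`
#'   (20 x dim matrix with residue rownames).
#' @export
load_property_table <- function(name = c("AAIndex", "PAAC", "PC6", "BLOSUM62"),
                                path = NULL, standardize = NULL) {
  name <- match.arg(name)
  if (is.null(path)) {
    file <- switch(name, AAIndex = "aaindex_reduced.tsv", PAAC = "paac_props.tsv",
                   PC6 = "pc6.tsv", BLOSUM62 = "blosum62.tsv")
    path <- system.file("extdata", file, package = "pepfusion", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  rows <- as.matrix(tab[, -1, drop = FALSE])
  rownames(rows) <- tab[[1]]
  missing <- setdiff(AA_ALPHABET, rownames(rows))
  if (length(missing))
    stop("property table lacks residue(s): ", paste(missing, collapse = ","))
  rows <- rows[AA_ALPHABET, , drop = FALSE]
  if (!all(is.finite(rows))) stop("property table has non-finite entries")
  if (is.null(standardize)) standardize <- name != "BLOSUM62"
  if (standardize) {
    mu <- colMeans(rows)
    sdv <- apply(rows, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    rows <- sweep(sweep(rows, 2L, mu), 2L, sdv, "/")
  }
  structure(list(name = name, dim = ncol(rows), rows = rows),
            class = "pf_property_table")
}

#' Sinusoidal positional encoding matrix
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i/d_model))` and entry
#' `(pos, 2i+1)` is `cos(pos / 10000^(2i/d_model))`, for positions
#' `0 .. max_len-1` (returned as rows 1..max_len).
#'
#' @param max_len Number of positions.
#' @param d_model Even encoding dimension.
#' @return Numeric matrix (max_len x d_model) with entries in \[-1, 1\].
#' @export
positional_encoding <- function(max_len, d_model) {
  if (max_len < 1L) stop("config error: max_len must be >= 1")
  if (d_model < 2L || d_model %% 2L != 0L)
    stop("config error: d_model must be even and >= 2")
  pos <- 0:(max_len - 1L)
  i <- 0:(d_model %/% 2L - 1L)
  angle <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, max_len, d_model)
  pe[, 2L * i + 1L] <- sin(angle)
  pe[, 2L * i + 2L] <- cos(angle)
  pe
}

new_stream <- function(name, values, mask, native_dim = ncol(values)) {
  values[!mask, ] <- 0
  structure(list(name = name, values = values, mask = mask,
                 native_dim = native_dim), class = "pf_feature_stream")
}

#' Per-position property encoding of a tokenized sequence
#'
#' Row j holds the table row of the residue at position j; masked (padding)
#' positions are all-zero.
#'
#' @param tokens List with `tokens` and `mask` from [tokenize()].
#' @param table A [load_property_table()] result.
#' @return A `pf_feature_stream` (max_len x table$dim).
#' @export
encode_property_stream <- function(tokens, table) {
  tok <- tokens$tokens
  values <- matrix(0, length(tok), table$dim)
  valid <- which(tok > 0L)
  values[valid, ] <- table$rows[tok[valid], , drop = FALSE]
  new_stream(table$name, values, tokens$mask)
}

#' Amino-acid composition
#'
#' @param sequence Character scalar over the 20 standard residues.
#' @return Numeric 20-vector of residue frequencies (sums to 1), ordered as
#'   [AA_ALPHABET].
#' @export
encode_aac <- function(sequence) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("length error: empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx))
    stop("residue error: non-standard residue(s) ",
         paste(unique(chars[is.na(idx)]), collapse = ","))
  counts <- tabulate(idx, nbins = 20L)
  stats::setNames(counts / length(chars), AA_ALPHABET)
}

#' Gaussian-membership fuzzifier parameters
#'
#' @param centers,widths Numeric vectors, one entry per feature dimension;
#'   all widths must be positive.
#' @param trainable Whether the parameters are trained end-to-end when used
#'   inside a model.
#' @export
fuzzifier_params <- function(centers, widths, trainable = TRUE) {
  if (length(centers) != length(widths))
    stop("centers and widths must have equal length")
  if (any(widths <= 0)) stop("parameter error: widths must be positive")
  structure(list(centers = as.numeric(centers), widths = as.numeric(widths),
                 trainable = isTRUE(trainable)), class = "pf_fuzzifier")
}

#' Gaussian-membership fuzzification of a feature stream
#'
#' Each entry x of dimension k becomes `exp(-(x - c_k)^2 / (2 s_k^2))`,
#' mapping crisp standardized features to soft membership degrees in (0, 1].
#' The sequence mask is re-applied afterwards, so masked rows stay zero.
#'
#' @param stream A `pf_feature_stream` (or plain matrix plus `mask`).
#' @param params A [fuzzifier_params()] whose length equals the stream width.
#' @param mask Logical mask when `stream` is a plain matrix.
#' @return Object of the same kind as `stream`.
#' @export
gmf_fuzzify <- function(stream, params, mask = NULL) {
  is_stream <- inherits(stream, "pf_feature_stream")
  values <- if (is_stream) stream$values else stream
  if (is_stream) mask <- stream$mask
  if (length(params$centers) != ncol(values))
    stop("parameter error: fuzzifier length ", length(params$centers),
         " does not match stream width ", ncol(values))
  z <- sweep(values, 2L, params$centers)
  out <- exp(-sweep(z^2, 2L, 2 * params$widths^2, "/"))
  if (!is.null(mask)) out[!mask, ] <- 0
  if (is_stream) new_stream(stream$name, out, mask) else out
}

#' Residue chain graph of a tokenized sequence
#'
#' Path graph over the valid (unmasked) positions: each residue is connected
#' bidirectionally to its sequence neighbours. Positions are 0-based.
#'
#' @param tokens List with `tokens` and `mask` from [tokenize()].
#' @return A `pf_chain_graph` with `n_nodes` and an `edges` matrix (two
#'   columns, one directed edge per row; symmetric pairs).
#' @export
build_chain_graph <- function(tokens) {
  n <- sum(tokens$mask)
  if (n == 0L) stop("empty-graph error: sequence has no valid positions")
  if (n == 1L) {
    edges <- matrix(integer(0), 0L, 2L)
  } else {
    fwd <- cbind(0:(n - 2L), 1:(n - 1L))
    edges <- rbind(fwd, fwd[, 2:1, drop = FALSE])
  }
  colnames(edges) <- c("from", "to")
  structure(list(n_nodes = n, edges = edges), class = "pf_chain_graph")
}

#' Adjacency matrix of a chain graph
#'
#' @param graph A [build_chain_graph()] result.
#' @param size Optional padded size (>= n_nodes); extra rows/cols are zero.
#' @return Symmetric 0/1 matrix.
#' @export
chain_adjacency <- function(graph, size = graph$n_nodes) {
  A <- matrix(0L, size, size)
  if (nrow(graph$edges)) A[graph$edges + 1L] <- 1L
  A
}
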