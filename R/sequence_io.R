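# Multi-label peptide records, the labeled-FASTA dialect, tokenization and
# dataset splitting.

#' The 20 standard amino acids in alphabetical one-letter order
#'
#' Token `r` of the integer encoding is the r-th residue of this string
#' (A = 1, C = 2, ..., Y = 20); 0 is reserved for padding.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

NONSTANDARD_AA <- c("B", "J", "O", "U", "X", "Z")

#' Construct a label space
#'
#' An ordered, immutable set of functional category names. The order fixes
#' the column order of every label matrix for the lifetime of a run.
#'
#' @param names Character vector of unique category identifiers.
#' @return A `pf_label_space` with fields `names` and `size`.
#' @export
label_space <- function(names = default_label_space()$names) {
  names <- as.character(names)
  if (length(names) < 1L) stop("label space needs at least one category")
  if (anyDuplicated(names)) stop("label names must be unique")
  structure(list(names = names, size = length(names)), class = "pf_label_space")
}

#' Default 21-category therapeutic-peptide label space
#'
#' Anti-microbial (AMP) through tumor-homing (THP) peptides, the 21
#' functional classes of the standard multi-functional therapeutic peptide
#' benchmark.
#' @export
default_label_space <- function() {
  structure(list(
    names = c("AMP", "ABP", "ACP", "ACVP", "ADP", "AEP", "AFP", "AHIVP",
              "AHP", "AIP", "AMRSAP", "APP", "ATP", "AVP", "BBP", "BIP",
              "CPP", "DPPIP", "QSP", "SBP", "THP"),
    size = 21L), class = "pf_label_space")
}

#' Build a peptide record table
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of amino-acid sequences (upper-cased).
#' @param labels List of character vectors, one label subset per record.
#' @return data.frame with columns `id`, `sequence` and list-column `labels`.
#' @export
peptide_records <- function(id, sequence, labels = NULL) {
  if (is.null(labels)) labels <- rep(list(character(0)), length(id))
  stopifnot(length(id) == length(sequence), length(id) == length(labels))
  out <- data.frame(id = as.character(id), sequence = toupper(sequence),
                    stringsAsFactors = FALSE)
  out$labels <- lapply(labels, as.character)
  class(out) <- c("pf_records", "data.frame")
  out
}

# run code with a private RNG stream, restoring the caller's state
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Read the multi-label FASTA dialect
#'
#' Headers have the form `>id|LAB1,LAB2`; the label field may be empty (or
#' the `|` absent) only when `prediction_mode = TRUE`. Sequence lines up to
#' the next header are concatenated and upper-cased.
#'
#' Records whose sequence violates the residue policy or the length bounds
#' are rejected; their ids, line numbers and reasons are reported in a
#' warning and attached as attribute `"rejected"`.
#'
#' @param path Path to the FASTA file.
#' @param labels A [label_space()].
#' @param policy `"strict"` rejects sequences containing residues outside the
#'   20 standard amino acids; `"mask"` keeps them (such residues later map to
#'   padding token 0 with mask FALSE).
#' @param prediction_mode Allow records without labels.
#' @param min_len,max_len Accepted sequence length bounds.
#' @return A `pf_records` data.frame in file order.
#' @export
read_labeled_fasta <- function(path, labels = default_label_space(),
                               policy = c("strict", "mask"),
                               prediction_mode = FALSE,
                               min_len = 5L, max_len = 50L) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_at <- grep("^>", lines)
  if (!length(hdr_at)) stop("parse error: no FASTA header ('>') found in ", path)
  if (hdr_at[1] > 1 && any(nzchar(trimws(lines[seq_len(hdr_at[1] - 1)]))))
    stop("parse error at line 1: sequence data before first header")

  ids <- character(0); seqs <- character(0); labs <- list(); lineno <- integer(0)
  rejected <- data.frame(id = character(0), line = integer(0),
                         reason = character(0), stringsAsFactors = FALSE)
  n <- length(hdr_at)
  ends <- c(hdr_at[-1] - 1L, length(lines))
  for (k in seq_len(n)) {
    ln <- hdr_at[k]
    header <- sub("^>", "", lines[ln])
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    id <- trimws(parts[1])
    if (!nzchar(id))
      stop("parse error at line ", ln, ": empty identifier in header")
    lab_field <- if (length(parts) >= 2L) trimws(parts[2]) else ""
    rec_labels <- if (nzchar(lab_field)) trimws(strsplit(lab_field, ",")[[1]]) else character(0)
    unknown <- setdiff(rec_labels, labels$names)
    if (length(unknown))
      stop("validation error at line ", ln, ": unknown label(s) ",
           paste(unknown, collapse = ", "))
    if (!length(rec_labels) && !prediction_mode)
      stop("validation error at line ", ln, ": record '", id,
           "' has no labels (only allowed in prediction mode)")
    body <- lines[(ln + 1L):ends[k]]
    seq <- toupper(gsub("[[:space:]]", "", paste(body, collapse = "")))
    bad <- setdiff(strsplit(seq, "")[[1]], AA_ALPHABET)
    reason <- NULL
    if (length(bad) && policy == "strict") {
      reason <- paste0("non-standard residue(s) ", paste(unique(bad), collapse = ","))
    } else if (nchar(seq) < min_len || nchar(seq) > max_len) {
      reason <- paste0("length ", nchar(seq), " outside [", min_len, ",", max_len, "]")
    }
    if (!is.null(reason)) {
      rejected <- rbind(rejected, data.frame(id = id, line = ln, reason = reason,
                                             stringsAsFactors = FALSE))
      next
    }
    ids <- c(ids, id); seqs <- c(seqs, seq)
    labs[[length(labs) + 1L]] <- rec_labels
    lineno <- c(lineno, ln)
  }
  if (nrow(rejected)) {
    warning("rejected ", nrow(rejected), " record(s): ",
            paste(sprintf("%s (line %d: %s)", rejected$id, rejected$line,
                          rejected$reason), collapse = "; "))
  }
  out <- peptide_records(ids, seqs, labs)
  attr(out, "rejected") <- rejected
  out
}

#' Write records in the multi-label FASTA dialect
#'
#' @param records A `pf_records` data.frame.
#' @param path Output path.
#' @export
write_labeled_fasta <- function(records, path) {
  headers <- sprintf(">%s|%s", records$id,
                     vapply(records$labels, paste, "", collapse = ","))
  writeLines(as.vector(rbind(headers, records$sequence)), path)
  invisible(path)
}

#' Integer-encode and pad one sequence
#'
#' Residue r maps to its alphabetical rank among the 20 standard amino acids
#' (A = 1, ..., Y = 20); positions beyond the sequence are padded with token
#' 0 and mask FALSE.
#'
#' @param sequence Character scalar.
#' @param max_len Padded length (default 50).
#' @param length_policy `"reject"` errors on sequences longer than `max_len`;
#'   `"truncate"` keeps the first `max_len` residues with a warning.
#' @param residue_policy `"strict"` errors on non-standard residues; `"mask"`
#'   maps them to token 0 with mask FALSE.
#' @return List with integer `tokens` and logical `mask`, both length `max_len`.
#' @export
tokenize <- function(sequence, max_len = 50L,
                     length_policy = c("reject", "truncate"),
                     residue_policy = c("strict", "mask")) {
  length_policy <- match.arg(length_policy)
  residue_policy <- match.arg(residue_policy)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("length error: empty sequence")
  if (nchar(sequence) > max_len) {
    if (length_policy == "reject")
      stop("length error: sequence of length ", nchar(sequence),
           " exceeds max_len = ", max_len)
    warning("truncating sequence to ", max_len, " residues")
    sequence <- substr(sequence, 1L, max_len)
  }
  chars <- strsplit(sequence, "")[[1]]
  tok <- match(chars, AA_ALPHABET)
  if (anyNA(tok)) {
    if (residue_policy == "strict")
      stop("residue error: non-standard residue(s) ",
           paste(unique(chars[is.na(tok)]), collapse = ","))
    tok[is.na(tok)] <- 0L
  }
  tokens <- integer(max_len)
  tokens[seq_along(tok)] <- tok
  mask <- tokens != 0L
  list(tokens = tokens, mask = mask)
}

#' Tokenize a batch of records into matrices
#'
#' @param records `pf_records` data.frame or character vector of sequences.
#' @inheritParams tokenize
#' @return List with integer matrix `tokens` (n x max_len) and logical matrix
#'   `mask` of the same shape.
#' @export
tokenize_batch <- function(records, max_len = 50L,
                           residue_policy = c("strict", "mask")) {
  residue_policy <- match.arg(residue_policy)
  seqs <- if (is.character(records)) records else records$sequence
  toks <- lapply(seqs, tokenize, max_len = max_len,
                 residue_policy = residue_policy)
  list(tokens = do.call(rbind, lapply(toks, `[[`, "tokens")),
       mask = do.call(rbind, lapply(toks, `[[`, "mask")))
}

#' Label subsets to a binary matrix
#'
#' @param records `pf_records` data.frame (or list of label subsets).
#' @param labels A [label_space()].
#' @return Integer matrix (n x labels$size), column order `labels$names`.
#' @export
label_matrix <- function(records, labels = default_label_space()) {
  sets <- if (is.data.frame(records)) records$labels else records
  Y <- matrix(0L, length(sets), labels$size,
              dimnames = list(NULL, labels$names))
  for (i in seq_along(sets)) Y[i, match(sets[[i]], labels$names)] <- 1L
  Y
}

#' Random train/test split
#'
#' @param records `pf_records` data.frame.
#' @param fraction Train fraction in (0, 1); the train set gets
#'   `floor(fraction * n)` records.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(records, fraction, seed) {
  n <- nrow(records)
  if (n < 1L) stop("no records to split")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("config error: fraction must lie strictly in (0, 1)")
  n_train <- floor(fraction * n)
  idx <- local_seed(seed, sample.int(n, n_train))
  list(train = records[sort(idx), , drop = FALSE],
       test = records[setdiff(seq_len(n), idx), , drop = FALSE])
}
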