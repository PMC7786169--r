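# Dictionary of tools and the fixed-length vector encodings consumed by the
# network: a tool sequence becomes a length-25 integer vector (indices, then
# trailing zeros) and a label set becomes a multi-hot bit vector over the
# vocabulary. Index 0 is reserved for padding and never assigned to a tool.

#' Build the tool vocabulary
#'
#' Assigns indices 1..V to every canonical tool id appearing in any
#' subsequence or label set, in lexicographic (C-locale) order so rebuilding
#' from the same corpus always yields the identical mapping. Index 0 is
#' reserved for sequence padding.
#'
#' @param samples Non-empty list of `training_sample` objects.
#' @return A `tool_vocabulary`: list with `index_of` (named integer vector),
#'   `id_of` (character vector, position = index) and `size`.
#' @export
build_vocabulary <- function(samples) {
  if (length(samples) == 0L) stop("empty corpus", call. = FALSE)
  tools <- unique(unlist(lapply(samples, function(s)
    c(s$subsequence, s$shared_labels, s$nonshared_labels))))
  tools <- sort(tools, method = "radix")
  index_of <- seq_along(tools)
  names(index_of) <- tools
  structure(list(index_of = index_of, id_of = tools, size = length(tools)),
            class = "tool_vocabulary")
}

#' @export
print.tool_vocabulary <- function(x, ...) {
  cat(sprintf("<tool_vocabulary> %d tools (index 0 = padding)\n", x$size))
  invisible(x)
}

vocab_lookup <- function(vocab, ids, what = "tool") {
  idx <- vocab$index_of[ids]
  if (anyNA(idx)) {
    stop(sprintf("unknown %s: %s", what,
                 paste(ids[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  unname(idx)
}

#' Encode a tool sequence as a fixed-length index vector
#'
#' Replaces each tool by its dictionary index, preserving order, and pads
#' with trailing zeros to length `max_len` (e.g. indices 12, 6, 75 become
#' `[12, 6, 75, 0, ..., 0]`).
#'
#' @param seq Character vector of tool ids (may be empty), at most `max_len`.
#' @param vocab A `tool_vocabulary`.
#' @param max_len Encoded length (default 25).
#' @return Integer vector of length `max_len`.
#' @export
encode_sequence <- function(seq, vocab, max_len = 25L) {
  n <- length(seq)
  if (n > max_len) {
    stop(sprintf("sequence of %d tools exceeds max_len = %d", n, max_len),
         call. = FALSE)
  }
  out <- integer(max_len)
  if (n > 0L) out[seq_len(n)] <- vocab_lookup(vocab, seq)
  out
}

#' Decode an index vector back to tool ids
#'
#' Inverse of [encode_sequence()]: drops the zero padding and maps indices
#' back through the dictionary.
#'
#' @param encoded Integer vector with non-zero indices before the padding.
#' @param vocab A `tool_vocabulary`.
#' @return Character vector of tool ids.
#' @export
decode_sequence <- function(encoded, vocab) {
  idx <- encoded[encoded != 0L]
  if (any(idx < 1L | idx > vocab$size)) {
    stop("index outside vocabulary", call. = FALSE)
  }
  vocab$id_of[idx]
}

#' Encode a label set as a multi-hot bit vector
#'
#' @param labels Character vector of tool ids (possibly empty).
#' @param vocab A `tool_vocabulary`.
#' @return Integer 0/1 vector of length `vocab$size` with ones at the
#'   labels' positions (index i at position i).
#' @export
encode_labels <- function(labels, vocab) {
  out <- integer(vocab$size)
  if (length(labels) > 0L) {
    out[vocab_lookup(vocab, unique(labels), "label")] <- 1L
  }
  out
}

#' Encode a sample list as network-ready matrices
#'
#' Stacks the per-sample encodings into an `encoded_dataset`: an
#' N x `max_len` integer matrix of subsequences and three N x V bit
#' matrices of labels (shared, non-shared, and their elementwise union —
#' the combined matrix the loss is trained on).
#'
#' @param samples List of `training_sample` objects.
#' @param vocab A `tool_vocabulary`.
#' @param max_len Encoded sequence length (default 25).
#' @return An `encoded_dataset`: list with `sequences`, `shared_labels`,
#'   `nonshared_labels`, `combined_labels`, `vocab_size`, `max_len`.
#' @export
encode_dataset <- function(samples, vocab, max_len = 25L) {
  n <- length(samples)
  sequences <- matrix(0L, nrow = n, ncol = max_len)
  shared <- matrix(0L, nrow = n, ncol = vocab$size)
  nonshared <- matrix(0L, nrow = n, ncol = vocab$size)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    sequences[i, ] <- encode_sequence(s$subsequence, vocab, max_len)
    shared[i, ] <- encode_labels(s$shared_labels, vocab)
    nonshared[i, ] <- encode_labels(s$nonshared_labels, vocab)
  }
  combined <- pmax(shared, nonshared)
  if (n > 0L && any(rowSums(combined) == 0L)) {
    stop("every sample must carry at least one label", call. = FALSE)
  }
  structure(list(sequences = sequences, shared_labels = shared,
                 nonshared_labels = nonshared, combined_labels = combined,
                 vocab_size = vocab$size, max_len = max_len),
            class = "encoded_dataset")
}
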