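# Class-balanced batch construction. Raw label frequencies in workflow
# corpora are heavily skewed; batches are therefore drawn by two-stage
# uniform sampling — first a label tool uniformly from the set of last
# tools, then a training sequence uniformly from the sequences carrying that
# label — which flattens the label distribution seen by the network.

#' Build the last-tool index over training samples
#'
#' For every tool that occurs as a label ("last tool" of a fragment) in the
#' training data, records the positions of all training samples carrying it.
#' Multi-label samples are indexed under every one of their labels.
#'
#' @param train Non-empty list of `training_sample` objects.
#' @param vocab A `tool_vocabulary`.
#' @return A `last_tool_index`: list with `sample_ids_of` (named list,
#'   name = label tool index as character, value = integer sample positions)
#'   and `n_samples`.
#' @export
build_last_tool_index <- function(train, vocab) {
  if (length(train) == 0L) stop("empty training set", call. = FALSE)
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(train)) {
    s <- train[[i]]
    labels <- c(s$shared_labels, s$nonshared_labels)
    for (idx in vocab_lookup(vocab, labels, "label")) {
      key <- as.character(idx)
      assign(key, c(get0(key, envir = acc, ifnotfound = integer(0)), i),
             envir = acc)
    }
  }
  keys <- sort(as.integer(ls(acc)))
  sample_ids_of <- lapply(as.character(keys), get, envir = acc)
  names(sample_ids_of) <- as.character(keys)
  structure(list(sample_ids_of = sample_ids_of, n_samples = length(train)),
            class = "last_tool_index")
}

#' Draw one epoch of class-balanced batches
#'
#' Yields `floor(n_samples / batch_size)` batches (e.g. 2,000 training
#' sequences with batch size 100 give 20 batches). Each batch element is
#' drawn by the two-stage rule: a label tool uniformly from the index keys,
#' then a sample uniformly from that tool's list. Sampling is with
#' replacement across the epoch, so rare labels are oversampled relative to
#' their raw frequency. Deterministic for a fixed seed.
#'
#' @param index A `last_tool_index`.
#' @param n_samples Training-set size driving the batch count.
#' @param batch_size Sequences per batch (>= 1, <= `n_samples`).
#' @param rng_seed Integer seed.
#' @return List of integer vectors of sample positions, each of length
#'   `batch_size`. Attribute `"label_draws"` records the label tool index
#'   drawn for every element (used to audit sampling flatness).
#' @export
sample_epoch_batches <- function(index, n_samples, batch_size, rng_seed = 1L) {
  stopifnot(batch_size >= 1L, n_samples >= batch_size)
  keys <- names(index$sample_ids_of)
  if (length(keys) == 0L) stop("empty last-tool index", call. = FALSE)
  n_batches <- n_samples %/% batch_size
  with_seed(rng_seed, {
    label_draws <- sample(keys, n_batches * batch_size, replace = TRUE)
    ids <- vapply(label_draws, function(k) {
      members <- index$sample_ids_of[[k]]
      members[sample.int(length(members), 1L)]
    }, integer(1), USE.NAMES = FALSE)
    batches <- split(ids, rep(seq_len(n_batches), each = batch_size))
    names(batches) <- NULL
    structure(batches, label_draws = as.integer(label_draws))
  })
}
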