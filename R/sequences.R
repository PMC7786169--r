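# Decomposition of workflow DAGs into tool sequences. Every contiguous
# directed subpath of length >= 2 becomes a fragment; the fragment's last
# tool is the label of the preceding subsequence, so one subsequence
# accumulates multiple labels across the corpus (multi-label). Labels carry
# the provenance of the workflows they came from: shared (published,
# non-deleted, non-erroneous) or non-shared, with shared taking precedence.

SEQ_SEP <- "\x1f"

seq_key <- function(ids) paste(ids, collapse = SEQ_SEP)
key_to_seq <- function(key) strsplit(key, SEQ_SEP, fixed = TRUE)[[1L]]

#' Enumerate tool-sequence paths of a workflow graph
#'
#' Returns every contiguous directed subpath with at least 2 tools — i.e.
#' every length-\eqn{\ge 2} contiguous fragment of every source-to-sink path.
#' Duplicate id lists (the same tools reached along different branches) are
#' collapsed. Fragmenting a workflow this way exposes higher-order
#' dependencies: a fragment's last tool is conditioned on *all* prior tools
#' in the fragment, not only its immediate predecessor.
#'
#' @param graph A `workflow_graph`.
#' @return List of character vectors, each a path of canonical tool ids.
#' @export
enumerate_paths <- function(graph) {
  stopifnot(inherits(graph, "workflow_graph"))
  edges <- graph$edges
  if (nrow(edges) == 0L) return(list())
  if (!graph_is_acyclic(edges)) {
    stop("workflow graph contains a cycle", call. = FALSE)
  }
  succ <- split(edges$child_tool, edges$parent_tool)
  paths <- new.env(parent = emptyenv())
  extend <- function(path) {
    tail_tool <- path[length(path)]
    if (length(path) >= 2L) assign(seq_key(path), path, envir = paths)
    for (nxt in succ[[tail_tool]]) extend(c(path, nxt))
  }
  for (start in unique(edges$parent_tool)) extend(start)
  out <- as.list(paths)
  unname(out[order(names(out), method = "radix")])
}

#' Extract multi-label training samples from a workflow corpus
#'
#' For each enumerated path of length \eqn{n \le} `max_len`, the first
#' \eqn{n-1} tools form the subsequence and the \eqn{n}-th tool is one of its
#' labels; longer paths are discarded. Labels are pooled corpus-wide per
#' unique subsequence. A label enters the shared set if any contributing
#' workflow is shared, otherwise the non-shared set; a label seen in both
#' provenances is kept only as shared (shared precedence).
#'
#' @param graphs List of `workflow_graph` objects.
#' @param max_len Maximum path length retained (default 25), so subsequences
#'   have at most `max_len - 1` tools.
#' @return List of `training_sample` objects with fields `subsequence`
#'   (character vector), `shared_labels` and `nonshared_labels` (character
#'   vectors, disjoint, jointly non-empty).
#' @export
extract_samples <- function(graphs, max_len = 25L) {
  stopifnot(max_len >= 2L)
  shared_pool <- new.env(parent = emptyenv())
  nonshared_pool <- new.env(parent = emptyenv())
  add <- function(pool, key, label) {
    assign(key, union(get0(key, envir = pool, ifnotfound = character(0)),
                      label), envir = pool)
  }
  for (g in graphs) {
    pool <- if (isTRUE(g$is_shared)) shared_pool else nonshared_pool
    for (path in enumerate_paths(g)) {
      n <- length(path)
      if (n > max_len) next
      add(pool, seq_key(path[-n]), path[n])
    }
  }
  keys <- sort(union(ls(shared_pool), ls(nonshared_pool)), method = "radix")
  lapply(keys, function(key) {
    shared <- get0(key, envir = shared_pool, ifnotfound = character(0))
    nonshared <- setdiff(
      get0(key, envir = nonshared_pool, ifnotfound = character(0)), shared
    )
    structure(
      list(subsequence = key_to_seq(key),
           shared_labels = sort(shared, method = "radix"),
           nonshared_labels = sort(nonshared, method = "radix")),
      class = "training_sample"
    )
  })
}

#' @export
print.training_sample <- function(x, ...) {
  cat(sprintf("<training_sample> %s -> shared {%s} non-shared {%s}\n",
              paste(x$subsequence, collapse = " > "),
              paste(x$shared_labels, collapse = ", "),
              paste(x$nonshared_labels, collapse = ", ")))
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Split samples into training and test partitions
#'
#' Uniform random split over unique samples; a subsequence never appears in
#' both partitions, which prevents label leakage between training and
#' evaluation. Deterministic for a fixed seed.
#'
#' @param samples List of `training_sample` objects (at least 2).
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer RNG seed.
#' @return List with elements `train`, `test` (lists of samples) and `seed`.
#' @export
split_train_test <- function(samples, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples to split", call. = FALSE)
  n_train <- as.integer(floor(fraction * n + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = samples[sort(idx)], test = samples[-sort(idx)], seed = seed)
}

#' Export training samples as TSV
#'
#' One row per sample: the subsequence and each label set as comma-joined
#' canonical tool ids.
#'
#' @param samples List of `training_sample` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_samples_tsv <- function(samples, path) {
  out <- data.frame(
    subsequence = vapply(samples, function(s)
      paste(s$subsequence, collapse = ","), character(1)),
    shared_labels = vapply(samples, function(s)
      paste(s$shared_labels, collapse = ","), character(1)),
    nonshared_labels = vapply(samples, function(s)
      paste(s$nonshared_labels, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
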