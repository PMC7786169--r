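# Independent oracles and fixture builders used across the suite. These
# deliberately use different algorithms from the package implementation.

# Kahn topological sort: TRUE iff the edge set is acyclic.
kahn_acyclic <- function(edges) {
  nodes <- unique(c(edges$parent_tool, edges$child_tool))
  if (length(nodes) == 0L) return(TRUE)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in edges$child_tool) indeg[v] <- indeg[v] + 1L
  queue <- names(indeg)[indeg == 0L]
  removed <- 0L
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]; removed <- removed + 1L
    for (v in edges$child_tool[edges$parent_tool == u]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) queue <- c(queue, v)
    }
  }
  removed == length(nodes)
}

# Brute-force fragment enumeration: list all maximal source-to-sink paths,
# then every contiguous window of length >= 2, deduplicated.
brute_subpaths <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  children <- split(edges$child_tool, edges$parent_tool)
  sources <- setdiff(edges$parent_tool, edges$child_tool)
  maximal <- list()
  walk <- function(path) {
    succ <- children[[path[length(path)]]]
    if (is.null(succ)) {
      maximal[[length(maximal) + 1L]] <<- path
    } else {
      for (v in succ) walk(c(path, v))
    }
  }
  for (s in sources) walk(s)
  frags <- character(0)
  for (p in maximal) {
    n <- length(p)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        frags <- c(frags, paste(p[i:j], collapse = "\x1f"))
      }
    }
  }
  sort(unique(frags))
}

# Brute-force sample pooling: fragments -> (subsequence, label, shared) rows.
brute_samples <- function(graphs, max_len = 25L) {
  shared <- list(); nonshared <- list()
  for (g in graphs) {
    for (key in brute_subpaths(g$edges)) {
      p <- strsplit(key, "\x1f", fixed = TRUE)[[1L]]
      if (length(p) > max_len) next
      sub <- paste(p[-length(p)], collapse = "\x1f")
      lab <- p[length(p)]
      if (isTRUE(g$is_shared)) shared[[sub]] <- union(shared[[sub]], lab)
      else nonshared[[sub]] <- union(nonshared[[sub]], lab)
    }
  }
  keys <- sort(union(names(shared), names(nonshared)))
  lapply(stats::setNames(keys, keys), function(k) {
    s <- shared[[k]]
    if (is.null(s)) s <- character(0)
    ns <- setdiff(nonshared[[k]], s)
    if (is.null(ns)) ns <- character(0)
    list(shared = sort(s), nonshared = sort(ns))
  })
}

# Random DAG on n nodes: edges only from lower to higher node index.
random_dag <- function(n_nodes, p_edge = 0.3) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(parent_tool = nodes[pairs[keep, 1L]],
                      child_tool = nodes[pairs[keep, 2L]],
                      stringsAsFactors = FALSE)
  edges
}

# Scalar reference implementation of the weighted cross-entropy.
scalar_wbce <- function(p_true, p_pred, w, eps = 1e-7) {
  total <- 0
  for (i in seq_along(p_true)) {
    p <- min(max(p_pred[i], eps), 1 - eps)
    total <- total + (p_true[i] * log(p) + (1 - p_true[i]) * log(1 - p)) * w[i]
  }
  -total / length(p_true)
}

# Construct a workflow_graph without going through a file.
wf_graph <- function(edges, id = "w1", shared = TRUE) {
  ns <- asNamespace("toolrec")
  get("new_workflow_graph", ns)(
    id,
    data.frame(parent_tool = vapply(edges, `[`, character(1), 1L),
               child_tool = vapply(edges, `[`, character(1), 2L),
               stringsAsFactors = FALSE),
    shared
  )
}

# Construct a training_sample directly.
ts <- function(subsequence, shared = character(0), nonshared = character(0)) {
  structure(list(subsequence = subsequence,
                 shared_labels = shared, nonshared_labels = nonshared),
            class = "training_sample")
}

# Vocabulary over explicitly supplied tool ids (sorted, indices 1..V).
vocab_of <- function(tools) {
  build_vocabulary(list(ts(tools[1], shared = tools)))
}

# A small trained-ish model whose scores depend only on the dense bias:
# zeroing all parameters except bd makes every query score sigmoid(bd).
bias_model <- function(vocab, bias, config = model_config(
    embedding_dim = 4, gru_units = 4, dropout_embed = 0, dropout_between = 0,
    dropout_out = 0, batch_size = 4, epochs = 1), shared_tools = NULL) {
  m <- build_model(config, vocab, shared_tools = shared_tools)
  m$params <- lapply(m$params, function(p) p * 0)
  m$params$bd <- bias
  m$trained <- TRUE
  m
}

# Connection-table TSV writer for handcrafted rows.
write_conn_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "workflow_id\tparent_tool\tchild_tool\tpublished\tdeleted\thas_errors"
  writeLines(c(header, rows), path)
  path
}

write_usage_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("tool_id\tmonth\tcount", rows), path)
  path
}
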