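# Seeded synthetic workflow corpora with exactly known next-tool ground
# truth. Tools are partitioned into layers and a fixed sparse successor map
# is drawn once (each tool feeds at most `fanout` tools of the next layer);
# workflows are random walks through that map with random branch points, so
# every generated graph is acyclic by construction and every edge (u, v)
# satisfies v in ground_truth[[u]]. Monthly usage series with
# constant / increasing / decreasing / bursty trends emulate real tool-usage
# patterns.

#' Specification of a layered tool-compatibility grammar
#'
#' @param n_tools Total number of tools (>= `n_layers`).
#' @param n_layers Number of layers (>= 2; edges only go to the next layer).
#' @param fanout Maximum successors per tool (>= 1).
#' @param p_shared Probability that a generated workflow is shared
#'   (published, non-deleted, non-erroneous). Default 0.2: published
#'   workflows are a minority on public workflow servers.
#' @param n_workflows Number of workflows to generate.
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @param p_branch Probability that a walk forks at a tool with several
#'   successors (default 0.25).
#' @param tool_prefix Prefix of generated tool ids (default `"tool"`),
#'   useful for building disjoint sub-grammars.
#' @return A `grammar_spec`.
#' @export
grammar_spec <- function(n_tools = 40L, n_layers = 5L, fanout = 2L,
                         p_shared = 0.2, n_workflows = 400L, seed = 1L,
                         p_branch = 0.25, tool_prefix = "tool") {
  stopifnot(n_tools >= n_layers, n_layers >= 2L, fanout >= 1L,
            p_shared >= 0, p_shared <= 1, n_workflows >= 1L,
            p_branch >= 0, p_branch <= 1)
  structure(list(n_tools = as.integer(n_tools),
                 n_layers = as.integer(n_layers),
                 fanout = as.integer(fanout), p_shared = p_shared,
                 n_workflows = as.integer(n_workflows),
                 seed = as.integer(seed), p_branch = p_branch,
                 tool_prefix = tool_prefix),
            class = "grammar_spec")
}

resample <- function(x, size) x[sample.int(length(x), size)]

#' Generate a synthetic workflow corpus
#'
#' Draws the layered successor map once, then generates `n_workflows`
#' workflows as random walks from a first-layer tool to the last layer,
#' forking with probability `p_branch` at tools with multiple successors.
#' Each workflow is flagged shared with probability `p_shared`.
#'
#' @param spec A `grammar_spec`.
#' @return List with `graphs` (list of `workflow_graph`), `ground_truth`
#'   (named list: tool -> character vector of its allowed successors) and
#'   `layers` (list of per-layer tool ids).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "grammar_spec"))
  with_seed(spec$seed, {
    tools <- sprintf("%s_%03d", spec$tool_prefix, seq_len(spec$n_tools))
    layer_id <- sort(rep_len(seq_len(spec$n_layers), spec$n_tools))
    layers <- split(tools, layer_id)
    ground_truth <- list()
    for (l in seq_len(spec$n_layers - 1L)) {
      nxt <- layers[[l + 1L]]
      for (tool in layers[[l]]) {
        k <- min(spec$fanout, length(nxt))
        ground_truth[[tool]] <- sort(resample(nxt, k))
      }
    }
    graphs <- vector("list", spec$n_workflows)
    for (i in seq_len(spec$n_workflows)) {
      active <- resample(layers[[1L]], 1L)
      parents <- character(0)
      children <- character(0)
      while (length(active) > 0L) {
        next_active <- character(0)
        for (u in active) {
          succ <- ground_truth[[u]]
          if (is.null(succ)) next  # last layer
          take <- if (length(succ) > 1L &&
                      stats::runif(1) < spec$p_branch) 2L else 1L
          chosen <- resample(succ, take)
          parents <- c(parents, rep(u, take))
          children <- c(children, chosen)
          next_active <- c(next_active, chosen)
        }
        active <- unique(next_active)
      }
      edges <- unique(data.frame(parent_tool = parents, child_tool = children,
                                 stringsAsFactors = FALSE))
      graphs[[i]] <- new_workflow_graph(
        sprintf("wf_%05d", i), edges, stats::runif(1) < spec$p_shared
      )
    }
    list(graphs = graphs, ground_truth = ground_truth, layers = layers)
  })
}

#' Generate synthetic monthly usage series
#'
#' Assigns each tool a usage trend — constant, linearly increasing,
#' linearly decreasing to zero, or bursty — and draws Poisson counts around
#' the trend. Decreasing trends reach intensity exactly 0 in the final
#' month. Deterministic per seed.
#'
#' @param tools Character vector of tool ids, or a single integer n (tools
#'   are then named as by [generate_corpus()] with prefix `"tool"`).
#' @param months Number of months (default 12, the trailing year).
#' @param seed Integer seed.
#' @param end_month Last month of the series as `"YYYY-MM"`.
#' @return List of `usage_series`. Attributes `"trend"` and `"base"` record
#'   each tool's trend type and baseline intensity.
#' @export
generate_usage <- function(tools, months = 12L, seed = 1L,
                           end_month = "2025-12") {
  stopifnot(months >= 2L)
  if (is.numeric(tools) && length(tools) == 1L) {
    tools <- sprintf("tool_%03d", seq_len(tools))
  }
  last <- month_to_ordinal(end_month)
  month_labels <- ordinal_to_month(seq(last - months + 1L, last))
  trends <- rep_len(c("constant", "increasing", "decreasing", "bursty"),
                    length(tools))
  with_seed(seed, {
    trends <- sample(trends)  # random assignment, still seeded
    series <- vector("list", length(tools))
    bases <- numeric(length(tools))
    for (i in seq_along(tools)) {
      base <- round(exp(stats::runif(1, log(20), log(500))))
      bases[i] <- base
      lambda <- switch(trends[i],
        constant = rep(base, months),
        increasing = seq(base * 0.2, base, length.out = months),
        decreasing = seq(base, 0, length.out = months),
        bursty = {
          l <- rep(base * 0.2, months)
          l[resample(seq_len(months), 2L)] <- base * 4
          l
        })
      series[[i]] <- new_usage_series(tools[i], month_labels,
                                      stats::rpois(months, lambda))
    }
    names(series) <- tools
    structure(series, trend = stats::setNames(trends, tools),
              base = stats::setNames(bases, tools))
  })
}

#' Write a synthetic corpus to the TSV dialects of the readers
#'
#' Emits `workflow_connections.tsv` and `tool_usage.tsv` under `dir`, in
#' exactly the formats consumed by [read_workflow_connections()] and
#' [read_tool_usage()].
#'
#' @param corpus Return value of [generate_corpus()].
#' @param usage Return value of [generate_usage()].
#' @param dir Output directory (created if missing).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_corpus_tsv <- function(corpus, usage, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  conn <- file.path(dir, "workflow_connections.tsv")
  use <- file.path(dir, "tool_usage.tsv")
  write_workflow_connections(corpus$graphs, conn)
  write_tool_usage(usage, use)
  invisible(c(conn, use))
}
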