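# Reading and validation of the two input tables: workflow tool-connection
# edges and monthly tool usage counts. Tool identifiers are canonicalized so
# that version variants of one tool collapse onto a single id.

#' Canonicalize a raw tool identifier
#'
#' Galaxy-style tool ids embed the toolshed repository path and a trailing
#' version, e.g.
#' `"toolshed.g2.bx.psu.edu/repos/iuc/trimmomatic/trimmomatic/0.38.0"`.
#' The canonical id is the tool name: the second-to-last `/`-separated
#' component. Ids without a `/` are already canonical and returned unchanged,
#' which makes the function idempotent.
#'
#' @param raw_id Character vector of raw tool ids. Must be non-empty strings.
#' @return Character vector of canonical ids.
#' @examples
#' normalize_tool_id("toolshed.g2.bx.psu.edu/repos/iuc/trimmomatic/trimmomatic/0.38.0")
#' normalize_tool_id("Cut1")
#' @export
normalize_tool_id <- function(raw_id) {
  if (length(raw_id) == 0L) return(character(0))
  if (!is.character(raw_id) || anyNA(raw_id) || any(!nzchar(raw_id))) {
    stop("tool ids must be non-empty strings", call. = FALSE)
  }
  out <- vapply(strsplit(raw_id, "/", fixed = TRUE), function(parts) {
    if (length(parts) == 1L) parts else parts[length(parts) - 1L]
  }, character(1))
  if (any(!nzchar(out))) {
    stop("canonicalization produced an empty tool id", call. = FALSE)
  }
  out
}

new_workflow_graph <- function(workflow_id, edges, is_shared) {
  structure(
    list(workflow_id = workflow_id, edges = edges, is_shared = is_shared),
    class = "workflow_graph"
  )
}

#' @export
print.workflow_graph <- function(x, ...) {
  cat(sprintf(
    "<workflow_graph> %s: %d edges, %s\n", x$workflow_id, nrow(x$edges),
    if (x$is_shared) "shared" else "non-shared"
  ))
  invisible(x)
}

graph_is_acyclic <- function(edges) {
  if (nrow(edges) == 0L) return(TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(edges$parent_tool, edges$child_tool), directed = TRUE
  )
  igraph::is_dag(g)
}

parse_flag <- function(x, column) {
  v <- rep(NA, length(x))
  v[tolower(x) %in% c("true", "t", "1")] <- TRUE
  v[tolower(x) %in% c("false", "f", "0")] <- FALSE
  if (anyNA(v)) {
    stop(sprintf("unparsable boolean in column '%s': %s",
                 column, x[which(is.na(v))[1L]]), call. = FALSE)
  }
  v
}

read_tsv_table <- function(path, required) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  tab
}

#' Read a workflow tool-connection table
#'
#' Parses a TSV with one row per directed tool-to-tool edge and the columns
#' `workflow_id`, `parent_tool`, `child_tool`, `published`, `deleted`,
#' `has_errors`. Rows are grouped by workflow; a workflow is *shared* when it
#' is published, not deleted and not erroneous — the provenance category used
#' to rank its labels first at recommendation time. Tool ids are
#' canonicalized with [normalize_tool_id()]; self-edges created by version
#' collapsing are dropped, and workflows whose edge set contains a cycle are
#' discarded with a warning (a workflow is by definition a DAG).
#'
#' @param path Path to the TSV file.
#' @return List of `workflow_graph` objects, each with fields `workflow_id`,
#'   `edges` (data.frame of `parent_tool`, `child_tool`) and `is_shared`.
#' @export
read_workflow_connections <- function(path) {
  tab <- read_tsv_table(path, c("workflow_id", "parent_tool", "child_tool",
                                "published", "deleted", "has_errors"))
  if (nrow(tab) == 0L) return(list())
  published <- parse_flag(tab$published, "published")
  deleted <- parse_flag(tab$deleted, "deleted")
  has_errors <- parse_flag(tab$has_errors, "has_errors")
  parent <- normalize_tool_id(tab$parent_tool)
  child <- normalize_tool_id(tab$child_tool)
  shared <- published & !deleted & !has_errors

  graphs <- list()
  dropped <- character(0)
  for (wid in unique(tab$workflow_id)) {
    rows <- which(tab$workflow_id == wid)
    edges <- unique(data.frame(parent_tool = parent[rows],
                               child_tool = child[rows],
                               stringsAsFactors = FALSE))
    self <- edges$parent_tool == edges$child_tool
    if (any(self)) edges <- edges[!self, , drop = FALSE]
    if (!graph_is_acyclic(edges)) {
      dropped <- c(dropped, wid)
      next
    }
    graphs[[length(graphs) + 1L]] <-
      new_workflow_graph(wid, edges, all(shared[rows]))
  }
  if (length(dropped) > 0L) {
    warning(sprintf("dropped %d cyclic workflow(s): %s", length(dropped),
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  graphs
}

#' Write a workflow connection table
#'
#' Serializes workflow graphs back to the TSV dialect read by
#' [read_workflow_connections()], so that a parse/serialize round trip is
#' graph-identical.
#'
#' @param graphs List of `workflow_graph` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_workflow_connections <- function(graphs, path) {
  rows <- lapply(graphs, function(g) {
    if (nrow(g$edges) == 0L) return(NULL)
    data.frame(workflow_id = g$workflow_id,
               parent_tool = g$edges$parent_tool,
               child_tool = g$edges$child_tool,
               published = tolower(as.character(g$is_shared)),
               deleted = "false",
               has_errors = "false",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(workflow_id = character(0), parent_tool = character(0),
                      child_tool = character(0), published = character(0),
                      deleted = character(0), has_errors = character(0))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

month_to_ordinal <- function(month) {
  ok <- grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", month)
  if (any(!ok)) {
    stop(sprintf("malformed month: %s", month[which(!ok)[1L]]), call. = FALSE)
  }
  yr <- as.integer(substr(month, 1L, 4L))
  mo <- as.integer(substr(month, 6L, 7L))
  yr * 12L + (mo - 1L)
}

ordinal_to_month <- function(ord) {
  sprintf("%04d-%02d", ord %/% 12L, ord %% 12L + 1L)
}

new_usage_series <- function(tool, months, counts) {
  structure(list(tool = tool, months = months, counts = counts),
            class = "usage_series")
}

#' Read a monthly tool-usage table
#'
#' Parses a TSV with columns `tool_id`, `month` (ISO `"YYYY-MM"`) and
#' `count`, covering the trailing year of tool executions. Counts of version
#' variants that canonicalize to the same tool are summed per month. Each
#' tool's series is aligned to the `horizon_months` consecutive months ending
#' at the latest month present anywhere in the table; months without a row
#' are filled with 0.
#'
#' @param path Path to the TSV file.
#' @param horizon_months Number of trailing months to retain (default 12,
#'   i.e. the past year).
#' @return List of `usage_series` objects with fields `tool`, `months`
#'   (character vector of `"YYYY-MM"`) and `counts` (non-negative integers).
#' @export
read_tool_usage <- function(path, horizon_months = 12L) {
  stopifnot(horizon_months >= 1L)
  tab <- read_tsv_table(path, c("tool_id", "month", "count"))
  if (nrow(tab) == 0L) return(list())
  count <- suppressWarnings(as.numeric(tab$count))
  if (anyNA(count) || any(count < 0) || any(count != floor(count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  ord <- month_to_ordinal(tab$month)
  tool <- normalize_tool_id(tab$tool_id)

  last <- max(ord)
  horizon <- seq(last - horizon_months + 1L, last)
  keep <- ord %in% horizon
  agg <- stats::aggregate(
    list(count = count[keep]),
    by = list(tool = tool[keep], ord = ord[keep]), FUN = sum
  )
  months <- ordinal_to_month(horizon)
  lapply(split(agg, agg$tool), function(rows) {
    counts <- integer(horizon_months)
    counts[match(rows$ord, horizon)] <- as.integer(rows$count)
    new_usage_series(rows$tool[1L], months, counts)
  })
}

#' Write a monthly tool-usage table
#'
#' Inverse of [read_tool_usage()]: emits the `tool_id`/`month`/`count` TSV
#' dialect. Zero-count months are written explicitly.
#'
#' @param usage List of `usage_series` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tool_usage <- function(usage, path) {
  rows <- lapply(usage, function(s) {
    data.frame(tool_id = s$tool, month = s$months, count = s$counts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tool_id = character(0), month = character(0),
                      count = integer(0))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
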