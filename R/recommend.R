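# Inference interface: score a partial workflow and return a ranked
# recommendation list. Tools that ever appeared as shared labels (published,
# non-deleted, non-erroneous provenance) are promoted above non-shared
# predictions; administrators can overwrite predictions for a given last
# tool and append newly added tools.

#' Score a query tool sequence
#'
#' Encodes the query with the model's vocabulary and runs a deterministic
#' forward pass, returning one probability-like score per vocabulary tool.
#'
#' @param model A trained `recommender_model`.
#' @param query Character vector of 1 to `max_len - 1` known tool ids.
#' @return Named numeric vector of length V with values in (0, 1).
#' @export
score_query <- function(model, query) {
  if (length(query) == 0L) stop("empty query", call. = FALSE)
  if (length(query) > model$config$max_len - 1L) {
    stop(sprintf("query longer than %d tools", model$config$max_len - 1L),
         call. = FALSE)
  }
  enc <- encode_sequence(query, model$vocabulary, model$config$max_len)
  drop(predict_scores(model, enc))
}

#' Recommend next tools for a query sequence
#'
#' Scores every vocabulary tool, partitions the candidates into shared /
#' non-shared by the persisted category map (tools that ever occurred as a
#' shared label are shared-capable; when the model carries no category map,
#' all predictions are flagged non-shared), sorts each block by descending
#' score and concatenates shared first, truncated to `max_items`. An
#' `overrides` entry matching the query's last tool replaces the predictions
#' entirely; `extra_tools` (e.g. newly added tools not yet in the model) are
#' appended at the end flagged `override`.
#'
#' @param model A trained `recommender_model`.
#' @param query Character vector of known tool ids (1..`max_len - 1`).
#' @param max_items Maximum number of predicted items returned.
#' @param overrides Optional named list: last tool id -> character vector of
#'   replacement recommendations.
#' @param extra_tools Optional character vector appended after the ranked
#'   items.
#' @return A `recommendation_result`: list with `query` and `items` (a
#'   data.frame with columns `tool`, `score`, `category`). Override items
#'   carry `NA` scores.
#' @export
recommend_tools <- function(model, query, max_items = 5L, overrides = NULL,
                            extra_tools = NULL) {
  stopifnot(max_items >= 1L)
  if (length(query) == 0L) stop("empty query", call. = FALSE)
  vocab_lookup(model$vocabulary, query)  # validate before any branch
  last_tool <- query[length(query)]
  if (!is.null(overrides) && !is.null(overrides[[last_tool]])) {
    items <- data.frame(tool = overrides[[last_tool]], score = NA_real_,
                        category = "override", stringsAsFactors = FALSE)
  } else {
    scores <- score_query(model, query)
    shared_capable <- names(scores) %in% model$shared_tools
    blocks <- list(
      shared = which(shared_capable),
      nonshared = which(!shared_capable)
    )
    rows <- lapply(names(blocks), function(cat_name) {
      idx <- blocks[[cat_name]]
      if (length(idx) == 0L) return(NULL)
      idx <- idx[order(-scores[idx], idx)]
      data.frame(tool = names(scores)[idx], score = unname(scores[idx]),
                 category = cat_name, stringsAsFactors = FALSE)
    })
    items <- do.call(rbind, rows)
    items <- items[seq_len(min(max_items, nrow(items))), , drop = FALSE]
  }
  if (!is.null(extra_tools) && length(extra_tools) > 0L) {
    extra <- setdiff(extra_tools, items$tool)
    if (length(extra) > 0L) {
      items <- rbind(items, data.frame(tool = extra, score = NA_real_,
                                       category = "override",
                                       stringsAsFactors = FALSE))
    }
  }
  rownames(items) <- NULL
  structure(list(query = query, items = items, max_items = max_items),
            class = "recommendation_result")
}

#' @export
print.recommendation_result <- function(x, ...) {
  cat(sprintf("<recommendation_result> after %s:\n",
              paste(x$query, collapse = " > ")))
  for (i in seq_len(nrow(x$items))) {
    cat(sprintf("  %d. %s (%s%s)\n", i, x$items$tool[i], x$items$category[i],
                if (is.na(x$items$score[i])) "" else
                  sprintf(", %.3f", x$items$score[i])))
  }
  invisible(x)
}

#' Serialize a recommendation result as JSON
#'
#' @param result A `recommendation_result`.
#' @return A JSON string.
#' @export
recommendation_json <- function(result) {
  jsonlite::toJSON(list(query = result$query, items = result$items),
                   dataframe = "rows", na = "null", auto_unbox = FALSE,
                   digits = NA)
}
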