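# Precision@k evaluation, split by shared / non-shared label provenance,
# plus the usage-frequency metric of predicted tools and multi-run
# mean +/- SD aggregation.

#' Precision at k for one prediction
#'
#' Takes the k highest-scoring tool indices (ties broken by ascending tool
#' index, for determinism) and returns the fraction of them that are true
#' labels: e.g. if exactly 1 of the top 2 is correct, precision@2 = 1/2 =
#' 0.5.
#'
#' @param scores Numeric vector of length V (one score per tool).
#' @param true_labels Integer vector of true label indices.
#' @param k Number of top predictions considered (1 <= k <= V).
#' @return Precision in [0, 1]; `NA_real_` when `true_labels` is empty (the
#'   sample carries no label in the evaluated category and is skipped).
#' @export
precision_at_k <- function(scores, true_labels, k) {
  stopifnot(k >= 1L)
  if (k > length(scores)) stop("k exceeds the number of tools", call. = FALSE)
  if (length(true_labels) == 0L) return(NA_real_)
  top <- order(-scores, seq_along(scores))[seq_len(k)]
  sum(top %in% true_labels) / k
}

top_k_indices <- function(scores, k) {
  # rows of a score matrix -> N x k matrix of top indices, deterministic ties
  res <- apply(scores, 1L, function(s) order(-s, seq_along(s))[seq_len(k)])
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

mean_precision_at_k <- function(scores, label_matrix, k) {
  keep <- rowSums(label_matrix) > 0L
  if (!any(keep)) return(NA_real_)
  top <- top_k_indices(scores[keep, , drop = FALSE], k)
  lab <- label_matrix[keep, , drop = FALSE]
  hits <- vapply(seq_len(nrow(top)), function(i)
    sum(lab[i, top[i, ]]), numeric(1))
  mean(hits / k)
}

#' Evaluate a model on a test set
#'
#' Computes mean precision@k for each k, separately against the shared and
#' non-shared label sets (and their combined union). Samples with no label
#' in a category are excluded from that category's mean rather than scored
#' 0; a category with no labelled samples at all is reported as `NA`.
#'
#' @param model A trained `recommender_model`.
#' @param test An `encoded_dataset` for the test split.
#' @param ks Integer vector of cutoffs (default `c(1, 2)`).
#' @return A `precision_report` data.frame with columns `k`, `category`
#'   (shared / nonshared / combined), `precision` and `n` (samples entering
#'   the mean).
#' @export
evaluate_model <- function(model, test, ks = c(1L, 2L)) {
  stopifnot(inherits(test, "encoded_dataset"))
  if (test$vocab_size != model$vocabulary$size) {
    stop("vocabulary mismatch between model and test set", call. = FALSE)
  }
  scores <- predict_scores(model, test$sequences)
  cats <- list(shared = test$shared_labels,
               nonshared = test$nonshared_labels,
               combined = test$combined_labels)
  rows <- list()
  for (k in ks) {
    for (cat_name in names(cats)) {
      lab <- cats[[cat_name]]
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, category = cat_name,
        precision = mean_precision_at_k(scores, lab, k),
        n = sum(rowSums(lab) > 0L), stringsAsFactors = FALSE
      )
    }
  }
  structure(do.call(rbind, rows), class = c("precision_report", "data.frame"))
}

#' Mean summed usage weight of the top-k predicted tools
#'
#' For each test sample, sums the usage-derived weights of the k
#' highest-scoring tools (shared and non-shared predictions pooled) and
#' averages over samples — the usage-frequency metric of predictions. With
#' all weights equal to 1 the metric equals k.
#'
#' @param model A trained `recommender_model`.
#' @param test An `encoded_dataset`.
#' @param weights A `tool_weights` (missing tools use its default).
#' @param k Cutoff.
#' @return Non-negative scalar.
#' @export
usage_frequency_of_predictions <- function(model, test, weights, k) {
  scores <- predict_scores(model, test$sequences)
  w <- weights$weight_of
  top <- top_k_indices(scores, k)
  mean(vapply(seq_len(nrow(top)), function(i) sum(w[top[i, ]]), numeric(1)))
}

#' Repeat the split/train/evaluate experiment and aggregate
#'
#' Runs the full experiment `n_runs` times with distinct seeds — random
#' 80/20 split over unique samples, class-balanced training, per-epoch
#' validation — and aggregates the per-epoch metric trajectories into mean
#' and standard deviation bands across runs.
#'
#' @param samples List of `training_sample` objects (the full corpus).
#' @param config A `model_config`.
#' @param n_runs Number of experiment repetitions (>= 2, default 10).
#' @param seeds Optional integer vector of length `n_runs`; defaults to
#'   `1:n_runs`.
#' @param weights Optional `tool_weights` shared across runs.
#' @param fraction Training fraction (default 0.8).
#' @return List with `per_run` (long data.frame: run, epoch, metric, value)
#'   and `summary` (epoch, metric, mean, sd over runs).
#' @export
run_experiments <- function(samples, config, n_runs = 10L, seeds = NULL,
                            weights = NULL, fraction = 0.8) {
  stopifnot(n_runs >= 2L)
  seeds <- seeds %||% seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  vocab <- build_vocabulary(samples)
  shared_tools <- sort(unique(unlist(lapply(samples, `[[`, "shared_labels"))),
                       method = "radix")
  per_run <- list()
  for (r in seq_len(n_runs)) {
    sp <- split_train_test(samples, fraction = fraction, seed = seeds[r])
    train_enc <- encode_dataset(sp$train, vocab, config$max_len)
    test_enc <- encode_dataset(sp$test, vocab, config$max_len)
    idx <- build_last_tool_index(sp$train, vocab)
    model <- build_model(config, vocab, weights = weights,
                         shared_tools = shared_tools, init_seed = seeds[r])
    fit <- train_model(model, train_enc, sampler = idx,
                       validation = test_enc, seed = seeds[r])
    h <- fit$history
    per_run[[r]] <- do.call(rbind, lapply(
      c("train_loss", "val_loss", "val_precision1", "val_precision2"),
      function(metric) data.frame(run = r, epoch = h$epoch, metric = metric,
                                  value = h[[metric]],
                                  stringsAsFactors = FALSE)
    ))
  }
  long <- do.call(rbind, per_run)
  summary <- stats::aggregate(
    value ~ epoch + metric, data = long,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v))
  )
  summary <- data.frame(epoch = summary$epoch, metric = summary$metric,
                        mean = summary$value[, "mean"],
                        sd = summary$value[, "sd"],
                        stringsAsFactors = FALSE)
  list(per_run = long, summary = summary)
}

#' Export an experiment report as TSV
#'
#' Long-format result file (run, epoch, metric, value) of the kind used to
#' draw precision / loss / usage-frequency trajectories.
#'
#' @param report Return value of [run_experiments()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(report$per_run, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
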