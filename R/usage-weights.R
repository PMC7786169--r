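# Per-tool class weights from usage trends. Each tool's monthly usage over
# the trailing year is extrapolated one month ahead with support vector
# regression (grid search over kernel x degree with 5-fold CV), and the
# logarithm of the forecast becomes the tool's weight w_i in the training
# loss, so frequently used tools are penalized more when misclassified while
# the log keeps the handful of very heavily used tools from dominating.

SVR_GRID <- expand.grid(kernel = c("radial", "polynomial", "linear"),
                        degree = c(2L, 3L), stringsAsFactors = FALSE)

# Standardized-eps-SVR fit returning a prediction closure. A series whose
# training residuals all fall inside the epsilon tube (e.g. a constant
# series) produces an empty support-vector set, which e1071 treats as an
# error; such a fit degenerates to predicting the training mean.
svr_fit <- function(x, y, kernel, degree) {
  mx <- mean(x); sx <- stats::sd(x); if (is.na(sx) || sx == 0) sx <- 1
  my <- mean(y); sy <- stats::sd(y); if (is.na(sy) || sy == 0) sy <- 1
  fit <- tryCatch(
    e1071::svm(x = matrix((x - mx) / sx), y = (y - my) / sy,
               type = "eps-regression", kernel = kernel, degree = degree,
               scale = FALSE),
    error = function(e) NULL
  )
  function(xnew) {
    p <- if (is.null(fit)) rep(0, length(xnew)) else
      stats::predict(fit, matrix((xnew - mx) / sx))
    as.numeric(p) * sy + my
  }
}

svr_grid_search <- function(x, y, folds = 5L) {
  fold_id <- ((seq_along(x) - 1L) %% folds) + 1L
  cv_mse <- vapply(seq_len(nrow(SVR_GRID)), function(i) {
    se <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      pred <- svr_fit(x[tr], y[tr], SVR_GRID$kernel[i], SVR_GRID$degree[i])(x[!tr])
      se <- se + sum((pred - y[!tr])^2)
    }
    se / length(x)
  }, numeric(1))
  cbind(SVR_GRID, cv_mse = cv_mse)
}

#' Forecast next-month usage of one tool
#'
#' Fits the tool's 12 monthly counts (month ordinals 1..12 as the sole
#' regressor) with epsilon-SVR, grid-searching all 6 combinations of kernel
#' (`radial`, `polynomial`, `linear`) and degree (2, 3) under 5-fold
#' cross-validation scored by mean squared error, then refits the winning
#' configuration on all 12 months and predicts month 13. Negative
#' extrapolations are clipped to 0; an all-zero series forecasts 0 without
#' fitting.
#'
#' @param series A `usage_series` (12 monthly counts).
#' @return Non-negative forecast for the next month. The CV grid is attached
#'   as attribute `"grid"` (a 6-row data.frame of kernel, degree, cv_mse).
#' @export
fit_usage_trend <- function(series) {
  counts <- as.numeric(series$counts)
  if (length(counts) < 2L) stop("usage series too short", call. = FALSE)
  if (all(counts == 0)) {
    return(structure(0, grid = cbind(SVR_GRID, cv_mse = 0)))
  }
  x <- seq_along(counts)
  grid <- svr_grid_search(x, counts)
  best <- which.min(grid$cv_mse)
  forecast <- svr_fit(x, counts, grid$kernel[best],
                      grid$degree[best])(length(counts) + 1)
  structure(max(0, forecast), grid = grid)
}

#' Compute per-tool class weights from usage forecasts
#'
#' Each vocabulary tool with a usage series gets weight
#' \eqn{\ln(1 + \hat{u})}, where \eqn{\hat{u}} is its forecast next-month
#' usage from [fit_usage_trend()]. Tools without usage data, or with a zero
#' forecast, receive `default_weight` so no label's loss contribution
#' vanishes. The log compresses the usage scale, preventing the few very
#' heavily used tools from dominating the loss.
#'
#' @param usage List of `usage_series` objects.
#' @param vocab A `tool_vocabulary`.
#' @param default_weight Weight for tools with no (or zero) usage; default 1.
#' @return A `tool_weights`: list with `weight_of` (numeric vector of length
#'   V, position = tool index), `default_weight`, and `forecast_of` (the raw
#'   forecasts, NA where absent).
#' @export
compute_tool_weights <- function(usage, vocab, default_weight = 1.0) {
  stopifnot(default_weight > 0)
  weights <- rep(default_weight, vocab$size)
  forecasts <- rep(NA_real_, vocab$size)
  for (s in usage) {
    idx <- vocab$index_of[s$tool]
    if (is.na(idx)) next  # usage rows for tools outside the corpus
    f <- as.numeric(fit_usage_trend(s))
    forecasts[idx] <- f
    if (f > 0) weights[idx] <- log1p(f)
  }
  names(weights) <- vocab$id_of
  structure(list(weight_of = weights, default_weight = default_weight,
                 forecast_of = forecasts),
            class = "tool_weights")
}

#' @export
print.tool_weights <- function(x, ...) {
  cat(sprintf("<tool_weights> %d tools, range [%.3f, %.3f]\n",
              length(x$weight_of), min(x$weight_of), max(x$weight_of)))
  invisible(x)
}

#' Export tool weights as a flat TSV
#'
#' @param weights A `tool_weights`.
#' @param path Output TSV path (columns tool_id, weight).
#' @return `path`, invisibly.
#' @export
write_tool_weights <- function(weights, path) {
  out <- data.frame(tool_id = names(weights$weight_of),
                    weight = unname(weights$weight_of),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
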