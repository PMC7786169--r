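# Bayesian (sequential model-based) hyperparameter optimization with a
# tree-structured Parzen estimator: observed configurations are split into
# a good and a bad group at the gamma quantile of validation loss, and new
# candidates are drawn from a Parzen-window density over the good group,
# ranked by the good/bad density ratio.

#' Describe a hyperparameter search space
#'
#' Each entry gives the range of one `model_config` field. Numeric entries
#' are `c(low, high)`; set `log = TRUE` dimensions by using
#' [tune_param()]. A dimension whose low equals its high is fixed.
#'
#' @param embedding_dim,gru_units Integer ranges (default 32..512).
#' @param dropout_embed,dropout_between,dropout_out Ranges in [0, 0.5].
#' @param learning_rate Log-uniform range (default 1e-4..1e-2).
#' @param batch_size Integer range (default 32..256).
#' @return A named list of `tune_param` descriptors.
#' @export
search_space <- function(embedding_dim = c(32, 512),
                         gru_units = c(32, 512),
                         dropout_embed = c(0, 0.5),
                         dropout_between = c(0, 0.5),
                         dropout_out = c(0, 0.5),
                         learning_rate = c(1e-4, 1e-2),
                         batch_size = c(32, 256)) {
  list(embedding_dim = tune_param(embedding_dim, integer = TRUE),
       gru_units = tune_param(gru_units, integer = TRUE),
       dropout_embed = tune_param(dropout_embed),
       dropout_between = tune_param(dropout_between),
       dropout_out = tune_param(dropout_out),
       learning_rate = tune_param(learning_rate, log = TRUE),
       batch_size = tune_param(batch_size, integer = TRUE))
}

#' One search-space dimension
#'
#' @param range Numeric `c(low, high)` with `low <= high`.
#' @param integer Round draws to integers.
#' @param log Sample uniformly on the log scale.
#' @return A `tune_param` descriptor.
#' @export
tune_param <- function(range, integer = FALSE, log = FALSE) {
  stopifnot(length(range) == 2L, range[1] <= range[2],
            !log || range[1] > 0)
  structure(list(low = range[1], high = range[2], integer = integer,
                 log = log), class = "tune_param")
}

draw_uniform <- function(p) {
  x <- if (p$log) exp(stats::runif(1, log(p$low), log(p$high))) else
    stats::runif(1, p$low, p$high)
  if (p$integer) x <- round(x)
  min(max(x, p$low), p$high)
}

to_scale <- function(p, x) if (p$log) log(x) else x

parzen_density <- function(p, obs, x) {
  # Parzen mixture over observations on the (possibly log) sampling scale
  lo <- to_scale(p, p$low); hi <- to_scale(p, p$high)
  bw <- max((hi - lo) / max(4, length(obs)), (hi - lo) * 0.05, 1e-9)
  mean(stats::dnorm(to_scale(p, x), mean = to_scale(p, obs), sd = bw))
}

draw_near <- function(p, obs) {
  lo <- to_scale(p, p$low); hi <- to_scale(p, p$high)
  if (hi <= lo) return(p$low)
  bw <- max((hi - lo) / max(4, length(obs)), (hi - lo) * 0.05)
  centre <- to_scale(p, obs[sample.int(length(obs), 1L)])
  x <- min(max(stats::rnorm(1, centre, bw), lo), hi)
  if (p$log) x <- exp(x)
  if (p$integer) x <- round(x)
  min(max(x, p$low), p$high)
}

#' Tune hyperparameters by Bayesian optimization
#'
#' Runs exactly `n_evals` short training evaluations. The first quarter are
#' uniform random draws from the space; each later configuration is proposed
#' by the tree-structured Parzen estimator (candidates sampled around the
#' best-scoring quarter of past configurations and ranked by good/bad
#' density ratio). Every evaluation trains for `epochs_per_eval` epochs on
#' an internal split of the training samples and is scored by validation
#' loss; the best-scoring configuration is returned.
#'
#' @param train List of `training_sample` objects (the training split).
#' @param space Named list of `tune_param` descriptors, as from
#'   [search_space()].
#' @param n_evals Number of configurations evaluated (default 20).
#' @param seed Integer seed.
#' @param epochs_per_eval Epochs per evaluation (default 2; tuning uses
#'   short runs).
#' @param base_config `model_config` supplying the fields not searched.
#' @return The best `model_config`; attribute `"trials"` holds a data.frame
#'   of every evaluated configuration and its validation loss.
#' @export
tune_hyperparameters <- function(train, space, n_evals = 20L, seed = 1L,
                                 epochs_per_eval = 2L,
                                 base_config = model_config()) {
  if (length(space) == 0L) stop("empty search space", call. = FALSE)
  stopifnot(n_evals >= 1L)
  vocab <- build_vocabulary(train)
  sp <- split_train_test(train, fraction = 0.8, seed = seed)
  tr_enc <- encode_dataset(sp$train, vocab, base_config$max_len)
  va_enc <- encode_dataset(sp$test, vocab, base_config$max_len)
  idx <- build_last_tool_index(sp$train, vocab)

  n_startup <- max(1L, min(n_evals, as.integer(ceiling(n_evals / 4))))
  gamma <- 0.25
  trials <- vector("list", n_evals)
  with_seed(seed, {
    for (i in seq_len(n_evals)) {
      cand <- if (i <= n_startup) {
        lapply(space, draw_uniform)
      } else {
        done <- do.call(rbind, lapply(trials[seq_len(i - 1L)], as.data.frame))
        ord <- order(done$loss)
        n_good <- max(1L, as.integer(ceiling(gamma * nrow(done))))
        good <- done[ord[seq_len(n_good)], , drop = FALSE]
        bad <- done[ord[-seq_len(n_good)], , drop = FALSE]
        if (nrow(bad) == 0L) bad <- good
        proposals <- lapply(seq_len(8L), function(j)
          lapply(names(space), function(nm) draw_near(space[[nm]], good[[nm]])))
        ratio <- vapply(proposals, function(pr) {
          lg <- 0
          for (d in seq_along(space)) {
            nm <- names(space)[d]
            l <- parzen_density(space[[nm]], good[[nm]], pr[[d]])
            g <- parzen_density(space[[nm]], bad[[nm]], pr[[d]])
            lg <- lg + log(l + 1e-12) - log(g + 1e-12)
          }
          lg
        }, numeric(1))
        stats::setNames(proposals[[which.max(ratio)]], names(space))
      }
      cfg_args <- utils::modifyList(unclass(base_config), cand)
      cfg_args$epochs <- as.integer(epochs_per_eval)
      cfg <- do.call(model_config, cfg_args)
      model <- build_model(cfg, vocab, init_seed = seed + i)
      fit <- train_model(model, tr_enc, sampler = idx, validation = va_enc,
                         seed = seed + i)
      loss <- utils::tail(fit$history$val_loss, 1L)
      trials[[i]] <- c(cand, list(loss = loss))
    }
  })
  done <- do.call(rbind, lapply(trials, as.data.frame))
  best <- trials[[which.min(done$loss)]]
  best$loss <- NULL
  cfg_args <- utils::modifyList(unclass(base_config), best)
  structure(do.call(model_config, cfg_args), trials = done)
}
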