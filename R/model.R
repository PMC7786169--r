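# The recommender network: embedding (padding index 0 masked) -> dropout ->
# GRU -> dropout -> GRU -> dropout -> dense sigmoid over the vocabulary.
# Both GRU layers use ELU candidate activations. The network models
# p(x_T | x_1, ..., x_{T-1}) as a multi-label score per tool and is trained
# by minimizing the usage-weighted cross-entropy with RMSProp. Forward pass,
# backpropagation through time and the optimizer are implemented directly
# with matrix operations; a finite-difference check in the test suite guards
# the gradients.

EPS_CLIP <- 1e-7

#' Logistic sigmoid
#'
#' \eqn{f(x) = 1 / (1 + e^{-x})}, mapping any real number into (0, 1);
#' numerically stable for large |x|.
#'
#' @param x Numeric vector or matrix.
#' @return Values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Exponential linear unit
#'
#' Identity for positive inputs, \eqn{\alpha(e^x - 1)} otherwise. Negative
#' outputs pull mean activations toward zero, which speeds up GRU training
#' relative to ReLU.
#'
#' @param x Numeric vector or matrix.
#' @param alpha Scale of the negative saturation (default 1).
#' @return Same shape as `x`.
#' @export
elu <- function(x, alpha = 1) {
  neg <- !is.na(x) & x < 0
  x[neg] <- alpha * (exp(x[neg]) - 1)
  x
}

elu_grad_from_act <- function(act, alpha = 1) {
  # derivative expressed via the activation value: 1 where positive,
  # act + alpha where negative (since act = alpha*(e^x - 1))
  g <- array(1, dim = dim(act) %||% length(act))
  neg <- act < 0
  g[neg] <- act[neg] + alpha
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Usage-weighted binary cross-entropy loss
#'
#' The training loss
#' \deqn{-(1/T)\sum_{i=1}^{T}\left[p^a_i \log p^b_i +
#'   (1 - p^a_i)\log(1 - p^b_i)\right] w_i}
#' over the label bit vector of length \eqn{T} (the vocabulary size), where
#' \eqn{p^a} is the true multi-hot vector, \eqn{p^b} the predicted scores
#' and \eqn{w_i} the per-tool usage weight. Predictions are clipped into
#' \eqn{[\epsilon, 1-\epsilon]} with \eqn{\epsilon = 10^{-7}} before the
#' logarithm. With all \eqn{w_i = 1} this is the ordinary multi-label binary
#' cross-entropy.
#'
#' @param p_true 0/1 vector of true labels, length T.
#' @param p_pred Predicted scores in (0, 1), length T.
#' @param w Positive weights, length T.
#' @return Non-negative scalar loss.
#' @export
weighted_crossentropy <- function(p_true, p_pred, w) {
  if (length(p_true) != length(p_pred) || length(p_pred) != length(w)) {
    stop("p_true, p_pred and w must have equal length", call. = FALSE)
  }
  p <- pmin(pmax(p_pred, EPS_CLIP), 1 - EPS_CLIP)
  -mean((p_true * log(p) + (1 - p_true) * log(1 - p)) * w)
}

#' Gradient of the weighted cross-entropy w.r.t. the predictions
#'
#' @inheritParams weighted_crossentropy
#' @return Vector of partial derivatives, length T.
#' @export
weighted_crossentropy_grad <- function(p_true, p_pred, w) {
  p <- pmin(pmax(p_pred, EPS_CLIP), 1 - EPS_CLIP)
  -(p_true / p - (1 - p_true) / (1 - p)) * w / length(p)
}

#' Network hyperparameter configuration
#'
#' @param embedding_dim Size of the learned per-tool embedding vector.
#' @param gru_units Hidden units in each of the two stacked GRU layers.
#' @param dropout_embed,dropout_between,dropout_out Dropout rates of the
#'   three dropout layers (after the embedding, between the GRU layers, and
#'   after the second GRU), each in [0, 1).
#' @param learning_rate RMSProp learning rate.
#' @param batch_size Sequences per training batch.
#' @param epochs Training iterations over the data (default 10).
#' @param max_len Encoded sequence length (default 25).
#' @return A `model_config` list.
#' @export
model_config <- function(embedding_dim = 32L, gru_units = 64L,
                         dropout_embed = 0.1, dropout_between = 0.1,
                         dropout_out = 0.1, learning_rate = 1e-3,
                         batch_size = 128L, epochs = 10L, max_len = 25L) {
  cfg <- list(embedding_dim = as.integer(embedding_dim),
              gru_units = as.integer(gru_units),
              dropout_embed = dropout_embed,
              dropout_between = dropout_between,
              dropout_out = dropout_out,
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              max_len = as.integer(max_len))
  ok <- cfg$embedding_dim >= 1L && cfg$gru_units >= 1L &&
    all(vapply(cfg[c("dropout_embed", "dropout_between", "dropout_out")],
               function(d) d >= 0 && d < 1, logical(1))) &&
    cfg$learning_rate > 0 && cfg$batch_size >= 1L && cfg$epochs >= 1L &&
    cfg$max_len >= 2L
  if (!ok) stop("invalid model configuration", call. = FALSE)
  structure(cfg, class = "model_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

orthogonal_init <- function(u) {
  # orthogonal recurrent kernels keep state norms stable across timesteps
  qr.Q(qr(matrix(stats::rnorm(u * u), u, u)))
}

init_gru_layer <- function(din, u) {
  list(Wz = glorot(din, u), Wr = glorot(din, u), Wh = glorot(din, u),
       Uz = orthogonal_init(u), Ur = orthogonal_init(u),
       Uh = orthogonal_init(u),
       bz = numeric(u), br = numeric(u), bh = numeric(u))
}

#' Build an untrained recommender model
#'
#' Assembles the architecture embedding(V+1 x embedding_dim, padding row
#' fixed at zero) -> dropout -> GRU(ELU) -> dropout -> GRU(ELU) -> dropout
#' -> dense(V, sigmoid). The output dimension equals the number of unique
#' tools, one score per tool.
#'
#' @param config A `model_config`.
#' @param vocab A `tool_vocabulary` with at least 2 tools.
#' @param weights Optional `tool_weights`; when NULL all tools weigh 1.
#' @param shared_tools Optional character vector of tools ever seen as
#'   shared labels, persisted for recommendation-time category ranking.
#' @param init_seed Seed for parameter initialization.
#' @return An untrained `recommender_model`.
#' @export
build_model <- function(config, vocab, weights = NULL, shared_tools = NULL,
                        init_seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  V <- vocab$size
  if (V < 2L) stop("vocabulary must contain at least 2 tools", call. = FALSE)
  d <- config$embedding_dim; u <- config$gru_units
  params <- with_seed(init_seed, {
    l1 <- init_gru_layer(d, u); names(l1) <- paste0(names(l1), "1")
    l2 <- init_gru_layer(u, u); names(l2) <- paste0(names(l2), "2")
    E <- rbind(numeric(d), matrix(stats::runif(V * d, -0.05, 0.05), V, d))
    c(list(E = E), l1, l2, list(Wd = glorot(u, V), bd = numeric(V)))
  })
  structure(list(config = config, vocabulary = vocab, weights = weights,
                 shared_tools = shared_tools %||% character(0),
                 params = params, trained = FALSE),
            class = "recommender_model")
}

#' @export
print.recommender_model <- function(x, ...) {
  cat(sprintf(
    "<recommender_model> V=%d tools, embedding %d, 2xGRU(%d), %strained (%s parameters)\n",
    x$vocabulary$size, x$config$embedding_dim, x$config$gru_units,
    if (x$trained) "" else "un", format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param model A `recommender_model`.
#' @return Integer: parameters across embedding, both GRU layers and the
#'   dense output layer (the padding embedding row is not counted).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1))) - model$config$embedding_dim
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

gru_forward <- function(p, sfx, inputs, mask) {
  Wz <- p[[paste0("Wz", sfx)]]; Wr <- p[[paste0("Wr", sfx)]]
  Wh <- p[[paste0("Wh", sfx)]]; Uz <- p[[paste0("Uz", sfx)]]
  Ur <- p[[paste0("Ur", sfx)]]; Uh <- p[[paste0("Uh", sfx)]]
  bz <- p[[paste0("bz", sfx)]]; br <- p[[paste0("br", sfx)]]
  bh <- p[[paste0("bh", sfx)]]
  B <- nrow(inputs[[1L]]); u <- ncol(Uz); L <- length(inputs)
  h <- matrix(0, B, u)
  cache <- vector("list", L)
  hs <- vector("list", L)
  for (t in seq_len(L)) {
    x <- inputs[[t]]
    h_prev <- h
    z <- sigmoid(add_bias(x %*% Wz + h_prev %*% Uz, bz))
    r <- sigmoid(add_bias(x %*% Wr + h_prev %*% Ur, br))
    hc <- elu(add_bias(x %*% Wh + (r * h_prev) %*% Uh, bh))
    h_new <- (1 - z) * h_prev + z * hc
    m <- mask[, t]
    h <- m * h_new + (1 - m) * h_prev
    cache[[t]] <- list(x = x, h_prev = h_prev, z = z, r = r, hc = hc, m = m)
    hs[[t]] <- h
  }
  list(h_last = h, hs = hs, cache = cache)
}

gru_backward <- function(p, sfx, cache, d_hs, d_h_last = NULL) {
  Wz <- p[[paste0("Wz", sfx)]]; Wr <- p[[paste0("Wr", sfx)]]
  Wh <- p[[paste0("Wh", sfx)]]; Uz <- p[[paste0("Uz", sfx)]]
  Ur <- p[[paste0("Ur", sfx)]]; Uh <- p[[paste0("Uh", sfx)]]
  L <- length(cache)
  g <- list(Wz = Wz * 0, Wr = Wr * 0, Wh = Wh * 0, Uz = Uz * 0, Ur = Ur * 0,
            Uh = Uh * 0, bz = numeric(ncol(Uz)), br = numeric(ncol(Uz)),
            bh = numeric(ncol(Uz)))
  d_inputs <- vector("list", L)
  dh_next <- if (is.null(d_h_last)) cache[[1L]]$h_prev * 0 else d_h_last
  for (t in rev(seq_len(L))) {
    cc <- cache[[t]]
    dh <- dh_next
    if (!is.null(d_hs) && !is.null(d_hs[[t]])) dh <- dh + d_hs[[t]]
    m <- cc$m
    dh_new <- m * dh
    dh_prev <- (1 - m) * dh
    dz <- dh_new * (cc$hc - cc$h_prev)
    dhc <- dh_new * cc$z
    dh_prev <- dh_prev + dh_new * (1 - cc$z)
    dah <- dhc * elu_grad_from_act(cc$hc)
    rh <- cc$r * cc$h_prev
    g$Wh <- g$Wh + crossprod(cc$x, dah)
    g$Uh <- g$Uh + crossprod(rh, dah)
    g$bh <- g$bh + colSums(dah)
    drh <- dah %*% t(Uh)
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r
    daz <- dz * cc$z * (1 - cc$z)
    dar <- dr * cc$r * (1 - cc$r)
    g$Wz <- g$Wz + crossprod(cc$x, daz)
    g$Uz <- g$Uz + crossprod(cc$h_prev, daz)
    g$bz <- g$bz + colSums(daz)
    g$Wr <- g$Wr + crossprod(cc$x, dar)
    g$Ur <- g$Ur + crossprod(cc$h_prev, dar)
    g$br <- g$br + colSums(dar)
    dh_prev <- dh_prev + daz %*% t(Uz) + dar %*% t(Ur)
    d_inputs[[t]] <- daz %*% t(Wz) + dar %*% t(Wr) + dah %*% t(Wh)
    dh_next <- dh_prev
  }
  names(g) <- paste0(names(g), sfx)
  list(grads = g, d_inputs = d_inputs)
}

dropout_mask <- function(nr, nc, rate, training) {
  if (!training || rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

forward_pass <- function(model, X, training = FALSE) {
  p <- model$params; cfg <- model$config
  B <- nrow(X); L <- ncol(X)
  mask <- (X != 0L) * 1
  emb <- vector("list", L)
  d0 <- vector("list", L)
  d1 <- vector("list", L)
  for (t in seq_len(L)) {
    e <- p$E[X[, t] + 1L, , drop = FALSE]
    d0[t] <- list(dropout_mask(B, cfg$embedding_dim, cfg$dropout_embed,
                               training))
    if (!is.null(d0[[t]])) e <- e * d0[[t]]
    emb[[t]] <- e
  }
  l1 <- gru_forward(p, "1", emb, mask)
  h1 <- l1$hs
  for (t in seq_len(L)) {
    d1[t] <- list(dropout_mask(B, cfg$gru_units, cfg$dropout_between,
                               training))
    if (!is.null(d1[[t]])) h1[[t]] <- h1[[t]] * d1[[t]]
  }
  l2 <- gru_forward(p, "2", h1, mask)
  h2 <- l2$h_last
  d2 <- dropout_mask(B, cfg$gru_units, cfg$dropout_out, training)
  h2d <- if (is.null(d2)) h2 else h2 * d2
  scores <- sigmoid(add_bias(h2d %*% p$Wd, p$bd))
  list(scores = scores, mask = mask, emb = emb, l1 = l1, l2 = l2,
       h1_dropped = h1, h2_dropped = h2d, d0 = d0, d1 = d1, d2 = d2)
}

backward_pass <- function(model, X, fw, d_scores_pre) {
  # d_scores_pre: gradient w.r.t. the dense pre-activations (B x V)
  p <- model$params
  L <- ncol(X)
  grads <- list(Wd = crossprod(fw$h2_dropped, d_scores_pre),
                bd = colSums(d_scores_pre))
  dh2 <- d_scores_pre %*% t(p$Wd)
  if (!is.null(fw$d2)) dh2 <- dh2 * fw$d2
  b2 <- gru_backward(p, "2", fw$l2$cache, d_hs = NULL, d_h_last = dh2)
  grads <- c(grads, b2$grads)
  d_h1 <- b2$d_inputs
  for (t in seq_len(L)) {
    if (!is.null(fw$d1[[t]])) d_h1[[t]] <- d_h1[[t]] * fw$d1[[t]]
  }
  b1 <- gru_backward(p, "1", fw$l1$cache, d_hs = d_h1, d_h_last = NULL)
  grads <- c(grads, b1$grads)
  dE <- p$E * 0
  for (t in seq_len(L)) {
    de <- b1$d_inputs[[t]]
    if (!is.null(fw$d0[[t]])) de <- de * fw$d0[[t]]
    acc <- rowsum(de, group = X[, t] + 1L)
    rows <- as.integer(rownames(acc))
    dE[rows, ] <- dE[rows, , drop = FALSE] + acc
  }
  dE[1L, ] <- 0  # padding embedding stays fixed at zero
  grads$E <- dE
  grads
}

#' Score encoded sequences with the model
#'
#' Deterministic forward pass (dropout disabled) producing one score per
#' vocabulary tool, each in (0, 1), interpreted as the probability that the
#' tool is the next one.
#'
#' @param model A `recommender_model`.
#' @param sequences Integer matrix N x max_len (or a single encoded vector).
#' @return Numeric matrix N x V of scores.
#' @export
predict_scores <- function(model, sequences) {
  if (is.null(dim(sequences))) sequences <- matrix(sequences, nrow = 1L)
  if (ncol(sequences) != model$config$max_len) {
    stop("encoded length does not match the model's max_len", call. = FALSE)
  }
  fw <- forward_pass(model, sequences, training = FALSE)
  colnames(fw$scores) <- model$vocabulary$id_of
  fw$scores
}

rmsprop_step <- function(params, grads, cache, lr, rho = 0.9, eps = 1e-7) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    cache[[nm]] <- if (is.null(cache[[nm]])) (1 - rho) * g^2 else
      rho * cache[[nm]] + (1 - rho) * g^2
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(cache[[nm]]) + eps)
  }
  params$E[1L, ] <- 0
  list(params = params, cache = cache)
}

batch_loss_and_grad <- function(model, X, Y, w, training = TRUE) {
  fw <- forward_pass(model, X, training = training)
  p <- pmin(pmax(fw$scores, EPS_CLIP), 1 - EPS_CLIP)
  B <- nrow(X); V <- ncol(Y)
  wm <- rep(w, each = B)
  loss <- -sum((Y * log(p) + (1 - Y) * log(1 - p)) * wm) / (B * V)
  # gradient through the sigmoid of the clipped BCE: (p - y) * w / (B V)
  d_pre <- (fw$scores - Y) * wm / (B * V)
  list(loss = loss, fw = fw, d_pre = d_pre)
}

#' Train the recommender model
#'
#' Runs `config$epochs` iterations of mini-batch training: each epoch draws
#' class-balanced batches from the last-tool sampler (or shuffled sequential
#' batches when `sampler` is NULL), computes the usage-weighted
#' cross-entropy of Eq.-style form against the combined (shared + non-shared)
#' label matrix, backpropagates through time and updates all parameters
#' with RMSProp. Deterministic for fixed seeds under single-threaded BLAS.
#'
#' @param model An untrained (or partially trained) `recommender_model`.
#' @param dataset An `encoded_dataset` built from the training split.
#' @param sampler Optional `last_tool_index` built from the same split; when
#'   supplied, batches are drawn by two-stage uniform label sampling.
#' @param validation Optional `encoded_dataset` used to record per-epoch
#'   validation loss and precision@1/@2 (combined labels).
#' @param seed Integer seed controlling dropout and batch draws.
#' @return List with `model` (trained) and `history` (data.frame with one
#'   row per epoch: epoch, train_loss, val_loss, val_precision1,
#'   val_precision2).
#' @export
train_model <- function(model, dataset, sampler = NULL, validation = NULL,
                        seed = 1L) {
  stopifnot(inherits(model, "recommender_model"),
            inherits(dataset, "encoded_dataset"))
  cfg <- model$config
  V <- model$vocabulary$size
  if (dataset$vocab_size != V) stop("vocabulary mismatch", call. = FALSE)
  w <- if (is.null(model$weights)) rep(1, V) else unname(model$weights$weight_of)
  n <- nrow(dataset$sequences)
  batch_size <- min(cfg$batch_size, n)
  cache <- list()
  history <- vector("list", cfg$epochs)
  with_seed(seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ep_seed <- (abs(seed) * 131L + epoch * 7L) %% 2147483647L
      if (!is.null(sampler)) {
        batches <- sample_epoch_batches(sampler, n, batch_size,
                                        rng_seed = ep_seed)
      } else {
        ord <- sample.int(n)
        n_b <- n %/% batch_size
        batches <- split(ord[seq_len(n_b * batch_size)],
                         rep(seq_len(n_b), each = batch_size))
      }
      losses <- numeric(length(batches))
      for (b in seq_along(batches)) {
        ids <- batches[[b]]
        X <- dataset$sequences[ids, , drop = FALSE]
        Y <- dataset$combined_labels[ids, , drop = FALSE]
        st <- batch_loss_and_grad(model, X, Y, w, training = TRUE)
        if (!is.finite(st$loss)) {
          stop(sprintf(
            "training diverged (non-finite loss) at epoch %d, batch %d; try a lower learning rate",
            epoch, b), call. = FALSE)
        }
        grads <- backward_pass(model, X, st$fw, st$d_pre)
        upd <- rmsprop_step(model$params, grads, cache, cfg$learning_rate)
        model$params <- upd$params
        cache <- upd$cache
        losses[b] <- st$loss
      }
      rec <- data.frame(epoch = epoch, train_loss = mean(losses),
                        val_loss = NA_real_, val_precision1 = NA_real_,
                        val_precision2 = NA_real_)
      if (!is.null(validation)) {
        scores <- predict_scores(model, validation$sequences)
        p <- pmin(pmax(scores, EPS_CLIP), 1 - EPS_CLIP)
        Yv <- validation$combined_labels
        wm <- rep(w, each = nrow(Yv))
        rec$val_loss <- -sum((Yv * log(p) + (1 - Yv) * log(1 - p)) * wm) /
          length(Yv)
        rec$val_precision1 <- mean_precision_at_k(scores, Yv, 1L)
        rec$val_precision2 <- mean_precision_at_k(scores, Yv, 2L)
      }
      history[[epoch]] <- rec
    }
  })
  model$trained <- TRUE
  list(model = model, history = do.call(rbind, history))
}

STORE_GROUPS <- c("network", "vocabulary", "tool_weights")

#' Save a recommender model store
#'
#' Writes a single hierarchical store (RDS) with the groups `network`
#' (layer parameters and configuration), `vocabulary` (the dictionary of
#' tools and their indices), `tool_weights` (the per-tool class weights)
#' and `categories` (shared-capable tools for recommendation ranking).
#'
#' @param model A `recommender_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "recommender_model"))
  store <- list(
    format = "toolrec-model-store", version = 1L,
    network = list(params = model$params, config = unclass(model$config),
                   trained = model$trained),
    vocabulary = unclass(model$vocabulary),
    tool_weights = if (is.null(model$weights)) list(weight_of = NULL) else
      unclass(model$weights),
    categories = list(shared_tools = model$shared_tools)
  )
  saveRDS(store, path)
  invisible(path)
}

#' Load a recommender model store
#'
#' Validates that all required groups are present and reconstructs a model
#' whose predictions are bitwise identical to the saved one.
#'
#' @param path Path written by [save_model()].
#' @return A `recommender_model`.
#' @export
load_model <- function(path) {
  store <- readRDS(path)
  missing <- setdiff(STORE_GROUPS, names(store))
  if (!is.list(store) || length(missing) > 0L) {
    stop(sprintf("corrupt model store: missing group(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cfg <- do.call(model_config, store$network$config)
  vocab <- structure(store$vocabulary, class = "tool_vocabulary")
  weights <- if (is.null(store$tool_weights$weight_of)) NULL else
    structure(store$tool_weights, class = "tool_weights")
  if (ncol(store$network$params$Wd) != vocab$size) {
    stop("corrupt model store: dense layer size does not match vocabulary",
         call. = FALSE)
  }
  structure(list(config = cfg, vocabulary = vocab, weights = weights,
                 shared_tools = store$categories$shared_tools %||% character(0),
                 params = store$network$params,
                 trained = isTRUE(store$network$trained)),
            class = "recommender_model")
}
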