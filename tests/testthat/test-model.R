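tiny_vocab <- function(n = 4L) vocab_of(sprintf("t%02d", seq_len(n)))

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(embedding_dim = 3L, gru_units = 3L, dropout_embed = 0,
         dropout_between = 0, dropout_out = 0, learning_rate = 1e-2,
         batch_size = 2L, epochs = 2L, max_len = 5L),
    list(...)
  )
  do.call(model_config, args)
}

test_that("sigmoid matches its closed form and identities", {
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(10), 0.9999546, tolerance = 1e-6)
  set.seed(1)
  x <- stats::rnorm(50, sd = 5)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 50), tolerance = 1e-12)
  expect_true(all(sigmoid(c(-1e4, 1e4)) >= 0 & sigmoid(c(-1e4, 1e4)) <= 1))
})

test_that("weighted cross-entropy matches a scalar reference loop", {
  expect_equal(weighted_crossentropy(c(1, 0), c(0.5, 0.5), c(1, 1)), log(2),
               tolerance = 1e-12)
  expect_lt(weighted_crossentropy(c(1, 0), c(1 - 1e-7, 1e-7), c(1, 1)), 1e-5)
  set.seed(2)
  for (i in 1:100) {
    n <- sample(2:20, 1L)
    p_true <- sample(0:1, n, replace = TRUE)
    p_pred <- stats::runif(n)
    w <- stats::runif(n, 0.1, 5)
    expect_equal(weighted_crossentropy(p_true, p_pred, w),
                 scalar_wbce(p_true, p_pred, w), tolerance = 1e-10)
  }
  expect_error(weighted_crossentropy(c(1, 0), c(0.5), c(1, 1)), "length")
})

test_that("the loss is linear in the weights and penalizes heavy labels", {
  p_true <- c(1, 0, 1)
  p_pred <- c(0.2, 0.6, 0.9)
  w <- c(1.5, 0.5, 2)
  expect_equal(weighted_crossentropy(p_true, p_pred, 2 * w),
               2 * weighted_crossentropy(p_true, p_pred, w), tolerance = 1e-12)
  # a w=10 misclassification costs 10x the same mistake at w=1
  miss10 <- weighted_crossentropy(1, 0.1, 10)
  miss1 <- weighted_crossentropy(1, 0.1, 1)
  expect_equal(miss10 / miss1, 10, tolerance = 1e-12)
})

test_that("loss gradient w.r.t. predictions passes a finite-difference check", {
  set.seed(3)
  p_true <- sample(0:1, 6, replace = TRUE)
  p_pred <- stats::runif(6, 0.05, 0.95)
  w <- stats::runif(6, 0.5, 3)
  ana <- weighted_crossentropy_grad(p_true, p_pred, w)
  eps <- 1e-6
  for (i in 1:6) {
    up <- replace(p_pred, i, p_pred[i] + eps)
    dn <- replace(p_pred, i, p_pred[i] - eps)
    num <- (weighted_crossentropy(p_true, up, w) -
              weighted_crossentropy(p_true, dn, w)) / (2 * eps)
    expect_equal(ana[i], num, tolerance = 1e-5)
  }
})

test_that("network parameter count matches closed-form shape arithmetic", {
  vocab <- vocab_of(sprintf("t%02d", 1:10))
  cfg <- tiny_config(embedding_dim = 8L, gru_units = 16L)
  m <- build_model(cfg, vocab)
  V <- 10L; d <- 8L; u <- 16L
  want <- V * d +                      # embedding (padding row excluded)
    3L * (d * u + u * u + u) +         # GRU layer 1
    3L * (u * u + u * u + u) +         # GRU layer 2
    u * V + V                          # dense output
  expect_identical(count_parameters(m), want)
  expect_identical(ncol(m$params$Wd), V)
})

test_that("prediction scores are one per tool, strictly inside (0,1)", {
  vocab <- tiny_vocab(6L)
  m <- build_model(tiny_config(), vocab)
  X <- rbind(c(1L, 2L, 0L, 0L, 0L), c(3L, 0L, 0L, 0L, 0L))
  scores <- predict_scores(m, X)
  expect_identical(dim(scores), c(2L, 6L))
  expect_true(all(scores > 0 & scores < 1))
  expect_identical(predict_scores(m, X), scores)  # deterministic
})

test_that("full-network gradients pass a finite-difference check", {
  vocab <- tiny_vocab(4L)
  m <- build_model(tiny_config(), vocab, init_seed = 7)
  X <- rbind(c(1L, 2L, 3L, 0L, 0L), c(2L, 4L, 0L, 0L, 0L))
  Y <- rbind(c(0, 0, 0, 1), c(1, 0, 1, 0))
  w <- c(1, 2.5, 0.7, 1.3)
  ns <- asNamespace("toolrec")
  blg <- get("batch_loss_and_grad", ns)
  bwd <- get("backward_pass", ns)
  st <- blg(m, X, Y, w, training = FALSE)
  grads <- bwd(m, X, st$fw, st$d_pre)
  eps <- 1e-6
  set.seed(11)
  for (nm in names(grads)) {
    p <- m$params[[nm]]
    probe <- sample(seq_along(p), min(6L, length(p)))
    for (i in probe) {
      if (nm == "E" && (i - 1L) %% nrow(p) + 1L == 1L) next  # padding row
      m1 <- m; m1$params[[nm]][i] <- p[i] + eps
      m2 <- m; m2$params[[nm]][i] <- p[i] - eps
      num <- (blg(m1, X, Y, w, FALSE)$loss - blg(m2, X, Y, w, FALSE)$loss) /
        (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and records one row per epoch", {
  # linearly separable toy grammar: each tool deterministically follows one
  set.seed(21)
  tools <- sprintf("t%02d", 1:6)
  samples <- c(
    lapply(1:5, function(i) ts(tools[i], shared = tools[i + 1L])),
    lapply(1:4, function(i) ts(tools[i:(i + 1L)], shared = tools[i + 2L]))
  )
  vocab <- build_vocabulary(samples)
  ds <- encode_dataset(samples, vocab, max_len = 5L)
  idx <- build_last_tool_index(samples, vocab)
  cfg <- tiny_config(embedding_dim = 8L, gru_units = 12L, epochs = 10L,
                     batch_size = 3L, learning_rate = 2e-2)
  m <- build_model(cfg, vocab)
  fit <- train_model(m, ds, sampler = idx, validation = ds, seed = 5)
  expect_identical(nrow(fit$history), 10L)
  expect_identical(fit$history$epoch, 1:10)
  expect_lt(tail(fit$history$train_loss, 1L), fit$history$train_loss[1L])
  expect_true(fit$model$trained)
  # same seeds reproduce the identical trajectory
  fit2 <- train_model(build_model(cfg, vocab), ds, sampler = idx,
                      validation = ds, seed = 5)
  expect_identical(fit$history, fit2$history)
})

test_that("the model store round-trips predictions bitwise", {
  vocab <- tiny_vocab(5L)
  m <- build_model(tiny_config(), vocab,
                   weights = compute_tool_weights(list(), vocab),
                   shared_tools = c("t01", "t03"))
  X <- matrix(c(1L, 4L, 0L, 0L, 0L), nrow = 1L)
  before <- predict_scores(m, X)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_scores(m2, X), before)
  expect_identical(m2$vocabulary$index_of, m$vocabulary$index_of)
  expect_identical(m2$weights$weight_of, m$weights$weight_of)
  expect_identical(m2$shared_tools, c("t01", "t03"))
  # dense output dimension always equals the stored vocabulary size
  expect_identical(ncol(m2$params$Wd), m2$vocabulary$size)
})

test_that("stores missing a required group are rejected", {
  vocab <- tiny_vocab(5L)
  m <- build_model(tiny_config(), vocab)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  store <- readRDS(path)
  for (group in c("network", "vocabulary", "tool_weights")) {
    broken <- store[setdiff(names(store), group)]
    bad <- tempfile(fileext = ".rds")
    saveRDS(broken, bad)
    expect_error(load_model(bad), "corrupt model store")
  }
})
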