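test_that("precision@k counts correct tools among the top k", {
  scores <- c(0.9, 0.8, 0.1, 0.05, 0.02)
  # exactly one of the two top-scoring tools is a true label -> 1/2 = 0.5
  expect_identical(precision_at_k(scores, true_labels = c(1L, 5L), k = 2L), 0.5)
  expect_identical(precision_at_k(scores, c(1L, 2L), 2L), 1.0)
  expect_identical(precision_at_k(scores, c(4L, 5L), 2L), 0.0)
  expect_identical(precision_at_k(scores, integer(0), 1L), NA_real_)
  expect_error(precision_at_k(scores, 1L, 6L), "exceeds")
  # deterministic tie-break by ascending tool index
  expect_identical(precision_at_k(c(0.5, 0.5, 0.5), 1L, 1L), 1.0)
  expect_identical(precision_at_k(c(0.5, 0.5, 0.5), 3L, 1L), 0.0)
})

test_that("precision@k equals a brute-force sort-and-count oracle", {
  set.seed(17)
  for (rep in 1:200) {
    V <- sample(3:30, 1L)
    scores <- stats::runif(V)
    labs <- sample.int(V, sample(1:3, 1L))
    k <- sample(1:3, 1L)
    ranked <- order(scores, decreasing = TRUE)
    want <- sum(ranked[seq_len(k)] %in% labs) / k
    expect_identical(precision_at_k(scores, labs, k), want)
  }
})

test_that("hit count k * precision@k never decreases in k", {
  set.seed(18)
  for (rep in 1:30) {
    scores <- stats::runif(12)
    labs <- sample.int(12L, 3L)
    hits <- vapply(1:12, function(k)
      k * precision_at_k(scores, labs, k), numeric(1))
    expect_true(all(diff(hits) >= -1e-12))
  }
})

test_that("evaluation averages per category and skips unlabelled samples", {
  vocab <- vocab_of(c("a", "b", "c", "d"))
  # bias model always ranks tool "a" first, then "b"
  m <- bias_model(vocab, bias = c(4, 3, 2, 1))
  samples <- list(ts("b", shared = "a"),                  # shared hit
                  ts("c", shared = "d", nonshared = "b"), # shared miss
                  ts("d", nonshared = "a"))               # nonshared hit
  ds <- encode_dataset(samples, vocab, max_len = m$config$max_len)
  rep <- evaluate_model(m, ds, ks = 1L)
  p <- function(cat) rep$precision[rep$category == cat]
  expect_identical(p("shared"), 0.5)      # mean of {1, 0}, third excluded
  expect_identical(p("nonshared"), 0.5)   # mean of {0, 1}
  expect_identical(rep$n[rep$category == "shared"], 2L)
  # an always-right model scores precision@1 = 1 everywhere it is defined
  oracle_rep <- evaluate_model(
    bias_model(vocab, c(4, 3, 2, 1)),
    encode_dataset(list(ts("b", shared = "a"), ts("c", nonshared = "a")),
                   vocab, max_len = m$config$max_len),
    ks = 1L
  )
  expect_identical(oracle_rep$precision[oracle_rep$category == "combined"], 1.0)
  # a category with no labelled samples is reported NA, not 0
  only_shared <- encode_dataset(list(ts("b", shared = "a")), vocab,
                                max_len = m$config$max_len)
  rep2 <- evaluate_model(m, only_shared, ks = 1L)
  expect_true(is.na(rep2$precision[rep2$category == "nonshared"]))
})

test_that("usage-frequency of predictions sums top-k weights", {
  vocab <- vocab_of(c("a", "b", "c", "d"))
  m <- bias_model(vocab, bias = c(4, 3, 2, 1))
  ds <- encode_dataset(list(ts("b", shared = "a"), ts("c", shared = "a")),
                       vocab, max_len = m$config$max_len)
  tw <- compute_tool_weights(list(), vocab)          # all weights 1
  expect_identical(usage_frequency_of_predictions(m, ds, tw, k = 2L), 2)
  tw$weight_of[] <- c(5, 0.5, 0.5, 0.5)
  # top-1 is always tool "a" -> metric equals its weight
  expect_identical(usage_frequency_of_predictions(m, ds, tw, k = 1L), 5)
  # brute-force per-sample summation agrees
  set.seed(19)
  tw$weight_of[] <- stats::runif(4, 0.5, 3)
  scores <- predict_scores(m, ds$sequences)
  want <- mean(vapply(seq_len(nrow(scores)), function(i) {
    top <- order(-scores[i, ], seq_len(4L))[1:2]
    sum(tw$weight_of[top])
  }, numeric(1)))
  expect_equal(usage_frequency_of_predictions(m, ds, tw, k = 2L), want,
               tolerance = 1e-12)
})

test_that("repeated experiments aggregate per-epoch means and SDs", {
  set.seed(23)
  tools <- sprintf("t%02d", 1:6)
  samples <- c(
    lapply(1:5, function(i) ts(tools[i], shared = tools[i + 1L])),
    lapply(1:4, function(i) ts(tools[i:(i + 1L)], shared = tools[i + 2L])),
    lapply(1:3, function(i) ts(tools[i:(i + 2L)], nonshared = tools[i + 3L]))
  )
  cfg <- model_config(embedding_dim = 8, gru_units = 8, epochs = 2,
                      batch_size = 4, dropout_embed = 0, dropout_between = 0,
                      dropout_out = 0)
  rep <- run_experiments(samples, cfg, n_runs = 2L, seeds = c(1L, 2L))
  expect_identical(sort(unique(rep$per_run$run)), 1:2)
  expect_identical(nrow(rep$summary), 2L * 4L)  # epochs x metrics
  expect_true(all(rep$summary$sd >= 0, na.rm = TRUE))
  # one shared seed -> zero variance across runs
  same <- run_experiments(samples, cfg, n_runs = 2L, seeds = c(3L, 3L))
  expect_true(all(same$summary$sd == 0, na.rm = TRUE))
  # reproducibility of the whole experiment
  rep2 <- run_experiments(samples, cfg, n_runs = 2L, seeds = c(1L, 2L))
  expect_identical(rep$summary, rep2$summary)
})
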