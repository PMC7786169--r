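test_that("path enumeration returns every contiguous subpath of length >= 2", {
  g <- wf_graph(list(c("A", "B"), c("B", "C"), c("C", "D"), c("C", "E")))
  paths <- enumerate_paths(g)
  got <- sort(vapply(paths, paste, character(1), collapse = ">"))
  expect_identical(got, sort(c("A>B", "B>C", "C>D", "C>E", "A>B>C",
                               "B>C>D", "B>C>E", "A>B>C>D", "A>B>C>E")))
  expect_length(enumerate_paths(wf_graph(list(c("A", "B")))), 1L)
  empty <- wf_graph(list())
  empty$edges <- data.frame(parent_tool = character(0),
                            child_tool = character(0))
  expect_identical(enumerate_paths(empty), list())
  expect_error(enumerate_paths(wf_graph(list(c("A", "B"), c("B", "A")))),
               "cycle")
})

test_that("a workflow's last tools become multi-labels of the subsequence", {
  g <- wf_graph(list(c("A", "B"), c("B", "C"), c("C", "D"), c("C", "E")))
  samples <- extract_samples(list(g))
  expect_length(samples, 6L)
  key <- vapply(samples, function(s) paste(s$subsequence, collapse = ">"),
                character(1))
  abc <- samples[[which(key == "A>B>C")]]
  expect_identical(abc$shared_labels, c("D", "E"))
  expect_identical(abc$nonshared_labels, character(0))
})

test_that("label provenance pools shared-first across workflows", {
  g1 <- wf_graph(list(c("A", "B")), id = "w1", shared = TRUE)
  g2 <- wf_graph(list(c("A", "C")), id = "w2", shared = FALSE)
  g3 <- wf_graph(list(c("A", "B")), id = "w3", shared = FALSE)
  samples <- extract_samples(list(g1, g2, g3))
  expect_length(samples, 1L)
  s <- samples[[1L]]
  expect_identical(s$subsequence, "A")
  expect_identical(s$shared_labels, "B")     # shared precedence over w3
  expect_identical(s$nonshared_labels, "C")
  expect_length(intersect(s$shared_labels, s$nonshared_labels), 0L)
})

test_that("fragments longer than max_len are discarded", {
  chain <- sprintf("t%02d", 1:30)
  edges <- Map(c, chain[-30], chain[-1])
  samples <- extract_samples(list(wf_graph(edges)), max_len = 25L)
  lens <- vapply(samples, function(s) length(s$subsequence), integer(1))
  expect_lte(max(lens), 24L)
  # every prefix of an in-range chain appears with the next tool as label
  short <- extract_samples(list(wf_graph(Map(c, chain[1:9], chain[2:10]))))
  key <- vapply(short, function(s) paste(s$subsequence, collapse = ">"),
                character(1))
  for (k in 1:9) {
    prefix <- paste(chain[1:k], collapse = ">")
    i <- which(key == prefix)
    expect_length(i, 1L)
    expect_true(chain[k + 1L] %in% c(short[[i]]$shared_labels,
                                     short[[i]]$nonshared_labels))
  }
})

test_that("sample extraction matches brute-force enumeration on random DAGs", {
  set.seed(404)
  for (rep in 1:50) {
    edges <- random_dag(sample(3:12, 1L), p_edge = stats::runif(1, 0.15, 0.5))
    shared <- rep %% 2L == 0L
    g <- structure(list(workflow_id = "w", edges = edges, is_shared = shared),
                   class = "workflow_graph")
    got <- extract_samples(list(g))
    want <- brute_samples(list(g))
    expect_length(got, length(want))
    for (s in got) {
      k <- paste(s$subsequence, collapse = "\x1f")
      expect_identical(s$shared_labels, want[[k]]$shared)
      expect_identical(s$nonshared_labels, want[[k]]$nonshared)
    }
  }
})

test_that("train/test split is disjoint, sized and deterministic", {
  samples <- lapply(1:100, function(i) ts(sprintf("t%03d", i), shared = "x"))
  sp <- split_train_test(samples, fraction = 0.8, seed = 42)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  key <- function(ss) vapply(ss, function(s)
    paste(s$subsequence, collapse = ","), character(1))
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  sp2 <- split_train_test(samples, fraction = 0.8, seed = 42)
  expect_identical(key(sp$train), key(sp2$train))

  sp3 <- split_train_test(lapply(1:101, function(i)
    ts(sprintf("u%03d", i), shared = "x")), fraction = 0.5, seed = 9)
  expect_true(length(sp3$train) %in% c(50L, 51L))
  expect_error(split_train_test(samples[1], seed = 1), "at least 2")
})

test_that("samples export to the comma-joined TSV dialect", {
  samples <- list(ts(c("a", "b"), shared = "c", nonshared = c("d", "e")))
  path <- tempfile(fileext = ".tsv")
  write_samples_tsv(samples, path)
  tab <- read.delim(path, colClasses = "character")
  expect_identical(tab$subsequence, "a,b")
  expect_identical(tab$nonshared_labels, "d,e")
})
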