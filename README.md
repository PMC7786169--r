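# toolrec

Next-tool recommendation for scientific workflow construction.

Researchers on platforms such as Galaxy assemble analyses as workflows —
directed acyclic graphs (DAGs) of tools in which each edge feeds one tool's
output into the next tool's input. With thousands of tools available,
picking a sensible next step is hard, and a statistically wrong choice can
produce results that run without error but mean nothing. `toolrec` learns
from an existing workflow corpus to score every tool on how plausible it is
as the *next* tool for a partial sequence, and ranks recommendations with
high-quality (published, non-deleted, non-erroneous — "shared") provenance
first.

## The model

Workflows are decomposed into all contiguous tool sequences of length ≥ 2;
the last tool of each fragment is a label of the preceding subsequence, and
labels are pooled per unique subsequence, giving a multi-label task: the
model estimates

    p(x_T | x_1, x_2, ..., x_{T-1})

with a gated recurrent unit (GRU) network — embedding (index 0 = padding,
sequences encoded to length 25 with trailing zeros) → dropout → GRU →
dropout → GRU → dropout → dense sigmoid over the vocabulary, ELU
activations in both GRU layers. Training minimises a usage-weighted
cross-entropy with RMSProp:

    loss = -(1/T) * sum_i [ p_i^a * log(p_i^b) + (1 - p_i^a) * log(1 - p_i^b) ] * w_i

where `w_i = ln(1 + forecast next-month usage of tool i)`; the forecast
comes from ε-SVR over the trailing 12 months of usage, grid-searched over
3 kernels × 2 degrees with 5-fold CV. Batches are drawn by two-stage
uniform sampling (uniform over label tools, then uniform over that tool's
sequences) to flatten the heavy label skew of real corpora. Evaluation is
precision@k (k = 1, 2), reported separately for shared and non-shared
labels, with mean ± SD across repeated seeded runs. A seeded synthetic
corpus generator with exactly known next-tool ground truth makes the whole
pipeline testable without access to a workflow server.

## Worked example

```r
library(toolrec)

## a seeded synthetic corpus written in the package's TSV dialects
dir <- tempfile()
spec <- grammar_spec(n_tools = 30, n_layers = 5, fanout = 2,
                     n_workflows = 250, p_shared = 0.3, seed = 42)
write_corpus_tsv(generate_corpus(spec),
                 generate_usage(sprintf("tool_%03d", 1:30), seed = 42), dir)

## ingest -> decompose -> encode -> weight -> train
graphs  <- read_workflow_connections(file.path(dir, "workflow_connections.tsv"))
series  <- read_tool_usage(file.path(dir, "tool_usage.tsv"))
samples <- extract_samples(graphs)
vocab   <- build_vocabulary(samples)
weights <- compute_tool_weights(series, vocab)
sp      <- split_train_test(samples, fraction = 0.8, seed = 42)
train_ds <- encode_dataset(sp$train, vocab)
test_ds  <- encode_dataset(sp$test, vocab)
sampler  <- build_last_tool_index(sp$train, vocab)
shared   <- sort(unique(unlist(lapply(samples, `[[`, "shared_labels"))))

cfg <- model_config(embedding_dim = 32, gru_units = 64, epochs = 10,
                    batch_size = 2, learning_rate = 1e-2,
                    dropout_embed = 0.05, dropout_between = 0.05,
                    dropout_out = 0.05)
model <- build_model(cfg, vocab, weights = weights, shared_tools = shared,
                     init_seed = 42)
fit <- train_model(model, train_ds, sampler = sampler,
                   validation = test_ds, seed = 42)

tail(fit$history, 3)
#>    epoch train_loss val_loss val_precision1 val_precision2
#> 8      8     0.0289   0.2555         0.8667         0.8667
#> 9      9     0.0417   0.3338         0.9000         0.8167
#> 10    10     0.0273   0.3330         0.9000         0.8500

evaluate_model(fit$model, test_ds)
#>   k  category precision  n
#> 1 1    shared 0.9000000 30
#> 2 1 nonshared 0.0000000  1
#> 3 1  combined 0.9000000 30
#> 4 2    shared 0.8333333 30
#> 5 2 nonshared 0.5000000  1
#> 6 2  combined 0.8500000 30

save_model(fit$model, file.path(dir, "model.rds"))
recommend_tools(load_model(file.path(dir, "model.rds")),
                c("tool_003", "tool_008"), max_items = 3)
#> <recommendation_result> after tool_003 > tool_008:
#>   1. tool_018 (shared, 1.000)
#>   2. tool_014 (shared, 1.000)
#>   3. tool_013 (shared, 0.000)
```

After 10 epochs the model ranks a correct continuation first for 90% of
held-out contexts (`val_precision1`), and the two tools it is confident
about after `tool_003 > tool_008` are exactly the grammar's allowed
successors, shared labels first. The per-epoch history, the category
split, and `usage_frequency_of_predictions()` reproduce the result-file
metrics the evaluation module exports with `write_report_tsv()`.

Command-line entry points wrap the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "simulate.R", package = "toolrec"))') \
    --out corpus/ --n-tools 40 --seed 1
Rscript $(Rscript -e 'cat(system.file("cli", "recommend.R", package = "toolrec"))') \
    --model model.rds --tools "tool_003,tool_008" --topk 3
```

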