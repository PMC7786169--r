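---
title: "Recommending the next tool in a scientific workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending the next tool in a scientific workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(toolrec)
```

## The problem

Platforms such as Galaxy let researchers chain thousands of analysis tools
into workflows — directed acyclic graphs (DAGs) in which each edge feeds one
tool's output into the next tool's input. Choosing a sensible next tool from
such a catalogue is hard, especially for newcomers, and a wrong choice (say,
a count-based statistical model applied to continuous intensities) produces
results that run fine but mean nothing. `toolrec` builds a recommender that,
given a partial tool sequence, scores every known tool on how plausible it
is as the next step, learning purely from the connection patterns in an
existing corpus of workflows — no tool annotations, datatype metadata or
ontology terms are used.

## From workflow graphs to training samples

Each workflow DAG is decomposed into **tool sequences**: every contiguous
directed subpath with at least 2 tools. For a fragment of length $n$, the
first $n-1$ tools form the input subsequence and the $n$-th tool is a
label. Because one subsequence may be continued in different ways across
the corpus, labels are pooled per unique subsequence, making the task
**multi-label**: the model estimates

$$p(x_T \mid x_1, x_2, \ldots, x_{T-1})$$

for every candidate tool $x_T$. Decomposing into *all* contiguous
fragments, not only prefixes of maximal paths, was a deliberate choice:
fragments starting mid-workflow give the learner many short and long
contexts, and the same rule makes a tool depend on all of its predecessors
in the fragment (a higher-order dependency), not only the immediately
preceding one. Fragments longer than 25 tools are discarded; a brute-force
fragment enumerator in the test suite pins this rule on random DAGs.

Labels carry provenance. A workflow that is published, not deleted and not
erroneous is **shared**; its labels form the high-quality category that is
ranked first at recommendation time. All other workflows contribute
**non-shared** labels. A label seen in both categories is kept as shared
only (shared precedence), so the two sets never overlap.

The train/test split is a uniform random 80/20 draw over *unique*
subsequences, so no subsequence can appear on both sides of the split. The
paper-scale corpus leaves label leakage between identical subsequences
unaddressed; splitting by unique subsequence closes that hole at the cost
of making held-out contexts genuinely unseen.

## Encoding

A dictionary assigns each tool an index $1..V$ in lexicographic order
(deterministic, so rebuilding a model store from the same corpus reproduces
the identical mapping); index 0 is reserved for padding and is never a
tool. A subsequence becomes a length-25 integer vector — indices in order,
then trailing zeros — and each label set becomes a multi-hot bit vector of
length $V$. The loss is trained on the elementwise union of the shared and
non-shared bit vectors; provenance only matters at evaluation and ranking
time.

## Class imbalance and two-stage uniform sampling

Raw label frequencies in workflow corpora are extremely skewed: a handful
of generic text-manipulation tools terminate tens of thousands of
fragments while specialised tools appear a few times. Training batches are
therefore drawn by a two-stage rule: first a *label tool* is drawn
uniformly from the set of last tools, then a training sequence is drawn
uniformly from the sequences carrying that label. An epoch consists of
$\lfloor n/\text{batch} \rfloor$ batches (2,000 sequences at batch size 100
give 20 batches), sampled with replacement so rare labels are oversampled.
The suite checks flatness on a 900/50/50 skew: each label's draw count
stays within 5 standard deviations of the uniform multinomial expectation.

Sampling with replacement within an epoch is a documented choice: a
balanced epoch over a skewed corpus is impossible without repeating
sequences that carry rare labels.

## Usage-derived class weights

Tools that are heavily used *right now* should be penalised more when
misclassified, and stale tools should fade. Each tool's monthly usage
counts over the trailing 12 months are extrapolated one month ahead with
$\varepsilon$-support-vector regression; the regressor input is simply the
month ordinal $1..12$. A grid search over all 6 combinations of kernel
(radial, polynomial, linear) and degree (2, 3) is scored by 5-fold
cross-validated mean squared error (CV scoring is not specified upstream;
MSE is the standard regression choice), the winner is refit on all 12
months and evaluated at month 13, clipped below at 0. The class weight is

$$w_i = \ln(1 + \hat{u}_i),$$

where $\hat{u}_i$ is the forecast. The logarithm compresses the scale so
that forecasts spanning $10$ to $10^5$ keep a weight ratio under 6 and the
few very popular tools cannot dominate the loss. The log base, the $+1$
offset and the zero-usage case are this package's decisions: $\ln(1+x)$
keeps weights finite at $x = 0$, and tools with no usage data (or a zero
forecast) receive a floor weight of 1.0 so their loss contribution never
vanishes. Deterministic interleaved CV folds (`fold = (i - 1) mod 5 + 1`)
make the whole procedure reproducible. Two numerical details: a training
fold whose residuals all fall inside the $\varepsilon$-tube (e.g. a
constant series) yields an empty support-vector set, which degenerates to
predicting the fold mean; an all-zero series shortcuts to a forecast of 0
without fitting.

## The network

The classifier is: embedding ($V{+}1 \times d$, padding row fixed at zero)
→ dropout → GRU → dropout → GRU → dropout → dense($V$) with a sigmoid

$$f(x) = \frac{1}{1 + e^{-x}}$$

on every output, so each tool receives an independent probability-like
score in $(0,1)$. Both GRU layers use ELU candidate activations, whose
negative values keep mean activations near zero and speed up training. The
loss is the usage-weighted cross-entropy

$$\mathrm{loss} = -\frac{1}{T} \sum_{i=1}^{T}
  \left[ p^a_i \log p^b_i + (1 - p^a_i) \log (1 - p^b_i) \right] w_i,$$

with $T = V$ the label-vector length, $p^a$ the true multi-hot vector and
$p^b$ the predictions, minimised with RMSProp (decay 0.9). With all
$w_i = 1$ this is ordinary multi-label binary cross-entropy; a $w = 10$
label misclassified costs exactly ten times the same mistake at $w = 1$.

The forward pass, backpropagation through time and the optimizer are
implemented directly in R matrix code. Correctness rests on two guards in
the test suite: the loss matches an independent scalar-loop reference to
$10^{-10}$ on random inputs, and every parameter group of a small network
passes a central finite-difference gradient check.

Numerical choices worth knowing:

* predictions are clipped into $[\epsilon, 1-\epsilon]$, $\epsilon =
  10^{-7}$, before any logarithm;
* padded timesteps carry the hidden state through unchanged, so trailing
  zeros never contaminate the final state, and the padding embedding row
  is excluded from updates;
* input kernels use Glorot-uniform initialisation, recurrent kernels are
  orthogonal, embeddings uniform $\pm 0.05$; all draws are seeded, so runs
  are reproducible under single-threaded BLAS;
* a non-finite training loss aborts with a diagnostic rather than
  continuing silently.

## Hyperparameter tuning

`tune_hyperparameters()` performs sequential model-based (Bayesian)
optimisation with a tree-structured Parzen estimator: after a random
start-up quarter, observed configurations are split at the best-quartile
boundary of validation loss, candidates are drawn from per-dimension
Parzen mixtures over the good group and ranked by the good/bad density
ratio. Exactly `n_evals` (default 20) short trainings are run, each scored
by validation loss on an internal 80/20 split of the training samples. The
default search ranges (embedding and GRU width 32–512, dropout 0–0.5,
learning rate $10^{-4}$–$10^{-2}$ log-uniform, batch size 32–256) are
package defaults, overridable per dimension through `search_space()`.

## Evaluation

`precision_at_k` takes the $k$ highest-scoring tools (ties broken by
ascending tool index, for determinism) and returns the fraction that are
true labels: one correct tool in the top 2 gives $1/2 = 0.5$ exactly.
Means are reported separately for shared and non-shared label sets (plus
their union); a sample with no label in a category is *excluded* from that
category's mean rather than scored 0 — precision@2 is simply undefined for
a sample with no shared label, and scoring it 0 would conflate "undefined"
with "wrong". `run_experiments()` repeats split → train → evaluate with
distinct seeds (default 10 runs) and aggregates per-epoch trajectories
into means and standard deviations; `usage_frequency_of_predictions()`
reports the mean summed weight of the top-$k$ predictions, the metric that
shows whether the weighted loss steers recommendations toward currently
used tools.

## Recommendation ranking

At inference, all $V$ tools are scored in one forward pass. The network
produces a single score vector, but recommendations must rank shared
provenance first; since the corpus, not the network, knows which tools are
shared-capable, the extraction step persists the set of tools ever seen as
shared labels into the model store, and `recommend_tools()` partitions
candidates with it: shared block first, each block sorted by descending
score, truncated to `max_items` (truncation therefore never drops a shared
item while keeping a non-shared one). A model without a category map — or
a corpus where a context was never seen — degrades gracefully to a single
ranked list flagged non-shared. Administrators can replace the predictions
for a given last tool (`overrides`) or append newly added tools
(`extra_tools`), which appear flagged `override`.

## The model store

`save_model()` writes one hierarchical store (an RDS file) with the groups
the system needs to be reconstructed elsewhere: network parameters and
configuration, the dictionary of tools and their indices, the per-tool
usage weights, and the shared-capable tool set. `load_model()` validates
the three required groups and rebuilds a model whose predictions are
bitwise identical to the saved one; a store missing a group is rejected as
corrupt.

## The synthetic corpus

Real workflow corpora are private; the package therefore ships a seeded
generator whose ground truth is exactly enumerable. Tools are partitioned
into layers and each non-terminal tool is assigned exactly `fanout`
successors in the next layer, drawn once per seed; workflows are random
walks from a first-layer tool to the last layer, forking with probability
`p_branch` (default 0.25). Layering forbids skip and back edges, so every
generated graph is acyclic by construction and every edge respects the
successor map — testability was deliberately preferred over realism here.
The uniform fanout keeps corpus coverage even, so at the default 400
workflows the pooled label set of essentially every context saturates to
the full ground-truth successor set. Workflows are flagged shared with
probability `p_shared = 0.2`, reflecting that published workflows are a
minority on public servers. Usage series are Poisson draws around
constant, linearly increasing, linearly decreasing-to-zero, or bursty
intensity profiles.

What the generator does *not* emulate: version-suffixed tool identifiers,
skip connections, overlapping sub-communities of tools, non-stationary
grammar drift, and the heavy-tailed label skew of real corpora (its
fragment frequencies are far more uniform). Passing the recovery study
therefore shows that the pipeline learns a learnable grammar end to end —
not that it reaches any particular accuracy on a real server's corpus.

## Study sizes used by the test suite

The end-to-end recovery study trains a small model (embedding 32, 64 GRU
units, dropout 0.05, learning rate $10^{-2}$, batch size 2, 10 epochs) on
corpora from the 40-tool, 5-layer, fanout-2 grammar with 400 workflows,
and requires held-out precision@1 of at least 0.90 in the majority of 3
seeded runs. A small batch size is used deliberately: these corpora
contain only a few hundred unique subsequences, and with an epoch defined
as $\lfloor n/\text{batch}\rfloor$ batches, small batches are what provide
enough optimizer steps within 10 epochs. Unit tests run on corpora of
10–250 workflows and networks of 3–64 units so the whole suite stays
within a couple of minutes on one CPU.

## Known limitations

* Contexts whose only occurrence falls in the test split are unlearnable
  by construction (nothing in training ends at that tool); they bound the
  attainable held-out precision slightly below 1 even on a noiseless
  grammar.
* The SVR forecast uses month ordinals only; seasonality or usage shocks
  are out of scope.
* Scores are per-tool independent sigmoids, not a normalised distribution
  over tools; they are comparable within a query but are not calibrated
  probabilities.
* Training is single-threaded R matrix code: ideal for corpora up to a few
  thousand unique sequences, not for a million-sequence server dump.
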