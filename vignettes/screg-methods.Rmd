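---
title: "Model, objectives and design choices in screg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, objectives and design choices in screg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`screg` fits a small bidirectional transformer to raw single-cell RNA-seq
counts and reads cell-type gene networks out of its attention heads. This
vignette is the package's account of the model, its training objectives, the
network-extraction and benchmarking machinery, and the design decisions that
were genuinely open — with the reasoning behind each choice. Everything
quantitative claimed here is computed by the package's test suite or by
`scripts/acceptance.R`; this document states no number that the code does not
itself produce.

## The input representation

A cell enters the model as a set of per-gene tokens plus a handful of
placeholder tokens. Each gene token is the **sum of three streams**:

1. **Gene identity** — a frozen per-gene embedding standing in for a
   protein-language-model summary of the gene's product. The package loads a
   precomputed table when one is available; otherwise it draws unit-scale
   Gaussian vectors, deterministic per `(gene_id, seed)` so the vocabulary
   does not depend on processing order. Identity embeddings are frozen by
   default (a `trainable_gene_embeddings` flag enables updates, the ablation
   variant), preserving the ability to address genes never seen in training.
2. **Expression** — a two-layer MLP (each layer
   `Dropout(ReLU(LayerNorm(Linear(.))))`, dims 1 → d → d) applied to
   `log2(1 + count)`. Raw log counts rather than ranks or bins: the MLP
   learns its own metric of expression and extrapolates to unseen count
   magnitudes.
3. **Genome location** — genes are binned into location indices (consecutive
   genes on a chromosome closer than 10 kb share an index; chromosome
   boundaries always increment, since regulatory neighborhoods do not span
   chromosomes) and the index enters through the standard sinusoidal
   positional encoding. Ties in start coordinate are broken by
   `(start, gene_id)` for determinism. How unplaced scaffolds should be
   ordered is left open; the synthetic gene tables avoid them.

During training only a random **context** of expressed genes is shown
(default 2200 in the full-scale configuration; far smaller in the toy
configurations used throughout this package's tests). Cells with fewer
expressed genes are padded with randomly chosen unexpressed genes at count 0:
together with the denoising objective this teaches the model which zeros are
dropout and which are biological, as a function of sequencing depth.
Sampling is uniform without replacement — no weighting is applied because
none is specified for the sampling of expressed genes. Any context length
≥ 1 is accepted at inference; the package's evaluation routines simply pass
each cell's full profile.

The placeholder tokens (total-count token first, then a default cell token
and one per label class) are learned embeddings shared across cells. The
total-count token additionally carries the encoded `log2(1 + t)` of the
cell's total transcript count; whether this token is "one of the
placeholders" or a separate stream was ambiguous, and it is implemented as a
placeholder position whose input adds the encoded total — this keeps the
decoder's positional indexing uniform. Because the requested output depth
enters only here, overriding `t` at inference reconstructs the profile at any
requested sequencing depth.

## The transformer and the decoders

The backbone is a bidirectional (unmasked) pre-norm transformer with `n`
layers, `h` heads, dimension `d`, a 4x-wide GELU MLP, dropout 0.1, and
stochastic depth whose drop probability grows by 0.02 per layer. Attention is
the exact `softmax(QK^T / sqrt(d_k)) V`; there is no approximate or fused
path, and the test suite pins the implementation to a naive recomputation
within 1e-4 (the contract any optimized path would also have to satisfy).
With stochastic depth and dropout off, the forward pass is a deterministic
function of weights and input, which the tests check bitwise.

There being no deep-learning framework underneath, forward, backward and the
AdamW optimizer are written directly in base R against BLAS. The backward
pass is verified against central finite differences for every parameter
family (encoders, attention, MLPs, layer norms, decoders, placeholders) at
relative tolerance 1e-4.

**Expression decoder.** A `[d, d, 3]` MLP maps each gene's output embedding
to raw `(a, b, c)`, interpreted as `mu = exp(clamp(a))`,
`theta = exp(clamp(b))` (NB inverse-dispersion) and zero-inflation logit
`rho = c`. The likelihood is zero-inflated negative binomial:
`L(x) = pi * I(x = 0) + (1 - pi) * NB(x | mu, theta)` with
`pi = sigmoid(rho)`, evaluated in log space via log-gamma. Positivity via
`exp` with clamping to [-15, 15] is a choice the source formulas leave open;
it is the standard ZINB parameterization and the clamp prevents the overflow
these likelihoods are prone to. The zero-count branch is derived directly
from the mixture definition (a published closed form for that branch is
inconsistent with the mixture and was not transcribed); the implementation is
instead validated against a brute-force numerically normalized PMF oracle
built from `dnbinom`, to 1e-6 over a 1000-point parameter grid, and reduces
to NB as `rho -> -Inf` and further to Poisson as `theta -> Inf`. NB-only and
MSE-on-log-counts decoders are available behind `loss = "nb"` / `"mse"`.

**Class decoder.** Each label class has its own `[d, d, d_A]` MLP from its
placeholder's output embedding to one logit per **leaf** label of the class
ontology — only the most specific terms carry logits. The final layer is
initialized with weights around 1 and bias -0.12 (the description of this
initialization assigns two values to the bias; -0.12 is used and documented
here). The notation for the classifier output applies a sigmoid, while the
loss applies another activation on top; this is read as notation overload,
and the loss consumes raw logits with a softmax cross-entropy. Coarse labels
are handled by the hierarchical loss below; predictions can be lifted to any
coarser ontology node by summing descendant-leaf probabilities, and the
pre-sigmoid logits double as compact cell embeddings.

## The three pretraining objectives

All components are summed without scaling; removing a task removes exactly
its component.

**Denoising.** Each profile is downsampled through a zero-inflated Poisson:
`p ~ Poisson(x * r * s)`, keep mask `I(u >= r * s)`,
`x_hat = max((x - p) * keep, 0)`, with `r = 0.6` and scale `s = 0.55` (0.55
rather than 0.5 for numerical reasons, as specified). Roughly half the
removed counts come from thinning, half from whole-gene dropout; the mean
retained fraction is analytically bracketed in `[(1 - rs)^2, 1 - rs]` =
[0.4489, 0.67] at the defaults, and the test asserts that bracket rather than
a nominal "60% dropped", which the mechanism only approximates. The model
sees the noisy profile (the context is sampled from it) and must output ZINB
parameters for the **true** counts at the sampled gene positions; the loss is
the mean negative log-likelihood.

**Classification.** For each class, softmax cross-entropy over leaf logits.
A coarse (internal-node) label collapses its descendant-leaf logit block into
a single log-sum-exp logit; the loss equals
`LSE(all) - LSE(descendants)`, i.e. the negative log of the summed softmax
probability of the descendants — the tests verify both this marginalization
identity and that the loss depends on descendant logits only through their
LSE. Cells with an unknown label contribute zero. Classification uses the
embeddings from the same noisy-profile pass as denoising (one pass for both).

**Bottleneck + contrastive.** The model then acts as its own decoder: a
second forward pass receives gene tokens stripped of their expression stream
(identity + location only) and the first pass's placeholder **output**
embeddings as placeholder inputs, and must reconstruct the true profile under
the ZINB loss. Gradients flow through those embeddings back into the
encoder pass, which the tests confirm by finite differences. The total-count
position carries the true `t` re-encoded (not the pass-1 output); this is
what makes depth-controlled reconstruction possible. A contrastive term —
the mean over ordered pairs of a cell's class-embedding set (total-count
excluded) of `1 - cos` — is added as printed; note that minimizing `1 - cos`
*aligns* embeddings, whereas the stated intent is to push them apart, so a
`contrastive_sign = "repel"` switch implements `1 + cos` as the alternative.
Whether the pair set ranges over cells or over a cell's embedding set is also
ambiguous; the per-cell set is the default as it matches the disentanglement
goal.

## Optimization and the data loader

AdamW (decoupled weight decay 0.01) at learning rate 1e-4, 500 warmup steps,
gradient clipping at global norm 100, batch size 64, plateau LR decay by 0.6
with patience 1, early stop after 3 consecutive validation increases, a 98/2
train/validation split, and optional stochastic weight averaging at the
stated 0.03 averaging rate — these are the `train_config()` defaults.
Validation uses a frozen noisy batch so successive evaluations are
comparable. Cells are drawn by a weighted sampler: with `c` the size of a
cell's joint-label group, its weight is `50 / (c + 50)`, which caps the
boost of the rarest groups at about 50-fold per cell. The group is the joint
tuple over all label columns, matching the intent of sampling by rarity of
the label combination.

QC follows the published thresholds: drop cells expressing fewer than 200
genes, then reject a dataset with fewer than 100 surviving cells, fewer than
10,000 genes, or more than 95% of cells removed. Rejection is a typed
outcome. `screg()` does not apply QC implicitly — a toy vocabulary would
always fail the 10,000-gene dataset threshold — so QC is an explicit,
overridable step.

**Toy-scale study conditions.** The tests train a 2-layer, 2-head, d = 64
model on 5,000 synthetic cells (80 genes, 4 imbalanced groups) for 2,000
steps with batch 8, context 16 and learning rate 1e-3. Batch, context and
learning rate are toy-scale choices made up front: the 1e-4 default is tuned
to schedules orders of magnitude longer, and a small vocabulary needs no
2200-gene context. SWA is off by default at this scale — uniform averaging
over a short, high-rate tail has nothing to average. Under these conditions
the suite checks that the total loss falls, that held-out denoising improves
over the noisy input (Spearman delta > 0 at 70% downsampling), that the
trained model beats an untrained copy on held-out denoising likelihood, and
that label prediction on a balanced held-out subset beats the majority-class
baseline — each by 3-seed majority, since single toy runs are noisy.

## The synthetic-data generator

No simulator is defined by the method itself, so the package plants its own:
a one-step linear structural-equation model. Per group, a latent
log-expression vector; per cell, Gaussian latent noise (sd 0.5) added and
propagated one step through the planted weighted network
(`v = softplus(u + A u)`); normalized to proportions; scaled by a log-normal
library size (sd 0.3, mean parameterized so the expected depth equals
`mean_depth`); sampled negative binomial at the configured dispersion; then
hit by per-(cell, gene) complete dropout at `sigmoid(dropout_logit)`.
Defaults: 4 groups with geometrically decaying proportions (imbalance),
depth 1500, dispersion 3, dropout logit -2, two batches with mild
multiplicative gene effects. The per-cell latent noise is what routes the
planted network into gene–gene covariance — without it, within-group genes
would be independent and network recovery would be untestable; a test
verifies that planted edges carry more partial correlation than non-edges.

What the generator does **not** emulate: regulatory dynamics (one propagation
step, no feedback or time), realistic dispersion–mean trends, ambient RNA,
doublets, or depth-dependent dropout (dropout is uniform given the logit).
Tests passing on this generator therefore demonstrate that the machinery is
correct and that the model can exploit planted covariance — not that it
recovers real regulatory biology.

## Networks from attention, and benchmarking

For a set of cells of one state, queries and keys are averaged **before**
the softmax: `softmax(mean(Q) mean(K)^T / sqrt(d_k))` per head — a meta-cell
attention that reduces exactly to single-cell attention for one cell. The
mean over cells is arithmetic and unweighted, and is accumulated streaming so
the cell set can be large. Placeholder rows/columns are dropped before
assembly. Rows of the row-stochastic matrix are read as **targets**, columns
as **regulators** (each target distributes unit mass over its few
regulators); `orient()` transposes involutively for ground truths with the
opposite sparsity structure, and `subset_to_tf()` restricts regulator columns
for GRN-style comparisons. Genome-wide networks are assembled blockwise:
random gene blocks (sampled from the pooled expressed profile, like the
training context), per-head attention scattered into a vocabulary-sized
matrix and averaged by pair co-occurrence; never co-sampled pairs are `NA` —
absent, distinct from zero attention.

**Head selection** classifies ground-truth edges from per-head attention
scores with a ridge model (targets ±1, squared error, L2 penalty 1,
nonnegative coefficients, no intercept — solved exactly by NNLS on the
ridge-augmented system) on half the pairs, negatives subsampled to at most
10x the positives; heads with positive coefficient are averaged
**unweighted**. The classifier only selects. If no coefficient is positive
the selection falls back to all heads with a warning rather than failing.

**Metrics.** The early precision ratio here is the diagnostic odds ratio
`(TP*TN)/(FP*FN)` at the cutoff yielding K predicted edges (K = number of
true edges): 1 is random, infinity perfect. That formula is what is printed
for "EPR", although early precision conventionally means precision@K over
prevalence; the odds-ratio form is primary and the conventional form sits
behind `mode = "precision_ratio"`. Ties at the K-th score are broken by a
seeded shuffle so exactly K predictions are always made; self-pairs are
excluded from the candidate universe. AUPRC sweeps every cutoff, floors the
area at the prevalence line (subtract, then clip at zero), and does not
extrapolate past the last achieved recall, so a perfect ranking scores
exactly `1 - prevalence` and a random one about 0. Both metrics are pinned
to exhaustive enumeration on all small universes and are invariant to
monotone score transforms. Hub enrichment ranks genes by row sums, column
sums, or eigenvector centrality and applies the weighted running-sum
statistic (weight exponent 1, cross-checked against an independent
implementation) with a gene-label permutation null (default 1000
permutations); FDR is Benjamini–Hochberg over the permutation p-values — a
documented simplification of the normalized-score permutation FDR. Ground
truths come from TSV edge lists or from perturbation p-value matrices
thresholded at 0.05 (self-edges removed).

## Numerical and degenerate-input conventions

Log-space likelihoods throughout; log-sum-exp for all mixtures and collapsed
logits; Spearman correlations use average ranks for ties; denoising is scored
only over genes expressed in the true profile, skipping cells with fewer than
3 of them (counted, not silently dropped); the 5000-most-variable-gene
restriction of the denoising protocol is a flag, on by default, computed from
variance of log-normalized counts. Reported denoised profiles are expected
counts `(1 - pi) * mu`, not samples, so evaluation is deterministic.
Downsampling at `r = 0` is the identity; an all-zero cell stays all-zero; a
`mean_depth` of 0 yields an all-zero matrix. Divergent training (non-finite
loss) aborts with the offending component and step.

## Known limitations

- The transformer is exact but interpreted R: fine at the toy scales the
  package targets (thousands of cells, tens to hundreds of genes), not a
  pretraining engine.
- Classification through the placeholder-token pathway learns slowly in tiny
  models; at the toy scale it reliably beats chance on balanced groups but
  not necessarily an imbalanced majority baseline.
- Inhibitory vs activating edges are not modeled; attention scores are
  nonnegative.
- The contrastive term's printed sign aligns rather than repels embeddings;
  both are available, neither is claimed superior here.
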