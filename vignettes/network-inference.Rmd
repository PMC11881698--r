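---
title: "Contrastive graph-attention link prediction for gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive graph-attention link prediction for gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnlink)
```

## The problem

A gene regulatory network (GRN) is a directed graph whose edges run from
transcription factors (TFs) to the target genes they regulate. Single-cell
RNA sequencing provides a gene-by-cell expression matrix `X` (M genes, N
cells) at cellular resolution, but it is noisy, high-dimensional and riddled
with dropout zeros; known regulatory interactions, typically curated from
ChIP-seq or interaction databases, cover only a fraction of the true network.
`grnlink` treats GRN inference as supervised link prediction: given `X` and a
partially observed edge set, score every unobserved (TF, gene) pair for the
probability that a regulatory interaction exists.

## The model

**Graph views.** The observed network defines the *preserved* view. A
*perturbed* view is drawn by removing each edge independently with
probability `removal_prob` (default 0.2). No edges are ever added, so the
perturbed edge set is a subset of the preserved one; node features (the
expression rows) are shared, only the topology is augmented. A fresh
perturbed view is drawn every epoch, which stress-tests the model under the
extreme sparsity it will meet on poorly annotated systems.

**Encoder.** A two-layer multi-head graph-attention (GAT) network encodes
every gene. For head `k` of a layer with weight `W_k`, the attention logit of
the pair (i, j) is a learnable vector applied to the concatenation
`[W_k g_i || W_k g_j]`, passed through a LeakyReLU (slope 0.2) and
softmax-normalised over the neighbourhood of `i`, so incoming weights always
sum to one. Layer 1 concatenates its `K` head outputs after the ELU
activation; layer 2, being the last, averages the head aggregates before one
final ELU, yielding the representation `h_i` (and `ĥ_i` on the perturbed
view). One parameter set serves both views; weight sharing is what makes the
inter-view comparison meaningful.

**Contrastive objective.** For each anchor gene in one view, the same gene
in the other view is the positive, all other genes are negatives, and the
per-anchor loss is the negative log-softmax of the temperature-scaled cosine
similarity (an InfoNCE loss with temperature `tau`). Both anchor directions
are averaged over the contrasted node set. This pulls the two views of the
same gene together while keeping distinct genes separated, sharpening the
embeddings when labeled edges are scarce.

**Decoder.** Each view's representation is projected by its own small MLP
(independent parameters, identical architecture); the link probability of a
pair is `sigmoid` of the dot product of the two projected embeddings. Both
views are scored against the *same* labels — the perturbed view must
reconstruct the original graph — giving two summed binary cross-entropy
terms. The full objective is

```
L  =  L_preserved + L_perturbed + beta * L_contrastive
```

with `beta = 0.5` by default.

**Training.** Adam at learning rate 0.003. Optimisation runs in two phases:
a supervised pre-training phase (default 10 epochs) with the augmentation
active but the contrastive term off, then the full objective (default 20
epochs). After every epoch the validation AUPRC is computed on the
un-augmented training adjacency and the best-scoring checkpoint is kept.
Inference always runs on the un-augmented training adjacency with the
preserved-view head (averaging both heads is available via
`eval_view = "mean"`).

## Data protocols

Two split schemes mirror the standard benchmark protocols:

* `string_like` (sparse functional networks): 1/3 of positives to test, then
  1/5 of the remaining training pool to validation;
* `celltype_specific` (dense ChIP networks): 2/3 train, 1/10 validation,
  remainder test.

Fractional sizes are floored for the smaller part with the remainder going
to the larger, so counts are deterministic (300 positives give 160/40/100
and 200/30/70 respectively). Train and validation negatives are drawn 1:1
with their positives, test negatives at a configurable ratio (default 1:1),
all uniformly without replacement from ordered (TF, gene) pairs that are not
ground-truth positives; self-pairs are excluded because a dot-product
decoder scores a node against itself degenerately. The adjacency used for
message passing is built from training positives only — validation and test
edges never leak into the graph. `filter_genes()` applies the usual
preprocessing: genes detected in fewer than 10% of cells are dropped, a
variance-significance screen (chi-square test of each gene's log1p-variance
against the median variance, Bonferroni-corrected at 0.01) removes flat
genes, and the "TFs + top-k" convention keeps all surviving TFs plus the
top-k most variable targets. The screen is pluggable (`pvalue_fun`) so an
alternative highly-variable-gene test can be swapped in.

## Few-shot transfer

To transfer between cell lines with different cell counts, both expression
matrices are projected onto their top-d left singular components scaled by
the singular values (`svd_align()`), giving a common feature dimension. The
per-component sign is fixed (each component sums positive) so aligned
features are deterministic and comparable across datasets. The model is
trained fully on the source cell line, then fine-tuned on a stratified 5%
sample of the target's known interactions (stratified by TF with
largest-remainder quotas, so every well-connected regulator contributes and
the total is exactly `round(0.05 * P)`); the remaining 95% plus sampled
negatives form the test set. Fine-tuning repeats the normal training loop
with fewer epochs (default 5) and no pre-training phase. Setting
`pretrain = FALSE` trains from scratch on the 5% sample — the baseline that
quantifies what source pre-training buys.

## The synthetic planted-GRN generator

`simulate_grn()` makes the whole pipeline testable without downloads. TF
profiles are i.i.d. log-normal (right-skewed, positive, like normalised
expression); each (TF, target) edge is planted independently with
probability `edge_density`; a regulated target is `effect_size` times the
mean of its regulators' profiles plus Gaussian noise (`noise_sd`);
unregulated targets are pure noise; finally entries are zeroed independently
with probability `dropout_rate`. The defaults (5 TFs, 200 targets, 200
cells, density 0.05, effect 1.0, noise 0.5, dropout 0.3) produce a small,
sparse, dropout-ridden dataset in which most regulated targets have exactly
one regulator — an easy but non-trivial recovery problem.

What the generator does *not* emulate: negative-binomial count noise,
library-size variation, cell subpopulations, indirect (TF-to-TF cascade)
regulation, and expression-dependent dropout. Passing the planted-recovery
tests therefore shows the machinery is correct and can exploit a linear
co-expression signal; it does not certify performance on real scRNA-seq
data, where the signal is weaker and confounded.

## Numerical choices

* **Self-loops** are inserted before every softmax so isolated nodes (after
  heavy edge removal) aggregate their own features instead of producing an
  undefined softmax.
* **Message passing is undirected by default**: in a bipartite TF-to-target
  edge list, targets would otherwise never receive messages. A `directed`
  flag restores one-way aggregation.
* **Zero-norm embeddings** have cosine similarity 0 against anything (and a
  zero gradient), avoiding NaNs early in training.
* **The contrastive node set** defaults to nodes incident to at least one
  training edge; `contrastive_nodes = "all"` uses every gene.
* **Probabilities are clipped** to `[1e-7, 1 - 1e-7]` inside the BCE.
* **BCE is summed** over pairs, matching the objective as stated; a mean
  mode exists because the mean interacts more predictably with `beta` when
  dataset sizes vary.
* **Ranking ties** break deterministically by (TF index, gene index).
* All randomness is drawn under locally scoped seeds, so every stage is
  byte-identical given its seed and the caller's RNG state is never
  disturbed.

## Defaults that the data do not pin down

Architecture sizes are not dictated by the method: we use K = 2 heads,
128-dimensional attention layers, and a 64/32 MLP head as common GAT
practice; the temperature defaults to 0.5 (the usual NT-Xent choice); 10
pre-training epochs precede the 20 training epochs; fine-tuning uses 5
epochs. All are `train_config()` / `transfer_config()` fields.

The test-suite and acceptance benchmarks run the planted generator at its
defaults and split it with the `celltype_specific` scheme (a planted network
with a handful of well-connected TFs resembles the dense-ChIP regime). The
transfer benchmarks align features with `svd_dim = 64`: the alignment
dimension must not exceed `min(M, N)` = 200 on these fixtures, and 64
components already capture virtually all the variance of a rank-5-plus-noise
matrix. Oracle-equivalence checks run on graphs of at most 10 nodes, where
brute-force loops are exact and instant; recovery, ablation and transfer
checks use the 205-gene default fixture, which trains in a few seconds per
run.

## Limitations

* Training is full-batch and CPU-bound; it is comfortable at benchmark scale
  (hundreds to a few thousand genes) but not engineered for atlas-scale
  graphs.
* The decoder's dot product is symmetric, so edge directionality comes
  entirely from restricting candidates to (TF, gene) orientation.
* Model selection needs a usable validation set; with none (as in
  fine-tuning), the final-epoch parameters are used.
* The contrastive term's benefit on real data cannot be established by the
  planted benchmark; on it, the ablation is checked only for non-inferiority.
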