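# grnlink

Supervised gene regulatory network (GRN) inference from single-cell
expression data, framed as link prediction on a bipartite transcription
factor (TF) → target-gene graph.

Given a gene × cell expression matrix `X ∈ R^{M×N}` and a partially
observed set of regulatory edges, `grnlink` learns gene representations
with a two-layer multi-head graph-attention (GAT) encoder applied to two
views of the network — the observed graph and a randomly edge-dropped copy
— and scores unobserved (TF, gene) pairs with dual dot-product decoders.
Three terms drive learning:

```
L = L_preserved + L_perturbed + β · L_contrastive
```

where `L_preserved` and `L_perturbed` are binary cross-entropies of
`p = sigmoid(hᵢ·hⱼ)` on the two views (both scored against the observed
labels, so the perturbed view must reconstruct the original graph), and
`L_contrastive` is an inter-view InfoNCE loss with temperature τ: the same
gene across views is a positive pair, every other gene a negative, under
cosine similarity. Contrasting views of the graph reduces the model's
dependence on the (usually tiny) set of known interactions. Few-shot
transfer to a sparsely annotated cell line is supported by aligning both
cell lines' features with a truncated SVD, pre-training on the data-rich
source, and fine-tuning on a stratified 5% sample of the target's edges.

A planted-GRN simulator (`simulate_grn()`) generates expression with a
known linear TF→target signal plus dropout, so the entire pipeline is
developed, tested and benchmarked without external downloads.

## Worked example

```r
library(grnlink)

# a planted network: 5 TFs, 200 targets, 200 cells, 30% dropout
sim <- simulate_grn(synthetic_spec(seed = 7))
sim$expr
#> ExpressionMatrix: 205 genes (5 TFs) x 200 cells
sim$net
#> RegulatoryNetwork: 65 edges over 205 nodes

# 2/3 train, 1/10 validation, remainder test; negatives sampled 1:1
split <- split_dataset(sim$net, sim$expr, "celltype_specific", seed = 7)
split
#> DatasetSplit (celltype_specific): train 43 pos / 43 neg; val 6 pos / 6 neg; test 16 pos / 16 neg

# 10 supervised pre-training epochs + 20 full-objective epochs, Adam lr 0.003
model <- grn_train(split, sim$expr, train_config(seed = 7))
evaluate_model(model, split, sim$expr)
#> EvalResult: AUROC 0.9102, AUPRC 0.9470 (16 pos / 16 neg)

# rank unobserved TF-gene pairs by predicted probability
rank_predictions(model, sim$expr, split$train_adjacency, k = 5)
#>    tf gene tf_idx gene_idx score
#> 1 TF1  G22      1       27     1
#> 2 TF1  G87      1       92     1
#> 3 TF1 G109      1      114     1
#> 4 TF3  G92      3       97     1
#> 5 TF3 G103      3      108     1
```

The held-out AUROC of 0.91 means the model ranks a random true interaction
above a random non-interaction 91% of the time; AUPRC is reported alongside
because it is the metric sensitive to class imbalance. Several top-ranked
unobserved pairs are in fact planted edges that were held out of training.

## Command-line use

`inst/scripts/grnlink` wraps the same functions as subcommands
(`simulate`, `split`, `train`, `evaluate`, `transfer`, `predict`); every
run writes a JSON manifest (resolved configuration, input checksums,
package version, metrics) next to its outputs:

```sh
Rscript inst/scripts/grnlink simulate --seed 1 --out sim/
Rscript inst/scripts/grnlink train --expr sim/expression.tsv \
    --network sim/network.tsv --tf-list sim/tf_list.txt --out run/
Rscript inst/scripts/grnlink evaluate --model run/model.rds \
    --expr sim/expression.tsv --tf-list sim/tf_list.txt --out run/
```

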