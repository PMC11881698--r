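#' Transfer-learning configuration
#'
#' @param svd_dim number of singular components d for feature alignment.
#' @param finetune_fraction fraction of the target cell line's known
#'   interactions used for fine-tuning (default 0.05, i.e. 5%); the rest
#'   form the test set.
#' @param finetune_epochs full-objective epochs during fine-tuning (fewer
#'   than a full training run).
#' @return An object of class `TransferConfig`.
#' @export
transfer_config <- function(svd_dim = 256L, finetune_fraction = 0.05,
                            finetune_epochs = 5L) {
  stopifnot(svd_dim >= 1, finetune_fraction > 0, finetune_fraction < 1,
            finetune_epochs >= 0)
  structure(list(svd_dim = as.integer(svd_dim),
                 finetune_fraction = finetune_fraction,
                 finetune_epochs = as.integer(finetune_epochs)),
            class = "TransferConfig")
}

#' Align expression features by truncated SVD
#'
#' Source and target cell lines have different cell counts, so their
#' expression matrices cannot feed one encoder directly. Truncated singular
#' value decomposition X ~ U_d S_d V_d' projects each gene onto its top-d
#' left singular components scaled by the singular values (rows of U_d S_d),
#' giving both cell lines a common d-dimensional feature space.
#'
#' @param expr an [expression_matrix()] (M genes x N cells).
#' @param d number of components; must satisfy `d <= min(M, N)`.
#' @return An [expression_matrix()] of shape M x d whose "cells" are the
#'   singular components `SV1..SVd`.
#' @export
svd_align <- function(expr, d) {
  d <- as.integer(d)
  M <- nrow(expr$values); N <- ncol(expr$values)
  if (d > min(M, N)) {
    stop(sprintf("svd_align: d = %d exceeds min(M, N) = %d", d, min(M, N)))
  }
  dec <- svd(expr$values, nu = d, nv = 0)
  # fix the per-component sign ambiguity (flip so each component sums
  # positive) so features are deterministic and comparable across datasets
  flip <- ifelse(colSums(dec$u) < 0, -1, 1)
  feats <- dec$u %*% diag(flip * dec$d[seq_len(d)], d, d)
  expression_matrix(feats, expr$gene_ids, sprintf("SV%d", seq_len(d)),
                    expr$is_tf)
}

# Stratified sample of positive edges by TF using the largest-remainder
# method: per-TF quota floor(frac * n_tf), remaining slots to the TFs with
# the largest fractional remainders (ties by TF index), so the total is
# exactly round(frac * n_edges). Strata with a zero quota are permitted.
stratified_edge_sample <- function(net, fraction, seed) {
  edges <- net$edges
  P <- nrow(edges)
  total <- round(fraction * P)
  if (total < 1) stop("fine-tune fraction selects no edges")
  tfs <- sort(unique(edges[, 1]))
  n_tf <- vapply(tfs, function(t) sum(edges[, 1] == t), numeric(1))
  quota <- floor(fraction * n_tf)
  rem <- fraction * n_tf - quota
  short <- total - sum(quota)
  if (short > 0) {
    extra <- order(-rem, tfs)[seq_len(short)]
    quota[extra] <- quota[extra] + 1
  } else if (short < 0) {
    over <- order(rem, -tfs)
    over <- over[quota[over] > 0][seq_len(-short)]
    quota[over] <- quota[over] - 1
  }
  local_seed(seed, {
    take <- unlist(lapply(seq_along(tfs), function(ti) {
      rows <- which(edges[, 1] == tfs[ti])
      if (quota[ti] == 0) integer(0) else
        rows[sample.int(length(rows), quota[ti])]
    }))
    sort(take)
  })
}

# assemble a DatasetSplit for fine-tuning: sampled positives (plus 1:1
# negatives) train the model; the remaining positives (plus negatives at
# test_neg_ratio) form the test set
finetune_split <- function(net, expr, fraction, test_neg_ratio, seed) {
  take <- stratified_edge_sample(net, fraction, seed)
  ft_pos <- net$edges[take, , drop = FALSE]
  te_pos <- net$edges[-take, , drop = FALSE]
  if (nrow(ft_pos) == 0) stop("empty fine-tune set")
  tr_neg <- sample_negatives(net, expr, nrow(ft_pos), seed = seed + 1L)
  te_neg <- sample_negatives(net, expr, round(test_neg_ratio * nrow(te_pos)),
                             exclude = as.matrix(tr_neg[, c("tf", "gene")]),
                             seed = seed + 2L)
  as_set <- function(p, n) {
    labeled_pairs(c(p[, 1], n$tf), c(p[, 2], n$gene),
                  c(rep(1L, nrow(p)), n$label))
  }
  split <- structure(list(
    train = as_set(ft_pos, tr_neg),
    val = labeled_pairs(),
    test = as_set(te_pos, te_neg),
    train_adjacency = regulatory_network(ft_pos, net$num_nodes),
    scheme = "finetune"
  ), class = "DatasetSplit")
  validate_split(split, net)
  split
}

#' Few-shot transfer between cell lines
#'
#' Pre-trains on a source cell line with abundant known interactions, then
#' fine-tunes on a small stratified fraction of a target cell line's known
#' interactions and evaluates on the rest. Both cell lines' expression
#' matrices are first aligned to a common `svd_dim`-dimensional feature
#' space with [svd_align()]. The fine-tune sample is stratified by TF
#' (largest-remainder quotas), so well-connected regulators all contribute
#' edges. Fine-tuning re-runs the normal training loop, only with fewer
#' epochs and no pre-training phase; with `pretrain = FALSE` the source
#' stage is skipped and the model trains from scratch on the fine-tune set
#' with the full schedule (the no-transfer baseline).
#'
#' @param source list with `expr` ([expression_matrix()]) and `split`
#'   ([split_dataset()]) of the source cell line.
#' @param target list with `expr` and `net` (full known positives) of the
#'   target cell line.
#' @param tcfg a [transfer_config()].
#' @param cfg a [train_config()] used for the source stage and (with the
#'   reduced epoch count) for fine-tuning.
#' @param seed seed for the fine-tune sampling and training.
#' @param test_neg_ratio negatives per positive in the target test set.
#' @param pretrain run the source pre-training stage (default `TRUE`).
#' @return A list with `result` ([eval_result()] on the target test set),
#'   `model` (the fine-tuned `grn_model`) and `split` (the fine-tune split).
#' @export
grn_transfer <- function(source, target, tcfg = transfer_config(),
                         cfg = train_config(), seed = cfg$seed,
                         test_neg_ratio = 1, pretrain = TRUE) {
  tgt_expr <- svd_align(target$expr, tcfg$svd_dim)
  split <- finetune_split(target$net, tgt_expr, tcfg$finetune_fraction,
                          test_neg_ratio, seed)
  if (pretrain) {
    src_expr <- svd_align(source$expr, tcfg$svd_dim)
    base <- grn_train(source$split, src_expr, cfg)
    ft_cfg <- cfg
    ft_cfg$pretrain_epochs <- 0L
    ft_cfg$epochs <- tcfg$finetune_epochs
    ft_cfg$seed <- as.integer(seed)
    model <- grn_train(split, tgt_expr, ft_cfg, init = base)
  } else {
    scratch_cfg <- cfg
    scratch_cfg$seed <- as.integer(seed)
    model <- grn_train(split, tgt_expr, scratch_cfg)
  }
  list(result = evaluate_model(model, split, tgt_expr), model = model,
       split = split)
}
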