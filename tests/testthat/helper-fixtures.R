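# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# deterministic small expression matrix with the first `n_tfs` genes as TFs
tiny_expr <- function(n_genes = 6, n_cells = 4, n_tfs = 2, seed = 1) {
  vals <- grnlink:::local_seed(seed,
    matrix(stats::rlnorm(n_genes * n_cells), n_genes, n_cells))
  expression_matrix(vals,
                    gene_ids = sprintf("g%d", seq_len(n_genes)),
                    cell_ids = sprintf("c%d", seq_len(n_cells)),
                    is_tf = seq_len(n_genes) <= n_tfs)
}

tiny_net <- function(edges, n_nodes) {
  regulatory_network(matrix(unlist(edges), ncol = 2, byrow = TRUE), n_nodes)
}

# a random TF->target network over expr's genes with exactly n_edges edges
random_net <- function(expr, n_edges, seed = 1) {
  tfs <- which(expr$is_tf)
  M <- length(expr$gene_ids)
  cand <- expand.grid(tf = tfs, target = seq_len(M))
  cand <- cand[cand$tf != cand$target, ]
  idx <- grnlink:::local_seed(seed, sample.int(nrow(cand), n_edges))
  regulatory_network(as.matrix(cand[idx, ]), M)
}

# small random encoder + features for oracle comparisons
tiny_encoder <- function(n_feat = 4, heads = 2, d1 = 3, d2 = 3, seed = 1,
                         activation = "elu") {
  encoder_params(n_feat, heads = heads, d1 = d1, d2 = d2,
                 activation = activation, seed = seed)
}

# the synthetic setup used by the heavier pipeline tests
default_sim <- function(seed) {
  simulate_grn(synthetic_spec(n_tfs = 5, n_genes = 200, n_cells = 200,
                              edge_density = 0.05, effect_size = 1.0,
                              noise_sd = 0.5, dropout_rate = 0.3,
                              seed = seed))
}
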