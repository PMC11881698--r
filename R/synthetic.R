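#' Specification for a planted regulatory network simulation
#'
#' Describes a synthetic single-cell expression dataset with a known (planted)
#' TF-to-target network, used to exercise and validate the whole inference
#' pipeline without external data. TF expression profiles are drawn i.i.d.
#' from a log-normal distribution (mimicking positive, right-skewed
#' expression); each (TF, target) edge is planted independently with
#' probability `edge_density`; a regulated target's profile is
#' `effect_size` times the mean of its regulators' profiles plus Gaussian
#' noise; unregulated targets are pure noise; finally entries are zeroed
#' independently with probability `dropout_rate` to mimic scRNA-seq dropout.
#'
#' @param n_tfs number of transcription factors.
#' @param n_genes number of non-TF target genes.
#' @param n_cells number of cells (columns).
#' @param edge_density per-(TF, target) planting probability in (0, 1).
#' @param effect_size linear regulatory effect multiplying the regulator mean.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param dropout_rate independent zero-masking probability in \[0, 1).
#' @param seed RNG seed.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_tfs = 5L, n_genes = 200L, n_cells = 200L,
                           edge_density = 0.05, effect_size = 1.0,
                           noise_sd = 0.5, dropout_rate = 0.3, seed = 1L) {
  stopifnot(n_tfs >= 1, n_genes >= 1, n_cells >= 1,
            edge_density > 0, edge_density < 1,
            noise_sd >= 0, dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells), edge_density = edge_density,
                 effect_size = effect_size, noise_sd = noise_sd,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Simulate a planted GRN with matching expression
#'
#' Draws a dataset according to a [synthetic_spec()]: the returned expression
#' matrix has `n_tfs + n_genes` rows (TFs first, flagged `is_tf`) and
#' `n_cells` columns; the returned network holds the planted TF-to-target
#' edges. Regulated targets carry a linear trace of their regulators'
#' profiles, so the signal the link predictor must exploit (co-expression of a
#' target with its true regulators above random TFs) is present by
#' construction and testable in closed form when `noise_sd = 0` and
#' `dropout_rate = 0`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `expr` ([expression_matrix()]) and `net`
#'   ([regulatory_network()]).
#' @export
simulate_grn <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  local_seed(spec$seed, {
    M <- spec$n_tfs + spec$n_genes
    tf_rows <- matrix(stats::rlnorm(spec$n_tfs * spec$n_cells,
                                    meanlog = 0, sdlog = 1),
                      spec$n_tfs, spec$n_cells)
    # plant each (TF, target) edge independently
    planted <- matrix(stats::runif(spec$n_tfs * spec$n_genes) <
                        spec$edge_density,
                      spec$n_tfs, spec$n_genes)
    target_rows <- matrix(stats::rnorm(spec$n_genes * spec$n_cells,
                                       sd = spec$noise_sd),
                          spec$n_genes, spec$n_cells)
    regulated <- which(colSums(planted) > 0)
    for (g in regulated) {
      regs <- which(planted[, g])
      signal <- if (length(regs) == 1L) tf_rows[regs, ] else
        colMeans(tf_rows[regs, , drop = FALSE])
      target_rows[g, ] <- spec$effect_size * signal + target_rows[g, ]
    }
    values <- rbind(tf_rows, target_rows)
    if (spec$dropout_rate > 0) {
      mask <- matrix(stats::runif(M * spec$n_cells) < spec$dropout_rate,
                     M, spec$n_cells)
      values[mask] <- 0
    }
    gene_ids <- c(sprintf("TF%d", seq_len(spec$n_tfs)),
                  sprintf("G%d", seq_len(spec$n_genes)))
    cell_ids <- sprintf("C%d", seq_len(spec$n_cells))
    is_tf <- c(rep(TRUE, spec$n_tfs), rep(FALSE, spec$n_genes))
    expr <- expression_matrix(values, gene_ids, cell_ids, is_tf)
    idx <- which(planted, arr.ind = TRUE)
    edges <- cbind(idx[, 1], spec$n_tfs + idx[, 2])
    net <- regulatory_network(edges, M, is_tf)
    list(expr = expr, net = net)
  })
}
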