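#' Construct an expression matrix object
#'
#' Bundles a genes-by-cells numeric matrix with gene/cell identifiers and a
#' per-gene transcription-factor (TF) flag. This is the container every other
#' function in the package consumes: rows are genes (TFs and targets alike),
#' columns are cells, and values are expression measurements in arbitrary
#' units (typically log-normalised counts).
#'
#' @param values numeric matrix, M genes x N cells; must be finite.
#' @param gene_ids character vector of M unique gene identifiers.
#' @param cell_ids character vector of N unique cell identifiers.
#' @param is_tf logical vector of length M flagging transcription factors.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `is_tf`.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids,
                              is_tf = rep(FALSE, nrow(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  is_tf <- as.logical(is_tf)
  if (nrow(values) != length(gene_ids)) {
    stop("nrow(values) must equal length(gene_ids)")
  }
  if (ncol(values) != length(cell_ids)) {
    stop("ncol(values) must equal length(cell_ids)")
  }
  if (length(is_tf) != length(gene_ids)) {
    stop("is_tf must have one flag per gene")
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (!all(is.finite(values))) stop("expression values must all be finite")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 is_tf = is_tf),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes (%d TFs) x %d cells\n",
              length(x$gene_ids), sum(x$is_tf), length(x$cell_ids)))
  invisible(x)
}

#' Construct a regulatory network
#'
#' A directed edge set of (TF, target) gene-index pairs over the genes of a
#' companion [expression_matrix()]. Indices are 1-based row indices into that
#' matrix. Duplicate ordered pairs are collapsed.
#'
#' @param edges two-column integer matrix (or data frame) of (tf, target)
#'   indices; may have zero rows.
#' @param num_nodes total number of genes M the indices refer to.
#' @param is_tf optional logical vector; when given, every source index must
#'   be flagged as a TF.
#' @return An object of class `RegulatoryNetwork` with elements `edges`
#'   (E x 2 integer matrix, columns `tf`, `target`) and `num_nodes`.
#' @export
regulatory_network <- function(edges, num_nodes, is_tf = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(integer(0), 0, 2)
  }
  if (ncol(edges) != 2) stop("edges must have two columns (tf, target)")
  storage.mode(edges) <- "integer"
  num_nodes <- as.integer(num_nodes)
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > num_nodes)) {
      stop("edge indices must lie in [1, num_nodes]")
    }
    edges <- edges[!duplicated(paste(edges[, 1], edges[, 2])), , drop = FALSE]
    if (!is.null(is_tf) && !all(is_tf[edges[, 1]])) {
      stop("every edge source must be a flagged TF")
    }
  }
  colnames(edges) <- c("tf", "target")
  structure(list(edges = edges, num_nodes = num_nodes),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d edges over %d nodes\n",
              nrow(x$edges), x$num_nodes))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

# canonical "tf:target" string keys, used for set algebra on edge sets
pair_key <- function(tf, target) paste(tf, target, sep = ":")
edge_keys <- function(net) pair_key(net$edges[, 1], net$edges[, 2])

#' Construct a labeled pair set
#'
#' Holds (tf, gene, label) triples used as supervised examples; label 1 marks
#' a known regulatory interaction, 0 a sampled non-interaction.
#'
#' @param tf,gene integer gene indices.
#' @param label 0/1 integer labels.
#' @return A data frame of class `LabeledPairSet` with columns `tf`, `gene`,
#'   `label`.
#' @export
labeled_pairs <- function(tf = integer(0), gene = integer(0),
                          label = integer(0)) {
  tf <- as.integer(tf); gene <- as.integer(gene); label <- as.integer(label)
  if (length(tf) != length(gene) || length(tf) != length(label)) {
    stop("tf, gene and label must have equal length")
  }
  if (length(label) && !all(label %in% c(0L, 1L))) {
    stop("labels must be 0 or 1")
  }
  if (anyDuplicated(pair_key(tf, gene))) {
    stop("an ordered (tf, gene) pair appears twice")
  }
  structure(data.frame(tf = tf, gene = gene, label = label),
            class = c("LabeledPairSet", "data.frame"))
}

#' Read an expression matrix from delimited text
#'
#' Expects genes as rows: the first column holds gene identifiers and the
#' header row holds cell identifiers. The delimiter (comma or tab) is
#' auto-detected from the header line.
#'
#' @param path file path.
#' @param tf_ids optional character vector of TF identifiers (e.g. read from a
#'   one-id-per-line TF list); genes in this set are flagged `is_tf`.
#' @return An [expression_matrix()] with rows in file order.
#' @export
load_expression <- function(path, tf_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"")
  gene_ids <- df[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(values) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value at gene '%s', cell '%s'",
                 gene_ids[bad[1, 1]], colnames(raw)[bad[1, 2]]))
  }
  if (anyNA(values)) {
    na <- which(is.na(values), arr.ind = TRUE)
    stop(sprintf("missing value at gene '%s', cell '%s'",
                 gene_ids[na[1, 1]], colnames(raw)[na[1, 2]]))
  }
  is_tf <- if (is.null(tf_ids)) rep(FALSE, length(gene_ids)) else
    gene_ids %in% tf_ids
  expression_matrix(values, gene_ids, colnames(raw), is_tf)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [load_expression()]: genes as rows, first column `gene`, header
#' row of cell identifiers.
#'
#' @param expr an [expression_matrix()].
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  # %.17g keeps a double exact through the text round trip
  vals <- apply(expr$values, 2, function(x) sprintf("%.17g", x))
  df <- data.frame(gene = expr$gene_ids, vals, check.names = FALSE)
  colnames(df) <- c("gene", expr$cell_ids)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regulatory network edge list
#'
#' Reads a two-column (TF id, target id) delimited file and maps identifiers
#' to row indices of `expr`. Records naming genes absent from `expr` are
#' dropped (a message reports the count); duplicates are collapsed. `expr` is
#' not modified: flag TFs either via `tf_ids` in [load_expression()] or with
#' [flag_tfs_from_network()].
#'
#' @param path file path; header optional (detected when the first row names
#'   no known gene and looks like `TF,Target`).
#' @param expr the companion [expression_matrix()].
#' @return A [regulatory_network()] over `expr`'s genes.
#' @export
load_network <- function(path, expr) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "character", quote = "\"")
  if (ncol(df) < 2) stop("network file must have two columns (TF, target)")
  df <- df[, 1:2]
  # header row: neither token is a known gene id
  if (nrow(df) && !(df[1, 1] %in% expr$gene_ids) &&
      !(df[1, 2] %in% expr$gene_ids)) {
    df <- df[-1, , drop = FALSE]
  }
  tf_idx <- match(df[[1]], expr$gene_ids)
  tg_idx <- match(df[[2]], expr$gene_ids)
  keep <- !is.na(tf_idx) & !is.na(tg_idx)
  dropped <- sum(!keep)
  if (dropped) {
    message(dropped, " edge record(s) referenced genes absent from the ",
            "expression matrix and were dropped")
  }
  edges <- cbind(tf_idx[keep], tg_idx[keep])
  edges <- edges[!duplicated(paste(edges[, 1], edges[, 2])), , drop = FALSE]
  if (nrow(edges) == 0) stop("no edges remain after mapping ids to ", path)
  regulatory_network(edges, length(expr$gene_ids))
}

#' Write a labeled pair set as three-column text
#'
#' @param pairs a [labeled_pairs()] set.
#' @param expr the companion [expression_matrix()] (to map indices to ids).
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_pairs <- function(pairs, expr, path, sep = "\t") {
  df <- data.frame(tf = expr$gene_ids[pairs$tf],
                   gene = expr$gene_ids[pairs$gene],
                   label = pairs$label)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flag as TFs the source genes of a network
#'
#' Convenience for inputs without an explicit TF list: every gene appearing as
#' an edge source becomes a flagged TF.
#'
#' @param expr an [expression_matrix()].
#' @param net a [regulatory_network()] over the same genes.
#' @return `expr` with `is_tf` set from `net`'s edge sources.
#' @export
flag_tfs_from_network <- function(expr, net) {
  is_tf <- expr$is_tf
  is_tf[unique(net$edges[, 1])] <- TRUE
  expression_matrix(expr$values, expr$gene_ids, expr$cell_ids, is_tf)
}

# variance of log1p-transformed expression, the ranking statistic behind the
# highly-variable-gene screen
log_variance <- function(values) {
  apply(log1p(pmax(values, 0)), 1, stats::var)
}

#' Default variance-significance screen
#'
#' Tests, per gene, whether the variance of log1p expression exceeds the
#' median gene variance, using the classical chi-square test of a sample
#' variance against a fixed null value: (n-1) s^2 / sigma0^2 ~ chi^2(n-1)
#' under the null. Returns raw upper-tail P-values (one per gene); the caller
#' applies the Bonferroni correction.
#'
#' @param values genes x cells matrix.
#' @return numeric vector of P-values, one per row.
#' @export
variance_pvalues <- function(values) {
  n <- ncol(values)
  v <- log_variance(values)
  sigma0 <- stats::median(v)
  if (sigma0 <= 0) sigma0 <- .Machine$double.eps
  stats::pchisq((n - 1) * v / sigma0, df = n - 1, lower.tail = FALSE)
}

#' Filter genes by detection rate, variance significance and variance rank
#'
#' Applies, in order: (1) a detection filter removing genes with nonzero
#' expression in fewer than `min_cell_fraction` of cells; (2) a
#' variance-significance screen keeping genes whose Bonferroni-corrected
#' P-value is at most `alpha`; (3) the "TFs + top-k" convention: all surviving
#' TFs are kept, plus the `top_k` most variable surviving non-TF genes.
#' Row order of the input is preserved.
#'
#' @param expr an [expression_matrix()].
#' @param min_cell_fraction minimum fraction of cells with nonzero expression.
#' @param alpha Bonferroni-corrected significance level for the variance
#'   screen.
#' @param top_k number of highly variable non-TF genes to retain.
#' @param pvalue_fun pluggable screen: a function mapping the genes x cells
#'   matrix to one raw P-value per gene (default [variance_pvalues()]).
#' @return The filtered [expression_matrix()].
#' @export
filter_genes <- function(expr, min_cell_fraction = 0.1, alpha = 0.01,
                         top_k = 500L, pvalue_fun = variance_pvalues) {
  stopifnot(min_cell_fraction >= 0, min_cell_fraction <= 1, top_k >= 1)
  values <- expr$values
  detected <- rowMeans(values != 0) >= min_cell_fraction
  if (!any(detected)) stop("no genes pass the detection filter")
  values_d <- values[detected, , drop = FALSE]
  p <- pvalue_fun(values_d)
  p_adj <- pmin(p * nrow(values_d), 1)   # Bonferroni
  sig <- p_adj <= alpha
  keep_d <- rep(FALSE, nrow(values_d))
  keep_d[sig] <- TRUE
  if (!any(keep_d)) stop("no genes pass the variance-significance screen")
  is_tf_d <- expr$is_tf[detected]
  # rank surviving non-TF genes by the variance criterion, keep top_k
  surv <- which(keep_d)
  surv_nontf <- surv[!is_tf_d[surv]]
  if (length(surv_nontf) > top_k) {
    v <- log_variance(values_d[surv_nontf, , drop = FALSE])
    ord <- surv_nontf[order(-v, surv_nontf)]
    drop_nontf <- ord[-seq_len(top_k)]
    keep_d[drop_nontf] <- FALSE
  }
  keep <- rep(FALSE, nrow(values))
  keep[which(detected)[keep_d]] <- TRUE
  if (!any(keep)) stop("no genes survive filtering")
  expression_matrix(values[keep, , drop = FALSE], expr$gene_ids[keep],
                    expr$cell_ids, expr$is_tf[keep])
}

# all (tf, gene) ordered pairs eligible as negatives: TF source, no self
# pairs, not a ground-truth positive, not excluded
negative_candidates <- function(net, expr, exclude_keys = character(0)) {
  tfs <- which(expr$is_tf)
  if (!length(tfs)) stop("expression matrix flags no TFs")
  cand_tf <- rep(tfs, each = net$num_nodes)
  cand_tg <- rep(seq_len(net$num_nodes), times = length(tfs))
  ok <- cand_tf != cand_tg
  keys <- pair_key(cand_tf, cand_tg)
  ok <- ok & !(keys %in% edge_keys(net)) & !(keys %in% exclude_keys)
  cbind(tf = cand_tf[ok], target = cand_tg[ok])
}

#' Sample negative (TF, gene) pairs
#'
#' Draws `count` distinct label-0 pairs uniformly without replacement from the
#' unobserved-interaction candidate space: ordered pairs (i, j) with gene i a
#' flagged TF, i != j, (i, j) not a ground-truth positive of `net`, and (i, j)
#' not in `exclude`.
#'
#' @param net the full ground-truth [regulatory_network()] (all positives).
#' @param expr the companion [expression_matrix()].
#' @param count number of negatives to draw.
#' @param exclude optional two-column matrix of additional pairs to exclude
#'   (e.g. negatives already assigned to another partition).
#' @param seed RNG seed; the draw is reproducible given the seed.
#' @return A [labeled_pairs()] set of `count` label-0 pairs.
#' @export
sample_negatives <- function(net, expr, count, exclude = NULL, seed = 1L) {
  count <- as.integer(count)
  excl_keys <- if (is.null(exclude) || nrow(exclude) == 0) character(0) else
    pair_key(exclude[, 1], exclude[, 2])
  cand <- negative_candidates(net, expr, excl_keys)
  if (count > nrow(cand)) {
    stop(sprintf("requested %d negatives but only %d unobserved pairs exist",
                 count, nrow(cand)))
  }
  if (count == 0L) return(labeled_pairs())
  idx <- local_seed(seed, sample.int(nrow(cand), count))
  labeled_pairs(cand[idx, 1], cand[idx, 2], rep(0L, count))
}

#' Split a network into train/validation/test labeled pairs
#'
#' Partitions the positive edges of `net` and samples negatives, mirroring the
#' two benchmark protocols for sparse functional networks and dense
#' cell-type-specific ChIP networks:
#'
#' * `"string_like"`: 1/3 of positives to test; of the remaining 2/3 training
#'   pool, 1/5 to validation and the rest to train.
#' * `"celltype_specific"`: 2/3 of positives to train, 1/10 to validation,
#'   remainder to test.
#'
#' Train and validation negatives are sampled 1:1 with their positives; test
#' negatives at `test_neg_ratio` per positive. All negatives are drawn from
#' unobserved (TF, gene) pairs (never colliding with any ground-truth
#' positive) and the three negative sets are disjoint. The training adjacency
#' is built from training positives only, so no validation/test edge leaks
#' into message passing.
#'
#' @param net ground-truth [regulatory_network()].
#' @param expr companion [expression_matrix()].
#' @param scheme `"string_like"` or `"celltype_specific"`.
#' @param test_neg_ratio negatives per positive in the test set.
#' @param seed RNG seed.
#' @return An object of class `DatasetSplit`: list with `train`, `val`,
#'   `test` ([labeled_pairs()]), `train_adjacency` ([regulatory_network()])
#'   and `scheme`.
#' @export
split_dataset <- function(net, expr, scheme = c("string_like",
                                                "celltype_specific"),
                          test_neg_ratio = 1, seed = 1L) {
  scheme <- match.arg(scheme)
  P <- n_edges(net)
  if (P == 0) stop("network has no edges to split")
  perm <- local_seed(seed, sample.int(P))
  if (scheme == "string_like") {
    n_test <- floor(P / 3)
    pool <- P - n_test
    n_val <- floor(pool / 5)
    n_train <- pool - n_val
    test_idx <- perm[seq_len(n_test)]
    val_idx <- perm[n_test + seq_len(n_val)]
    train_idx <- perm[n_test + n_val + seq_len(n_train)]
  } else {
    n_train <- floor(2 * P / 3)
    n_val <- floor(P / 10)
    n_test <- P - n_train - n_val
    train_idx <- perm[seq_len(n_train)]
    val_idx <- perm[n_train + seq_len(n_val)]
    test_idx <- perm[n_train + n_val + seq_len(n_test)]
  }
  pos <- function(idx) net$edges[idx, , drop = FALSE]
  tr_pos <- pos(train_idx); va_pos <- pos(val_idx); te_pos <- pos(test_idx)

  n_test_neg <- round(test_neg_ratio * nrow(te_pos))
  tr_neg <- sample_negatives(net, expr, nrow(tr_pos), seed = seed + 1L)
  excl <- tr_neg[, c("tf", "gene")]
  va_neg <- sample_negatives(net, expr, nrow(va_pos), exclude = as.matrix(excl),
                             seed = seed + 2L)
  excl <- rbind(as.matrix(excl), as.matrix(va_neg[, c("tf", "gene")]))
  te_neg <- sample_negatives(net, expr, n_test_neg, exclude = excl,
                             seed = seed + 3L)

  as_set <- function(p, n) {
    labeled_pairs(c(p[, 1], n$tf), c(p[, 2], n$gene),
                  c(rep(1L, nrow(p)), n$label))
  }
  split <- structure(list(
    train = as_set(tr_pos, tr_neg),
    val = as_set(va_pos, va_neg),
    test = as_set(te_pos, te_neg),
    train_adjacency = regulatory_network(tr_pos, net$num_nodes),
    scheme = scheme
  ), class = "DatasetSplit")
  validate_split(split, net)
  split
}

# leakage and disjointness guards, asserted on every constructed split
validate_split <- function(split, net) {
  pos_keys <- function(ps) pair_key(ps$tf[ps$label == 1], ps$gene[ps$label == 1])
  neg_keys <- function(ps) pair_key(ps$tf[ps$label == 0], ps$gene[ps$label == 0])
  tr <- pos_keys(split$train); va <- pos_keys(split$val); te <- pos_keys(split$test)
  if (length(intersect(tr, va)) || length(intersect(tr, te)) ||
      length(intersect(va, te))) {
    stop("positive partitions overlap")
  }
  if (!setequal(c(tr, va, te), edge_keys(net))) {
    stop("positive partitions do not cover the ground-truth edge set")
  }
  if (!setequal(edge_keys(split$train_adjacency), tr)) {
    stop("training adjacency must equal the training positives")
  }
  negs <- c(neg_keys(split$train), neg_keys(split$val), neg_keys(split$test))
  if (length(intersect(negs, edge_keys(net)))) {
    stop("a sampled negative collides with a ground-truth positive")
  }
  invisible(split)
}

#' @export
print.DatasetSplit <- function(x, ...) {
  f <- function(ps) sprintf("%d pos / %d neg", sum(ps$label == 1),
                            sum(ps$label == 0))
  cat(sprintf("DatasetSplit (%s): train %s; val %s; test %s\n", x$scheme,
              f(x$train), f(x$val), f(x$test)))
  invisible(x)
}
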