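test_that("expression round-trips through delimited text exactly", {
  expr <- tiny_expr(3, 2, 1, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, path)
  back <- load_expression(path, tf_ids = expr$gene_ids[expr$is_tf])
  expect_equal(dim(back$values), c(3, 2))
  expect_identical(back$gene_ids, expr$gene_ids)
  expect_identical(back$cell_ids, expr$cell_ids)
  expect_identical(back$is_tf, expr$is_tf)
  expect_equal(back$values, expr$values, tolerance = 0)
})

test_that("loading rejects duplicated gene ids and non-numeric cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2", "gA,1,2", "gA,3,4"), path)
  expect_error(load_expression(path), "duplicate gene ids.*gA")
  writeLines(c("gene,c1,c2", "gA,1,2", "gB,x,4"), path)
  expect_error(load_expression(path), "non-numeric.*gB.*c1")
})

test_that("network loading maps ids, drops unknowns and deduplicates", {
  expr <- tiny_expr(3, 2, 1)  # genes g1..g3
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TF,Target", "g1,g2", "g1,g3"), path)
  net <- load_network(path, expr)
  expect_equal(nrow(net$edges), 2)
  expect_equal(unname(net$edges[, 1]), c(1L, 1L))

  writeLines(c("TF,Target", "g1,g2", "g1,gD"), path)
  expect_message(net2 <- load_network(path, expr), "dropped")
  expect_equal(nrow(net2$edges), 1)

  writeLines(c("g1,g2", "g1,g2"), path)  # duplicate, no header
  expect_equal(nrow(load_network(path, expr)$edges), 1)

  writeLines(c("gX,gY"), path)
  expect_error(load_network(path, expr), "no edges remain")
})

test_that("gene filtering enforces detection, significance and top-k rules", {
  set.seed(42)
  n_cells <- 40
  # gene detected in 5% of cells must fall to the 10% detection filter
  rare <- c(stats::rlnorm(2), rep(0, n_cells - 2))
  strong <- matrix(stats::rlnorm(8 * n_cells, sdlog = 1.5), 8, n_cells)
  constant <- rep(1, n_cells)
  vals <- rbind(strong[1:2, ], rare, strong[3:8, ], constant)
  expr <- expression_matrix(vals, sprintf("g%d", 1:10), sprintf("c%d", 1:n_cells),
                            is_tf = c(TRUE, TRUE, rep(FALSE, 8)))
  filt <- filter_genes(expr, min_cell_fraction = 0.1, alpha = 0.01,
                       top_k = 500, pvalue_fun = function(v) rep(0, nrow(v)))
  expect_false("g3" %in% filt$gene_ids)   # the 5%-detected gene
  expect_true(all(c("g1", "g2") %in% filt$gene_ids))

  # top_k >= survivors keeps everything that passed the screens
  expect_equal(length(filt$gene_ids), 9)

  # a constant gene has zero log-variance: it ranks last and is the first
  # dropped when top_k trims the non-TF survivors
  filt2 <- filter_genes(expr, min_cell_fraction = 0.1, alpha = 0.01,
                        top_k = 3, pvalue_fun = function(v) rep(0, nrow(v)))
  expect_false("g10" %in% filt2$gene_ids)
  expect_true(all(c("g1", "g2") %in% filt2$gene_ids))  # TFs always kept
  expect_equal(sum(!filt2$is_tf), 3)

  # default screen: all-noise genes against alpha small enough -> error
  flat <- expression_matrix(matrix(1, 4, n_cells) +
                              matrix(stats::rnorm(4 * n_cells, sd = 1e-6), 4),
                            sprintf("f%d", 1:4), sprintf("c%d", 1:n_cells))
  expect_error(filter_genes(flat, min_cell_fraction = 0, alpha = 1e-12),
               "variance-significance")
})

test_that("split sizes follow the two protocols for 300 positives", {
  expr <- tiny_expr(40, 6, 20, seed = 5)
  net <- random_net(expr, 300, seed = 5)
  s1 <- split_dataset(net, expr, "string_like", seed = 9)
  expect_equal(sum(s1$train$label == 1), 160)
  expect_equal(sum(s1$val$label == 1), 40)
  expect_equal(sum(s1$test$label == 1), 100)
  # 1:1 negatives for train and val
  expect_equal(sum(s1$train$label == 0), 160)
  expect_equal(sum(s1$val$label == 0), 40)

  s2 <- split_dataset(net, expr, "celltype_specific", seed = 9)
  expect_equal(sum(s2$train$label == 1), 200)
  expect_equal(sum(s2$val$label == 1), 30)
  expect_equal(sum(s2$test$label == 1), 70)

  # test negative ratio is configurable
  s3 <- split_dataset(net, expr, "string_like", test_neg_ratio = 2, seed = 9)
  expect_equal(sum(s3$test$label == 0), 200)
})

test_that("splits partition positives, guard leakage and avoid collisions", {
  for (rep in 1:20) {
    expr <- tiny_expr(15, 5, 5, seed = rep)
    net <- random_net(expr, 20, seed = rep)
    scheme <- if (rep %% 2) "string_like" else "celltype_specific"
    s <- split_dataset(net, expr, scheme, seed = rep)
    key <- function(ps, lab) paste(ps$tf[ps$label == lab],
                                   ps$gene[ps$label == lab])
    pos <- c(key(s$train, 1), key(s$val, 1), key(s$test, 1))
    truth <- paste(net$edges[, 1], net$edges[, 2])
    expect_setequal(pos, truth)                  # no loss, no overlap
    expect_equal(anyDuplicated(pos), 0)
    adj <- paste(s$train_adjacency$edges[, 1], s$train_adjacency$edges[, 2])
    expect_setequal(adj, key(s$train, 1))        # leakage guard
    expect_length(intersect(adj, c(key(s$val, 1), key(s$test, 1))), 0)
    negs <- c(key(s$train, 0), key(s$val, 0), key(s$test, 0))
    expect_length(intersect(negs, truth), 0)     # negatives never positives
    expect_equal(anyDuplicated(negs), 0)
  }
})

test_that("splitting is deterministic given the seed", {
  expr <- tiny_expr(20, 5, 8, seed = 3)
  net <- random_net(expr, 60, seed = 3)
  a <- split_dataset(net, expr, "string_like", seed = 77)
  b <- split_dataset(net, expr, "string_like", seed = 77)
  expect_identical(a, b)
  c_ <- split_dataset(net, expr, "string_like", seed = 78)
  expect_false(identical(a$train, c_$train))
})

test_that("negative sampling enumerates the candidate space correctly", {
  # 3 genes, 2 TFs; brute-force candidate space: ordered (tf, j), j != tf,
  # minus the 2 positives -> (1,2),(1,3),(2,1),(2,3) minus 2 = 2 pairs
  expr <- tiny_expr(3, 3, 2, seed = 1)
  net <- tiny_net(list(c(1, 2), c(2, 3)), 3)
  brute <- expand.grid(tf = 1:2, j = 1:3)
  brute <- brute[brute$tf != brute$j, ]
  brute <- brute[!(paste(brute$tf, brute$j) %in% c("1 2", "2 3")), ]
  expect_equal(nrow(brute), 2)
  got <- sample_negatives(net, expr, 2, seed = 4)
  expect_setequal(paste(got$tf, got$gene),
                  paste(brute$tf, brute$j))
  expect_true(all(got$label == 0))

  expect_equal(nrow(sample_negatives(net, expr, 0, seed = 1)), 0)
  expect_error(sample_negatives(net, expr, 3, seed = 1), "only 2")

  s1 <- sample_negatives(net, expr, 1, seed = 10)
  s2 <- sample_negatives(net, expr, 1, seed = 10)
  expect_identical(s1, s2)
})

test_that("constructors reject malformed inputs", {
  expect_error(expression_matrix(matrix(1, 2, 2), c("a", "a"), c("c1", "c2")),
               "duplicate")
  expect_error(expression_matrix(matrix(c(1, NA, 1, 1), 2, 2), c("a", "b"),
                                 c("c1", "c2")), "finite")
  expect_error(regulatory_network(cbind(1, 5), num_nodes = 3), "indices")
  expect_error(labeled_pairs(c(1, 1), c(2, 2), c(1, 1)), "twice")
  expect_error(labeled_pairs(1, 2, 3), "labels")
})
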