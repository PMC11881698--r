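# small but learnable planted dataset for the optimisation tests
small_sim <- function(seed) {
  simulate_grn(synthetic_spec(n_tfs = 4, n_genes = 60, n_cells = 60,
                              edge_density = 0.15, effect_size = 1.0,
                              noise_sd = 0.3, dropout_rate = 0.1,
                              seed = seed))
}
small_cfg <- function(...) {
  train_config(heads = 2L, d1 = 16L, d2 = 16L, mlp_hidden = 16L, d_emb = 8L,
               ...)
}

test_that("zero epochs leave the initialisation untouched", {
  sim <- small_sim(1)
  split <- split_dataset(sim$net, sim$expr, "celltype_specific", seed = 1)
  cfg <- small_cfg(epochs = 0L, pretrain_epochs = 0L, seed = 4)
  model <- grn_train(split, sim$expr, cfg)
  fresh <- grnlink:::init_model(cfg, ncol(sim$expr$values), cfg$seed)
  expect_equal(model$encoder$weights, fresh$encoder$weights)
  expect_equal(model$heads$weights, fresh$heads$weights)
  expect_equal(nrow(model$log), 0)
})

test_that("training is deterministic and reduces the training loss", {
  sim <- small_sim(2)
  split <- split_dataset(sim$net, sim$expr, "celltype_specific", seed = 2)
  cfg <- small_cfg(epochs = 6L, pretrain_epochs = 4L, seed = 11)
  m1 <- grn_train(split, sim$expr, cfg)
  m2 <- grn_train(split, sim$expr, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$encoder$weights, m2$encoder$weights)
  expect_lt(m1$log$total[nrow(m1$log)], m1$log$total[1])
  # phases are labelled as configured
  expect_equal(sum(m1$log$phase == "pretrain"), 4)
  expect_equal(sum(m1$log$phase == "train"), 6)
  # contrastive loss inactive during pretraining
  expect_true(all(m1$log$L_con[m1$log$phase == "pretrain"] == 0))
})

test_that("the ablation flag changes only the phase-2 objective", {
  sim <- small_sim(3)
  split <- split_dataset(sim$net, sim$expr, "celltype_specific", seed = 3)
  on <- grn_train(split, sim$expr,
                  small_cfg(epochs = 3L, pretrain_epochs = 3L, seed = 7))
  off <- grn_train(split, sim$expr,
                   small_cfg(epochs = 3L, pretrain_epochs = 3L, seed = 7,
                             contrastive_enabled = FALSE))
  pre <- 1:3
  expect_equal(on$log$total[pre], off$log$total[pre], tolerance = 1e-12)
  expect_true(all(off$log$L_con == 0))
  expect_false(isTRUE(all.equal(on$log$total[4:6], off$log$total[4:6])))
})

test_that("evaluation reports correct metrics and refuses one-class tests", {
  sim <- small_sim(4)
  split <- split_dataset(sim$net, sim$expr, "celltype_specific", seed = 4)
  cfg <- small_cfg(epochs = 5L, pretrain_epochs = 5L, seed = 4)
  model <- grn_train(split, sim$expr, cfg)
  res <- evaluate_model(model, split, sim$expr)
  expect_s3_class(res, "EvalResult")
  expect_true(res$auroc >= 0 && res$auroc <= 1)
  expect_true(res$auprc >= 0 && res$auprc <= 1)
  expect_equal(res$n_pos, sum(split$test$label == 1))
  # determinism of the full pipeline result
  res2 <- evaluate_model(grn_train(split, sim$expr, cfg), split, sim$expr)
  expect_identical(res, res2)
  bad <- split
  bad$test <- labeled_pairs(c(1, 2), c(5, 6), c(1, 1))
  expect_error(evaluate_model(model, bad, sim$expr), "both classes")
})

test_that("SVD alignment satisfies the Eckart-Young properties", {
  expr <- tiny_expr(12, 9, 3, seed = 31)
  al <- svd_align(expr, 5)
  expect_equal(dim(al$values), c(12, 5))
  expect_identical(al$is_tf, expr$is_tf)

  # rank-1 input: one component reconstructs exactly
  u <- 1:6; v <- c(2, 4, 1)
  r1 <- expression_matrix(outer(u, v), sprintf("g%d", 1:6),
                          sprintf("c%d", 1:3))
  a1 <- svd_align(r1, 1)
  dec <- svd(outer(u, v))
  expect_equal(abs(as.numeric(a1$values)), abs(dec$u[, 1] * dec$d[1]),
               tolerance = 1e-8)

  # Frobenius reconstruction error is non-increasing in d
  X <- grnlink:::local_seed(5, matrix(stats::rnorm(12 * 9), 12, 9))
  rx <- expression_matrix(X, sprintf("g%d", 1:12), sprintf("c%d", 1:9))
  errs <- vapply(1:9, function(d) {
    dec <- svd(X)
    approx <- dec$u[, 1:d, drop = FALSE] %*%
      diag(dec$d[1:d], d, d) %*% t(dec$v[, 1:d, drop = FALSE])
    sqrt(sum((X - approx)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_error(svd_align(expr, 10), "exceeds")
})

test_that("ranked predictions exclude known edges and sort by score", {
  sim <- small_sim(6)
  split <- split_dataset(sim$net, sim$expr, "celltype_specific", seed = 6)
  model <- grn_train(split, sim$expr,
                     small_cfg(epochs = 3L, pretrain_epochs = 3L, seed = 6))
  top <- rank_predictions(model, sim$expr, split$train_adjacency, k = 25)
  expect_equal(nrow(top), 25)
  expect_true(all(diff(top$score) <= 0))
  known <- paste(split$train_adjacency$edges[, 1],
                 split$train_adjacency$edges[, 2])
  expect_length(intersect(paste(top$tf_idx, top$gene_idx), known), 0)
  expect_true(all(sim$expr$is_tf[top$tf_idx]))
  # k = 0 and k beyond the candidate count
  expect_equal(nrow(rank_predictions(model, sim$expr, split$train_adjacency,
                                     k = 0)), 0)
  all_cand <- rank_predictions(model, sim$expr, split$train_adjacency,
                               k = 10^6)
  n_tf <- sum(sim$expr$is_tf)
  expect_equal(nrow(all_cand),
               n_tf * (sim$net$num_nodes - 1) -
                 nrow(split$train_adjacency$edges))
})

test_that("training aborts on a divergent objective", {
  sim <- small_sim(7)
  split <- split_dataset(sim$net, sim$expr, "celltype_specific", seed = 7)
  cfg <- small_cfg(epochs = 2L, pretrain_epochs = 0L, seed = 7)
  bad_expr <- sim$expr
  bad_expr$values[1, 1] <- 1e154   # overflow under the dot-product decoder
  expect_error(grn_train(split, bad_expr, cfg), "non-finite")
})
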