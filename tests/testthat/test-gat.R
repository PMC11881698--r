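test_that("attention over a bare neighbourhood follows the softmax", {
  # single neighbour -> weight 1
  params <- tiny_encoder(n_feat = 2, heads = 1, d1 = 2, seed = 3)
  G <- matrix(c(1, 2, 3, 4), 2, 2)
  net <- tiny_net(list(c(1, 2)), 2)
  att <- attention_scores(params, G, net, head = 1, self_loops = FALSE)
  expect_equal(att$att, c(1, 1))  # i=1 from j=2 and (undirected) i=2 from j=1

  # two neighbours with identical features -> equal sims -> 0.5 each
  G3 <- rbind(c(1, 0), c(0, 1), c(0, 1))
  net3 <- tiny_net(list(c(1, 2), c(1, 3)), 3)
  att3 <- attention_scores(params, G3, net3, head = 1, self_loops = FALSE)
  into1 <- att3$att[att3$i == 1]
  expect_equal(into1, c(0.5, 0.5))
})

test_that("post-LeakyReLU logits {1, 0} softmax to e/(e+1) and 1/(e+1)", {
  params <- encoder_params(1, heads = 1, d1 = 1, seed = 1)
  params$weights$layer1[[1]]$W <- matrix(1, 1, 1)
  params$weights$layer1[[1]]$a_self <- 0
  params$weights$layer1[[1]]$a_neigh <- 1
  G <- matrix(c(0, 1, 0), 3, 1)        # logits: from j=2 -> 1, from j=3 -> 0
  net <- tiny_net(list(c(1, 2), c(1, 3)), 3)
  att <- attention_scores(params, G, net, head = 1, self_loops = FALSE)
  into1 <- att$att[att$i == 1]
  js <- att$j[att$i == 1]
  expected <- c(exp(1), exp(0)) / (exp(1) + exp(0))
  expect_equal(into1[order(js)], expected, tolerance = 1e-4)
  expect_equal(round(expected, 4), c(0.7311, 0.2689))
})

test_that("attention weights into every node sum to one in every head", {
  expr <- tiny_expr(8, 5, 3, seed = 9)
  net <- random_net(expr, 10, seed = 9)
  params <- tiny_encoder(n_feat = 5, heads = 2, seed = 9)
  for (h in 1:2) {
    att <- attention_scores(params, expr$values, net, head = h)
    sums <- tapply(att$att, att$i, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  }
})

test_that("layer identities hold for single neighbours and identity weights", {
  # K=1, identity W and sigma, single neighbour: output_i = g_j
  params <- encoder_params(2, heads = 1, d1 = 2, d2 = 2,
                           activation = "identity", seed = 2)
  params$weights$layer1[[1]]$W <- diag(2)
  G <- rbind(c(5, 6), c(7, 8))
  net <- tiny_net(list(c(1, 2)), 2)
  out <- gat_layer_concat(params, G, net, self_loops = FALSE)
  expect_equal(out[1, ], G[2, ])   # node 1 aggregates exactly g_2
  expect_equal(out[2, ], G[1, ])   # undirected: node 2 gets g_1

  # K=2 identical heads -> K=1 output repeated twice
  p2 <- encoder_params(2, heads = 2, d1 = 2, activation = "identity", seed = 2)
  p2$weights$layer1[[2]] <- p2$weights$layer1[[1]]
  out2 <- gat_layer_concat(p2, G, net, self_loops = FALSE)
  one <- gat_layer_concat(params, G, net, self_loops = FALSE)
  p1w <- p2
  p1w$weights$layer1 <- p1w$weights$layer1[1]
  p1w$config$heads <- 1L
  base <- gat_layer_concat(p1w, G, net, self_loops = FALSE)
  expect_equal(out2, cbind(base, base))

  # averaging layer: identity weights, single neighbour -> h_j
  params$weights$layer2[[1]]$W <- diag(2)
  avg <- gat_layer_average(params, G, net, self_loops = FALSE)
  expect_equal(avg[1, ], G[2, ])

  # K identical heads average to the single-head result
  p2$weights$layer2[[2]] <- p2$weights$layer2[[1]]
  p1w$weights$layer2 <- p2$weights$layer2[1]
  h1 <- matrix(stats::rnorm(8), 2, 4)
  expect_equal(gat_layer_average(p2, h1, net),
               gat_layer_average(p1w, h1, net), tolerance = 1e-12)
})

test_that("vectorized layers match the per-node loop oracle", {
  for (seed in 1:5) {
    expr <- tiny_expr(n_genes = 5 + seed, n_cells = 4, n_tfs = 2, seed = seed)
    net <- random_net(expr, 6 + seed, seed = seed)
    params <- tiny_encoder(n_feat = 4, heads = 2, d1 = 3, d2 = 3, seed = seed)
    G <- expr$values
    got1 <- gat_layer_concat(params, G, net)
    expect_equal(got1, oracle_layer(params, G, net, layer = 1),
                 tolerance = 1e-6)
    H1 <- got1
    got2 <- gat_layer_average(params, H1, net)
    p2 <- params
    expect_equal(got2, oracle_layer(p2, H1, net, layer = 2), tolerance = 1e-6)
  }
})

test_that("identical views produce identical embeddings under shared weights", {
  expr <- tiny_expr(10, 6, 3, seed = 12)
  net <- random_net(expr, 12, seed = 12)
  params <- tiny_encoder(n_feat = 6, seed = 12)
  emb <- encode(params, expr, make_views(net, removal_prob = 0, seed = 1))
  expect_identical(emb$preserved$layer2, emb$perturbed$layer2)
  expect_identical(emb$preserved$view, "preserved")
  expect_identical(emb$perturbed$view, "perturbed")
})

test_that("isolated nodes keep finite self-feature embeddings", {
  expr <- tiny_expr(6, 4, 2, seed = 13)
  net <- random_net(expr, 5, seed = 13)
  # removal probability 1 isolates every node in the perturbed view
  emb <- encode(tiny_encoder(n_feat = 4, seed = 13), expr,
                make_views(net, removal_prob = 1, seed = 1))
  expect_true(all(is.finite(emb$perturbed$layer2)))
  expect_equal(nrow(emb$perturbed$layer2), 6)
})

test_that("encoding is permutation-equivariant", {
  expr <- tiny_expr(7, 5, 3, seed = 14)
  net <- random_net(expr, 8, seed = 14)
  params <- tiny_encoder(n_feat = 5, seed = 14)
  views <- make_views(net, removal_prob = 0, seed = 1)
  base <- encode(params, expr, views)$preserved$layer2

  perm <- grnlink:::local_seed(99, sample(7))
  inv <- order(perm)
  expr_p <- expression_matrix(expr$values[perm, ], expr$gene_ids[perm],
                              expr$cell_ids, expr$is_tf[perm])
  net_p <- regulatory_network(cbind(inv[net$edges[, 1]], inv[net$edges[, 2]]),
                              7)
  out_p <- encode(params, expr_p, make_views(net_p, 0, seed = 1))$preserved$layer2
  expect_equal(out_p, base[perm, ], tolerance = 1e-10)
})
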