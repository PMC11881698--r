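# Independent brute-force oracles. These re-derive the quantities the package
# computes with naive loops so the vectorized implementations can be checked
# against them; they share no code with the implementation.

# per-node loop oracle for one attention layer (concat for layer 1, average
# for layer 2), with undirected neighbourhoods and optional self-loops
oracle_layer <- function(params, G, net, layer = 1, self_loops = TRUE) {
  cfg <- params$config
  act <- grnlink:::get_activation(cfg$activation)
  M <- net$num_nodes
  nbrs <- lapply(seq_len(M), function(i) {
    out <- net$edges[net$edges[, 1] == i, 2]
    if (!cfg$directed) out <- c(out, net$edges[net$edges[, 2] == i, 1])
    if (self_loops) out <- c(out, i)
    sort(unique(out))
  })
  heads <- params$weights[[if (layer == 1) "layer1" else "layer2"]]
  per_head <- lapply(heads, function(h) {
    Z <- G %*% h$W
    U <- matrix(0, M, ncol(Z))
    for (i in seq_len(M)) {
      js <- nbrs[[i]]
      if (!length(js)) next
      sims <- vapply(js, function(j) {
        sum(h$a_self * Z[i, ]) + sum(h$a_neigh * Z[j, ])
      }, numeric(1))
      e <- ifelse(sims > 0, sims, cfg$leaky_slope * sims)
      att <- exp(e - max(e)); att <- att / sum(att)
      for (t in seq_along(js)) U[i, ] <- U[i, ] + att[t] * Z[js[t], ]
    }
    U
  })
  if (layer == 1) {
    do.call(cbind, lapply(per_head, act$f))
  } else {
    act$f(Reduce(`+`, per_head) / cfg$heads)
  }
}

# per-anchor loop oracle for the inter-view InfoNCE loss
oracle_inter_view <- function(h, h_hat, tau, nodes = seq_len(nrow(h))) {
  A <- h[nodes, , drop = FALSE]
  B <- h_hat[nodes, , drop = FALSE]
  n <- nrow(A)
  cos <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) 0 else sum(u * v) / (nu * nv)
  }
  tot <- 0
  for (i in seq_len(n)) {
    num_p <- exp(cos(A[i, ], B[i, ]) / tau)
    den_p <- sum(vapply(seq_len(n),
                        function(j) exp(cos(A[i, ], B[j, ]) / tau),
                        numeric(1)))
    num_q <- exp(cos(B[i, ], A[i, ]) / tau)
    den_q <- sum(vapply(seq_len(n),
                        function(j) exp(cos(B[i, ], A[j, ]) / tau),
                        numeric(1)))
    tot <- tot + (-log(num_p / den_p)) + (-log(num_q / den_q))
  }
  tot / (2 * n)
}

# brute-force pairwise-comparison AUROC oracle
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# step-wise precision-recall oracle walking distinct thresholds
oracle_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_r <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n_pos
    area <- area + prec * (rec - prev_r)
    prev_r <- rec
  }
  area
}
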