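#' Initialise parameters for the two-layer graph-attention encoder
#'
#' The encoder follows the classic multi-head graph-attention design: layer 1
#' projects each gene's expression profile through a per-head weight matrix,
#' scores each (gene, neighbour) pair with a learnable attention vector
#' applied to the concatenated projections, normalises scores with a
#' per-neighbourhood softmax (after a LeakyReLU), aggregates neighbours by the
#' attention weights, and concatenates the K head outputs. Layer 2 repeats the
#' mechanism on the layer-1 output but averages heads instead of
#' concatenating, yielding the final per-gene representation h^(2). One
#' parameter set serves both graph views (weight sharing is what makes the
#' inter-view contrast meaningful).
#'
#' @param n_features input feature dimension (number of cells, or SVD
#'   components after alignment).
#' @param heads number of attention heads K.
#' @param d1 per-head output dimension of layer 1 (layer-1 output is
#'   `heads * d1` wide after concatenation).
#' @param d2 output dimension of layer 2 (head-averaged).
#' @param leaky_slope negative slope of the LeakyReLU applied to raw
#'   attention logits.
#' @param activation elementwise nonlinearity sigma: `"elu"`, `"relu"`,
#'   `"tanh"` or `"identity"`.
#' @param directed if `FALSE` (default) message passing treats the adjacency
#'   as undirected, so targets also aggregate from their regulators; if
#'   `TRUE`, gene i aggregates only from j with (i, j) an edge.
#' @param log1p_features apply `log1p` to the expression features before
#'   encoding.
#' @param seed RNG seed for Glorot initialisation.
#' @return An object of class `EncoderParams`: list with `config` and
#'   `weights` (nested list of per-head `W`, `a_self`, `a_neigh`).
#' @export
encoder_params <- function(n_features, heads = 2L, d1 = 128L, d2 = 128L,
                           leaky_slope = 0.2, activation = "elu",
                           directed = FALSE, log1p_features = FALSE,
                           seed = 1L) {
  stopifnot(heads >= 1, d1 >= 1, d2 >= 1, n_features >= 1)
  get_activation(activation)  # validate name early
  init_head <- function(fan_in, d) {
    list(W = glorot(fan_in, d),
         a_self = stats::runif(d, -sqrt(3 / d), sqrt(3 / d)),
         a_neigh = stats::runif(d, -sqrt(3 / d), sqrt(3 / d)))
  }
  weights <- local_seed(seed, list(
    layer1 = lapply(seq_len(heads), function(k) init_head(n_features, d1)),
    layer2 = lapply(seq_len(heads), function(k) init_head(heads * d1, d2))
  ))
  structure(list(
    config = list(n_features = n_features, heads = as.integer(heads),
                  d1 = as.integer(d1), d2 = as.integer(d2),
                  leaky_slope = leaky_slope, activation = activation,
                  directed = directed, log1p_features = log1p_features),
    weights = weights
  ), class = "EncoderParams")
}

# Message-passing edge list: rows (i, j) meaning node i aggregates from j.
# Self-loops guarantee every softmax neighbourhood is non-empty (isolated
# nodes fall back to their own features); undirected mode adds the reversed
# edges so targets receive messages from their regulators.
message_edges <- function(net, directed = FALSE, self_loops = TRUE) {
  e <- net$edges
  i <- e[, 1]; j <- e[, 2]
  if (!directed) {
    i <- c(i, e[, 2]); j <- c(j, e[, 1])
  }
  if (self_loops) {
    i <- c(i, seq_len(net$num_nodes))
    j <- c(j, seq_len(net$num_nodes))
  }
  keep <- !duplicated(pair_key(i, j))
  list(i = i[keep], j = j[keep], n = net$num_nodes)
}

# scatter a per-edge vector into a per-node sum (groups may be sparse)
scatter_sum <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Forward pass of one attention head. Returns the pre-activation aggregate U
# and the intermediates needed for the backward pass.
head_forward <- function(head, G, msg, slope) {
  Z <- G %*% head$W
  s <- as.numeric(Z %*% head$a_self)[msg$i] +
    as.numeric(Z %*% head$a_neigh)[msg$j]
  if (!all(is.finite(s))) {
    bad <- msg$i[which(!is.finite(s))[1]]
    stop("non-finite attention score at node ", bad)
  }
  e <- leaky_relu(s, slope)
  mx <- scatter_max(e, msg$i, msg$n)
  em <- exp(e - mx[msg$i])
  denom <- scatter_sum(em, msg$i, msg$n)
  att <- em / denom[msg$i]
  P <- Matrix::sparseMatrix(i = msg$i, j = msg$j, x = att,
                            dims = c(msg$n, msg$n))
  U <- as.matrix(P %*% Z)
  list(Z = Z, s = s, att = att, P = P, U = U)
}

scatter_max <- function(x, group, n) {
  out <- rep(-Inf, n)
  m <- vapply(split(x, group), max, numeric(1))
  out[as.integer(names(m))] <- m
  out
}

# Backward pass of one head: given dL/dU, produce gradients for the head's
# weights and the input features.
head_backward <- function(head, G, msg, cache, dU, slope) {
  Z <- cache$Z
  datt <- rowSums(dU[msg$i, , drop = FALSE] * Z[msg$j, , drop = FALSE])
  dZ <- as.matrix(Matrix::crossprod(cache$P, dU))
  # softmax backward within each neighbourhood
  csum <- scatter_sum(cache$att * datt, msg$i, msg$n)
  de <- cache$att * (datt - csum[msg$i])
  ds <- de * leaky_relu_grad(cache$s, slope)
  d_self_node <- scatter_sum(ds, msg$i, msg$n)
  d_neigh_node <- scatter_sum(ds, msg$j, msg$n)
  dZ <- dZ + outer(d_self_node, head$a_self) + outer(d_neigh_node, head$a_neigh)
  list(W = crossprod(G, dZ),
       a_self = as.numeric(crossprod(Z, d_self_node)),
       a_neigh = as.numeric(crossprod(Z, d_neigh_node)),
       dG = dZ %*% t(head$W))
}

# Full encoder forward with cache: layer 1 (concat heads), layer 2 (average
# heads), shared activation sigma.
encoder_forward <- function(params, G, net) {
  cfg <- params$config
  act <- get_activation(cfg$activation)
  msg <- message_edges(net, cfg$directed)
  l1 <- lapply(params$weights$layer1, head_forward, G = G, msg = msg,
               slope = cfg$leaky_slope)
  H1 <- do.call(cbind, lapply(l1, function(h) act$f(h$U)))
  l2 <- lapply(params$weights$layer2, head_forward, G = H1, msg = msg,
               slope = cfg$leaky_slope)
  Uavg <- Reduce(`+`, lapply(l2, `[[`, "U")) / cfg$heads
  H2 <- act$f(Uavg)
  list(H1 = H1, H2 = H2, Uavg = Uavg, l1 = l1, l2 = l2, msg = msg, G = G)
}

encoder_backward <- function(params, cache, dH2) {
  cfg <- params$config
  act <- get_activation(cfg$activation)
  K <- cfg$heads
  dUavg <- dH2 * act$grad(cache$Uavg)
  dH1 <- matrix(0, nrow(cache$H1), ncol(cache$H1))
  g_layer2 <- vector("list", K)
  for (k in seq_len(K)) {
    bk <- head_backward(params$weights$layer2[[k]], cache$H1, cache$msg,
                        cache$l2[[k]], dUavg / K, cfg$leaky_slope)
    dH1 <- dH1 + bk$dG
    bk$dG <- NULL
    g_layer2[[k]] <- bk
  }
  g_layer1 <- vector("list", K)
  d1 <- cfg$d1
  for (k in seq_len(K)) {
    cols <- (k - 1L) * d1 + seq_len(d1)
    dUk <- dH1[, cols, drop = FALSE] * act$grad(cache$l1[[k]]$U)
    bk <- head_backward(params$weights$layer1[[k]], cache$G, cache$msg,
                        cache$l1[[k]], dUk, cfg$leaky_slope)
    bk$dG <- NULL
    g_layer1[[k]] <- bk
  }
  list(layer1 = g_layer1, layer2 = g_layer2)
}

prep_features <- function(params, expr) {
  G <- expr$values
  if (ncol(G) != params$config$n_features) {
    stop(sprintf("encoder expects %d input features but expression has %d",
                 params$config$n_features, ncol(G)))
  }
  if (params$config$log1p_features) G <- log1p(pmax(G, 0))
  G
}

#' Normalised attention scores of one head
#'
#' Computes, for every message-passing pair (i, j), the softmax-normalised
#' attention weight att_ij of the requested head and layer: the raw logit is
#' the head's attention vector applied to the concatenated projections of i
#' and j, passed through a LeakyReLU, then normalised over each node's
#' neighbourhood so that the weights aggregating into any node sum to one.
#'
#' @param params an [encoder_params()] object.
#' @param features per-gene input feature matrix for the requested layer
#'   (the expression matrix for layer 1, layer-1 output for layer 2).
#' @param net [regulatory_network()] supplying the topology.
#' @param head head index in `1..K`.
#' @param layer 1 or 2.
#' @param self_loops insert self-loops before normalising (the encoder always
#'   does; disable to inspect the bare neighbourhood softmax).
#' @return A data frame with columns `i`, `j`, `att`; for every node i
#'   present, `sum(att[i == i0])` is 1.
#' @export
attention_scores <- function(params, features, net, head = 1L, layer = 1L,
                             self_loops = TRUE) {
  stopifnot(layer %in% c(1L, 2L))
  w <- params$weights[[if (layer == 1L) "layer1" else "layer2"]]
  if (head < 1 || head > length(w)) stop("head index out of range")
  msg <- message_edges(net, params$config$directed, self_loops)
  if (!length(msg$i)) stop("no message-passing edges (empty neighbourhoods)")
  hf <- head_forward(w[[head]], features, msg, params$config$leaky_slope)
  data.frame(i = msg$i, j = msg$j, att = hf$att)
}

#' Layer-1 graph attention: head-concatenated output
#'
#' Runs the first encoder layer on `features` over `net`: per head, neighbour
#' features (projected by the head's weight) are aggregated with the head's
#' attention weights and passed through the activation; the K head outputs
#' are concatenated.
#'
#' @inheritParams attention_scores
#' @return Matrix of per-gene vectors, `num_nodes x (heads * d1)`.
#' @export
gat_layer_concat <- function(params, features, net, self_loops = TRUE) {
  cfg <- params$config
  act <- get_activation(cfg$activation)
  msg <- message_edges(net, cfg$directed, self_loops)
  l1 <- lapply(params$weights$layer1, head_forward, G = features, msg = msg,
               slope = cfg$leaky_slope)
  do.call(cbind, lapply(l1, function(h) act$f(h$U)))
}

#' Layer-2 graph attention: head-averaged output
#'
#' Runs the second encoder layer on `features` (normally the layer-1 output):
#' per-head aggregates are averaged over the K heads and the activation is
#' applied once to the average, so the output width is `d2` regardless of K.
#'
#' @inheritParams attention_scores
#' @return Matrix of per-gene vectors, `num_nodes x d2`.
#' @export
gat_layer_average <- function(params, features, net, self_loops = TRUE) {
  cfg <- params$config
  act <- get_activation(cfg$activation)
  msg <- message_edges(net, cfg$directed, self_loops)
  l2 <- lapply(params$weights$layer2, head_forward, G = features, msg = msg,
               slope = cfg$leaky_slope)
  act$f(Reduce(`+`, lapply(l2, `[[`, "U")) / cfg$heads)
}

#' Encode both graph views with shared parameters
#'
#' Runs the full two-layer encoder on the preserved and the perturbed view.
#' The feature matrix is identical for both views (only the topology is
#' augmented) and one parameter set serves both.
#'
#' @param params an [encoder_params()] object.
#' @param expr [expression_matrix()] providing node features.
#' @param views a [make_views()] pair.
#' @return A list with elements `preserved` and `perturbed`, each of class
#'   `GeneEmbeddings`: list with `layer1`, `layer2` (matrices) and `view`.
#' @export
encode <- function(params, expr, views) {
  G <- prep_features(params, expr)
  one <- function(net, label) {
    fwd <- encoder_forward(params, G, net)
    structure(list(layer1 = fwd$H1, layer2 = fwd$H2, view = label),
              class = "GeneEmbeddings")
  }
  list(preserved = one(views$preserved, "preserved"),
       perturbed = one(views$perturbed, "perturbed"))
}
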