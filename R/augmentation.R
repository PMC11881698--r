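#' Build the preserved/perturbed graph view pair
#'
#' The contrastive setup contrasts the observed network (preserved view)
#' against a randomly edge-dropped copy (perturbed view). Each edge of `net`
#' is removed independently with probability `removal_prob`; no edges are ever
#' added, so the perturbed edge set is a subset of the preserved one. Node
#' features are shared between views, so only the topology differs.
#'
#' @param net training-adjacency [regulatory_network()].
#' @param removal_prob per-edge Bernoulli removal probability in \[0, 1\].
#' @param seed RNG seed; the drop pattern is reproducible given the seed.
#' @return An object of class `GraphViewPair`: list with `preserved`,
#'   `perturbed` (both [regulatory_network()]) and `removal_prob`.
#' @export
make_views <- function(net, removal_prob = 0.2, seed = 1L) {
  stopifnot(removal_prob >= 0, removal_prob <= 1)
  E <- n_edges(net)
  drop <- local_seed(seed, stats::runif(E) < removal_prob)
  perturbed <- regulatory_network(net$edges[!drop, , drop = FALSE],
                                  net$num_nodes)
  structure(list(preserved = net, perturbed = perturbed,
                 removal_prob = removal_prob),
            class = "GraphViewPair")
}

#' @export
print.GraphViewPair <- function(x, ...) {
  cat(sprintf("GraphViewPair: %d edges preserved, %d kept after removal (p=%g)\n",
              n_edges(x$preserved), n_edges(x$perturbed), x$removal_prob))
  invisible(x)
}

#' Perturb a network by flipping edges
#'
#' Noise model for sensitivity studies: each existing edge is removed with
#' probability `flip_prob`, and for every removed edge one spurious edge is
#' added, drawn uniformly without replacement from unobserved (TF, gene)
#' pairs. The edge count is conserved.
#'
#' @param net [regulatory_network()] to perturb.
#' @param expr companion [expression_matrix()] (supplies the TF flags that
#'   define the candidate space for added edges).
#' @param flip_prob per-edge flip probability in \[0, 1\].
#' @param seed RNG seed.
#' @return A perturbed [regulatory_network()] with the same number of edges.
#' @export
flip_edges <- function(net, expr, flip_prob, seed = 1L) {
  stopifnot(flip_prob >= 0, flip_prob <= 1)
  E <- n_edges(net)
  local_seed(seed, {
    drop <- stats::runif(E) < flip_prob
    n_add <- sum(drop)
    kept <- net$edges[!drop, , drop = FALSE]
    if (n_add == 0) {
      regulatory_network(kept, net$num_nodes)
    } else {
      cand <- negative_candidates(net, expr)
      if (n_add > nrow(cand)) {
        stop(sprintf("cannot add %d edges: only %d unobserved pairs available",
                     n_add, nrow(cand)))
      }
      added <- cand[sample.int(nrow(cand), n_add), , drop = FALSE]
      regulatory_network(rbind(kept, added), net$num_nodes)
    }
  })
}
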