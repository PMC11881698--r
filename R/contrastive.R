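#' Contrastive-loss configuration
#'
#' @param tau softmax temperature (> 0) of the InfoNCE objective.
#' @param enabled ablation flag: when `FALSE` the training loop drops the
#'   contrastive term entirely.
#' @param node_set `"incident"` (default) restricts the contrasted nodes to
#'   those touching at least one training edge; `"all"` uses every gene.
#' @return An object of class `ContrastiveConfig`.
#' @export
contrastive_config <- function(tau = 0.5, enabled = TRUE,
                               node_set = c("incident", "all")) {
  stopifnot(tau > 0)
  structure(list(tau = tau, enabled = enabled,
                 node_set = match.arg(node_set)),
            class = "ContrastiveConfig")
}

#' Cosine similarity of two vectors
#'
#' Returns `u . v / (||u|| ||v||)`, with the convention that any zero-norm
#' input yields 0 (rather than NaN), which keeps early training finite when
#' an embedding collapses to zero.
#'
#' @param u,v numeric vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# Row-normalise a matrix; zero rows stay zero (cosine-0 convention).
row_normalize <- function(X) {
  n <- sqrt(rowSums(X^2))
  scale <- ifelse(n > 0, 1 / n, 0)
  list(U = X * scale, norm = n, scale = scale)
}

#' Inter-view contrastive (InfoNCE) loss
#'
#' For each anchor gene i in the preserved view, the positive pair is the
#' same gene in the perturbed view and the negatives are all other genes in
#' the perturbed view; similarities are cosine, scaled by the temperature,
#' and the per-anchor loss is the negative log-softmax of the positive
#' (denominator over all N' genes including the positive). The symmetric
#' term anchors in the perturbed view, and the final loss averages both
#' directions over the N' contrasted nodes.
#'
#' @param h,h_hat per-gene embedding matrices (preserved / perturbed view,
#'   same row count), normally the layer-2 encoder outputs.
#' @param cfg a [contrastive_config()].
#' @param nodes optional integer vector restricting the loss to a node
#'   subset (rows of `h`); defaults to all rows.
#' @param grad if `TRUE`, also return gradients with respect to `h` and
#'   `h_hat` (full-size matrices, zero outside `nodes`).
#' @return The scalar loss, or (with `grad = TRUE`) a list with `loss`,
#'   `dh`, `dh_hat`.
#' @export
inter_view_loss <- function(h, h_hat, cfg = contrastive_config(),
                            nodes = NULL, grad = FALSE) {
  if (nrow(h) != nrow(h_hat)) stop("views have mismatched node counts")
  if (is.null(nodes)) nodes <- seq_len(nrow(h))
  Np <- length(nodes)
  if (Np == 0) stop("empty contrastive node set")
  A <- h[nodes, , drop = FALSE]
  B <- h_hat[nodes, , drop = FALSE]
  na <- row_normalize(A)
  nb <- row_normalize(B)
  S <- tcrossprod(na$U, nb$U) / cfg$tau   # S[i, j] = theta(h_i, h_hat_j) / tau
  # log-softmax over rows (preserved anchors) and columns (perturbed anchors)
  lse_row <- apply(S, 1, function(r) {
    m <- max(r); m + log(sum(exp(r - m)))
  })
  lse_col <- apply(S, 2, function(cc) {
    m <- max(cc); m + log(sum(exp(cc - m)))
  })
  loss <- sum((lse_row - diag(S)) + (lse_col - diag(S))) / (2 * Np)
  if (!grad) return(loss)

  P_row <- exp(S - lse_row)        # row-softmax: preserved anchors
  P_col <- exp(t(t(S) - lse_col))  # column-softmax: perturbed anchors
  # dL/dS from both directions, averaged over 2*Np anchors
  dS <- (P_row + P_col - 2 * diag(Np)) / (2 * Np * cfg$tau)
  dA_u <- dS %*% nb$U              # grad wrt normalised rows of A
  dB_u <- crossprod(dS, na$U)
  # back through row normalisation: d(x/||x||) with zero rows frozen at 0
  unnorm <- function(X_u, dU, nn) {
    proj <- rowSums(dU * X_u)
    (dU - X_u * proj) * nn$scale
  }
  dA <- unnorm(na$U, dA_u, na)
  dB <- unnorm(nb$U, dB_u, nb)
  dh <- matrix(0, nrow(h), ncol(h)); dh[nodes, ] <- dA
  dh_hat <- matrix(0, nrow(h_hat), ncol(h_hat)); dh_hat[nodes, ] <- dB
  list(loss = loss, dh = dh, dh_hat = dh_hat)
}

# nodes incident to at least one edge of the (training) network
incident_nodes <- function(net) sort(unique(as.integer(net$edges)))
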