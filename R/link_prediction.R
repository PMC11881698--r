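#' Initialise the dual projection heads
#'
#' Two multilayer perceptrons of identical architecture but independent
#' parameters map the encoder output h^(2) to low-dimensional link-scoring
#' embeddings: one head for the preserved view, one for the perturbed view.
#' Default architecture: `d2 -> hidden -> d_emb` with the ELU nonlinearity
#' between layers and a linear output.
#'
#' @param d_in input dimension (the encoder's d2).
#' @param hidden hidden-layer width.
#' @param d_emb output embedding dimension.
#' @param activation hidden-layer nonlinearity.
#' @param seed RNG seed for initialisation.
#' @return An object of class `ProjectionHeads`: list with `config` and
#'   `weights$preserved` / `weights$perturbed`, each `W1, b1, W2, b2`.
#' @export
projection_heads <- function(d_in, hidden = 64L, d_emb = 32L,
                             activation = "elu", seed = 1L) {
  get_activation(activation)
  init_mlp <- function() {
    list(W1 = glorot(d_in, hidden), b1 = numeric(hidden),
         W2 = glorot(hidden, d_emb), b2 = numeric(d_emb))
  }
  weights <- local_seed(seed, list(preserved = init_mlp(),
                                   perturbed = init_mlp()))
  structure(list(config = list(d_in = as.integer(d_in),
                               hidden = as.integer(hidden),
                               d_emb = as.integer(d_emb),
                               activation = activation),
                 weights = weights),
            class = "ProjectionHeads")
}

mlp_forward <- function(w, X, act) {
  A1 <- sweep(X %*% w$W1, 2, w$b1, `+`)
  H1 <- act$f(A1)
  E <- sweep(H1 %*% w$W2, 2, w$b2, `+`)
  list(A1 = A1, H1 = H1, E = E)
}

mlp_backward <- function(w, X, cache, dE, act) {
  dH1 <- dE %*% t(w$W2)
  dA1 <- dH1 * act$grad(cache$A1)
  list(grads = list(W1 = crossprod(X, dA1), b1 = colSums(dA1),
                    W2 = crossprod(cache$H1, dE), b2 = colSums(dE)),
       dX = dA1 %*% t(w$W1))
}

#' Project encoder embeddings through a view's MLP head
#'
#' @param heads a [projection_heads()] object.
#' @param h2 `GeneEmbeddings` from [encode()] (its `view` field selects the
#'   head), or a plain matrix combined with `view`.
#' @param view `"preserved"` or `"perturbed"`; taken from `h2$view` when
#'   `h2` is a `GeneEmbeddings`.
#' @return Matrix of per-gene link-scoring embeddings (`num_genes x d_emb`).
#' @export
project <- function(heads, h2, view = NULL) {
  if (inherits(h2, "GeneEmbeddings")) {
    view <- h2$view
    h2 <- h2$layer2
  }
  if (is.null(view)) stop("view must be given for a plain matrix input")
  view <- match.arg(view, c("preserved", "perturbed"))
  if (ncol(h2) != heads$config$d_in) {
    stop(sprintf("projection head expects %d columns, got %d",
                 heads$config$d_in, ncol(h2)))
  }
  act <- get_activation(heads$config$activation)
  mlp_forward(heads$weights[[view]], h2, act)$E
}

#' Score TF-gene pairs from embeddings
#'
#' The link probability of pair (i, j) is the logistic transform of the dot
#' product of the two genes' embeddings: `p = sigmoid(e_i . e_j)`. The score
#' is symmetric in i and j.
#'
#' @param emb per-gene embedding matrix.
#' @param pairs a [labeled_pairs()] set (or any data frame with `tf`, `gene`).
#' @return Numeric vector of probabilities in (0, 1), one per pair.
#' @export
score_pairs <- function(emb, pairs) {
  if (nrow(pairs) == 0) return(numeric(0))
  if (max(pairs$tf, pairs$gene) > nrow(emb)) stop("pair index out of range")
  logits <- rowSums(emb[pairs$tf, , drop = FALSE] *
                      emb[pairs$gene, , drop = FALSE])
  unname(sigmoid(logits))
}

#' Summed binary cross-entropy over labeled pairs
#'
#' `-sum_q [ y_q log p_q + (1 - y_q) log(1 - p_q) ]`, with probabilities
#' clipped to `[eps, 1 - eps]` so the loss stays finite. The perturbed view
#' is scored against the same labels as the preserved view, since the
#' objective is to reconstruct the original graph from the perturbed one.
#'
#' @param probs predicted probabilities.
#' @param pairs the [labeled_pairs()] carrying labels `y_q`.
#' @param mean_mode average over pairs instead of summing (off by default;
#'   the summed form matches the training objective).
#' @param eps clipping constant.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(probs, pairs, mean_mode = FALSE, eps = 1e-7) {
  if (length(probs) != nrow(pairs)) stop("one probability per pair required")
  p <- pmin(pmax(probs, eps), 1 - eps)
  y <- pairs$label
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (mean_mode) mean(ll) else sum(ll)
}

#' Combine the dual-view BCE losses and the contrastive loss
#'
#' The training objective is `L = L_preser + L_pertur + beta * L_con`, where
#' the two BCE terms score the preserved and the perturbed view against the
#' same labels and beta balances the contrastive term.
#'
#' @param lp preserved-view BCE loss.
#' @param lq perturbed-view BCE loss.
#' @param lc contrastive loss.
#' @param beta balance hyper-parameter (>= 0); default 0.5.
#' @return An object of class `LossBundle`: list with `L_preser`,
#'   `L_pertur`, `L_con`, `beta`, `total`.
#' @export
total_loss <- function(lp, lq, lc, beta = 0.5) {
  stopifnot(beta >= 0)
  structure(list(L_preser = lp, L_pertur = lq, L_con = lc, beta = beta,
                 total = lp + lq + beta * lc),
            class = "LossBundle")
}

#' @export
print.LossBundle <- function(x, ...) {
  cat(sprintf(
    "LossBundle: total %.6g = %.6g (preserved) + %.6g (perturbed) + %g * %.6g (contrastive)\n",
    x$total, x$L_preser, x$L_pertur, x$beta, x$L_con))
  invisible(x)
}

# BCE gradient with respect to the embedding matrix, in the summed form:
# d/d logit = (p - y); contributions scatter to both endpoints of each pair.
bce_backward <- function(emb, pairs, mean_mode = FALSE) {
  probs <- score_pairs(emb, pairs)
  g <- probs - pairs$label
  if (mean_mode) g <- g / nrow(pairs)
  dE <- matrix(0, nrow(emb), ncol(emb))
  idx <- c(pairs$tf, pairs$gene)
  contrib <- rbind(g * emb[pairs$gene, , drop = FALSE],
                   g * emb[pairs$tf, , drop = FALSE])
  agg <- rowsum(contrib, idx)
  dE[as.integer(rownames(agg)), ] <- agg
  dE
}
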