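#' Training configuration
#'
#' Collects every hyper-parameter of the optimisation and of the model
#' architecture. The optimisation defaults follow the reference protocol:
#' Adam at learning rate 0.003, 20 training epochs preceded by 10 supervised
#' pre-training epochs (graph augmentation kept, contrastive term omitted),
#' edge-removal probability 0.2, and beta = 0.5 balancing the contrastive
#' term. Architecture defaults (2 heads, 128-dimensional layers, ELU) follow
#' common graph-attention practice and are all configurable.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param epochs number of full-objective training epochs.
#' @param pretrain_epochs supervised pre-training epochs (dual-view BCE only).
#' @param removal_prob per-edge removal probability for the perturbed view.
#' @param tau contrastive temperature.
#' @param beta contrastive balance weight in the total loss.
#' @param seed RNG seed governing initialisation, per-epoch view sampling and
#'   every other stochastic choice of the run.
#' @param contrastive_enabled ablation flag; `FALSE` drops the contrastive
#'   term from the phase-2 objective (pre-training is unaffected).
#' @param contrastive_nodes `"incident"` or `"all"`: node set entering the
#'   contrastive loss.
#' @param eval_view `"preserved"` scores test pairs with the preserved-view
#'   head on the un-augmented training adjacency; `"mean"` averages the
#'   preserved and perturbed heads' probabilities.
#' @param heads,d1,d2,leaky_slope,activation,directed,log1p_features encoder
#'   hyper-parameters, see [encoder_params()].
#' @param mlp_hidden,d_emb projection-head widths, see [projection_heads()].
#' @param bce_mean average (rather than sum) the BCE over pairs.
#' @return An object of class `TrainConfig`.
#' @export
train_config <- function(learning_rate = 0.003, epochs = 20L,
                         pretrain_epochs = 10L, removal_prob = 0.2,
                         tau = 0.5, beta = 0.5, seed = 1L,
                         contrastive_enabled = TRUE,
                         contrastive_nodes = "incident",
                         eval_view = c("preserved", "mean"),
                         heads = 2L, d1 = 128L, d2 = 128L,
                         leaky_slope = 0.2, activation = "elu",
                         directed = FALSE, log1p_features = FALSE,
                         mlp_hidden = 64L, d_emb = 32L, bce_mean = FALSE) {
  stopifnot(learning_rate > 0, epochs >= 0, pretrain_epochs >= 0,
            removal_prob >= 0, removal_prob <= 1, tau > 0, beta >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 removal_prob = removal_prob, tau = tau, beta = beta,
                 seed = as.integer(seed),
                 contrastive_enabled = contrastive_enabled,
                 contrastive_nodes = contrastive_nodes,
                 eval_view = match.arg(eval_view),
                 heads = as.integer(heads), d1 = as.integer(d1),
                 d2 = as.integer(d2), leaky_slope = leaky_slope,
                 activation = activation, directed = directed,
                 log1p_features = log1p_features,
                 mlp_hidden = as.integer(mlp_hidden),
                 d_emb = as.integer(d_emb), bce_mean = bce_mean),
            class = "TrainConfig")
}

# initialise a fresh model (encoder + projection heads) from a TrainConfig
init_model <- function(cfg, n_features, seed) {
  encoder <- encoder_params(n_features, heads = cfg$heads, d1 = cfg$d1,
                            d2 = cfg$d2, leaky_slope = cfg$leaky_slope,
                            activation = cfg$activation,
                            directed = cfg$directed,
                            log1p_features = cfg$log1p_features, seed = seed)
  heads <- projection_heads(cfg$d2, hidden = cfg$mlp_hidden,
                            d_emb = cfg$d_emb, activation = cfg$activation,
                            seed = seed + 1L)
  structure(list(encoder = encoder, heads = heads, cfg = cfg, log = NULL),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cc <- x$encoder$config
  cat(sprintf(
    "grn_model: GAT encoder (%d heads, %d -> %dx%d -> %d) + dual MLP heads (%d -> %d -> %d)\n",
    cc$heads, cc$n_features, cc$heads, cc$d1, cc$d2,
    x$heads$config$d_in, x$heads$config$hidden, x$heads$config$d_emb))
  if (!is.null(x$log)) {
    cat(sprintf("  trained %d epochs; best val AUPRC %s\n", nrow(x$log),
                if (is.null(x$best_val_auprc)) "n/a" else
                  sprintf("%.4f", x$best_val_auprc)))
  }
  invisible(x)
}

# one joint forward/backward pass; returns losses and parameter gradients
train_step <- function(weights, templates, G, views, pairs, cfg,
                       with_contrastive) {
  enc <- templates$encoder; enc$weights <- weights$encoder
  heads <- templates$heads; heads$weights <- weights$heads
  act <- get_activation(heads$config$activation)

  fwd_p <- encoder_forward(enc, G, views$preserved)
  fwd_q <- encoder_forward(enc, G, views$perturbed)
  mlp_p <- mlp_forward(heads$weights$preserved, fwd_p$H2, act)
  mlp_q <- mlp_forward(heads$weights$perturbed, fwd_q$H2, act)

  probs_p <- score_pairs(mlp_p$E, pairs)
  probs_q <- score_pairs(mlp_q$E, pairs)
  lp <- bce_loss(probs_p, pairs, mean_mode = cfg$bce_mean)
  lq <- bce_loss(probs_q, pairs, mean_mode = cfg$bce_mean)

  lc <- 0
  dH2_con_p <- dH2_con_q <- NULL
  if (with_contrastive) {
    nodes <- if (cfg$contrastive_nodes == "incident") {
      incident_nodes(views$preserved)
    } else {
      seq_len(views$preserved$num_nodes)
    }
    iv <- inter_view_loss(fwd_p$H2, fwd_q$H2,
                          contrastive_config(tau = cfg$tau),
                          nodes = nodes, grad = TRUE)
    lc <- iv$loss
    dH2_con_p <- cfg$beta * iv$dh
    dH2_con_q <- cfg$beta * iv$dh_hat
  }
  bundle <- total_loss(lp, lq, lc, beta = cfg$beta)

  dE_p <- bce_backward(mlp_p$E, pairs, mean_mode = cfg$bce_mean)
  dE_q <- bce_backward(mlp_q$E, pairs, mean_mode = cfg$bce_mean)
  back_p <- mlp_backward(heads$weights$preserved, fwd_p$H2, mlp_p, dE_p, act)
  back_q <- mlp_backward(heads$weights$perturbed, fwd_q$H2, mlp_q, dE_q, act)
  dH2_p <- back_p$dX
  dH2_q <- back_q$dX
  if (!is.null(dH2_con_p)) {
    dH2_p <- dH2_p + dH2_con_p
    dH2_q <- dH2_q + dH2_con_q
  }
  g_enc_p <- encoder_backward(enc, fwd_p, dH2_p)
  g_enc_q <- encoder_backward(enc, fwd_q, dH2_q)

  list(bundle = bundle,
       grads = list(encoder = tree_add(g_enc_p, g_enc_q),
                    heads = list(preserved = back_p$grads,
                                 perturbed = back_q$grads)))
}

# deterministic full-adjacency scores used for validation/test/ranking
model_scores <- function(model, G, net, pairs) {
  fwd <- encoder_forward(model$encoder, G, net)
  act <- get_activation(model$heads$config$activation)
  E_p <- mlp_forward(model$heads$weights$preserved, fwd$H2, act)$E
  p <- score_pairs(E_p, pairs)
  if (model$cfg$eval_view == "mean") {
    E_q <- mlp_forward(model$heads$weights$perturbed, fwd$H2, act)$E
    p <- (p + score_pairs(E_q, pairs)) / 2
  }
  p
}

#' Train the contrastive link-prediction model
#'
#' Two-phase optimisation with Adam: a supervised pre-training phase
#' (`pretrain_epochs`) minimising only the dual-view BCE (graph augmentation
#' kept, contrastive term omitted), then `epochs` of the full objective
#' `L_preser + L_pertur + beta * L_con`. A fresh perturbed view is drawn
#' every epoch. After each epoch the validation AUPRC is computed on the
#' un-augmented training adjacency, and the checkpoint with the best
#' validation AUPRC is returned (the final parameters if no usable
#' validation set exists). The run is fully determined by `cfg$seed`.
#'
#' @param split a [split_dataset()] result; only its training pairs and
#'   training adjacency drive optimisation.
#' @param expr companion [expression_matrix()] (node features).
#' @param cfg a [train_config()].
#' @param init optional `grn_model` to continue from (used for fine-tuning);
#'   when given, its architecture must match `cfg`.
#' @return A `grn_model`: encoder and head parameters, the config, a
#'   per-epoch log (`epoch`, `phase`, loss components, `val_auprc`) and the
#'   best validation AUPRC seen.
#' @export
grn_train <- function(split, expr, cfg = train_config(), init = NULL) {
  G <- NULL
  model <- if (is.null(init)) {
    init_model(cfg, ncol(expr$values), cfg$seed)
  } else {
    stopifnot(inherits(init, "grn_model"))
    m <- init; m$cfg <- cfg; m$log <- NULL; m
  }
  G <- prep_features(model$encoder, expr)
  templates <- list(encoder = model$encoder, heads = model$heads)
  weights <- list(encoder = model$encoder$weights,
                  heads = model$heads$weights)
  pairs <- split$train
  adjacency <- split$train_adjacency
  if (nrow(pairs) == 0) stop("training pair set is empty")

  total_epochs <- cfg$pretrain_epochs + cfg$epochs
  has_val <- nrow(split$val) > 0 && length(unique(split$val$label)) == 2
  log <- vector("list", total_epochs)
  best <- list(weights = weights, val = -Inf)

  local_seed(cfg$seed, {
    opt <- adam_init(weights, lr = cfg$learning_rate)
    for (epoch in seq_len(total_epochs)) {
      phase2 <- epoch > cfg$pretrain_epochs
      vseed <- sample.int(.Machine$integer.max - 1L, 1L)
      views <- make_views(adjacency, cfg$removal_prob, seed = vseed)
      step <- train_step(weights, templates, G, views, pairs, cfg,
                         with_contrastive = phase2 && cfg$contrastive_enabled)
      if (!is.finite(step$bundle$total)) {
        stop("non-finite training loss at epoch ", epoch)
      }
      upd <- adam_step(opt, weights, step$grads)
      opt <- upd$state
      weights <- upd$params

      val_auprc <- NA_real_
      if (has_val) {
        m <- model
        m$encoder$weights <- weights$encoder
        m$heads$weights <- weights$heads
        val_auprc <- auprc(model_scores(m, G, adjacency, split$val),
                           split$val$label)
        if (val_auprc > best$val) {
          best <- list(weights = weights, val = val_auprc)
        }
      }
      log[[epoch]] <- data.frame(
        epoch = epoch, phase = if (phase2) "train" else "pretrain",
        L_preser = step$bundle$L_preser, L_pertur = step$bundle$L_pertur,
        L_con = step$bundle$L_con, total = step$bundle$total,
        val_auprc = val_auprc)
    }
  })

  final <- if (has_val && is.finite(best$val)) best$weights else weights
  model$encoder$weights <- final$encoder
  model$heads$weights <- final$heads
  model$cfg <- cfg
  model$log <- if (total_epochs > 0) do.call(rbind, log) else
    data.frame(epoch = integer(0), phase = character(0),
               L_preser = numeric(0), L_pertur = numeric(0),
               L_con = numeric(0), total = numeric(0),
               val_auprc = numeric(0))
  model$best_val_auprc <- if (has_val && is.finite(best$val)) best$val else NULL
  model
}

#' Score arbitrary pairs with a trained model
#'
#' Inference always runs on the un-augmented adjacency (removal disabled):
#' the preserved-view head's probability is the model's prediction (or the
#' mean of both heads when the config says so).
#'
#' @param model a trained `grn_model`.
#' @param expr [expression_matrix()] of node features.
#' @param net adjacency used for message passing (normally the training
#'   adjacency).
#' @param pairs pairs to score.
#' @return Probabilities in (0, 1), one per pair.
#' @export
predict_pairs <- function(model, expr, net, pairs) {
  model_scores(model, prep_features(model$encoder, expr), net, pairs)
}

#' Evaluate a trained model on the test partition
#'
#' @param model a trained `grn_model`.
#' @param split the [split_dataset()] providing the test pairs and training
#'   adjacency.
#' @param expr companion [expression_matrix()].
#' @return An [eval_result()] with test AUROC and AUPRC.
#' @export
evaluate_model <- function(model, split, expr) {
  labels <- split$test$label
  if (length(unique(labels)) < 2) {
    stop("test set must contain both classes")
  }
  scores <- predict_pairs(model, expr, split$train_adjacency, split$test)
  eval_result(auroc(scores, labels), auprc(scores, labels),
              sum(labels == 1), sum(labels == 0))
}

#' Rank candidate regulatory interactions
#'
#' Scores every (TF, gene) pair not present in the supplied edge set
#' (self-pairs excluded) and returns the top `k` by predicted probability,
#' ties broken deterministically by (TF index, gene index).
#'
#' @param model a trained `grn_model`.
#' @param expr companion [expression_matrix()].
#' @param net the known/training edge set; its edges are excluded from the
#'   candidates and it supplies the message-passing topology.
#' @param k number of top pairs to return; if larger than the candidate
#'   count, all candidates are returned.
#' @return A data frame `tf`, `gene` (identifiers), `tf_idx`, `gene_idx`,
#'   `score`, ordered by score descending.
#' @export
rank_predictions <- function(model, expr, net, k = 100L) {
  cand <- negative_candidates(net, expr)
  empty <- data.frame(tf = character(0), gene = character(0),
                      tf_idx = integer(0), gene_idx = integer(0),
                      score = numeric(0))
  if (k <= 0 || nrow(cand) == 0) return(empty)
  pairs <- data.frame(tf = cand[, 1], gene = cand[, 2])
  scores <- predict_pairs(model, expr, net, pairs)
  ord <- order(-scores, pairs$tf, pairs$gene)
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(tf = expr$gene_ids[pairs$tf[top]],
             gene = expr$gene_ids[pairs$gene[top]],
             tf_idx = pairs$tf[top], gene_idx = pairs$gene[top],
             score = scores[top])
}
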