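# Graph convolutional model: stacked GraphConv layers (self term plus
# neighbour sum, each with its own weight matrix) with ReLU and GraphNorm,
# a global readout to a fixed-length graph embedding, and two dense layers
# with either a log-softmax single-label head or a raw-score multi-label
# head. Forward, backward and the optimizer are implemented here with BLAS
# matrix products and sparse adjacency operators.

# rowsum with group names stripped (groups are 1..ng in order)
.rowsum0 <- function(x, g) {
  r <- rowsum(x, g)
  rownames(r) <- NULL
  r
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.contract_violation <- function(msg) {
  stop(structure(
    class = c("meshgcn_contract_violation", "error", "condition"),
    list(message = msg, call = NULL)))
}

#' One GraphConv layer
#'
#' Computes, for every node v, `activation(x_v W1 + sum_{u in N(v)} x_u W2 +
#' bias)`: the node's own features through `W1` plus the sum of its graph
#' neighbours' features through `W2`. Nodes without neighbours receive only
#' the self term. Bond features are not consumed by this aggregation.
#'
#' @param node_features Numeric matrix (n_nodes x F_in).
#' @param edge_index 2-column integer matrix of directed edges (1-based),
#'   each undirected bond present in both directions; or a precomputed
#'   sparse adjacency matrix.
#' @param params List with `W1`, `W2` (F_in x F_out) and `bias` (length
#'   F_out).
#' @param activation Function applied elementwise; default ReLU.
#' @return Matrix (n_nodes x F_out).
#' @export
graph_conv <- function(node_features, edge_index, params,
                       activation = .relu) {
  X <- as.matrix(node_features)
  if (ncol(X) != nrow(params$W1) || !all(dim(params$W1) == dim(params$W2))) {
    .contract_violation("graph_conv: feature width does not match W1/W2")
  }
  A <- if (inherits(edge_index, "Matrix")) edge_index else {
    ei <- edge_index
    if (is.null(dim(ei))) ei <- matrix(ei, ncol = 2)
    if (nrow(ei) > 0 && max(ei) > nrow(X)) {
      .contract_violation("graph_conv: edge index out of range")
    }
    n <- nrow(X)
    if (nrow(ei) == 0) {
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(n, n))
    } else {
      Matrix::sparseMatrix(i = ei[, 1], j = ei[, 2], x = 1, dims = c(n, n))
    }
  }
  Z <- X %*% params$W1 + as.matrix(A %*% X) %*% params$W2
  Z <- sweep(Z, 2, params$bias, "+")
  activation(Z)
}

#' GraphNorm: per-graph feature normalization with a learnable mean gate
#'
#' For each graph g in the batch and feature f:
#' `out = gamma * (h - alpha * mean_g(h)) / sqrt(mean_g((h - alpha *
#' mean_g(h))^2) + eps) + beta`. Statistics never mix nodes of different
#' graphs; `alpha` gates how much of the per-graph mean is subtracted.
#'
#' @param node_features Matrix (n_nodes x F).
#' @param graph_membership Integer vector assigning every node to a graph.
#' @param params List with vectors `alpha`, `gamma`, `beta` (length F) and
#'   scalar `epsilon`.
#' @return Matrix of the same shape.
#' @export
graph_norm <- function(node_features, graph_membership, params) {
  H <- as.matrix(node_features)
  m <- as.integer(graph_membership)
  if (length(m) != nrow(H)) {
    .contract_violation("graph_norm: membership length != n_nodes")
  }
  ng <- max(m)
  cnt <- tabulate(m, ng)
  if (any(cnt == 0)) .contract_violation("graph_norm: empty graph in batch")
  mu <- .rowsum0(H, m) / cnt                     # ng x F
  D <- H - (mu[m, , drop = FALSE] *
              matrix(params$alpha, nrow(H), ncol(H), byrow = TRUE))
  s2 <- .rowsum0(D * D, m) / cnt
  sd_ <- sqrt(s2 + params$epsilon)
  Xhat <- D / sd_[m, , drop = FALSE]
  sweep(Xhat * matrix(params$gamma, nrow(H), ncol(H), byrow = TRUE),
        2, params$beta, "+")
}

#' Global pooling readout
#'
#' Aggregates node features into one row per graph.
#'
#' @param node_features Matrix (n_nodes x F).
#' @param graph_membership Integer node-to-graph assignment.
#' @param mode `"sum"` (default), `"mean"`, or `"max"`.
#' @return Matrix (n_graphs x F).
#' @export
global_pool <- function(node_features, graph_membership,
                        mode = c("sum", "mean", "max")) {
  mode <- match.arg(mode)
  H <- as.matrix(node_features)
  m <- as.integer(graph_membership)
  ng <- max(m)
  switch(mode,
    sum  = .rowsum0(H, m),
    mean = .rowsum0(H, m) / tabulate(m, ng),
    max  = {
      out <- matrix(-Inf, ng, ncol(H))
      for (g in seq_len(ng)) {
        out[g, ] <- apply(H[m == g, , drop = FALSE], 2, max)
      }
      out
    })
}

# ---------------------------------------------------------------------------
# model construction

#' Initialize a GCN classification model
#'
#' Builds the layer stack: `n_conv` GraphConv+ReLU+GraphNorm blocks whose
#' final width is the graph embedding length (1024 by default), a readout,
#' dense layer FC1 with ReLU and dropout, and dense layer FC2 with 3, 5 or
#' 12 outputs. Weights use a uniform fan-in initialization driven by `seed`.
#' GraphNorm starts with the learnable mean gate closed (`alpha = 0`,
#' `gamma = 1`, `beta = 0`): a fully open gate would make every per-graph
#' feature sum exactly zero, leaving the sum readout blind at
#' initialization.
#'
#' @param n_features Input atom-feature width.
#' @param n_outputs Number of classes (3, 5 or 12).
#' @param head `"log-softmax"` for single-label tasks or
#'   `"sigmoid-multilabel"` for the multi-label task.
#' @param conv_widths Widths of the GraphConv layers; the last entry is the
#'   graph embedding length.
#' @param fc1_width Width of the first dense layer.
#' @param dropout_rate Dropout probability applied after FC1 in training
#'   mode.
#' @param readout_mode Readout aggregation, see [global_pool()].
#' @param seed Integer seed for weight initialization.
#' @return A `gcn_model` object.
#' @export
gcn_model <- function(n_features, n_outputs,
                      head = c("log-softmax", "sigmoid-multilabel"),
                      conv_widths = c(256, 512, 1024),
                      fc1_width = 512, dropout_rate = 0.4,
                      readout_mode = "sum", seed = 0L) {
  head <- match.arg(head)
  stopifnot(n_outputs >= 2, length(conv_widths) >= 1)
  model <- .with_seed(seed, {
    uinit <- function(fin, fout) {
      b <- 1 / sqrt(fin)
      matrix(stats::runif(fin * fout, -b, b), fin, fout)
    }
    widths <- c(n_features, conv_widths)
    conv_layers <- lapply(seq_along(conv_widths), function(t) {
      list(
        conv = list(W1 = uinit(widths[t], widths[t + 1]),
                    W2 = uinit(widths[t], widths[t + 1]),
                    bias = numeric(widths[t + 1])),
        norm = list(alpha = rep(0, widths[t + 1]),
                    gamma = rep(1, widths[t + 1]),
                    beta = rep(0, widths[t + 1]),
                    epsilon = 1e-5)
      )
    })
    latent <- conv_widths[length(conv_widths)]
    list(conv_layers = conv_layers,
         fc1 = list(W = uinit(latent, fc1_width), b = numeric(fc1_width)),
         fc2 = list(W = uinit(fc1_width, n_outputs), b = numeric(n_outputs)))
  })
  structure(c(model, list(
    n_features = n_features, n_outputs = n_outputs, head = head,
    conv_widths = conv_widths, fc1_width = fc1_width,
    dropout_rate = dropout_rate, readout_mode = readout_mode,
    seed = as.integer(seed))), class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf(
    "<gcn_model> %d -> [%s] conv, FC1 %d, FC2 %d outputs, head %s\n",
    x$n_features, paste(x$conv_widths, collapse = ", "),
    x$fc1_width, x$n_outputs, x$head))
  invisible(x)
}

# run RNG-dependent code under a seed, restoring global RNG state afterwards
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# ---------------------------------------------------------------------------
# forward / backward

.log_softmax <- function(S) {
  mx <- apply(S, 1, max)
  Z <- S - mx
  Z - log(rowSums(exp(Z)))
}

# Forward pass over a prebuilt batch (see .batch_graphs). Returns scores,
# FC1 latents and, when keep_cache, all intermediates needed for backprop.
.forward_batch <- function(model, batch, training_mode = FALSE,
                           dropout_mask = NULL, keep_cache = FALSE) {
  X <- batch$X
  if (ncol(X) != model$n_features) {
    .contract_violation("forward: node feature width does not match model")
  }
  A <- batch$A
  m <- batch$membership
  cache <- list(layers = list())
  H <- X
  for (t in seq_along(model$conv_layers)) {
    ly <- model$conv_layers[[t]]
    AX <- as.matrix(A %*% H)
    Z <- H %*% ly$conv$W1 + AX %*% ly$conv$W2
    Z <- sweep(Z, 2, ly$conv$bias, "+")
    R <- .relu(Z)
    ng <- batch$n_graphs
    cnt <- batch$n_nodes
    mu <- .rowsum0(R, m) / cnt
    D <- R - mu[m, , drop = FALSE] *
      matrix(ly$norm$alpha, nrow(R), ncol(R), byrow = TRUE)
    s2 <- .rowsum0(D * D, m) / cnt
    sd_ <- sqrt(s2 + ly$norm$epsilon)
    Xhat <- D / sd_[m, , drop = FALSE]
    Hn <- Xhat * matrix(ly$norm$gamma, nrow(R), ncol(R), byrow = TRUE)
    Hn <- sweep(Hn, 2, ly$norm$beta, "+")
    if (keep_cache) {
      cache$layers[[t]] <- list(H_in = H, AX = AX, Z = Z, R = R, mu = mu,
                                Xhat = Xhat, sd = sd_)
    }
    H <- Hn
  }
  L <- global_pool(H, m, model$readout_mode)       # n_graphs x latent
  Z1 <- sweep(L %*% model$fc1$W, 2, model$fc1$b, "+")
  H1 <- .relu(Z1)
  H1d <- H1
  if (training_mode && model$dropout_rate > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(
        stats::runif(length(H1)) >= model$dropout_rate,
        nrow(H1), ncol(H1)) * 1
    }
    H1d <- H1 * dropout_mask / (1 - model$dropout_rate)
  }
  S <- sweep(H1d %*% model$fc2$W, 2, model$fc2$b, "+")
  scores <- if (model$head == "log-softmax") .log_softmax(S) else S
  if (keep_cache) {
    cache$H_last <- H; cache$L <- L; cache$Z1 <- Z1; cache$H1 <- H1
    cache$H1d <- H1d; cache$dropout_mask <- dropout_mask; cache$S <- S
  }
  list(scores = scores, latents_fc1 = H1, latents_readout = L,
       cache = cache)
}

#' Forward pass of the model over molecular graphs
#'
#' Applies the GraphConv/ReLU/GraphNorm stack, the readout, FC1 (with
#' dropout in training mode) and FC2. The single-label head returns
#' log-softmax rows (each row exponentiates to a probability vector); the
#' multi-label head returns raw scores. FC1 activations are returned for
#' embedding diagnostics.
#'
#' @param model A [gcn_model()].
#' @param graphs List of `molecular_graph` objects (or a prebuilt batch).
#' @param training_mode Logical; enables dropout.
#' @return List with `scores` (n_graphs x n_outputs), `latents_fc1` (the
#'   FC1 activations) and `latents_readout` (the pooled graph embedding,
#'   1024-length under the default widths) — both latent readings are
#'   exposed for embedding diagnostics.
#' @export
gcn_forward <- function(model, graphs, training_mode = FALSE) {
  batch <- if (is.list(graphs) && !is.null(graphs$A)) graphs else
    .batch_graphs(if (inherits(graphs, "molecular_graph")) list(graphs)
                  else graphs)
  out <- .forward_batch(model, batch, training_mode = training_mode)
  list(scores = out$scores, latents_fc1 = out$latents_fc1,
       latents_readout = out$latents_readout)
}

# Backward pass: grad of mean loss wrt every parameter. g_S is the gradient
# at the FC2 pre-activation scores.
.backward_batch <- function(model, batch, cache, g_S) {
  grads <- list()
  p <- model$dropout_rate
  g_H1d <- g_S %*% t(model$fc2$W)
  grads$fc2 <- list(W = t(cache$H1d) %*% g_S, b = colSums(g_S))
  if (!is.null(cache$dropout_mask)) {
    g_H1 <- g_H1d * cache$dropout_mask / (1 - p)
  } else {
    g_H1 <- g_H1d
  }
  g_Z1 <- g_H1 * (cache$Z1 > 0)
  grads$fc1 <- list(W = t(cache$L) %*% g_Z1, b = colSums(g_Z1))
  g_L <- g_Z1 %*% t(model$fc1$W)
  # readout backward (sum pooling)
  if (!identical(model$readout_mode, "sum")) {
    .contract_violation("training supports the sum readout")
  }
  m <- batch$membership
  g_H <- g_L[m, , drop = FALSE]
  grads$conv_layers <- vector("list", length(model$conv_layers))
  for (t in rev(seq_along(model$conv_layers))) {
    ly <- model$conv_layers[[t]]
    cc <- cache$layers[[t]]
    cnt <- batch$n_nodes
    gamma <- matrix(ly$norm$gamma, nrow(g_H), ncol(g_H), byrow = TRUE)
    g_beta <- colSums(g_H)
    g_gamma <- colSums(g_H * cc$Xhat)
    g_Xhat <- g_H * gamma
    # through x_hat = D / sd with sd^2 = mean_g(D^2) + eps
    mean_gx <- .rowsum0(g_Xhat * cc$Xhat, m) / cnt
    g_D <- (g_Xhat - cc$Xhat * mean_gx[m, , drop = FALSE]) /
      cc$sd[m, , drop = FALSE]
    # D = R - alpha * mu_g(R)
    sum_gD <- .rowsum0(g_D, m)
    alpha <- ly$norm$alpha
    g_alpha <- -colSums(cc$mu * sum_gD)
    g_R <- g_D - (sum_gD / cnt)[m, , drop = FALSE] *
      matrix(alpha, nrow(g_D), ncol(g_D), byrow = TRUE)
    g_Z <- g_R * (cc$Z > 0)
    g_W1 <- t(cc$H_in) %*% g_Z
    g_W2 <- t(cc$AX) %*% g_Z
    g_b <- colSums(g_Z)
    g_H <- g_Z %*% t(ly$conv$W1) +
      as.matrix(batch$A %*% (g_Z %*% t(ly$conv$W2)))
    grads$conv_layers[[t]] <- list(
      conv = list(W1 = g_W1, W2 = g_W2, bias = g_b),
      norm = list(alpha = g_alpha, gamma = g_gamma, beta = g_beta))
  }
  grads
}

# ---------------------------------------------------------------------------
# losses

#' Weighted negative log likelihood loss
#'
#' `sum_i w[y_i] * (-log_prob_i[y_i]) / sum_i w[y_i]` — the standard
#' weighted-mean convention for class-weighted NLL.
#'
#' @param log_probs Matrix of row log-probabilities (n x C).
#' @param targets Integer class indices, 0-based or 1-based (0-based codes
#'   are detected by the presence of a 0).
#' @param class_weights Optional positive weight per class (length C);
#'   defaults to unit weights.
#' @return Scalar loss (attribute `grad` carries d loss / d log_probs for
#'   internal use).
#' @export
nll_loss <- function(log_probs, targets, class_weights = NULL) {
  C <- ncol(log_probs)
  t1 <- .as_one_based(targets, C)
  if (any(t1 < 1 | t1 > C)) .contract_violation("nll_loss: target out of range")
  w <- if (is.null(class_weights)) rep(1, C) else class_weights
  if (length(w) != C) .contract_violation("nll_loss: weight length != classes")
  wi <- w[t1]
  picked <- log_probs[cbind(seq_len(nrow(log_probs)), t1)]
  loss <- sum(wi * (-picked)) / sum(wi)
  g <- matrix(0, nrow(log_probs), C)
  g[cbind(seq_len(nrow(log_probs)), t1)] <- -wi / sum(wi)
  attr(loss, "grad") <- g
  loss
}

.as_one_based <- function(targets, C) {
  t <- as.integer(targets)
  if (any(t == 0L) || (length(t) > 0 && max(t) == C - 1L && min(t) >= 0L)) {
    t + 1L
  } else t
}

#' Multi-label soft margin loss
#'
#' Mean over samples of the per-class binary cross entropy on sigmoid-
#' transformed scores: `-(1/C) * sum_c [y_c log sigma(x_c) + (1 - y_c)
#' log(1 - sigma(x_c))]`.
#'
#' @param scores Raw score matrix (n x C).
#' @param target_binary 0/1 matrix of the same shape.
#' @return Scalar loss (attribute `grad` carries d loss / d scores).
#' @export
multilabel_soft_margin_loss <- function(scores, target_binary) {
  Y <- as.matrix(target_binary)
  if (!all(Y %in% c(0, 1))) {
    .contract_violation("multilabel_soft_margin_loss: non-binary target")
  }
  if (!all(dim(Y) == dim(scores))) {
    .contract_violation("multilabel_soft_margin_loss: shape mismatch")
  }
  S <- as.matrix(scores)
  # numerically stable BCE-with-logits
  loss_el <- pmax(S, 0) - S * Y + log1p(exp(-abs(S)))
  loss <- mean(rowMeans(loss_el))
  sig <- 1 / (1 + exp(-S))
  attr(loss, "grad") <- (sig - Y) / (nrow(Y) * ncol(Y))
  loss
}

#' Predict classes for molecular graphs
#'
#' Single-label tasks return the argmax class per graph (0-based codes);
#' the multi-label task returns, per graph, the set of classes whose
#' sigmoid-transformed score exceeds `threshold` (an empty set is allowed).
#'
#' @param object A trained [gcn_model()].
#' @param graphs List of `molecular_graph` objects.
#' @param threshold Multi-label score threshold on the probability scale.
#' @param ... Unused.
#' @return For single-label: integer vector of 0-based class codes with the
#'   score matrix as attribute `scores`. For multi-label: a 0/1 matrix
#'   (n_graphs x n_outputs) with attribute `scores`.
#' @export
predict.gcn_model <- function(object, graphs, threshold = 0.5, ...) {
  out <- gcn_forward(object, graphs, training_mode = FALSE)
  if (object$head == "log-softmax") {
    pred <- max.col(out$scores, ties.method = "first") - 1L
    attr(pred, "scores") <- out$scores
    pred
  } else {
    prob <- 1 / (1 + exp(-out$scores))
    pred <- (prob > threshold) * 1
    attr(pred, "scores") <- out$scores
    pred
  }
}

# ---------------------------------------------------------------------------
# checkpointing

#' Save a model checkpoint
#'
#' Writes a versioned binary checkpoint containing the model parameters,
#' architecture and any attached metadata. Round-trips bit-exactly through
#' [load_gcn_model()].
#'
#' @param model A `gcn_model`.
#' @param path File path.
#' @param metadata Optional list (task kind, label space, training seed,
#'   resolved config ...) stored alongside the parameters.
#' @return `path`, invisibly.
#' @export
save_gcn_model <- function(model, path, metadata = list()) {
  obj <- list(format = "meshgcn-checkpoint", version = 1L,
              model = model, metadata = metadata)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_gcn_model()].
#' @return List with `model` and `metadata`.
#' @export
load_gcn_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "meshgcn-checkpoint")) {
    stop("not a meshgcn checkpoint: ", path)
  }
  obj[c("model", "metadata")]
}
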