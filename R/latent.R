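# Embedding diagnostics: FC1 latent vectors from a trained model, the
# all-ones "dummy" baseline embedding of the untrained architecture, and a
# pluggable 2D projection for cluster inspection.

#' Extract latent drug embeddings
#'
#' Runs each graph through the model with dropout disabled and returns a
#' latent vector per drug: by default the activations of the first dense
#' layer (FC1), or alternatively the pooled graph embedding produced by
#' the readout (1024-length under the default widths).
#'
#' @param model A trained [gcn_model()].
#' @param graphs List of `molecular_graph` objects.
#' @param layer `"fc1"` (default) or `"readout"`.
#' @return An `embedding_matrix`: list with `ids`, `vectors`, `source`.
#' @export
extract_latents <- function(model, graphs, layer = c("fc1", "readout")) {
  layer <- match.arg(layer)
  out <- gcn_forward(model, graphs, training_mode = FALSE)
  structure(list(
    ids = vapply(graphs, function(g) as.character(g$id), character(1)),
    vectors = if (layer == "fc1") out$latents_fc1 else out$latents_readout,
    source = layer), class = "embedding_matrix")
}

#' Baseline embedding from an all-ones model
#'
#' Forward pass of the untrained architecture with every GraphConv and
#' dense weight set to 1 and biases 0; GraphNorm is set to the identity
#' (`gamma = 1`, `beta = 0`, `alpha = 0`) because per-graph statistics of a
#' constant-weight network are degenerate. This shows the distribution of
#' the raw (pre-training) graph signal.
#'
#' @param graphs List of `molecular_graph` objects.
#' @param schema The [feature_schema()] the graphs were built with.
#' @param conv_widths,fc1_width Architecture widths (defaults as in
#'   [gcn_model()]).
#' @return An `embedding_matrix` with `source = "dummy"`.
#' @export
dummy_embedding <- function(graphs, schema = feature_schema(),
                            conv_widths = c(256, 512, 1024),
                            fc1_width = 512) {
  model <- gcn_model(schema$atom_width, n_outputs = 2,
                     conv_widths = conv_widths, fc1_width = fc1_width,
                     dropout_rate = 0, seed = 0L)
  for (t in seq_along(model$conv_layers)) {
    d <- dim(model$conv_layers[[t]]$conv$W1)
    model$conv_layers[[t]]$conv$W1 <- matrix(1, d[1], d[2])
    model$conv_layers[[t]]$conv$W2 <- matrix(1, d[1], d[2])
    model$conv_layers[[t]]$conv$bias <- numeric(d[2])
    model$conv_layers[[t]]$norm$alpha <- rep(0, d[2])
    model$conv_layers[[t]]$norm$gamma <- rep(1, d[2])
    model$conv_layers[[t]]$norm$beta <- rep(0, d[2])
  }
  model$fc1$W <- matrix(1, nrow(model$fc1$W), ncol(model$fc1$W))
  model$fc1$b <- numeric(ncol(model$fc1$W))
  out <- gcn_forward(model, graphs, training_mode = FALSE)
  structure(list(
    ids = vapply(graphs, function(g) as.character(g$id), character(1)),
    vectors = out$latents_fc1,
    source = "dummy"), class = "embedding_matrix")
}

#' Project an embedding to 2D
#'
#' Reduces an embedding matrix to two dimensions with a pluggable
#' projector. The default is nonmetric multidimensional scaling on
#' Euclidean distances started from a principal-coordinates configuration;
#' `"pca"` gives the first two principal components. Both are deterministic
#' given `seed`.
#'
#' @param embedding An `embedding_matrix` (or plain numeric matrix).
#' @param seed Integer seed.
#' @param method `"nmds"` (default) or `"pca"`, or a function
#'   `(matrix, seed) -> n x 2 matrix` supplying a custom projector.
#' @return Matrix (n x 2) with the ids as row names.
#' @export
project_2d <- function(embedding, seed = 0L, method = c("nmds", "pca")) {
  X <- if (inherits(embedding, "embedding_matrix")) embedding$vectors else
    as.matrix(embedding)
  ids <- if (inherits(embedding, "embedding_matrix")) embedding$ids else
    rownames(X)
  if (nrow(X) < 4) stop("project_2d: need at least 4 points")
  if (is.function(method)) {
    Y <- method(X, seed)
  } else {
    method <- match.arg(method)
    Y <- .with_seed(seed, {
      if (method == "pca") {
        keep <- which(apply(X, 2, stats::sd) > 0)
        if (length(keep) < 2) keep <- seq_len(ncol(X))
        stats::prcomp(X[, keep, drop = FALSE], center = TRUE,
                      scale. = FALSE)$x[, 1:2, drop = FALSE]
      } else {
        # jitter duplicated points minutely so the distance matrix has no
        # exact zeros off-diagonal (NMDS requirement)
        d <- stats::dist(X)
        if (any(d < 1e-12)) {
          X <- X + matrix(stats::rnorm(length(X), sd = 1e-8),
                          nrow(X), ncol(X))
          d <- stats::dist(X)
        }
        fit <- vegan::monoMDS(d, k = 2, model = "global")
        fit$points[, 1:2, drop = FALSE]
      }
    })
  }
  Y <- as.matrix(Y)[, 1:2, drop = FALSE]
  colnames(Y) <- c("dim1", "dim2")
  if (!is.null(ids)) rownames(Y) <- ids
  Y
}

#' Write an embedding or projection as TSV
#'
#' @param embedding An `embedding_matrix` or projected matrix.
#' @param path Output path (`id`, dims..., optional `label`).
#' @param labels Optional per-row labels.
#' @return `path`, invisibly.
#' @export
write_embedding_tsv <- function(embedding, path, labels = NULL) {
  X <- if (inherits(embedding, "embedding_matrix")) embedding$vectors else
    as.matrix(embedding)
  ids <- if (inherits(embedding, "embedding_matrix")) embedding$ids else
    rownames(X)
  df <- data.frame(id = if (is.null(ids)) seq_len(nrow(X)) else ids,
                   X, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- labels
  write_tsv(df, path)
}
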