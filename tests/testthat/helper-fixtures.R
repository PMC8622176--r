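# Shared fixtures: tiny graph datasets and random graphs for oracle tests.

test_schema <- feature_schema()

# small featurized dataset (cached per test run)
.fixture_cache <- new.env(parent = emptyenv())

tiny_dataset <- function(n_per_class = 4, n_classes = 3, seed = 3,
                         salt_fraction = 0) {
  key <- paste(n_per_class, n_classes, seed, salt_fraction, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    recs <- generate_single_label(fixture_spec(
      n_per_class = n_per_class, n_classes = n_classes,
      salt_fraction = salt_fraction, seed = seed))
    .fixture_cache[[key]] <- filter_and_dedup(recs, test_schema)$dataset
  }
  .fixture_cache[[key]]
}

# random small attributed graph for layer-math oracles: symmetric edge
# list + feature matrix
random_graph <- function(n_nodes, n_feat) {
  X <- matrix(stats::rnorm(n_nodes * n_feat), n_nodes, n_feat)
  A <- matrix(0, n_nodes, n_nodes)
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq(i + 1, n_nodes)) {
      if (stats::runif(1) < 0.5) A[i, j] <- A[j, i] <- 1
    }
  }
  ei <- which(A == 1, arr.ind = TRUE)
  list(X = X, A = A, edge_index = unname(ei))
}

# dense-adjacency oracle for the GraphConv layer
dense_conv_oracle <- function(X, A, W1, W2, bias, act = function(z) pmax(z, 0)) {
  Z <- X %*% W1 + A %*% X %*% W2
  act(sweep(Z, 2, bias, "+"))
}

# wrap a feature matrix + adjacency as a molecular_graph-like object for
# model-level tests
as_graph_obj <- function(id, X, edge_index, labels = 0L) {
  structure(list(id = id, smiles_canonical = NA_character_,
                 node_features = X, edge_index = edge_index,
                 edge_features = matrix(0, nrow(edge_index), 1),
                 labels = labels, n_nodes = nrow(X)),
            class = "molecular_graph")
}
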