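test_that("graph_conv matches its closed-form examples", {
  # pure neighbour exchange on a two-node path
  p <- list(W1 = matrix(0, 1, 1), W2 = matrix(1, 1, 1), bias = 0)
  out <- graph_conv(matrix(c(1, 2), 2, 1), rbind(c(1, 2), c(2, 1)), p,
                    activation = identity)
  expect_equal(as.numeric(out), c(2, 1))

  # identity configuration leaves input unchanged
  X <- matrix(rnorm(12), 4, 3)
  ei <- rbind(c(1, 2), c(2, 1), c(3, 4), c(4, 3))
  pid <- list(W1 = diag(3), W2 = matrix(0, 3, 3), bias = rep(0, 3))
  expect_equal(graph_conv(X, ei, pid, identity), X)

  # triangle with ReLU
  p2 <- list(W1 = matrix(2, 1, 1), W2 = matrix(1, 1, 1), bias = 0)
  tri <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  expect_equal(as.numeric(graph_conv(matrix(1:3, 3, 1), tri, p2)),
               c(7, 8, 9))

  expect_error(graph_conv(X, ei, p, identity),
               class = "meshgcn_contract_violation")
})

test_that("graph_conv agrees with the dense-adjacency oracle on random graphs", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    f_in <- sample(1:5, 1)
    f_out <- sample(1:5, 1)
    g <- random_graph(n, f_in)
    W1 <- matrix(rnorm(f_in * f_out), f_in, f_out)
    W2 <- matrix(rnorm(f_in * f_out), f_in, f_out)
    b <- rnorm(f_out)
    got <- graph_conv(g$X, g$edge_index, list(W1 = W1, W2 = W2, bias = b))
    want <- dense_conv_oracle(g$X, g$A, W1, W2, b)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("graph_norm follows the gated normalization formula per graph", {
  gn <- list(alpha = 1, gamma = 1, beta = 0, epsilon = 1e-5)
  out <- graph_norm(matrix(c(-1, 1), 2, 1), c(1, 1), gn)
  expect_equal(as.numeric(out), c(-1, 1), tolerance = 1e-4)

  # single-node graph: zero-variance case guarded by epsilon -> beta
  gn2 <- list(alpha = 1, gamma = 2, beta = 0.7, epsilon = 1e-5)
  out2 <- graph_norm(matrix(5, 1, 1), 1L, gn2)
  expect_equal(as.numeric(out2), 0.7)

  # batch independence: two identical graphs normalize identically
  H <- matrix(rnorm(8), 4, 2)
  gn3 <- list(alpha = rep(0.5, 2), gamma = c(1, 2), beta = c(0, 1),
              epsilon = 1e-5)
  single <- graph_norm(H, rep(1, 4), gn3)
  batch <- graph_norm(rbind(H, H), rep(c(1, 2), each = 4), gn3)
  expect_equal(batch[1:4, ], single)
  expect_equal(batch[5:8, ], single)

  expect_error(graph_norm(H, c(1, 1, 3, 3), gn3),
               class = "meshgcn_contract_violation")
})

test_that("global_pool aggregates per graph in all modes", {
  X <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(as.numeric(global_pool(X, c(1, 1, 1), "sum")), 6)
  expect_equal(as.numeric(global_pool(X, c(1, 1, 1), "mean")), 2)
  expect_equal(as.numeric(global_pool(X, c(1, 1, 1), "max")), 3)
  # interleaved batch equals pooling each graph alone
  set.seed(1)
  X2 <- matrix(rnorm(12), 6, 2)
  mem <- c(1, 2, 1, 2, 1, 2)
  for (mode in c("sum", "mean", "max")) {
    got <- global_pool(X2, mem, mode)
    for (g in 1:2) {
      alone <- global_pool(X2[mem == g, , drop = FALSE],
                           rep(1, sum(mem == g)), mode)
      expect_equal(got[g, , drop = FALSE], alone)
    }
  }
  expect_error(global_pool(X, c(1, 1, 1), "median"))
})

test_that("forward produces valid log-probabilities and is deterministic", {
  ds <- tiny_dataset()
  model <- gcn_model(test_schema$atom_width, 3, conv_widths = c(8, 16),
                     fc1_width = 8, seed = 5)
  out1 <- gcn_forward(model, ds)
  out2 <- gcn_forward(model, ds)
  expect_identical(out1, out2)
  expect_equal(rowSums(exp(out1$scores)), rep(1, length(ds)))
  expect_equal(dim(out1$latents_fc1), c(length(ds), 8))
})

test_that("graph-level scores are invariant to node permutation and batching", {
  set.seed(9)
  model <- gcn_model(4, 3, conv_widths = c(6, 8), fc1_width = 5, seed = 2)
  for (i in 1:10) {
    g <- random_graph(sample(3:7, 1), 4)
    obj <- as_graph_obj("g", g$X, g$edge_index)
    s1 <- gcn_forward(model, list(obj))$scores
    # permuted copy
    perm <- sample(nrow(g$X))
    inv <- order(perm)
    ei_p <- cbind(inv[g$edge_index[, 1]], inv[g$edge_index[, 2]])
    obj_p <- as_graph_obj("gp", g$X[perm, , drop = FALSE], ei_p)
    s2 <- gcn_forward(model, list(obj_p))$scores
    expect_equal(s1, s2, tolerance = 1e-12)
    # batch invariance
    other <- random_graph(4, 4)
    batch <- gcn_forward(model, list(obj, as_graph_obj("o", other$X,
                                                       other$edge_index)))
    expect_equal(batch$scores[1, , drop = FALSE], s1, tolerance = 1e-12)
  }
})

test_that("with W2 = 0 the model sees only the multiset of node features", {
  model <- gcn_model(3, 2, conv_widths = c(5, 6), fc1_width = 4, seed = 3)
  for (t in seq_along(model$conv_layers)) {
    model$conv_layers[[t]]$conv$W2 <- model$conv_layers[[t]]$conv$W2 * 0
  }
  set.seed(2)
  X <- matrix(rnorm(12), 4, 3)
  path <- rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(3, 4), c(4, 3))
  star <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(1, 4), c(4, 1))
  s_path <- gcn_forward(model, list(as_graph_obj("p", X, path)))$scores
  s_star <- gcn_forward(model, list(as_graph_obj("s", X, star)))$scores
  expect_equal(s_path, s_star)
})

test_that("losses match their analytic values", {
  # uniform 3-class prediction -> log 3
  lp <- log(matrix(1 / 3, 2, 3))
  expect_equal(as.numeric(nll_loss(lp, c(0, 1))), log(3))
  # perfect prediction -> 0
  perfect <- matrix(c(0, -50, -50), 1, 3)
  expect_equal(as.numeric(nll_loss(perfect, 0L)), 0)
  # weighted mean convention: weights (2,1), losses (a,b) -> (2a+b)/3
  a <- 0.7; b <- 1.3
  lp2 <- rbind(c(-a, log1p(-exp(-a))), c(log1p(-exp(-b)), -b))
  expect_equal(as.numeric(nll_loss(lp2, c(0, 1), c(2, 1))),
               (2 * a + b) / 3)
  expect_error(nll_loss(lp, c(0, 5)), class = "meshgcn_contract_violation")

  expect_equal(as.numeric(multilabel_soft_margin_loss(
    matrix(0, 2, 3), matrix(c(1, 0, 1, 1, 0, 0), 2, 3))), log(2))
  expect_equal(as.numeric(multilabel_soft_margin_loss(
    matrix(c(100, -100), 1, 2), matrix(c(1, 0), 1, 2))), 0,
    tolerance = 1e-12)
  expect_equal(as.numeric(multilabel_soft_margin_loss(
    matrix(c(1, -1), 1, 2), matrix(c(1, 0), 1, 2))), 0.3132617,
    tolerance = 1e-6)
  expect_error(multilabel_soft_margin_loss(matrix(0, 1, 2),
                                           matrix(c(1, 2), 1, 2)),
               class = "meshgcn_contract_violation")
})

test_that("prediction follows argmax / thresholded sigmoid", {
  ds <- tiny_dataset()[1:2]
  m_single <- gcn_model(test_schema$atom_width, 3, conv_widths = c(4),
                        fc1_width = 3, seed = 1)
  # direct score-level checks
  expect_equal(max.col(matrix(c(-0.1, -3, -4), 1, 3)) - 1L, 0L)
  prob <- 1 / (1 + exp(-c(2, -2, 0.1)))
  expect_equal(which(prob > 0.5), c(1, 3))
  p1 <- predict(m_single, ds)
  expect_true(all(p1 %in% 0:2))
  m_multi <- gcn_model(test_schema$atom_width, 3, conv_widths = c(4),
                       fc1_width = 3, head = "sigmoid-multilabel", seed = 1)
  p2 <- predict(m_multi, ds)
  expect_true(all(p2 %in% c(0, 1)))
  expect_equal(dim(p2), c(2, 3))
})

test_that("checkpoints round-trip bit-exactly", {
  model <- gcn_model(7, 3, conv_widths = c(4, 6), fc1_width = 5, seed = 8)
  path <- tempfile(fileext = ".rds")
  save_gcn_model(model, path, metadata = list(task = "task3", seed = 8))
  back <- load_gcn_model(path)
  expect_identical(back$model, model)
  expect_identical(back$metadata$task, "task3")
  suppressWarnings(
    expect_error(load_gcn_model(tempfile()), "cannot open|not a meshgcn"))
})
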