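test_that("class weights are normalized inverse frequencies", {
  expect_equal(as.numeric(class_weights(c(5, 5, 5))), rep(1 / 3, 3))
  expect_equal(as.numeric(class_weights(10)), 1)
  # independent reciprocal-normalization oracle
  counts <- c(1139, 1177, 788)
  oracle <- (1 / counts) / sum(1 / counts)
  expect_equal(as.numeric(class_weights(counts)), oracle, tolerance = 1e-12)
  expect_equal(round(as.numeric(class_weights(counts)), 4),
               c(0.2930, 0.2835, 0.4235))
  expect_equal(sum(class_weights(counts)), 1, tolerance = 1e-12)
  # scale invariance and monotonicity
  expect_equal(as.numeric(class_weights(counts * 7)),
               as.numeric(class_weights(counts)), tolerance = 1e-12)
  w <- as.numeric(class_weights(c(10, 20, 40)))
  expect_true(all(diff(w) < 0))
  expect_error(class_weights(c(5, 0)), class = "meshgcn_undefined_weight")
})

test_that("stratified k-fold balances every class across folds", {
  labels <- rep(c("A", "B"), c(10, 5))
  sp <- stratified_kfold(labels, k = 5, seed = 0)
  tab <- table(sp$fold_of, labels)
  expect_true(all(tab[, "A"] == 2))
  expect_true(all(tab[, "B"] == 1))
  # determinism
  expect_identical(sp, stratified_kfold(labels, k = 5, seed = 0))
  expect_false(identical(stratified_kfold(labels, k = 5, seed = 1)$fold_of,
                         stratified_kfold(labels, k = 5, seed = 2)$fold_of))
  # 26 samples of one class -> fold sizes {6,5,5,5,5}
  sp26 <- stratified_kfold(rep("x", 26), k = 5, seed = 2)
  expect_equal(sort(tabulate(sp26$fold_of + 1, 5), decreasing = TRUE),
               c(6, 5, 5, 5, 5))
  expect_error(stratified_kfold(c("a", "b"), k = 5))
})

test_that("iterative pairwise split balances label pairs", {
  # all samples share one label set -> plain balanced split
  Y <- matrix(1L, 10, 2)
  sp <- iterative_multilabel_split(Y, k = 5, seed = 0)
  expect_equal(unname(tabulate(sp$fold_of + 1, 5)), rep(2L, 5))

  # a pair occurring exactly 5 times lands once per fold
  Y2 <- matrix(0L, 10, 3)
  Y2[1:5, c(1, 2)] <- 1L
  Y2[6:10, 3] <- 1L
  sp2 <- iterative_multilabel_split(Y2, k = 5, seed = 1)
  expect_equal(unname(tabulate(sp2$fold_of[1:5] + 1, 5)), rep(1L, 5))

  # determinism and partition property
  expect_identical(sp2, iterative_multilabel_split(Y2, k = 5, seed = 1))
  expect_true(all(!is.na(sp2$fold_of)))
  expect_true(all(sp2$fold_of %in% 0:4))

  expect_error(iterative_multilabel_split(matrix(0L, 3, 2), k = 2))
})

test_that("iterative split keeps per-label fold frequencies near proportional", {
  set.seed(4)
  n <- 200
  Y <- matrix(0L, n, 4)
  Y[cbind(seq_len(n), sample(4, n, replace = TRUE, prob = c(.4, .3, .2, .1)))] <- 1L
  extra <- runif(n) < 0.3
  for (i in which(extra)) {
    Y[i, sample(which(Y[i, ] == 0), 1)] <- 1L
  }
  sp <- iterative_multilabel_split(Y, k = 5, seed = 7)
  for (j in seq_len(ncol(Y))) {
    per_fold <- vapply(0:4, function(f) sum(Y[sp$fold_of == f, j]),
                       numeric(1))
    expect_lte(max(abs(per_fold - sum(Y[, j]) / 5)), 1 + 1e-9)
  }
})

test_that("training reduces loss, is seed-deterministic, and can overfit", {
  ds <- tiny_dataset(4, 3, seed = 3)
  cfg <- train_config("task3", epochs = 150, seed = 1,
                      conv_widths = c(16, 32), fc1_width = 16)
  fit <- gcn_train(cfg, ds)
  expect_true(all(is.finite(fit$history$loss)))
  # averaged over 5-epoch windows, the training loss is non-increasing
  win <- colMeans(matrix(fit$history$loss, nrow = 5))
  expect_lt(win[length(win)], win[1])
  y <- vapply(ds, function(g) g$labels, integer(1))
  expect_equal(mean(predict(fit$model, ds) == y), 1)

  fit2 <- gcn_train(cfg, ds)
  expect_identical(fit$model, fit2$model)
  expect_identical(fit$history, fit2$history)

  cfg3 <- train_config("task3", epochs = 150, seed = 2,
                       conv_widths = c(16, 32), fc1_width = 16)
  fit3 <- gcn_train(cfg3, ds)
  expect_false(identical(fit$model$fc2$W, fit3$model$fc2$W))
})

test_that("training writes a complete checkpoint", {
  ds <- tiny_dataset(4, 3, seed = 3)
  cfg <- train_config("task3", epochs = 3, seed = 1,
                      conv_widths = c(8), fc1_width = 6)
  path <- tempfile(fileext = ".rds")
  fit <- gcn_train(cfg, ds, checkpoint_path = path)
  ck <- load_gcn_model(path)
  expect_identical(ck$model, fit$model)
  expect_equal(ck$metadata$seed, 1L)
  expect_equal(ck$metadata$config$task, "task3")
  expect_equal(sum(ck$metadata$class_weights), 1, tolerance = 1e-12)
})

test_that("cross validation reports the full metric set per task type", {
  ds <- tiny_dataset(5, 3, seed = 6)
  cfg <- train_config("task3", epochs = 10, seed = 0,
                      conv_widths = c(8, 12), fc1_width = 8)
  rep_ <- gcn_cross_validate(cfg, ds)
  expect_setequal(rep_$summary$metric, c("accuracy", "bac", "mcc", "auroc",
                                         "ap"))
  expect_equal(nrow(rep_$per_fold), 5)
  expect_true(all(rep_$summary$mean >= -1 & rep_$summary$mean <= 1))
  expect_equal(rep_$representative$fold, 4)
  expect_equal(dim(rep_$representative$confusion), c(3, 3))
  # per-class fold sizes differ by at most one in the underlying split
  y <- vapply(ds, function(g) g$labels, integer(1))
  for (cl in unique(y)) {
    sizes <- tabulate(rep_$split$fold_of[y == cl] + 1, 5)
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("multi-label training and CV run end to end with the multi-label metric set", {
  spec <- fixture_spec(n_per_class = 25, n_classes = 3, salt_fraction = 0,
                       seed = 8)
  recs <- generate_multilabel(spec)
  ds <- filter_and_dedup(recs, test_schema)$dataset
  cfg <- train_config("multilabel", epochs = 8, seed = 1, n_classes = 3L,
                      conv_widths = c(8, 12), fc1_width = 8)
  rep_ <- gcn_cross_validate(cfg, ds)
  expect_setequal(rep_$summary$metric,
                  c("accuracy", "subset_accuracy", "fbeta", "auroc", "ap"))
  expect_true(all(rep_$summary$mean >= 0 & rep_$summary$mean <= 1))
  expect_equal(rep_$split$kind, "iterative-pairwise")
  # weighted multi-label loss path also trains
  cfgw <- train_config("multilabel", epochs = 2, seed = 1, n_classes = 3L,
                       conv_widths = c(8), fc1_width = 6,
                       weight_multilabel_loss = TRUE)
  fitw <- gcn_train(cfgw, ds)
  expect_true(all(is.finite(fitw$history$loss)))
})

test_that("train config defaults follow the task table", {
  c3 <- train_config("task3")
  expect_equal(c3$learning_rate, 5e-4)
  expect_equal(c3$batch_size, 256L)
  expect_equal(c3$dropout, 0.4)
  expect_equal(c3$n_conv_layers, 3L)
  expect_equal(c3$n_dense_layers, 2L)
  c12 <- train_config("task12")
  expect_equal(c12$batch_size, 512L)
  expect_equal(c12$dropout, 0.25)
  cm <- train_config("multilabel")
  expect_equal(cm$batch_size, 512L)
  expect_equal(cm$dropout, 0.25)
  expect_equal(cm$n_classes, 12L)
})
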