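# Training: inverse-frequency class weights, stratified and iterative
# pairwise multi-label 5-fold splitting, and the Adam optimization loop.

#' Normalized inverse-frequency class weights
#'
#' For class counts `c_i`, the weight of class i is
#' `w_i = (1/c_i) / sum_k (1/c_k)`, so that rarer classes receive larger
#' weights and the weights sum to one.
#'
#' @param counts Positive class sizes.
#' @return Numeric weight vector summing to 1 (class `class_weights`).
#' @examples
#' class_weights(c(1139, 1177, 788))
#' @export
class_weights <- function(counts) {
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop(structure(
      class = c("meshgcn_undefined_weight", "error", "condition"),
      list(message = "class_weights: all class counts must be positive",
           call = NULL)))
  }
  inv <- 1 / counts
  w <- inv / sum(inv)
  class(w) <- c("class_weights", "numeric")
  w
}

#' Task hyperparameter configuration
#'
#' Per-task default hyperparameters: learning rate 0.0005, Adam, 3 GraphConv
#' layers and 2 dense layers for every task; batch size 256 and dropout 0.4
#' for the 3- and 5-class tasks, batch size 512 and dropout 0.25 for the
#' 12-class and multi-label tasks.
#'
#' @param task `"task3"`, `"task5"`, `"task12"` or `"multilabel"`.
#' @param epochs Number of training epochs (default 300).
#' @param seed Integer seed controlling weight initialization, batching and
#'   dropout.
#' @param n_folds Number of cross-validation folds.
#' @param conv_widths,fc1_width Architecture widths (last conv width is the
#'   graph embedding length).
#' @param weight_multilabel_loss If `TRUE`, apply class weights to the
#'   multi-label loss as well (off by default; weights are used for the
#'   single-label NLL only).
#' @param ... Overrides for any stored field (e.g. `batch_size`,
#'   `learning_rate`, `dropout`).
#' @return A `train_config` list.
#' @export
train_config <- function(task = c("task3", "task5", "task12", "multilabel"),
                         epochs = 300L, seed = 0L, n_folds = 5L,
                         conv_widths = c(256, 512, 1024), fc1_width = 512,
                         weight_multilabel_loss = FALSE, ...) {
  task <- match.arg(task)
  base <- list(
    task = task,
    n_classes = switch(task, task3 = 3L, task5 = 5L, 12L),
    learning_rate = 5e-4,
    batch_size = if (task %in% c("task3", "task5")) 256L else 512L,
    optimizer = "adam",
    n_conv_layers = 3L,
    n_dense_layers = 2L,
    dropout = if (task %in% c("task3", "task5")) 0.4 else 0.25,
    epochs = as.integer(epochs),
    seed = as.integer(seed),
    n_folds = as.integer(n_folds),
    conv_widths = conv_widths,
    fc1_width = fc1_width,
    weight_multilabel_loss = weight_multilabel_loss
  )
  dots <- list(...)
  base[names(dots)] <- dots
  structure(base, class = "train_config")
}

#' Stratified k-fold split for single-label data
#'
#' Assigns folds class by class so that within every class the fold sizes
#' differ by at most one; per-class shuffling and the rotation of fold
#' offsets are driven solely by `seed`.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A `split_plan`: list with `fold_of` (integer vector of fold
#'   indices 0..k-1, aligned with `labels`) and `kind = "stratified"`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 0L) {
  n <- length(labels)
  if (k > n) stop("stratified_kfold: more folds than samples")
  fold_of <- integer(n)
  .with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(as.character(labels)))) {
      idx <- which(as.character(labels) == cl)
      idx <- idx[sample.int(length(idx))]
      f <- (seq_along(idx) - 1L + offset) %% k
      fold_of[idx] <- f
      offset <- (offset + length(idx)) %% k
    }
  })
  structure(list(fold_of = fold_of, kind = "stratified", k = as.integer(k),
                 seed = as.integer(seed)), class = "split_plan")
}

#' Iterative pairwise-co-occurrence multi-label k-fold split
#'
#' Second-order iterative stratification: samples are described by the
#' unordered pairs of their labels (a single-label sample contributes its
#' self-pair), and assignment proceeds from the currently rarest pair,
#' giving each sample to the fold with the greatest remaining desire for
#' that pair; ties are broken by the largest remaining fold capacity, then
#' by seeded uniform choice.
#'
#' @param label_matrix Binary matrix (n x C); every row must have at least
#'   one active label.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A `split_plan` with `kind = "iterative-pairwise"`.
#' @export
iterative_multilabel_split <- function(label_matrix, k = 5L, seed = 0L) {
  Y <- as.matrix(label_matrix)
  n <- nrow(Y)
  if (k > n) stop("iterative_multilabel_split: more folds than samples")
  if (any(rowSums(Y) < 1)) {
    stop("iterative_multilabel_split: every sample needs at least one label")
  }
  C <- ncol(Y)
  pair_key <- function(i, j) paste0(i, ":", j)
  # second-order evidence per sample: each label singleton plus every
  # unordered label pair, so both pair co-occurrence and per-label
  # marginals are balanced across folds
  sample_pairs <- lapply(seq_len(n), function(s) {
    lb <- which(Y[s, ] > 0)
    keys <- as.character(lb)
    if (length(lb) > 1) {
      cmb <- utils::combn(lb, 2)
      keys <- c(keys, apply(cmb, 2, function(p) pair_key(p[1], p[2])))
    }
    keys
  })
  all_pairs <- sort(unique(unlist(sample_pairs)))
  pair_count <- table(factor(unlist(sample_pairs), levels = all_pairs))
  # desired count of each pair per fold, and fold capacities
  desire <- matrix(as.numeric(pair_count) / k, nrow = k,
                   ncol = length(all_pairs), byrow = TRUE,
                   dimnames = list(NULL, all_pairs))
  capacity <- rep(n / k, k)
  fold_of <- rep(NA_integer_, n)
  remaining_with_pair <- function(p) {
    which(is.na(fold_of) &
            vapply(sample_pairs, function(sp) p %in% sp, logical(1)))
  }
  .with_seed(seed, {
    while (any(is.na(fold_of))) {
      live <- vapply(all_pairs, function(p) length(remaining_with_pair(p)),
                     integer(1))
      active <- which(live > 0)
      if (length(active) == 0) {
        # no pairs left (cannot happen: every sample has >= 1 pair)
        break
      }
      p <- all_pairs[active[which.min(live[active])]]
      for (s in remaining_with_pair(p)) {
        d <- desire[, p]
        cand <- which(d == max(d))
        if (length(cand) > 1) {
          cand <- cand[capacity[cand] == max(capacity[cand])]
        }
        f <- if (length(cand) > 1) cand[sample.int(length(cand), 1)] else cand
        fold_of[s] <- f - 1L
        for (sp in sample_pairs[[s]]) desire[f, sp] <- desire[f, sp] - 1
        capacity[f] <- capacity[f] - 1
      }
    }
  })
  structure(list(fold_of = fold_of, kind = "iterative-pairwise",
                 k = as.integer(k), seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s, k = %d, seed = %d; fold sizes: %s\n",
              x$kind, x$k, x$seed,
              paste(tabulate(x$fold_of + 1L, x$k), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# optimization

.adam_state <- function(params) {
  if (is.numeric(params)) return(list(m = params * 0, v = params * 0))
  lapply(params, .adam_state)
}

# one Adam update over the nested parameter list; returns list(p, s)
.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.numeric(params)) {
    m <- beta1 * state$m + (1 - beta1) * grads
    v <- beta2 * state$v + (1 - beta2) * grads * grads
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    return(list(p = params - lr * mhat / (sqrt(vhat) + eps),
                s = list(m = m, v = v)))
  }
  out_p <- params
  out_s <- state
  keys <- if (is.null(names(params))) seq_along(params) else names(params)
  for (i in keys) {
    r <- .adam_step(params[[i]], grads[[i]], state[[i]], lr, t,
                    beta1, beta2, eps)
    out_p[[i]] <- r$p
    out_s[[i]] <- r$s
  }
  list(p = out_p, s = out_s)
}

# extract the trainable parameter subtree of a model
.model_params <- function(model) {
  list(conv_layers = lapply(model$conv_layers, function(ly) {
    list(conv = ly$conv[c("W1", "W2", "bias")],
         norm = ly$norm[c("alpha", "gamma", "beta")])
  }), fc1 = model$fc1, fc2 = model$fc2)
}

.set_model_params <- function(model, params) {
  for (t in seq_along(model$conv_layers)) {
    model$conv_layers[[t]]$conv[c("W1", "W2", "bias")] <-
      params$conv_layers[[t]]$conv
    model$conv_layers[[t]]$norm[c("alpha", "gamma", "beta")] <-
      params$conv_layers[[t]]$norm
  }
  model$fc1 <- params$fc1
  model$fc2 <- params$fc2
  model
}

# labels of a dataset as an integer vector (single-label) or matrix
.dataset_labels <- function(dataset) {
  l1 <- dataset[[1]]$labels
  if (length(l1) > 1) {
    t(vapply(dataset, function(g) as.numeric(g$labels), numeric(length(l1))))
  } else {
    vapply(dataset, function(g) as.integer(g$labels), integer(1))
  }
}

#' Train one GCN model
#'
#' Trains on every fold except `fold` (or on the whole dataset when
#' `split = NULL`) with Adam at the configured settings. For single-label
#' tasks the negative log likelihood loss is weighted with
#' [class_weights()] computed from the training portion's class counts;
#' the multi-label task uses the soft margin loss (optionally weighted via
#' the config switch). Batching, weight initialization and dropout are all
#' driven by `config$seed`, so a (data, config, seed) triple fully
#' determines the result.
#'
#' @param config A [train_config()].
#' @param dataset List of labeled `molecular_graph` objects built with one
#'   schema.
#' @param split Optional [stratified_kfold()] /
#'   [iterative_multilabel_split()] plan.
#' @param fold Held-out fold index (0-based) when `split` is given.
#' @param checkpoint_path Optional path; when set, the final model, resolved
#'   config and seed are written there with [save_gcn_model()].
#' @return List with `model` (trained `gcn_model`), `history` (data frame
#'   `epoch`, `loss`), and `train_index`.
#' @export
gcn_train <- function(config, dataset, split = NULL, fold = NULL,
                      checkpoint_path = NULL) {
  stopifnot(inherits(config, "train_config"))
  multilabel <- identical(config$task, "multilabel")
  idx <- seq_along(dataset)
  if (!is.null(split)) {
    stopifnot(!is.null(fold))
    idx <- which(split$fold_of != fold)
  }
  if (length(idx) == 0) stop("gcn_train: empty training fold")
  train_set <- dataset[idx]
  labels <- .dataset_labels(train_set)

  n_feat <- ncol(train_set[[1]]$node_features)
  model <- gcn_model(
    n_features = n_feat, n_outputs = config$n_classes,
    head = if (multilabel) "sigmoid-multilabel" else "log-softmax",
    conv_widths = config$conv_widths, fc1_width = config$fc1_width,
    dropout_rate = config$dropout, readout_mode = "sum",
    seed = config$seed)

  cw <- NULL
  if (!multilabel) {
    counts <- tabulate(labels + 1L, config$n_classes)
    if (any(counts == 0)) {
      # classes absent from this training portion get no weight mass
      cw <- rep(0, config$n_classes)
      cw[counts > 0] <- class_weights(counts[counts > 0])
    } else {
      cw <- as.numeric(class_weights(counts))
    }
  } else if (isTRUE(config$weight_multilabel_loss)) {
    cw <- as.numeric(class_weights(pmax(colSums(labels), 1)))
  }

  # fixed seeded batching; one batch when the fold fits the batch size
  n <- length(train_set)
  order_ <- .with_seed(config$seed + 1L, sample.int(n))
  starts <- seq(1, n, by = config$batch_size)
  batches <- lapply(starts, function(s) {
    sel <- order_[s:min(s + config$batch_size - 1, n)]
    b <- .batch_graphs(train_set[sel])
    b$sel <- sel
    b
  })

  params <- .model_params(model)
  state <- .adam_state(params)
  history <- numeric(config$epochs)
  step <- 0L
  rng_seed <- config$seed + 2L
  .with_seed(rng_seed, {
    for (epoch in seq_len(config$epochs)) {
      ep_loss <- 0
      for (b in batches) {
        mdl <- .set_model_params(model, params)
        out <- .forward_batch(mdl, b, training_mode = TRUE,
                              keep_cache = TRUE)
        if (multilabel) {
          Y <- labels[b$sel, , drop = FALSE]
          if (is.null(cw)) {
            loss <- multilabel_soft_margin_loss(out$scores, Y)
            g_S <- attr(loss, "grad")
          } else {
            loss <- multilabel_soft_margin_loss(out$scores, Y)
            g_S <- attr(loss, "grad") *
              matrix(cw * length(cw), nrow(Y), ncol(Y), byrow = TRUE)
            loss <- as.numeric(loss)
          }
        } else {
          y <- labels[b$sel]
          loss <- nll_loss(out$scores, y, cw)
          g_lp <- attr(loss, "grad")
          # log-softmax backward: g_S = g_lp - softmax * rowSums(g_lp)
          sm <- exp(out$cache$S - apply(out$cache$S, 1, max))
          sm <- sm / rowSums(sm)
          g_S <- g_lp - sm * rowSums(g_lp)
        }
        grads <- .backward_batch(mdl, b, out$cache, g_S)
        step <- step + 1L
        r <- .adam_step(params, grads, state, config$learning_rate, step)
        params <- r$p; state <- r$s
        ep_loss <- ep_loss + as.numeric(loss) * length(b$sel)
      }
      history[epoch] <- ep_loss / n
    }
  })
  model <- .set_model_params(model, params)
  result <- list(model = model,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      loss = history),
                 train_index = idx)
  if (!is.null(checkpoint_path)) {
    save_gcn_model(model, checkpoint_path,
                   metadata = list(config = unclass(config),
                                   seed = config$seed,
                                   class_weights = cw))
  }
  result
}

#' k-fold cross validation with metric aggregation
#'
#' Builds the task-appropriate split (stratified for single-label,
#' iterative pairwise for multi-label), trains one model per fold,
#' evaluates each on its held-out fold with the metric suite, and reports
#' the mean and sample standard deviation of every metric over folds. The
#' final fold is the designated representative fold: its confusion matrix
#' (single-label) or per-class counts are attached to the report.
#'
#' @param config A [train_config()].
#' @param dataset List of labeled `molecular_graph` objects.
#' @param split Optional precomputed `split_plan`; by default one is built
#'   from the labels and `config$seed`.
#' @return A `metrics_report`: list with `per_fold` (data frame of fold x
#'   metric), `summary` (data frame `metric`, `mean`, `std`),
#'   `representative` (fold-5 evaluation details), `models` (per-fold
#'   trained models) and `split`.
#' @export
gcn_cross_validate <- function(config, dataset, split = NULL) {
  multilabel <- identical(config$task, "multilabel")
  labels <- .dataset_labels(dataset)
  if (is.null(split)) {
    split <- if (multilabel) {
      iterative_multilabel_split(labels, k = config$n_folds,
                                 seed = config$seed)
    } else {
      stratified_kfold(labels, k = config$n_folds, seed = config$seed)
    }
  }
  per_fold <- list()
  models <- list()
  representative <- NULL
  for (fold in seq_len(config$n_folds) - 1L) {
    fit <- gcn_train(config, dataset, split, fold)
    models[[fold + 1L]] <- fit$model
    val_idx <- which(split$fold_of == fold)
    val_set <- dataset[val_idx]
    pred <- predict(fit$model, val_set)
    scores <- attr(pred, "scores")
    if (multilabel) {
      Y <- labels[val_idx, , drop = FALSE]
      prob <- 1 / (1 + exp(-scores))
      mts <- multilabel_metrics(Y, pred, prob)
      row <- data.frame(fold = fold, accuracy = mts$accuracy,
                        subset_accuracy = mts$subset_accuracy,
                        fbeta = mts$fbeta, auroc = mts$auroc, ap = mts$ap)
    } else {
      y <- labels[val_idx]
      prob <- exp(scores)
      mts <- multiclass_metrics(y, as.integer(pred), prob)
      row <- data.frame(fold = fold, accuracy = mts$accuracy, bac = mts$bac,
                        mcc = mts$mcc, auroc = mts$auroc, ap = mts$ap)
    }
    per_fold[[fold + 1L]] <- row
    if (fold == config$n_folds - 1L) {
      representative <- list(fold = fold, metrics = mts)
      if (!multilabel) {
        representative$confusion <- confusion_matrix(
          labels[val_idx], as.integer(pred), config$n_classes)
        representative$confusion_normalized <- confusion_matrix(
          labels[val_idx], as.integer(pred), config$n_classes,
          normalize_rows = TRUE)
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- setdiff(names(per_fold), "fold")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_fold[[m]]), numeric(1)),
    std = vapply(metric_cols, function(m) stats::sd(per_fold[[m]]),
                 numeric(1)),
    row.names = NULL)
  structure(list(per_fold = per_fold, summary = summary,
                 representative = representative, models = models,
                 split = split, config = config),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> task %s, %d folds\n", x$config$task,
              x$config$n_folds))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
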