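#' Convert a SMILES string into an attributed molecular graph
#'
#' The molecule is salt-stripped, parsed, and turned into an undirected graph
#' with one node per heavy atom and each bond stored as two directed edges
#' with identical bond features. Molecules that fail to parse or that have
#' fewer than two heavy atoms after salt stripping are returned as rejection
#' records rather than errors.
#'
#' @param id Identifier carried through to the graph.
#' @param smiles SMILES string.
#' @param schema A [feature_schema()].
#' @param labels Either a single integer class code (single-label) or a named
#'   or unnamed 0/1 vector over the label space (multi-label). May be `NULL`
#'   for unlabeled molecules.
#' @return A `molecular_graph` object (fields `id`, `smiles_canonical`,
#'   `node_features` (n x F_atom), `edge_index` (2-column integer matrix of
#'   directed edges, 1-based), `edge_features`, `labels`, `n_nodes`) or a
#'   `graph_rejection` object with fields `id` and `reason`.
#' @examples
#' g <- smiles_to_graph("ethanol", "CCO", feature_schema(), labels = 0L)
#' g$n_nodes
#' @export
smiles_to_graph <- function(id, smiles, schema = feature_schema(),
                            labels = NULL) {
  reject <- function(reason) {
    structure(list(id = id, smiles = smiles, reason = reason),
              class = "graph_rejection")
  }
  stripped <- tryCatch(strip_salts(smiles),
                       error = function(e) NULL)
  if (is.null(stripped)) return(reject("parse failure"))
  mol <- .parse_molecule(stripped)
  if (is.null(mol)) return(reject("parse failure"))
  if (mol$n_heavy < 2) return(reject("fewer than two nodes"))

  node_features <- t(vapply(seq_len(mol$n_heavy), function(i) {
    featurize_atom(as.list(mol$atoms[i, ]), schema)
  }, numeric(schema$atom_width)))

  nb <- nrow(mol$bonds)
  if (nb > 0) {
    edge_index <- cbind(
      c(mol$bonds$a1, mol$bonds$a2),
      c(mol$bonds$a2, mol$bonds$a1)
    )
    bf <- t(vapply(seq_len(nb), function(k) {
      featurize_bond(as.list(mol$bonds[k, c("bond_type", "stereo",
                                            "conjugated")]), schema)
    }, numeric(schema$bond_width)))
    edge_features <- rbind(bf, bf)
  } else {
    edge_index <- matrix(integer(0), ncol = 2)
    edge_features <- matrix(numeric(0), ncol = schema$bond_width)
  }
  storage.mode(edge_index) <- "integer"

  structure(list(
    id = id,
    smiles_canonical = canonical_smiles(stripped),
    node_features = node_features,
    edge_index = edge_index,
    edge_features = edge_features,
    labels = labels,
    n_nodes = mol$n_heavy,
    atoms = mol$atoms,
    bonds = mol$bonds
  ), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d nodes, %d directed edges [%s]\n",
              x$id, x$n_nodes, nrow(x$edge_index), x$smiles_canonical))
  invisible(x)
}

#' Build a deduplicated graph dataset from SMILES records
#'
#' Converts each record with [smiles_to_graph()], drops parse failures and
#' sub-two-atom molecules, and keeps exactly one graph per unique canonical
#' salt-stripped structure. When `reference` is supplied (e.g. the training
#' set, when preparing a test set), any record whose canonical structure
#' already appears in the reference is dropped and logged as a cross-set
#' duplicate. All drops are logged, never silent.
#'
#' @param records Data frame with columns `id`, `smiles`, and either a
#'   `label` column or one 0/1 column per class (multi-label).
#' @param schema A [feature_schema()].
#' @param reference Optional: a character vector of canonical SMILES, or a
#'   dataset returned by this function, to deduplicate against.
#' @return A list with `dataset` (list of `molecular_graph`) and `rejections`
#'   (data frame `id`, `reason`).
#' @export
filter_and_dedup <- function(records, schema = feature_schema(),
                             reference = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("id", "smiles") %in% names(records)))
  label_cols <- setdiff(names(records), c("id", "smiles"))
  get_labels <- function(i) {
    if (length(label_cols) == 0) return(NULL)
    if (identical(label_cols, "label")) return(records$label[i])
    v <- as.numeric(records[i, label_cols])
    names(v) <- label_cols
    v
  }
  ref_canon <- character(0)
  if (!is.null(reference)) {
    ref_canon <- if (is.list(reference) && !is.null(reference$dataset)) {
      vapply(reference$dataset, function(g) g$smiles_canonical, character(1))
    } else if (is.character(reference)) reference
    else stop("reference must be a dataset or character vector")
  }
  dataset <- list()
  seen <- character(0)
  rej <- list()
  for (i in seq_len(nrow(records))) {
    g <- smiles_to_graph(records$id[i], records$smiles[i], schema,
                         labels = get_labels(i))
    if (inherits(g, "graph_rejection")) {
      rej[[length(rej) + 1]] <- data.frame(id = g$id, reason = g$reason,
                                           stringsAsFactors = FALSE)
      next
    }
    key <- g$smiles_canonical
    if (key %in% ref_canon) {
      rej[[length(rej) + 1]] <- data.frame(
        id = g$id, reason = "duplicate of reference set",
        stringsAsFactors = FALSE)
    } else if (key %in% seen) {
      rej[[length(rej) + 1]] <- data.frame(
        id = g$id, reason = "duplicate structure",
        stringsAsFactors = FALSE)
    } else {
      seen <- c(seen, key)
      dataset[[length(dataset) + 1]] <- g
    }
  }
  rejections <- if (length(rej) > 0) do.call(rbind, rej) else
    data.frame(id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  list(dataset = dataset, rejections = rejections)
}

#' Per-class dataset summary table
#'
#' Tabulates training and test counts per MeSH class and the proportion of
#' test compounds over the class total, x/(x+y), reported both raw and
#' rounded to two decimals, with a totals row.
#'
#' @param train_labels Integer class codes of the training molecules.
#' @param test_labels Integer class codes of the test molecules.
#' @param label_space A [mesh_label_space()] (or compatible data frame with
#'   `class_name` and `code`).
#' @return Data frame with columns `class_name`, `code`, `train_count`,
#'   `test_count`, `test_proportion` (raw), `test_proportion_2dp`; the final
#'   row is the totals row (`class_name == "Total"`). An empty class has
#'   `NA` proportion.
#' @examples
#' ls12 <- mesh_label_space("task12")
#' summarize_dataset(rep(0:2, c(5, 3, 2)), rep(0:2, c(1, 1, 1)),
#'                   mesh_label_space("task3"))
#' @export
summarize_dataset <- function(train_labels, test_labels, label_space) {
  stopifnot(all(train_labels %in% label_space$code),
            all(test_labels %in% label_space$code))
  y <- vapply(label_space$code, function(cd) sum(train_labels == cd),
              numeric(1))
  x <- vapply(label_space$code, function(cd) sum(test_labels == cd),
              numeric(1))
  prop <- ifelse(x + y > 0, x / (x + y), NA_real_)
  out <- data.frame(
    class_name = label_space$class_name,
    code = label_space$code,
    train_count = y,
    test_count = x,
    test_proportion = prop,
    test_proportion_2dp = round(prop, 2),
    stringsAsFactors = FALSE
  )
  tot_prop <- sum(x) / (sum(x) + sum(y))
  rbind(out, data.frame(
    class_name = "Total", code = NA_integer_,
    train_count = sum(y), test_count = sum(x),
    test_proportion = tot_prop, test_proportion_2dp = round(tot_prop, 2),
    stringsAsFactors = FALSE))
}

#' Read a labeled SMILES table
#'
#' Reads the delimited-text dialect the pipeline consumes: header row,
#' columns `id`, `smiles`, and either `label` or one 0/1 column per class.
#'
#' @param path CSV (`,`) or TSV (`\t`) file path; the delimiter is inferred
#'   from the extension (`.tsv`/`.tab` means tab).
#' @return Data frame.
#' @export
read_smiles_table <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  if (!all(c("id", "smiles") %in% names(df))) {
    stop("input table must have 'id' and 'smiles' columns")
  }
  df$id <- as.character(df$id)
  df
}

#' Write a tab-separated table
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Stack a list of molecular graphs into one batch: block-diagonal sparse
# adjacency, row-bound node features, node->graph membership, and a sparse
# pooling indicator (n_graphs x n_nodes).
.batch_graphs <- function(graphs) {
  n_nodes <- vapply(graphs, function(g) g$n_nodes, integer(1))
  offsets <- cumsum(c(0L, n_nodes[-length(n_nodes)]))
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  ei <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edge_index
    if (nrow(e) == 0) return(matrix(integer(0), ncol = 2))
    e + offsets[i]
  }))
  N <- sum(n_nodes)
  A <- if (nrow(ei) > 0) {
    Matrix::sparseMatrix(i = ei[, 1], j = ei[, 2], x = 1, dims = c(N, N))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(N, N))
  }
  membership <- rep(seq_along(graphs), n_nodes)
  P <- Matrix::sparseMatrix(i = membership, j = seq_len(N), x = 1,
                            dims = c(length(graphs), N))
  list(X = X, A = A, membership = membership, P = P,
       n_nodes = n_nodes, n_graphs = length(graphs))
}
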