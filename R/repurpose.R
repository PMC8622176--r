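# Co-occurrence network analysis of multi-label label sets: build true and
# predicted MeSH class co-occurrence networks, diff them, and extract drugs
# whose predicted label sets contain classes absent from their recorded
# ones — the repurposing candidates.

.pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = " || ")
}

#' Build a MeSH class co-occurrence network
#'
#' Every drug contributes one co-occurrence to each unordered pair of the
#' classes in its label set (a 3-label drug contributes to 3 pairs;
#' single-label drugs contribute no edges). Edge display widths follow
#' `w = 0.5 * log2(N + 1)`.
#'
#' @param label_sets List of character vectors (or a 0/1 matrix with class
#'   names as columns): the label set of each drug.
#' @param classes Optional character vector fixing the node set; defaults
#'   to the union of observed labels.
#' @return A `cooc_network`: list with `nodes`, `edges` (data frame
#'   `class_a`, `class_b`, `count`, `width`).
#' @examples
#' net <- cooccurrence_network(list(c("a", "b"), c("a", "b"), c("a", "c")))
#' net$edges
#' @export
cooccurrence_network <- function(label_sets, classes = NULL) {
  if (is.matrix(label_sets) || is.data.frame(label_sets)) {
    cn <- colnames(label_sets)
    stopifnot(!is.null(cn))
    M <- as.matrix(label_sets)
    label_sets <- lapply(seq_len(nrow(M)), function(i) cn[M[i, ] > 0])
  }
  if (is.null(classes)) classes <- sort(unique(unlist(label_sets)))
  pairs <- unlist(lapply(label_sets, function(ls) {
    ls <- unique(as.character(ls))
    if (length(ls) < 2) return(character(0))
    cmb <- utils::combn(sort(ls), 2)
    .pair_id(cmb[1, ], cmb[2, ])
  }))
  if (length(pairs) == 0) {
    edges <- data.frame(class_a = character(0), class_b = character(0),
                        count = numeric(0), width = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    tab <- table(pairs)
    ab <- strsplit(names(tab), " || ", fixed = TRUE)
    edges <- data.frame(
      class_a = vapply(ab, `[`, character(1), 1),
      class_b = vapply(ab, `[`, character(1), 2),
      count = as.numeric(tab),
      stringsAsFactors = FALSE)
    edges$width <- edge_width(edges$count)
    edges <- edges[order(-edges$count, edges$class_a, edges$class_b), ]
    rownames(edges) <- NULL
  }
  structure(list(nodes = classes, edges = edges), class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("<cooc_network> %d nodes, %d edges, total co-occurrences %d\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$count)))
  invisible(x)
}

#' Edge display width from a co-occurrence count
#'
#' `w = 0.5 * log2(N + 1)`.
#'
#' @param N Non-negative integer co-occurrence count (vectorized).
#' @return Numeric width(s).
#' @export
edge_width <- function(N) {
  stopifnot(all(N >= 0))
  0.5 * log2(N + 1)
}

#' Diff two co-occurrence networks
#'
#' Splits edge pairs into those shared by both networks (with their count
#' deltas, predicted minus true), pairs present only in the true network
#' (associations the model failed to learn) and pairs present only in the
#' predicted network (where the model may have learnt something new —
#' candidate repurposing territory).
#'
#' @param net_true,net_pred `cooc_network` objects over the same label
#'   space.
#' @return List with data frames `shared` (`class_a`, `class_b`,
#'   `count_true`, `count_pred`, `delta`), `only_true`, `only_pred`.
#' @export
network_diff <- function(net_true, net_pred) {
  key <- function(e) .pair_id(e$class_a, e$class_b)
  et <- net_true$edges; ep <- net_pred$edges
  kt <- key(et); kp <- key(ep)
  shared_k <- intersect(kt, kp)
  it <- match(shared_k, kt); ip <- match(shared_k, kp)
  shared <- data.frame(
    class_a = et$class_a[it], class_b = et$class_b[it],
    count_true = et$count[it], count_pred = ep$count[ip],
    delta = ep$count[ip] - et$count[it],
    stringsAsFactors = FALSE)
  only_true <- et[!(kt %in% kp), c("class_a", "class_b", "count"),
                  drop = FALSE]
  only_pred <- ep[!(kp %in% kt), c("class_a", "class_b", "count"),
                  drop = FALSE]
  rownames(shared) <- rownames(only_true) <- rownames(only_pred) <- NULL
  list(shared = shared, only_true = only_true, only_pred = only_pred)
}

#' Extract drug repurposing candidates
#'
#' A drug is a candidate when its predicted label set contains at least one
#' class absent from its recorded (true) set; the novel classes are the
#' candidate repurposing indications, the lost classes are recorded
#' indications the model did not predict. Candidates are sorted by the
#' number of novel classes (descending), then by id.
#'
#' @param ids Drug identifiers.
#' @param true_sets,predicted_sets Lists of character vectors aligned with
#'   `ids`.
#' @return Data frame `id`, `true_classes`, `predicted_classes`, `novel`,
#'   `lost` (sets serialized as `;`-joined strings), plus a list-column
#'   representation in the attribute `"sets"`.
#' @export
repurposing_candidates <- function(ids, true_sets, predicted_sets) {
  if (length(ids) != length(true_sets) ||
      length(ids) != length(predicted_sets)) {
    stop("repurposing_candidates: ids and label sets must align")
  }
  rows <- list()
  sets <- list()
  for (i in seq_along(ids)) {
    tr <- unique(as.character(true_sets[[i]]))
    pr <- unique(as.character(predicted_sets[[i]]))
    novel <- setdiff(pr, tr)
    if (length(novel) == 0) next
    lost <- setdiff(tr, pr)
    rows[[length(rows) + 1]] <- data.frame(
      id = as.character(ids[i]),
      true_classes = paste(sort(tr), collapse = ";"),
      predicted_classes = paste(sort(pr), collapse = ";"),
      novel = paste(sort(novel), collapse = ";"),
      lost = paste(sort(lost), collapse = ";"),
      n_novel = length(novel),
      stringsAsFactors = FALSE)
    sets[[length(sets) + 1]] <- list(id = as.character(ids[i]), true = tr,
                                     predicted = pr, novel = novel,
                                     lost = lost)
  }
  if (length(rows) == 0) {
    out <- data.frame(id = character(0), true_classes = character(0),
                      predicted_classes = character(0), novel = character(0),
                      lost = character(0), n_novel = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "sets") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$n_novel, out$id)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "sets") <- sets[ord]
  out
}

#' Export a co-occurrence network
#'
#' Writes the edge list as TSV (`class_a`, `class_b`, `count`, `width`)
#' and, optionally, the network as GraphML.
#'
#' @param net A `cooc_network`.
#' @param tsv_path Edge-list TSV path.
#' @param graphml_path Optional GraphML path.
#' @return `tsv_path`, invisibly.
#' @export
write_cooc_network <- function(net, tsv_path, graphml_path = NULL) {
  write_tsv(net$edges, tsv_path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("class_a", "class_b")], directed = FALSE,
      vertices = data.frame(name = net$nodes))
    igraph::E(g)$count <- net$edges$count
    igraph::E(g)$width <- net$edges$width
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(tsv_path)
}
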