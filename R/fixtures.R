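# Synthetic labeled-SMILES generator. Each class is tied to a chemically
# meaningful substructure motif (branched alkane, chloroaromatic,
# carboxylic acid, amine, ether, thiol, nitrile, ketone, fluoroaromatic,
# pyridine, sulfonamide, acetamide) decorated with random alkyl chains, so
# the class signal is learnable by a small message-passing network. Records
# can carry counter-ion salts and multi-label molecules concatenate the
# motifs of each of their classes.

# motifs in left-attachable (string start) and right-attachable (appended
# after a chain carbon) SMILES forms
.MOTIFS <- data.frame(
  name = c("branched_alkane", "chloro_aromatic", "carboxylic_acid",
           "primary_amine", "methyl_ether", "thiol", "nitrile", "ketone",
           "fluoro_aromatic", "pyridine", "sulfonamide", "acetamide"),
  left = c("CC(C)(C)", "Clc1ccc(cc1)", "OC(=O)", "NC", "COC", "SC",
           "N#C", "CC(=O)", "Fc1ccc(cc1)", "c1ccc(nc1)", "NS(=O)(=O)",
           "CC(=O)N"),
  right = c("C(C)(C)C", "c1ccc(Cl)cc1", "C(=O)O", "CN", "COC", "CS",
            "C#N", "C(C)=O", "c1ccc(F)cc1", "c1cccnc1", "S(N)(=O)=O",
            "NC(C)=O"),
  stringsAsFactors = FALSE
)

#' Specification for the synthetic SMILES generator
#'
#' @param n_per_class Molecules per class (single-label), or total number
#'   of molecules (multi-label).
#' @param n_classes Number of classes (2..12); class c uses the c-th
#'   bundled substructure motif.
#' @param class_ratios Optional relative class sizes (single-label) or
#'   primary-label sampling weights (multi-label); defaults to balanced.
#' @param cooccurrence Optional C x C matrix of pairwise probabilities: for
#'   a molecule with primary label i, each other label j is added
#'   independently with probability `cooccurrence[i, j]` (multi-label
#'   only). Defaults to 0.2 off-diagonal.
#' @param salt_fraction Probability that a record carries a counter-ion
#'   fragment (`.[Na+]` or `.Cl`).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_per_class = 10L, n_classes = 3L,
                         class_ratios = NULL, cooccurrence = NULL,
                         salt_fraction = 0.1, seed = 0L) {
  stopifnot(n_classes >= 2, n_classes <= nrow(.MOTIFS),
            salt_fraction >= 0, salt_fraction <= 1)
  if (is.null(class_ratios)) class_ratios <- rep(1, n_classes)
  stopifnot(length(class_ratios) == n_classes, all(class_ratios >= 0))
  if (is.null(cooccurrence)) {
    cooccurrence <- matrix(0.2, n_classes, n_classes)
    diag(cooccurrence) <- 0
  }
  stopifnot(all(dim(cooccurrence) == n_classes),
            all(cooccurrence >= 0 & cooccurrence <= 1))
  structure(list(n_per_class = as.integer(n_per_class),
                 n_classes = as.integer(n_classes),
                 class_ratios = class_ratios,
                 cooccurrence = cooccurrence,
                 salt_fraction = salt_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.random_chain <- function() {
  k <- sample(2:8, 1)
  parts <- rep("C", k)
  if (stats::runif(1) < 0.5) {
    pos <- sample(seq_len(k), 1)
    parts[pos] <- "C(C)"
  }
  if (k >= 4 && stats::runif(1) < 0.25) {
    pos <- sample(seq_len(k), 1)
    parts[pos] <- "C(CC)"
  }
  tail <- sample(c("", "C", "CC", "C(C)C"), 1)
  paste0(paste(parts, collapse = ""), tail)
}

# draw a chain whose salt-free molecule is canonically distinct from all
# previously generated ones; beyond max_try, extend deterministically
.unique_molecule <- function(build, seen, max_try = 30L) {
  for (i in seq_len(max_try)) {
    smi <- build()
    can <- canonical_smiles(smi)
    if (!is.na(can) && !(can %in% seen)) return(list(smiles = smi, canon = can))
  }
  while (TRUE) {
    smi <- paste0(smi, "C")
    can <- canonical_smiles(smi)
    if (!is.na(can) && !(can %in% seen)) return(list(smiles = smi, canon = can))
  }
}

.maybe_salt <- function(smiles, salt_fraction) {
  if (stats::runif(1) < salt_fraction) {
    paste0(smiles, sample(c(".[Na+]", ".Cl"), 1))
  } else smiles
}

#' Generate single-label synthetic SMILES records
#'
#' Class c molecules are built from the c-th motif plus a random alkyl
#' chain; a `salt_fraction` of records carry a counter-ion fragment.
#' Class sizes follow `n_per_class * class_ratios / max(class_ratios)`
#' (rounded, minimum 1).
#'
#' @param spec A [fixture_spec()].
#' @return Data frame with columns `id`, `smiles`, `label` (0-based class
#'   codes).
#' @examples
#' head(generate_single_label(fixture_spec(n_per_class = 5)))
#' @export
generate_single_label <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  ratios <- spec$class_ratios / max(spec$class_ratios)
  sizes <- pmax(1L, as.integer(round(spec$n_per_class * ratios)))
  .with_seed(spec$seed, {
    rows <- list()
    counter <- 0L
    seen <- character(0)
    for (cl in seq_len(spec$n_classes)) {
      for (i in seq_len(sizes[cl])) {
        counter <- counter + 1L
        u <- .unique_molecule(
          function() paste0(.MOTIFS$left[cl], .random_chain()), seen)
        seen <- c(seen, u$canon)
        rows[[counter]] <- data.frame(
          id = sprintf("mol%05d", counter),
          smiles = .maybe_salt(u$smiles, spec$salt_fraction),
          label = cl - 1L, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate multi-label synthetic SMILES records
#'
#' Each molecule draws a primary label from `class_ratios`, then adds each
#' other label j independently with probability `cooccurrence[primary, j]`.
#' The molecule concatenates the motifs of all its labels (primary motif at
#' the head, the rest as chain branches).
#'
#' @param spec A [fixture_spec()]; `n_per_class` is the total record count.
#' @return Data frame with columns `id`, `smiles`, and one 0/1 column
#'   `c0` ... per class.
#' @export
generate_multilabel <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  C <- spec$n_classes
  p_primary <- spec$class_ratios / sum(spec$class_ratios)
  .with_seed(spec$seed, {
    n <- spec$n_per_class
    Y <- matrix(0L, n, C, dimnames = list(NULL, paste0("c", seq_len(C) - 1)))
    smiles <- character(n)
    seen <- character(0)
    for (i in seq_len(n)) {
      primary <- sample.int(C, 1, prob = p_primary)
      labels <- primary
      for (j in setdiff(seq_len(C), primary)) {
        if (stats::runif(1) < spec$cooccurrence[primary, j]) {
          labels <- c(labels, j)
        }
      }
      Y[i, labels] <- 1L
      extras <- setdiff(labels, primary)
      u <- .unique_molecule(function() {
        s <- paste0(.MOTIFS$left[primary], .random_chain())
        for (j in extras) s <- paste0(s, "C(", .MOTIFS$right[j], ")")
        paste0(s, "CC")
      }, seen)
      seen <- c(seen, u$canon)
      smiles[i] <- .maybe_salt(u$smiles, spec$salt_fraction)
    }
    data.frame(id = sprintf("mol%05d", seq_len(n)), smiles = smiles, Y,
               stringsAsFactors = FALSE)
  })
}

#' Expected mean label-set size of a multi-label fixture
#'
#' @param spec A [fixture_spec()].
#' @return Scalar expectation of labels per molecule.
#' @export
expected_label_count <- function(spec) {
  p_primary <- spec$class_ratios / sum(spec$class_ratios)
  1 + sum(vapply(seq_len(spec$n_classes), function(i) {
    p_primary[i] * sum(spec$cooccurrence[i, -i])
  }, numeric(1)))
}

#' Bundled multi-label repurposing worked examples
#'
#' Nine drugs from the reference dataset whose recorded and predicted MeSH
#' label sets differ — the worked examples used to exercise the
#' repurposing-candidate extraction. Each entry gives the recorded (true)
#' classes and the model-predicted classes.
#'
#' @return List with `ids`, `true_sets`, `predicted_sets` (parallel lists
#'   of character vectors).
#' @export
repurposing_examples <- function() {
  list(
    ids = c("Ginsenoside Rb2", "Balofloxacin", "Dipyridamole", "Hypericin",
            "Lacosamide", "Otilonium bromide", "Palmitoylethanolamide",
            "Peppermint oil", "Tirofiban"),
    true_sets = list(
      c("Antineoplastic", "Lipid Regulating"),
      c("Anti-infective", "Antineoplastic"),
      c("Cardiovascular", "Hematologic"),
      c("Anti-infective", "Antineoplastic", "Central Nervous System"),
      c("Cardiovascular", "Central Nervous System"),
      c("Cardiovascular", "Gastrointestinal"),
      c("Anti-infective", "Anti-inflammatory", "Central Nervous System"),
      c("Central Nervous System", "Gastrointestinal"),
      c("Cardiovascular", "Hematologic")),
    predicted_sets = list(
      c("Anti-infective", "Central Nervous System"),
      c("Urological", "Antineoplastic"),
      c("Antineoplastic", "Lipid Regulating"),
      c("Anti-infective", "Antineoplastic", "Urological"),
      c("Antineoplastic", "Central Nervous System"),
      c("Anti-infective", "Urological"),
      c("Anti-infective", "Cardiovascular", "Urological"),
      c("Anti-infective", "Cardiovascular"),
      c("Central Nervous System", "Antineoplastic"))
  )
}

#' Bundled per-class train/test counts of the reference MeSH dataset
#'
#' The per-class single-label sample counts of the public
#' PubChem-derived MeSH therapeutic-use dataset: 12 classes with training
#' and test counts, the printed test proportion, and the task subgroups
#' each class belongs to. Used for worked-example bookkeeping tests and the
#' `summarize` command.
#'
#' @return Data frame `class_name`, `code`, `train_count`, `test_count`,
#'   `printed_proportion`, `tasks`.
#' @export
table1_fixture <- function() {
  ls <- mesh_label_space("task12")
  data.frame(
    class_name = ls$class_name,
    code = ls$code,
    train_count = c(1139L, 1177L, 788L, 258L, 2398L, 148L, 164L, 267L,
                    101L, 373L, 26L, 115L),
    test_count = c(176L, 347L, 152L, 46L, 776L, 33L, 21L, 47L, 8L, 64L,
                   10L, 18L),
    printed_proportion = c(0.13, 0.23, 0.16, 0.15, 0.24, 0.18, 0.11, 0.15,
                           0.07, 0.15, 0.28, 0.14),
    tasks = c(rep("3,5,12", 3), rep("5,12", 2), rep("12", 7)),
    stringsAsFactors = FALSE
  )
}
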