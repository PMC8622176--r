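#' Feature schema for atom and bond attributes
#'
#' Defines the categorical vocabularies and the encoding layout used to turn
#' atom and bond attributes into fixed-length numeric feature vectors. Nine
#' atom attributes are encoded (atomic number, chirality tag, heavy-atom
#' degree, formal charge, attached hydrogen count, radical electron count,
#' hybridization, aromaticity, ring membership) and three bond attributes
#' (bond type, stereo tag, conjugation). Every categorical vocabulary carries
#' a terminal `"other"` bucket that absorbs out-of-vocabulary values; the two
#' binary atom flags and the bond conjugation flag are encoded as 0/1 scalars.
#'
#' @param encoding_mode `"one-hot"` (default) expands each categorical
#'   attribute into a block of indicator columns; `"integer-index"` encodes
#'   each attribute as the 1-based index of its category.
#' @return An object of class `feature_schema` with elements
#'   `atom_vocabularies`, `bond_vocabularies`, `atom_flags`, `bond_flags`,
#'   `encoding_mode`, and the encoded vector lengths `atom_width` and
#'   `bond_width`.
#' @examples
#' sch <- feature_schema()
#' sch$atom_width
#' @export
feature_schema <- function(encoding_mode = c("one-hot", "integer-index")) {
  encoding_mode <- match.arg(encoding_mode)
  atom_vocab <- list(
    atomic_num    = c(1:100, "other"),
    chirality     = c("none", "cw", "ccw", "other"),
    degree        = c(0:10, "other"),
    formal_charge = c(-5:5, "other"),
    n_hs          = c(0:8, "other"),
    n_radicals    = c(0:4, "other"),
    hybridization = c("S", "SP", "SP2", "SP3", "SP3D", "SP3D2", "other")
  )
  bond_vocab <- list(
    bond_type = c("single", "double", "triple", "aromatic", "other"),
    stereo    = c("none", "cis", "trans", "other")
  )
  atom_flags <- c("aromatic", "in_ring")
  bond_flags <- "conjugated"
  n_cat <- function(v) vapply(v, length, integer(1))
  atom_width <- if (encoding_mode == "one-hot") {
    sum(n_cat(atom_vocab)) + length(atom_flags)
  } else {
    length(atom_vocab) + length(atom_flags)
  }
  bond_width <- if (encoding_mode == "one-hot") {
    sum(n_cat(bond_vocab)) + length(bond_flags)
  } else {
    length(bond_vocab) + length(bond_flags)
  }
  structure(
    list(
      atom_vocabularies = atom_vocab,
      bond_vocabularies = bond_vocab,
      atom_flags = atom_flags,
      bond_flags = bond_flags,
      encoding_mode = encoding_mode,
      atom_width = atom_width,
      bond_width = bond_width
    ),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> mode:", x$encoding_mode,
      "| atom width:", x$atom_width,
      "| bond width:", x$bond_width, "\n")
  invisible(x)
}

# Encode one categorical value against a vocabulary; unseen values land in
# the terminal "other" bucket.
.encode_cat <- function(value, vocab, one_hot) {
  idx <- match(as.character(value), as.character(vocab))
  if (is.na(idx)) idx <- length(vocab)
  if (one_hot) {
    v <- numeric(length(vocab))
    v[idx] <- 1
    v
  } else {
    as.numeric(idx)
  }
}

.encode_fields <- function(attributes, vocabs, flags, mode, what) {
  need <- c(names(vocabs), flags)
  missing <- setdiff(need, names(attributes))
  if (length(missing) > 0) {
    stop(structure(
      class = c("meshgcn_schema_violation", "error", "condition"),
      list(message = sprintf("missing %s attribute(s): %s", what,
                             paste(missing, collapse = ", ")),
           call = sys.call(-1))
    ))
  }
  one_hot <- identical(mode, "one-hot")
  enc <- unlist(lapply(names(vocabs), function(f) {
    .encode_cat(attributes[[f]], vocabs[[f]], one_hot)
  }), use.names = FALSE)
  c(enc, as.numeric(vapply(flags, function(f) {
    isTRUE(as.logical(attributes[[f]])) * 1
  }, numeric(1))))
}

#' Encode atom attributes as a feature vector
#'
#' @param atom_attributes Named list supplying all nine atom attributes:
#'   `atomic_num`, `chirality` (`"none"`, `"cw"`, `"ccw"`), `degree`,
#'   `formal_charge`, `n_hs`, `n_radicals`, `hybridization` (`"S"` ...
#'   `"SP3D2"`), `aromatic` (logical), `in_ring` (logical).
#' @param schema A [feature_schema()].
#' @return Numeric vector of length `schema$atom_width`. Out-of-vocabulary
#'   categorical values activate the `"other"` bucket of their group.
#' @export
featurize_atom <- function(atom_attributes, schema = feature_schema()) {
  .encode_fields(atom_attributes, schema$atom_vocabularies,
                 schema$atom_flags, schema$encoding_mode, "atom")
}

#' Encode bond attributes as a feature vector
#'
#' @param bond_attributes Named list supplying `bond_type` (`"single"`,
#'   `"double"`, `"triple"`, `"aromatic"`), `stereo` (`"none"`, `"cis"`,
#'   `"trans"`), and `conjugated` (logical).
#' @param schema A [feature_schema()].
#' @return Numeric vector of length `schema$bond_width`.
#' @export
featurize_bond <- function(bond_attributes, schema = feature_schema()) {
  .encode_fields(bond_attributes, schema$bond_vocabularies,
                 schema$bond_flags, schema$encoding_mode, "bond")
}

#' The 12 MeSH therapeutic-use classes and their integer codes
#'
#' Returns the ordered label space used throughout: MeSH class names with
#' contiguous 0-based integer codes, and the membership of each class in the
#' 3-, 5- and 12-class single-label task subgroups.
#'
#' @param task One of `"task3"`, `"task5"`, `"task12"` (or `"multilabel"`,
#'   which uses all 12 classes). Restricts the label space to the classes of
#'   that task subgroup.
#' @return A `label_space` object: data frame with columns `class_name`,
#'   `code`, `tasks`.
#' @export
mesh_label_space <- function(task = c("task12", "task3", "task5", "multilabel")) {
  task <- match.arg(task)
  classes <- c("Central Nervous System", "Antineoplastic", "Cardiovascular",
               "Gastrointestinal", "Anti-infective", "Reproductive Control",
               "Lipid Regulating", "Hematologic", "Respiratory System",
               "Anti-inflammatory", "Urological", "Dermatological")
  n <- switch(task, task3 = 3L, task5 = 5L, task12 = 12L, multilabel = 12L)
  out <- data.frame(
    class_name = classes[seq_len(n)],
    code = seq_len(n) - 1L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("label_space", "data.frame")
  out
}
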