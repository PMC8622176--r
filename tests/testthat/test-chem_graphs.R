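test_that("strip_salts keeps salt-free molecules unchanged and removes counter-ions", {
  expect_identical(strip_salts("CCO"), "CCO")
  desalted <- strip_salts("CC(=O)[O-].[Na+]")
  expect_identical(desalted, "CC(=O)[O-]")
  g <- smiles_to_graph("acetate", "CC(=O)[O-].[Na+]")
  expect_equal(g$n_nodes, 4)
  expect_error(strip_salts(""), class = "meshgcn_parse_failure")
  expect_error(strip_salts("not a smiles(("), class = "meshgcn_parse_failure")
})

test_that("strip_salts is idempotent and keeps the largest non-salt fragment", {
  for (s in c("CCO", "CC(=O)[O-].[Na+]", "CCN.Cl", "c1ccccc1C(=O)O.[K+]")) {
    once <- strip_salts(s)
    expect_identical(strip_salts(once), once)
  }
  expect_warning(res <- strip_salts("CCCCCC.CCO"), "largest fragment")
  expect_identical(res, "CCCCCC")
})

test_that("salt stripping and benzene perception agree with an independent toolkit", {
  script <- '
from rdkit import Chem
from rdkit.Chem.SaltRemover import SaltRemover
m = SaltRemover().StripMol(Chem.MolFromSmiles("CC(=O)[O-].[Na+]"),
                           dontRemoveEverything=True)
print(Chem.MolToSmiles(m))
b = Chem.MolFromSmiles("c1ccccc1")
for a in b.GetAtoms():
    print(a.GetAtomicNum(), int(a.GetIsAromatic()), int(a.IsInRing()),
          a.GetDegree(), a.GetTotalNumHs())
'
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE, stderr = FALSE))
  expect_gt(length(out), 1)
  # same desalted structure (canonical forms may differ textually)
  expect_identical(canonical_smiles(strip_salts("CC(=O)[O-].[Na+]")),
                   canonical_smiles(out[1]))
  ref <- do.call(rbind, lapply(out[-1], function(l) {
    as.integer(strsplit(l, " ")[[1]])
  }))
  g <- smiles_to_graph("benzene", "c1ccccc1")
  expect_equal(g$atoms$atomic_num, ref[, 1])
  expect_equal(as.integer(g$atoms$aromatic), ref[, 2])
  expect_equal(as.integer(g$atoms$in_ring), ref[, 3])
  expect_equal(g$atoms$degree, ref[, 4])
  expect_equal(g$atoms$n_hs, ref[, 5])
})

test_that("smiles_to_graph builds heavy-atom graphs with symmetric directed edges", {
  g <- smiles_to_graph("eth", "CCO", test_schema, labels = 0L)
  expect_s3_class(g, "molecular_graph")
  expect_equal(g$n_nodes, 3)
  expect_equal(nrow(g$edge_index), 4)

  r <- smiles_to_graph("methane", "C")
  expect_s3_class(r, "graph_rejection")
  expect_identical(r$reason, "fewer than two nodes")
  expect_s3_class(smiles_to_graph("bad", "xx(("), "graph_rejection")

  b <- smiles_to_graph("benzene", "c1ccccc1")
  expect_equal(b$n_nodes, 6)
  expect_equal(nrow(b$edge_index), 12)
  expect_true(all(b$atoms$aromatic))
  expect_true(all(b$atoms$in_ring))
})

test_that("every directed edge has its reverse with identical bond features", {
  for (g in tiny_dataset(3, 4, seed = 11)) {
    ei <- g$edge_index
    expect_true(nrow(ei) %% 2 == 0)
    key <- paste(ei[, 1], ei[, 2])
    rev_key <- paste(ei[, 2], ei[, 1])
    expect_setequal(key, rev_key)
    for (k in seq_len(nrow(ei))) {
      kr <- which(ei[, 1] == ei[k, 2] & ei[, 2] == ei[k, 1])
      expect_equal(g$edge_features[k, ], g$edge_features[kr, ])
    }
    expect_true(all(ei <= g$n_nodes))
    expect_gte(g$n_nodes, 2)
  }
})

test_that("graph construction is deterministic", {
  g1 <- smiles_to_graph("x", "NC(C)C(=O)Oc1ccccc1", test_schema, labels = 1L)
  g2 <- smiles_to_graph("x", "NC(C)C(=O)Oc1ccccc1", test_schema, labels = 1L)
  expect_identical(g1, g2)
})

test_that("atom featurization activates one category per group and buckets unknowns", {
  carbon <- list(atomic_num = 6, chirality = "none", degree = 4,
                 formal_charge = 0, n_hs = 0, n_radicals = 0,
                 hybridization = "SP3", aromatic = FALSE, in_ring = FALSE)
  v <- featurize_atom(carbon, test_schema)
  expect_length(v, test_schema$atom_width)
  # each categorical group has exactly one active slot
  offset <- 0
  for (vocab in test_schema$atom_vocabularies) {
    expect_equal(sum(v[offset + seq_along(vocab)]), 1)
    offset <- offset + length(vocab)
  }
  weird <- carbon
  weird$atomic_num <- 999
  w <- featurize_atom(weird, test_schema)
  vocab_n <- length(test_schema$atom_vocabularies$atomic_num)
  expect_equal(w[vocab_n], 1)  # terminal "other" bucket of the first group

  arom <- carbon
  arom$aromatic <- TRUE
  expect_equal(sum(featurize_atom(arom, test_schema) != v), 1)

  expect_error(featurize_atom(carbon[-1], test_schema),
               class = "meshgcn_schema_violation")
})

test_that("bond featurization is local to the changed attribute group", {
  single <- list(bond_type = "single", stereo = "none", conjugated = FALSE)
  v <- featurize_bond(single, test_schema)
  expect_length(v, test_schema$bond_width)
  expect_equal(sum(v), 2)  # two one-hot groups active, flag 0

  dbl <- single
  dbl$bond_type <- "double"
  d <- featurize_bond(dbl, test_schema)
  changed <- which(d != v)
  n_type <- length(test_schema$bond_vocabularies$bond_type)
  expect_true(all(changed <= n_type))

  b <- smiles_to_graph("benzene", "c1ccccc1")
  expect_true(all(b$bonds$bond_type == "aromatic"))
  aromatic_slot <- match("aromatic", test_schema$bond_vocabularies$bond_type)
  expect_true(all(b$edge_features[, aromatic_slot] == 1))
})

test_that("filter_and_dedup collapses equivalent structures and logs every drop", {
  res <- filter_and_dedup(data.frame(
    id = c("a", "b"), smiles = c("CCO", "OCC"), stringsAsFactors = FALSE))
  expect_length(res$dataset, 1)
  expect_equal(res$rejections$reason, "duplicate structure")

  res2 <- filter_and_dedup(
    data.frame(id = "t1", smiles = "CCO", stringsAsFactors = FALSE),
    reference = filter_and_dedup(data.frame(id = "r1", smiles = "CCO",
                                            stringsAsFactors = FALSE)))
  expect_length(res2$dataset, 0)
  expect_equal(res2$rejections$reason, "duplicate of reference set")

  res3 <- filter_and_dedup(data.frame(
    id = c("a", "b"), smiles = c("C", "CC"), stringsAsFactors = FALSE))
  expect_length(res3$dataset, 1)
  expect_equal(res3$rejections$reason, "fewer than two nodes")
})

test_that("permuted-atom SMILES of one molecule collapse to a single entry", {
  variants <- c("CC(C)CO", "OCC(C)C", "C(O)C(C)C")
  res <- filter_and_dedup(data.frame(
    id = paste0("v", seq_along(variants)), smiles = variants,
    stringsAsFactors = FALSE))
  expect_length(res$dataset, 1)
  expect_equal(nrow(res$rejections), 2)
})

test_that("summary table reproduces the reference per-class proportions", {
  tab <- table1_fixture()
  tr <- rep(tab$code, tab$train_count)
  te <- rep(tab$code, tab$test_count)
  s <- summarize_dataset(tr, te, mesh_label_space("task12"))
  expect_equal(s$test_proportion_2dp[1:12], tab$printed_proportion)
  expect_equal(s$test_count[13], 1698)
  expect_equal(s$train_count[13], sum(tab$train_count))
  # conservation: per-class counts sum to the inputs
  expect_equal(sum(s$train_count[1:12]), length(tr))
  expect_equal(sum(s$test_count[1:12]), length(te))

  s0 <- summarize_dataset(rep(0L, 100), integer(0), mesh_label_space("task3"))
  expect_equal(s0$test_proportion_2dp[1], 0)
  expect_true(is.na(s0$test_proportion[2]))  # empty class -> absent
})
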