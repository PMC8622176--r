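---
title: "Predicting MeSH therapeutic-use classes from molecular graphs"
author: "meshgcn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MeSH therapeutic-use classes from molecular graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Drugs catalogued in PubChem carry Medical Subject Headings (MeSH)
therapeutic-use annotations — central nervous system agents,
antineoplastics, cardiovascular agents, and so on. `meshgcn` treats the
assignment of these classes as a graph classification problem: a drug
molecule *is* a graph, with atoms as nodes and bonds as edges, and a graph
convolutional network learns to map that graph to its therapeutic class
(or to a set of classes, in the multi-label formulation). Because a
multi-label classifier sometimes predicts classes a drug is not recorded
to have, its "misclassifications" are a source of drug repurposing
hypotheses; the package includes the co-occurrence-network machinery to
mine them.

Four tasks are supported: single-label classification over 3, 5 or all 12
MeSH classes (`task3`, `task5`, `task12`), and a 12-class multi-label
task (`multilabel`).

## From SMILES to attributed graphs

Input molecules arrive as SMILES strings. Processing follows the standard
cheminformatics sequence:

1. **Salt stripping.** Multi-fragment SMILES are reduced to the drug
   fragment by removing fragments that match a curated counter-ion list
   (alkali/alkaline-earth cations, halides, ammonium, water, ammonia,
   nitrate, sulfate, phosphate, mesylate, tosylate, trifluoroacetate),
   matched by canonical SMILES. The stripper never returns an empty
   molecule: if every fragment matches the list, the largest fragment is
   kept. If several non-salt fragments remain, the largest is kept with a
   warning, so the model never sees a disconnected graph.
2. **Featurization.** Nine atom attributes (atomic number, chirality tag,
   heavy-atom degree, formal charge, attached-hydrogen count, radical
   electron count, hybridization, aromaticity, ring membership) and three
   bond attributes (type, stereo tag, conjugation) are encoded, by
   default one-hot per categorical attribute with a terminal
   "other" bucket, binary flags as 0/1 scalars. One-hot is the
   convention of the mainstream graph deep-learning stacks, and the
   "other" bucket makes the encoding total: unseen values never crash
   the featurizer. The default vocabularies (atomic number 1–100, degree
   0–10, charge −5..+5, H count 0–8, radicals 0–4, six hybridization
   states) cover drug-like chemistry.
3. **Filtering and deduplication.** Molecules with fewer than two heavy
   atoms after stripping are rejected (a single-node graph has no edge
   information), and duplicate structures — identified by canonical
   SMILES of the salt-stripped molecule — are collapsed to one record.
   A test set can additionally be deduplicated against a reference
   (training) set. Every drop is logged with its reason; nothing is
   silently discarded.

Parsing, canonicalization and the valence/aromaticity model are delegated
to OpenBabel (via ChemmineOB). The package derives the attributes the
featurizer needs on top of OpenBabel's output: hybridization and
aromaticity from Sybyl mol2 atom types, hydrogen counts from an
explicit-hydrogen conversion, ring membership by bridge detection on the
heavy-atom graph (a bond is in a ring iff it is not a bridge),
tetrahedral chirality from SDF atom parity, and radical counts from the
valence-model shortfall. Two approximations are documented rather than
hidden: the conjugation flag uses an explicit local rule (aromatic bonds;
multiple bonds adjacent to another multiple bond; single bonds joining
two pi-capable ends, at least one of them a true multiple bond), and
double-bond cis/trans tags are read off the generated 2D depiction only
when the input SMILES carries directional markers. Both are faithful for
the chemistry the fixtures generate and for typical drug-like inputs;
exotic conjugation or poly-ene stereochemistry may deviate from other
toolkits' perception.

Hydrogens are attribute counts, not graph nodes: node counts refer to
heavy atoms. Every undirected bond is stored as two directed edges with
identical bond features, which is the layout message-passing layers
expect.

## The model

The classifier stacks three GraphConv blocks, a readout, and two dense
layers. A GraphConv layer updates each node $v$ as

$$h_v^{(t)} = \sigma\!\left(h_v^{(t-1)} W_1^{(t)} +
  \sum_{u \in N(v)} h_u^{(t-1)} W_2^{(t)} + b^{(t)}\right),$$

the node's own features through one weight matrix plus the sum of its
neighbours' features through another, with $\sigma$ = ReLU. This is the
node-level (1-WL) member of the higher-order k-GNN family; bond features
are computed and stored but not consumed by this aggregation, which has
no edge-feature term. Each block is GraphConv → ReLU → GraphNorm, where
GraphNorm normalizes per graph and feature with a learnable mean gate
$\alpha$:

$$\hat h = \frac{h - \alpha\,\mu_g}{\sqrt{\mathrm{E}_g[(h-\alpha\mu_g)^2]
  + \varepsilon}}, \qquad \text{out} = \gamma\,\hat h + \beta.$$

Statistics never mix nodes of different graphs. The default conv widths
are 256 → 512 → 1024; the final width of 1024 is the graph embedding
length. A sum readout pools node features into that embedding (mean and
max are available; the readout is not dictated by the architecture's
provenance, and sum is the default because it preserves size
information). FC1 (1024 → 512 by default) with ReLU and dropout, then FC2
with 3/5/12 outputs. Single-label heads emit log-softmax rows trained
with class-weighted negative log likelihood; the multi-label head emits
raw scores trained with the multi-label soft margin loss, thresholded at
0.5 (probability scale) at prediction time.

### Numerical choices

* **Initialization.** Uniform fan-in weights under a recorded seed.
  GraphNorm starts with the mean gate closed ($\alpha = 0$, $\gamma = 1$,
  $\beta = 0$). This departs from the common $\alpha = 1$ start
  deliberately: with a fully open gate, each graph's normalized features
  sum to exactly zero, so a sum readout produces an identically zero
  embedding and gradient flow to the convolution weights is blocked at
  the first step. With few optimizer steps per epoch (one batch covers a
  whole fold at batch size 256), that saddle costs real convergence
  time; starting the gate closed avoids it, and the gate remains free to
  open during training.
* **GraphNorm scale.** The denominator uses the mean square of the gated
  deviation, $\mathrm{E}_g[(h-\alpha\mu_g)^2] + \varepsilon$ with
  $\varepsilon = 10^{-5}$; a single-node graph therefore maps to
  $\beta$.
* **Losses.** Weighted NLL uses the standard weighted-mean convention
  $\sum_i w_{y_i} \ell_i / \sum_i w_{y_i}$. The soft margin loss is
  computed with the numerically stable log1p/abs formulation.
* **Determinism and invariance.** With dropout off, the forward pass is
  deterministic; graph-level outputs are invariant to node relabelling
  and to batch composition up to floating-point summation order (BLAS
  and sparse products re-associate sums, so equality holds to ~1e-15
  relative, and the tests assert it at 1e-12). All randomness — weight
  init, batching, dropout, splits, fixtures — flows from explicit seeds,
  so a (data, config, seed) triple fully determines a checkpoint.
* **MCC convention.** The binary Matthews correlation returns 0 when its
  denominator vanishes (e.g. a constant predictor); the multiclass form
  is the covariance (R_k) generalization, which reduces exactly to the
  binary formula at two classes.

## Training protocol

Class imbalance is handled by normalized inverse-frequency weights
$w_i = (1/c_i)\big/\sum_k (1/c_k)$ with $c_i$ the class counts, so
$\sum w_i = 1$ and rare classes weigh more. Weights are computed from the
training portion of each fold only (never from held-out data) and are
applied to the single-label NLL; the multi-label loss is unweighted by
default, with a config switch to extend weighting to it.

Per-task hyperparameters: learning rate 5e-4 with Adam, 3 conv + 2 dense
layers for every task; batch size 256 and dropout 0.4 after FC1 for the
3- and 5-class tasks; batch size 512 and dropout 0.25 for the 12-class
and multi-label tasks. The epoch count is configurable (default 300, no
early stopping); the loss history is recorded per epoch and every run can
write a checkpoint carrying the resolved config and seed.

Cross validation uses 5 folds: stratified for single-label tasks (per
class, fold sizes differ by at most one) and second-order iterative
stratification for the multi-label task. The iterative splitter describes
each sample by its label singletons and unordered label pairs, repeatedly
takes the evidence with the fewest remaining samples, and assigns each
such sample to the fold with the greatest remaining desire for that
evidence, breaking ties by largest remaining fold capacity and then by
seeded uniform choice. Balancing pairs alone leaves per-label marginals
loose, which is why singletons participate as first-order evidence. Fold
metrics are aggregated as mean ± sample standard deviation (n − 1); the
final fold is the designated representative fold for confusion matrices.

## Evaluation

Single-label reports carry accuracy, balanced accuracy (mean per-class
recall), multiclass MCC, and one-vs-rest AUROC and average precision
averaged with class-support weights; classes absent from the evaluation
fold are excluded from the ranking-metric averages and logged. AUROC uses
the trapezoidal rule with midrank tie handling (delegated to pROC);
average precision is the thresholded sum
$\sum_n (\mathrm{REC}_n - \mathrm{REC}_{n-1})\,\mathrm{PRE}_n$, which
makes it invariant to monotone score transforms.

The multi-label "accuracy" is label-wise binary accuracy at the 0.5
threshold averaged over classes — the reading consistent with a
0.5-threshold convention at roughly 1.2 labels per molecule — and the
stricter subset exact-match accuracy is reported alongside it. F-beta
uses beta = 2 (recall-weighted) with support-weighted one-vs-rest
averaging by default; micro and per-sample averaging are available by
flag since the averaging convention is a genuine free choice.

## Repurposing networks

For the multi-label task, the true and predicted label sets each induce a
co-occurrence network: MeSH classes are nodes and every drug contributes
one co-occurrence to each unordered pair of its classes (a 3-label drug
contributes three pair counts; single-label drugs contribute none). Edge
display widths follow $w = \tfrac12 \log_2(N + 1)$. Diffing the two
networks separates pairs the model failed to learn (true-only) from pairs
where it may have learnt something new (predicted-only) — the latter is
where repurposing candidates live. At the drug level, any molecule whose
predicted set contains a class absent from its recorded set becomes a
candidate, with the novel and lost classes reported; candidates are
ranked by novel-class count, then id. Validation of a candidate remains
literature work, out of the package's scope.

## The synthetic fixture generator

Every pipeline stage is testable without external data through a
labeled-SMILES generator. Each class is tied to a chemically meaningful
substructure motif — branched alkane, chloroaromatic, carboxylic acid,
primary amine, ether, thiol, nitrile, ketone, fluoroaromatic, pyridine,
sulfonamide, acetamide — decorated with random alkyl chains; a
configurable fraction of records carries `.[Na+]` or `.Cl` counter-ions;
class ratios control imbalance; multi-label molecules draw a primary
class and add others by a pairwise co-occurrence matrix, concatenating
the motifs of all their classes. Generated molecules are kept canonically
unique within a run so deduplication does not shrink the dataset, and
generation is deterministic under the fixture specification's seed.

Motif-based generation was chosen over random graph rewiring so that the
class signal is chemically real and learnable by a three-layer
message-passing network. What passing tests on this fixture show is that
the pipeline is correct and that the model can extract substructure
signal; what they do not show is performance on real pharmaceutical
chemistry, whose class boundaries are far noisier, larger-ringed, more
stereochemically rich, and not linearly tied to single motifs. Runs
against the public PubChem-derived MeSH sets remain the external check
for that.

### Problem sizes used in the shipped checks

The packaged tests and the acceptance script exercise learning at desk
scale, chosen as the smallest sizes at which the claims are meaningful: a
300-molecule, 3-class fixture (100 per class, salt fraction 0.1, seed 0)
for 5-fold cross validation at 30 epochs, and a 30-molecule subset
overfit for 200 epochs to verify model capacity. The separable fixture
converges well within those epochs; the package default of 300 epochs is
intended for real, noisier data.

## Embedding diagnostics

`extract_latents()` returns each drug's FC1 activation vector (dropout
off); `dummy_embedding()` runs the untrained architecture with all
weights 1, biases 0, and GraphNorm set to the identity
($\gamma = 1, \beta = 0, \alpha = 0$, since the statistics of an
all-ones network are degenerate), showing the pre-training distribution
of the graph signal. Either embedding can be projected to 2D with
`project_2d()`, a pluggable projector with a fixed-seed contract: the
default is nonmetric multidimensional scaling on Euclidean distances from
a principal-coordinates start, `"pca"` is available, and any function
`(matrix, seed) -> n x 2` can be plugged in (UMAP or t-SNE
implementations drop in directly where available). Projector
hyperparameters beyond the seed are deliberately left to the plug-in.

## Known limitations

* GraphConv here is the node-level k = 1 variant; set-based k ≥ 2
  aggregation, edge-feature message passing and attention layers are out
  of scope.
* Bond features are featurized and stored but unused by the default
  layer; they await layer types with edge-feature terms.
* Chirality and bond-stereo perception depend on what OpenBabel exposes
  (SDF parity, depiction geometry); molecules with complex stereo may be
  tagged `other`/`none` where RDKit would assign a tag.
* Training runs on CPU with BLAS matrix products; it is intended for
  datasets in the thousands of molecules, not millions.

## A worked run

```{r example}
library(meshgcn)

schema <- feature_schema()
recs <- generate_single_label(fixture_spec(n_per_class = 100, n_classes = 3,
                                           salt_fraction = 0.1, seed = 0))
ds <- filter_and_dedup(recs, schema)$dataset

cfg <- train_config("task3", epochs = 30, seed = 1)
report <- gcn_cross_validate(cfg, ds)
print(report)

fit <- gcn_train(cfg, ds, report$split, fold = 0,
                 checkpoint_path = "fold0.rds")
emb <- extract_latents(fit$model, ds)
xy <- project_2d(emb, seed = 1)
```
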