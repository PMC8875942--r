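---
title: "Predicting lncRNA-miRNA associations from a heterogeneous molecular network"
author: "dwlmi authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lncRNA-miRNA associations from a heterogeneous molecular network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwlmi)
```

## The problem

Long non-coding RNAs (lncRNAs) regulate gene expression in part by
interacting with microRNAs (miRNAs), and cataloguing which lncRNA-miRNA
pairs interact is expensive to do experimentally. `dwlmi` frames the task as
link prediction on a single undirected heterogeneous network whose vertices
are five kinds of biological entities — lncRNA, miRNA, disease, protein and
drug — and whose edges span nine curated association classes (lncRNA-miRNA,
protein-miRNA, disease-miRNA, disease-lncRNA, protein-lncRNA,
disease-protein, protein-drug, disease-drug, protein-protein). The premise
is that two kinds of evidence jointly predict an interaction:

* **behavior information** — where a node sits in the association network,
  learned by DeepWalk from truncated random walks; and
* **attribute information** — what the node intrinsically is: its sequence
  composition, its position in a disease ontology, or its chemical
  structure.

Each node receives a 64-dimensional attribute vector and a 64-dimensional
behavior vector; their concatenation is the node's 128-dimensional
representation. A candidate pair is the 256-dimensional concatenation
(lncRNA half first) of the two node representations, scored by a random
forest trained on known associations versus an equal number of sampled
non-associations.

## Attribute vectors

**Sequences (lncRNA, miRNA, protein).** A sequence of length $L$ has
$L - k + 1$ overlapping $k$-mers; with $k = 3$ over a four-letter alphabet
there are $4^3 = 64$ possible words, and the attribute vector holds each
3-mer's count divided by $L - 2$, so entries sum to 1. RNA is mapped
U$\to$T before counting. Protein sequences are first reduced to four
physicochemical classes — (A,G,V), (I,L,F,P), (Y,M,T,S,C,W),
(H,N,Q,D,E,K,R) — which is the only way a protein admits the same 64-slot
3-mer space; the grouping is a fixed, configurable table, and unknown
residues fall into the largest class with a warning. Sequences too short to
form a 3-mer keep a zero attribute vector rather than being dropped.

**Diseases.** Each disease $D$ induces a DAG $DAG(D) = (D, N(D), E(D))$
from its positions in a MeSH-style hierarchy: $N(D)$ is the ancestor
closure, $E(D)$ the child-to-parent links. Every ancestor $t$ contributes

$$D_D(t) = \begin{cases} 1 & t = D\\
\Delta \cdot \max\{D_D(t') : t' \text{ a child of } t\} & t \neq D
\end{cases}$$

with decay factor $\Delta = 0.5$ by default, so a node's contribution is
$\Delta^h$ for its shortest hop distance $h$ from $D$. The semantic value
is $DV(D) = \sum_{t \in N(D)} D_D(t)$ and two diseases compare by the
Jaccard-style similarity

$$S_1(i,j) = \frac{\sum_{t \in N(i) \cap N(j)} \left(D_i(t) + D_j(t)\right)}
{DV(i) + DV(j)},$$

which is symmetric, lies in $[0,1]$, and is 1 on the diagonal. The package
ships a fixed worked-example pair of DAGs (systemic lupus erythematosus and
acne vulgaris) whose semantic values are exactly 2.5 and 2.375 at
$\Delta = 0.5$ and whose similarity is $0.375 / 4.875 \approx 0.0769$;
these anchor the regression tests. A disease's raw attribute vector is its
row of the similarity matrix — the only intrinsic numeric object the method
constructs for diseases.

**Drugs.** A drug's raw attribute vector is a hashed circular (Morgan-type,
ECFP) binary fingerprint of its structure, radius 2 and 1024 bits by
default, computed from SMILES with OpenBabel and OR-folded to the
configured width. Unparseable structures are dropped with a warning and the
node keeps a zero vector.

**Dimension unification.** Disease similarity profiles and drug
fingerprints do not have 64 dimensions, so each is passed through a stacked
autoencoder: rectifier encoder $h = \max(0, Wx + p)$ and rectifier decoder
trained stage-by-stage to minimise mean squared reconstruction error, with
stage sizes input $\to 256 \to 64$ for inputs wider than 256 and
input $\to 64$ otherwise. Training is full-batch gradient descent with
momentum 0.9 and a step-halving guard: an epoch that increases the loss by
more than 1% is rolled back with the learning rate halved, which keeps the
loss trace monotone up to that tolerance and avoids divergence without any
tuning. The decoder bias starts at the feature means so no output unit is
born dead under the rectifier. k-mer vectors are already 64-dimensional and
pass through unchanged by default (`sae_on_kmer` re-encodes them if set).

## Behavior vectors (DeepWalk)

All nine edge classes are walked identically as one unweighted, undirected
simple graph. The corpus is built in $\gamma$ passes; each pass shuffles
the vertex order and starts one truncated random walk of length $t$ per
vertex, each step uniform over the current node's neighbours. A skip-gram
model then maximises the likelihood of each walk's window-$w$ context given
the centre node's vector. Defaults: $d = 64$ (so attribute + behavior gives
the 128-d node vector), $w = 5$, $\gamma = 10$, $t = 40$, 5 epochs.

Two implementation choices matter:

* **Negative sampling, not hierarchical softmax.** The skip-gram objective
  is optimised with 5 negative samples per centre-context pair drawn from
  the unigram$^{0.75}$ distribution. This is the standard modern choice for
  DeepWalk-family embeddings, and a single-threaded deterministic
  implementation is simple; hierarchical softmax is not provided.
* **Determinism.** Walk generation and training use their own
  platform-independent xorshift generator seeded from the parameters, run
  single-threaded, so embeddings are bitwise reproducible. There is no
  multi-worker mode.

Isolated vertices (possible after edge masking) still emit length-one walks
but acquire no centre-context pairs; they receive the zero fallback vector
so that every candidate pair remains scoreable.

## Evaluation protocol

`kfold_cv()` follows the cross-validation protocol end to end. Positives
are all lncRNA-miRNA edges; an equal number of negatives is sampled
uniformly once per run from the non-edges; the pooled pairs are split into
$k = 5$ near-equal disjoint folds. In each fold the test positives are
removed from the graph and only 80% (`keep_fraction`, floor-rounded) of the
remaining lncRNA-miRNA training edges are kept for embedding — DeepWalk is
re-trained per fold on this masked graph, so no test edge influences any
behavior vector. Whether the 80% mask covers only the lncRNA-miRNA class
(default) or all classes is a config switch (`mask_scope`). Attribute
vectors use no edge information, so they are computed once per data set and
reused across folds. Metrics at the 0.5 score threshold are accuracy,
sensitivity, specificity, precision and the Matthews correlation
coefficient, plus the areas under the ROC curve (computed as the
tie-corrected Mann-Whitney statistic, identical to trapezoidal integration)
and the precision-recall curve; the report gives per-fold rows and
mean $\pm$ sample standard deviation. The report also retains, per fold,
the test pairs, training pairs and embedded edges so the no-leakage
property is directly auditable.

`rank_candidates()` implements the case-study protocol: every edge incident
to a query node is removed, the model is re-trained on the remaining
positives plus an equal negative sample, every opposite-type node is scored
as a partner and returned in descending order (top-20 extraction
supported).

## Synthetic fixtures

`gen_network()` emulates all four input kinds so the full pipeline runs
with no downloads. The lncRNA-miRNA layer is a planted block model — by
default 40 lncRNAs and 40 miRNAs in 4 blocks with within-block association
probability 0.5 and between-block probability 0.02 — because shared network
neighbourhoods plus correlated attributes are exactly the mechanism the
method exploits. The other eight classes are Erdős–Rényi scaffolding at
small densities (0.05–0.08). With `couple_attributes` (default on) each
block biases its members' nucleotide composition (preferred base
probability 0.55 versus 0.15), emulating the real-data situation in which
interacting molecules share sequence-composition signal; disease DAGs and
drug SMILES are block-agnostic. Generated hierarchies always include the
fixed worked-example DAG pair. Problem sizes throughout the tests (and the
two-block embedding benchmark: 30+30 nodes, $p = 0.5/0.02$) were chosen so
a full cross-validation completes in seconds to a couple of minutes on one
CPU.

What passing on fixtures does and does not show: it demonstrates the
mechanism — planted association structure is recovered well above the
matched null (equal within/between probabilities), with no fold leakage and
full determinism — but fixture graphs are two orders of magnitude smaller
than the curated databases, have no hubs or degree heterogeneity, and their
attribute signal is synthetic. Fixture performance numbers are therefore
not comparable to performance on real curated extracts.

A quantitative note on the planted-signal ceiling: with these default
probabilities, block parity is nearly the only signal available for held-out
pairs (within a block, edge presence is an independent coin flip), and a
classifier with perfect block knowledge would reach an AUC of only about
0.87; the random forest on concatenated pair features realises roughly
0.70–0.74 of mean AUC at this training-set size. The separation from the
null (≈ 0.48) is the meaningful property; the absolute level is bounded by
the fixture's information content, not by the implementation.

## Numerical and design choices

* Identifier unification is exact string match after lowercasing and
  whitespace stripping — deterministic and auditable, no fuzzy aliasing.
* The graph is simple and undirected; duplicate edges across databases
  collapse to one edge with a merged provenance list; self-pairs are
  dropped at ingestion with a logged count.
* Isolated nodes are kept everywhere (masking never changes the node set).
* The rectifier in the autoencoder equations is applied to the affine
  pre-activation, $\max(0, z)$ with $z = Wx + p$ — the conventional
  reading.
* Negatives are sampled once per CV run and folded with the positives
  (per-fold class balance ≈ 1:1) rather than re-sampled per fold.
* Random-forest: 100 trees, default impurity splitting, no depth cap; the
  positive-class score is the fraction of trees voting positive;
  classification threshold 0.5.
* Every stage seed derives from the master seed by a stable string hash of
  the stage name, so adding a stage never shifts another stage's stream and
  a manifest rerun is bitwise identical.
* Ties in ranking and ROC computation are handled by average ranks
  (Mann-Whitney tie correction); the PR curve is anchored at recall 0 with
  the first threshold's precision and integrated trapezoidally.

## Known limitations

* The drug module consumes SMILES only; no structure normalisation beyond
  what OpenBabel performs, and no 3D features.
* Disease attribute vectors depend on the disease set (a similarity-matrix
  row), so adding diseases changes all disease attributes.
* Walks are untyped; no metapath constraints or edge weights.
* The case-study protocol re-trains per query, which is accurate but not
  batched for many queries.
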