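---
title: "Predicting disease comorbidity with a subgraph-position-aware graph transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting disease comorbidity with a subgraph-position-aware graph transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two diseases are comorbid when they co-occur in the same patients more often
than independence would predict; clinically this is quantified by the
relative risk (RR) of co-occurrence. On the human interactome (HI) — the
network of protein–protein interactions — each disease corresponds to a
*disease module*: the set of nodes whose genes are associated with it.
The premise of network medicine is that the topology of these modules
(their overlap and their proximity in the network) carries the molecular
signal behind comorbidity.

`tspe` frames comorbidity prediction as binary classification of disease
*pairs*. The two modules of a pair are two sets of node tokens; an
encoder–decoder transformer attends over them and a scoring head turns the
decoder output into a probability that the pair is comorbid. Labels come
from thresholding RR: under the permissive **RR0** regime a pair is
positive iff RR > 0, under the conventional **RR1** regime iff RR ≥ 1.

## The model

**Input representation (SPE).** Nodes carry no features in the HI, so the
per-node representation is built from the graph and the disease labels:

1. *Node embedding* `M` (`N × 64`): skip-gram over biased second-order
   random walks with neutral parameters `p = q = 1` and window 2 — an
   ordinary random walk, embedding local connectivity.
2. *Laplacian positional encoding* (LPE): the eigenvectors of the
   normalized Laplacian `L̃ = I − D^{−1/2} A D^{−1/2}` for the `k = 64`
   smallest eigenvalues *strictly above zero*. Zero eigenvalues only count
   connected components, so they are excluded; the small nonzero
   eigenvectors encode cluster structure.
3. *Graph encoder embedding* (GEE): `Z = A W`, where `W[i, j] = 1/n_j` if
   node `i` belongs to disease `j` of size `n_j` (else 0). Entry
   `Z[i, j]` is the fraction of disease `j`'s module adjacent to node `i`
   — a direct, label-aware connectivity profile. Its width equals the
   disease count `K`, so it is compressed to the `d = 8` leading left
   singular vectors (GPE).
4. *Assembly*: `E = [(M + LPE), GPE]`, the subgraph positional encoding
   (SPE), giving model dimension 72. The ablation variants are `NoPE`
   (`E = M`, d = 64) and `LPE` (`E = M + LPE`, d = 64).

Eigenvector and singular-vector signs are underdetermined; every column is
sign-fixed so its largest-magnitude entry is positive. This replaces the
random sign-flipping sometimes used as augmentation and makes every
encoding bit-reproducible (sign augmentation could be layered on in
training, but is off by default and not implemented as a separate option).

**Transformer.** The first module of a pair feeds a standard transformer
encoder (3 layers, 8 heads, post-layer-norm, dropout 0.2 on each sublayer
output); the second feeds the decoder, whose self-attention is *unmasked*
— subgraphs have no token order, so no causal structure is imposed — plus
cross-attention to the encoder memory. No positional order is injected
anywhere: the network is permutation-equivariant over tokens, and tests
assert the final probability is invariant to token order on both sides.
The feed-forward width is the one architectural quantity the reference
configuration leaves open; the package defaults to `2·d_model` — at the
problem sizes it targets, the conventional `4·d_model` only adds
memorization capacity (and compute) without measurable benefit, and the
width is exposed in `model_config()` for users who want it.

**Scoring head.** With `X` (`d_model × n_B`) the decoder output, squared
column norms are softmax-normalized into a score simplex `s`, the columns
are pooled as `ŷ' = Σ_j s_j X_{:,j}`, and a linear + sigmoid read-out
yields the probability. Training minimizes binary cross-entropy in the
numerically stable fused logit form, with Adam at learning rate 1e-4 and
batch size 20. The optimizer is not part of the published configuration;
Adam is the transformer default and is recorded in the run config.

The neural core (forward, hand-derived backward, Adam) is compiled
RcppArmadillo, single-threaded and driven entirely by explicit seeds, so a
training run is bit-reproducible. The backward pass is validated against
finite differences in the test suite.

## Evaluation protocol

Stratified 10-fold cross-validation at the *pair* level: each fold keeps
the class proportions within one pair of the global share, and every pair
is tested exactly once. Inside each training fold, a stratified 10%
validation split drives early stopping (patience on validation loss) and
checkpoint selection; the classification threshold is the Youden point
(maximizing sensitivity + specificity − 1) *of the validation scores of
the selected checkpoint*, so test labels never influence any operating
choice. Reported per fold: ROC AUC, AUPRC (step-interpolated average
precision), accuracy at the Youden threshold (accuracy at 0.5 is emitted
alongside), and MCC at the Youden threshold. Aggregates are mean ± sd,
plus the same after dropping the single fold most deviant from the mean
on the primary metric (ROC AUC) — the outlier rule is a package decision,
as no standard definition exists.

Because splits are by pair, a disease can appear in both training and test
pairs; this is the inherited protocol of the benchmark lineage and is the
reason the harness makes no generalization claim across diseases.

The ablation harness (`compare_encodings()`) runs NoPE/LPE/SPE under
*identical* fold plans, per-fold initialization seeds, and batch orders,
so metric differences isolate the encoding; it emits per-fold paired
differences and paired t-tests.

## The synthetic benchmark

The clinical RR data behind the published benchmarks is not publicly
deposited, so the package ships a generator that emulates its structure at
desk scale and makes every stage testable end-to-end:

* **Graph**: a stochastic block model with 8 equal communities over 400
  nodes; the largest connected component is kept. Defaults `p_in = 0.25`,
  `p_out = 3e-4` were chosen once, by design: dense modules with a
  *sparse* community meta-graph make between-module path lengths vary
  widely, which is what gives the proximity signal its spread. (Denser
  meta-graphs collapse all between-community distances to ≈ 2 hops and
  the planted signal drowns in score noise.)
* **Disease modules**: 20 modules of 8–25 nodes, 80% drawn from a home
  community (cycling over communities), the rest uniform; modules may
  overlap, exercising multi-disease membership in `W`.
* **Pair scores**: latent signal = Jaccard overlap + proximity, with
  proximity = 1 − d_AB / max(d), where d_AB is the symmetrized mean
  minimum shortest-path distance between the modules (the canonical
  disease-module separation measure; unreachable pairs count as
  diameter + 1) and max(d) is the largest separation among the emitted
  pairs. The RR-like score is `2·signal + N(0, 0.2)`. Identical modules
  score exactly 4; the most separated disjoint pair scores ≈ 0. Under the
  defaults the RR1 labels keep the minority class above 20% and the
  scores track the latent signal with Spearman rank correlation ≈ 0.85.
  The additive noise bounds what any topology-only predictor can recover:
  the acceptance script reports the AUC of the *noise-free* signal
  against the labels (`signal_auc_ceiling`, ≈ 0.9), the effective ceiling
  of the benchmark, alongside a disease-marginal baseline
  (`marginal_baseline_roc_auc`, near chance) marking what pure
  disease-identity memorization achieves.

What the generator does *not* emulate: scale (13k nodes, 153 diseases in
the real HI), degree heterogeneity (SBM blocks are near-regular, real
interactomes are scale-free), curation biases, and clinically estimated
RR with patient-level uncertainty. Passing the synthetic acceptance runs
therefore demonstrates that the pipeline recovers a planted
topology-driven comorbidity signal — not clinical performance.

## Numerical and design choices

* Zero eigenvalues are detected at relative tolerance `1e-8` (scaled by
  the spectral radius). Zero-degree nodes get `D^{−1/2} = 0`, making an
  isolated node's Laplacian row the identity row.
* Eigendecompositions and SVDs are dense (`eigen`, `svd`); the graphs the
  package targets (hundreds to a few thousand nodes) are well inside the
  dense regime, so no iterative sparse solver path is provided.
* GEE multiplies the *plain adjacency* matrix; Laplacian-normalized
  variants exist in the literature but the adjacency form is the stated
  method here.
* Walk length 30, 10 walks per node, 5 skip-gram epochs, 5 negatives:
  standard node2vec-tooling defaults, recorded in `walk_config()` so they
  are auditable; only `p`, `q`, window and dimension are method-pinned.
* Ties in the Youden scan break toward the smaller threshold; thresholds
  are midpoints between adjacent distinct scores plus one cut below and
  above all scores. MCC returns 0 when a confusion marginal is zero.
* The first-listed disease of a (canonicalized, smaller-index-first) pair
  feeds the encoder. The architecture is not symmetric in the pair order;
  single-order inference is the default and symmetric averaging was
  deliberately left out to keep the published inference path.
* Padded tokens, when batches are assembled with masks, are excluded from
  attention as keys and dropped before the scoring head, so padding
  provably cannot change `s` or `ŷ'` (asserted by test).
* Per-stage seeds are derived from one global seed by stable hashing of
  stage names, so adding a stage never shifts another stage's randomness.

## Training in the small-sample regime

The clinical benchmark this method was built for has ~10,000 labelled
pairs; the desk-scale synthetic bundle has 190. Three training-loop
choices address that gap, all exposed in `train_run()` /
`model_config()` and all on the training side (the published model
settings — layers, heads, dropout, learning rate, batch size, validation
fraction — are kept):

* **Pair-order augmentation** (`augment_swap`): the encoder/decoder
  assignment makes the architecture asymmetric in the pair order, while
  comorbidity is symmetric. Training on both orientations of every
  training pair (added *after* the validation split, so no orientation of
  a validation pair is trained on) imposes that symmetry as a prior. This
  matters enormously at small n: without it the model converges to
  disease-identity memorization — its per-fold test AUC pattern is
  reproduced almost exactly by a predictor that only knows each disease's
  mean training label — and held-out AUC hovers near chance; with it the
  model is forced toward genuinely pairwise features.
* **Checkpoint burn-in** (`min_epochs`): with a ~17-pair validation split
  the untrained model's loss (≈ log 2 ≈ 0.693) is hard to beat by noise
  in the first epochs at learning rate 1e-4, so "best validation loss"
  otherwise freezes on an epoch-1 checkpoint in a majority of folds.
  Epochs below the burn-in are logged but not checkpoint-eligible.
* **A fixed epoch budget** (24 epochs of the doubled, augmented training
  set, patience disabled by setting it to the budget) for the shipped
  experiments: validation loss on this problem bottoms out at roughly
  700-900 gradient steps, and a fixed budget makes runtime
  deterministic. Held-out AUC still creeps up slowly beyond this budget,
  so users with more compute should raise `max_epochs` first.

Checkpoint selection and the Youden threshold still rest on ~17
validation pairs, the dominant source of fold-to-fold variance; this is
intrinsic to the scaled-down setting, and per-fold metrics should be read
with that in mind (a 19-pair test fold has an AUC standard error of
roughly 0.1).

The shipped acceptance experiments run the default 400-node bundle with
20 diseases (190 pairs), 10-fold cross-validation, the SPE and NoPE
variants under shared fold plans and initializations, and three replicate
seeds.

## Known limitations

* No GPU or multi-threaded path; the compiled core targets desk-scale
  experiments.
* SPE requires disease labels; unlabeled graphs can only use NoPE/LPE.
* The pair-level split protocol measures in-distribution ranking, not
  cross-disease generalization.
* `k` (LPE width) must equal the embedding dimension because the two are
  added; the assembly errors out otherwise rather than padding silently.
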