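---
title: "Predicting polyester biodegradability from monomer structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting polyester biodegradability from monomer structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput enzymatic assays can call a polyester *biodegradable* or
*non-biodegradable* within a day: the polymer film is incubated with a
lipase, ester hydrolysis releases diacid monomers, and the resulting pH drop
is read out through a pH-sensitive fluorophore. A polymer is called
biodegradable when the endpoint pH (18.5 h after enzyme addition, by
default) lies below 5.4. `polybiodeg` turns a table of such calls — one row
per polymer, identified only by its monomer pair — into a structure-based
classifier that can screen candidate polyesters *in silico*, together with
the safeguards that make such a small-data model usable: an applicability
domain that refuses predictions outside the model's competence, and
atom-level Shapley explanations that tie predictions back to chemistry.

The package ships the 48-polyester study dataset (25 biodegradable /
23 not, 20 polymers shared with an external literature screen) and a
synthetic-library generator with planted structure→label rules, so every
stage can also be exercised against known ground truth.

## From monomer pair to trimer

A polyester is a distribution of chain lengths, not one molecule. The model
input is a fixed *trimer* representation: the repeat unit, built by
condensing the diol with the diacid/diester (or by opening a lactone ring),
is joined head-to-tail three times and capped with one hydroxyl and one
carboxylic-acid end group. Three units is the shortest chain in which a
path-limited fingerprint cannot span the whole backbone in a single
feature, while still containing both chain ends and internal ester linkages
— the two motifs most relevant to enzymatic hydrolysis.

Choices made where the chemistry is genuinely underdetermined:

* **Branched polyols** (glycerol, diglycerol, sorbitol, xylitol) react
  through their two highest-ranked primary hydroxyls; pendant hydroxyls
  stay free. The polymers are treated as strictly linear; real samples
  surely contain branching, which this representation ignores.
* **Asymmetric monomers** are incorporated in a fixed head-to-tail
  orientation (lowest-canonical-rank reactive site first).
* **PEG400** is represented as H–(OCH~2~CH~2~)~9~–OH: nine ethylene-oxide
  units give 414 g/mol, the closest chain to the nominal 400. The registry
  is a plain CSV, so the constant is editable.
* **Lactide** opens into a two-lactic-unit repeat (one ring-ester bond is
  broken); the lactide–glycolide copolymer is built as a strictly
  alternating composite repeat. Stereochemistry is ignored throughout.
* **Eliminated molecules**: methanol per ester bond for dimethyl esters
  (2 heavy atoms per bond), water for diacids (1), nothing for
  ring-opening. Heavy-atom bookkeeping is asserted in the test suite for
  every polymer in the dataset.

## Featurisation

Two feature families are supported.

**Hashed subgraph fingerprints.** Every connected subgraph of 1 to
`max_path` bonds of the heavy-atom graph — linear *and* branched, in the
style of the classic Daylight/RDKit path fingerprint — is reduced to a
canonical fragment string (minimal DFS string over all traversals, so the
encoding is isomorphism-invariant), hashed with FNV-1a, and folded into
`n_bits` bits, two bits per fragment (double hashing). Only heavy atoms are
represented; aromatic atoms and ring bonds are coded in lowercase/`:`. The
implementation keeps, per molecule, the full map from every set bit to the
fragment string(s) and atom set(s) that set it. That trace is what makes
bit-level model explanations chemically interpretable, and it also exposes
*bit collisions* — chemically distinct fragments sharing a bit — instead of
hiding them. Fingerprint length (2048/4096/8192) and maximum path length
(4/5/6) are tuned inside the cross-validation, jointly with the model
hyperparameters.

**Descriptors.** The physicochemical battery of the chemistry toolkit
(OpenBabel properties: logP, TPSA, molar refractivity, H-bond counts, ...)
plus element, ring and functional-group counts. The battery is
toolkit-dependent; the package records its size (24 with the current
toolkit) rather than asserting any particular count.

**Zero-variance filtering with train/apply asymmetry.** Constant features
are dropped using a mask *learned on the training portion of each
cross-validation split and applied, never re-learned, to the corresponding
held-out portion*. Filtering once across the whole dataset before
cross-validation would leak the test folds' feature support into training;
the per-fold mask is the defensible reading and is the default (a flag
restores the whole-dataset variant). The mask is applied to fingerprints as
well as descriptors. Besides leakage hygiene this matters mechanically: the
random-forest backend draws `mtry` candidate features per split without a
fallback search, so feeding it thousands of constant bits would silently
degenerate the trees.

## Benchmarking protocol

`nested_cv()` runs stratified 5×5 nested cross-validation. The inner loop
grid-searches featurisation and model hyperparameters jointly and selects
by inner-fold accuracy (ties resolve to the first configuration in
grid-listing order); the outer loop estimates generalisation. Per-fold
class counts differ from the global ratio by at most one sample, and every
sample is predicted exactly once across outer folds — both are asserted.

* Random forest: probability forests (`ranger`) over 100/200/500 trees,
  depth 2/4/6, 2/5/10 split candidates.
* Neural network: a minimal multilayer perceptron written for this package
  — tanh hidden layers ((8,0), (16,0), (8,4), (16,8); a 0 denotes no second
  layer), sigmoid output, mean log-loss, full-batch L-BFGS with an
  iteration cap of 500/1000/1500 and no weight penalty. For fingerprint
  inputs with far more bits than samples the first layer is parameterised
  in the span of the training rows (inputs are mapped to kernel features
  `k(x) = X_train x`). Gradients of a first layer always lie in that span,
  so the reachable function class is unchanged; fitting cost becomes
  independent of the bit-space size, and predictions depend on a new
  molecule only through its fingerprint overlaps with the training set.

Metrics: accuracy, precision, recall, F1 (threshold 0.5; the data give no
reason to prefer an asymmetric operating point), ROC-AUC, and the Brier
score for calibration. Configurations are compared with the Friedman test
over the fold-by-configuration score matrix; pairwise follow-up uses the
Conover post-hoc test on within-fold rank sums (t-distributed with
(b−1)(k−1) degrees of freedom) under Holm's step-down correction. On the
study data no configuration wins: the package's tests assert
non-significance (p > 0.05) for accuracy and ROC-AUC, and the
random-forest-with-fingerprints configuration is kept as the reference
model because its features remain chemically interpretable.

Run-to-run variability matters at n = 48: fold assignment noise moves the
outer-fold means by several points. The benchmark functions therefore seed
every stochastic component from one run seed, and the reproduction checks
average over ten seeds.

## Applicability domain

Three nested gates, applied in order, with the verdict recording the first
failure:

1. **Validity** (bounding box over bits): a sample must contain only
   fingerprint bits observed in training and omit none of the bits present
   in *every* training sample. Adding training data can only grow this
   domain — asserted as a property test. Bit collisions can smuggle unseen
   chemistry through this gate; that is a limitation of any hashed
   representation.
2. **Reliability**: the mean Tanimoto similarity to the five nearest
   training neighbours, computed leave-one-out on the training set to
   locate the thresholds. Groups: low < 0.8 ≤ mid ≤ 0.9 < high (the
   boundary assignment is a choice; ties at the k-th neighbour resolve to
   the lowest-indexed sample; two empty fingerprints count as similarity 1,
   unreachable for real trimers). Calibration curves are drawn per group
   from held-out predictions only, with equal-count bins of at least
   `min_bin_size` samples (default 4; the last bin absorbs the remainder).
   On the study data the low-similarity group is visibly worse calibrated,
   so low-similarity predictions are rejected.
3. **Decidability**: probabilities within `decidability_delta` (default
   0.1) of 0.5 are rejected as inherently uncertain. The right width is
   use-case dependent — it trades coverage against error rate — which is
   why it is a configuration field, not a constant.

## Explanation

Shapley values for the forest are computed exactly, per tree and per leaf:
for a leaf with distinct path features F, the path-dependent expectation
E[f | x_S] factorises over edges into per-feature indicator/cover-ratio
weights, so the Shapley sum over coalitions of F (|F| ≤ tree depth ≤ 6) is
enumerated outright. This per-leaf enumeration is exponential only in tree
depth and is validated in the tests against a brute-force coalition oracle;
local accuracy (attributions + base value = predicted probability) is
asserted on every sample, as is the analogous sum identity for the Shapley
interaction matrix. The interaction scan on the study model shows no
materially large off-diagonal terms, consistent with an additive-signal
reading of the fingerprint model.

Bit-level values are decomposed onto atoms: each bit present in a molecule
splits its value equally over the union of atoms of the fragment(s) that
set it there (equal split is the only assumption-free choice given a bit is
a set-membership feature); absent-bit values — which carry real signal,
since missing a good fragment lowers the prediction — have no atoms and are
reported separately. Atom-score conservation is asserted per sample.
Global importance is the mean |Shapley value| over samples, with shares
normalised to sum to one; collision counts per bit come from the fingerprint
trace. On the study refit the importance is highly dispersed — the top
feature holds only a few percent of the total and the top 20 together under
a third — so single "magic fragments" should not be over-read.

## Synthetic ground truth

`generate_library()` draws diol × diacid pairs from editable pools (eight
diols, six of which carry an ether oxygen or pendant hydroxyl; six diacids:
four aliphatic of chain length 2/3/4/8 and two aromatic) and plants the
label with a structural rule; the default calls a polymer biodegradable iff
the diacid is aliphatic with chain length ≤ 4 *and* the diol carries an
oxygen beyond its two condensing hydroxyls. This yields ~37% positives at
the default pools. Labels are planted on structure and pH traces are derived
from labels — matching the causal direction of the assay — with degraders
following a monotone sigmoid decay to below the cutoff and non-degraders
fluctuating above pH 6, so the endpoint labelling rule recovers every
planted label by construction. Observed labels are the rule output XOR
independent flips at a configurable noise rate. Aromatic fragments are
negatively labelled by the rule on purpose: the sign of their Shapley
attributions is a known ground truth for the explanation stage.

Synthetic-scale tests use a reduced grid — one fingerprint setting
(2048 bits, path length 6: long enough to span both carbonyls of the
longest biodegradable diacid) and a 2×2 random-forest grid — and 200
polymers; these sizes are the package's chosen study conditions for the
synthetic checks. What passing synthetic tests shows is that the pipeline
recovers a planted, fingerprint-expressible rule; real biodegradability
also depends on molar mass, crystallinity, solubility and enzyme identity,
none of which the generator emulates.

Domain-shifted source/target pairs share a configurable fraction of the
monomer pools (held-out novel monomers fill the rest), which drives the
transfer-learning experiments: a chained model (the source model's
probability appended as one target feature, evaluated under the same
nested-CV protocol) and three-phase fine-tuning of the network (pre-train
on source; retrain the output layer — the final linear layer — on target;
one full-network pass at learning rate 1e-4). The external literature
dataset itself is not bundled; users who obtain it can pass it through the
same `chain()`/`finetune()` interface as any tibble of SMILES and labels.
Out-of-fold source predictions are deliberately not used in the chain:
source and target are distinct datasets, so no fold-level leakage arises
from fitting the source model once on all source data.

## Numerical and engineering notes

* All canonical SMILES come from OpenBabel; trimer construction is graph
  surgery on kekulised heavy-atom graphs, and identical inputs give
  byte-identical canonical SMILES.
* Fingerprint matrices are memoised per (molecule set, configuration);
  synthetic libraries fingerprint each distinct monomer pair once.
* Every stochastic component (fold shuffles, forest seeds, network
  initialisation) derives from the single run seed; repeated runs are
  bit-reproducible.
* The study-scale benchmark (the full default tuning grid, ten seeds) runs
  in roughly ten minutes on one CPU; the problem sizes used by the test
  suite (120–250 synthetic polymers, reduced grids, ten seeds where a check
  is about run-to-run spread) are stated in the tests themselves.
* The per-leaf Shapley enumeration is guarded at 20 distinct features per
  path; it is intended for the shallow forests of this package's grid, not
  for deep trees.

## Known limitations

* The trimer abstraction discards molar mass and dispersity, which the
  assay data say matter (several monomer pairs appear twice with different
  molar masses — one duplicated pair even carries consistent labels only
  because both samples degraded). A molar-mass-aware model is future work.
* Descriptor coverage (24 descriptors) is far narrower than large
  cheminformatics toolkits provide; descriptors are the secondary
  featurisation here.
* The assay itself can mislabel: slow degraders are capped at the endpoint,
  and oligomeric impurities can acidify without enzymatic degradation. The
  package models the assay's calls, not ground-truth environmental fate.
* Hash collisions make some bits chemically ambiguous; the collision report
  makes this visible but cannot remove it.
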