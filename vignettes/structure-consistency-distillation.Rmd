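---
title: "Structure-consistency distillation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-consistency distillation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdistill)
```

## The problem

Inverse protein folding designs an amino-acid sequence that folds into a
target backbone. Sequence-design models trained purely on reconstruction
loss score well on recovery but tend to produce near-duplicate designs.
Forward folding models could, in principle, grade each candidate sequence
for structural plausibility during training — but running a full folding
model inside the optimization loop is far too slow, and it is not
differentiable.

`scdistill` implements the alternative this package is built around:
*distill* a folding model's confidence metrics (a global pTM-style scalar
and a per-residue pLDDT-style track, both in (0,1)) into a small, fast,
differentiable sequence-to-score model, then use that frozen model's output
SC (structure consistency) as a regularizer on the design model's training
objective:

$$\mathcal{L} \;=\; \mathcal{L}_\mathrm{CE} \;+\; \alpha\,
  \mathcal{L}_\mathrm{SC}, \qquad
  \mathcal{L}_\mathrm{SC} \;=\; \sum_{i=1}^{N}\bigl(1 - SC(\hat{s}_i)\bigr),$$

with $\alpha = 1$ as the reference setting. Everything is exercisable at
desk scale: a synthetic module supplies toy backbones, graded structure
pairs, a planted sequence-to-score oracle, and a toy structure-conditioned
design task, so every stage of the pipeline is testable without external
data or GPUs.

## Structure metrics

**TM-score.** $\mathrm{TM} = \max_{\text{superpositions}}
\frac{1}{L_{ref}} \sum_i \frac{1}{1 + (d_i/d_0)^2}$ over corresponded
C$\alpha$ pairs, with $d_0 = 1.24\,(L_{ref}-15)^{1/3} - 1.8$ Å.
Choices made here:

* **Normalization length** is the reference length (the formula's $L_{ref}$),
  configurable via `l_norm`. Which chain normalizes is a genuine open point
  for distillation labels; reference-length normalization is the default
  and is explicit in the API.
* **$d_0$ clamp**: the cube-root formula is tiny or negative for
  $L_{ref} \le 21$; $d_0$ is clamped below at 0.5 Å so toy-sized inputs
  stay finite. This follows the metric's standard practice.
* **Superposition search**: deterministic and bounded. Both structures are
  first moved to a canonical principal-axes frame (this makes the search
  exactly invariant to the frames the structures arrive in). Seeds are
  Kabsch superpositions of the full correspondence, gapless fragments
  (halves and quarters at several offsets) and — for chains of at most 20
  residues, where the clamped $d_0$ makes the landscape multimodal — every
  residue triple. Each seed is refined by iterative reselection of pairs
  closer than 8, 6, 4 Å. A final stage polishes the ten best distinct
  candidates with Nelder-Mead and returns the maximum found. On small toys
  this converges to the same optimum as an independently coded brute-force
  search (Horn quaternion superpositions over all triples plus random
  restarts), to machine precision in our tests.
* **Correspondence** defaults to positional (same residue index), because
  distillation structure pairs share one sequence. No alignment search is
  performed; sequence alignment is out of scope.

**lDDT.** Superposition-free: for every atom pair in different residues
whose *reference* distance is within the 15 Å inclusion radius, the pair is
preserved at tolerance $t$ if $|d_{model} - d_{ref}| < t$; the per-residue
score averages the preserved fraction over tolerances
$\{0.5, 1, 2, 4\}$ Å (the metric's standard set — the four thresholds are
fixed by the defining publication), and the global score is the mean over
residues. Residues with no pair inside the radius are undefined and are
excluded from the mean, with a message. The default is C$\alpha$-only
(distillation corpora are backbone-level); an all-atom mode uses
`atom_records` when present. `lddt_from_dist()` exposes the distance-space
core so that exact threshold cases (e.g. a uniform +1.5 Å perturbation of
all pair distances, which passes tolerances 2 and 4 and fails 0.5 and 1,
giving exactly 0.5) can be constructed even when no 3-D coordinates realize
them.

**Burial classes.** A residue with $\ge 24$ other C$\alpha$ within 10 Å is
core, $\le 16$ surface, otherwise intermediate; `per_class_report()` uses
these classes to break recovery/diversity down by burial, the analysis that
shows core residues recovering better and surface residues diversifying
more.

## Score datasets and curation

Scores live strictly inside (0,1) and are discretized into 50 equal bins
(`score_binning()`), half-open with the final bin closed, so discretization
is total and deterministic; labels are **0-based**. Values exactly 0 or 1
are clamped inward by one machine epsilon. pLDDT-style tracks are stored
normalized to (0,1) even where folding tools report 0-100; convert at I/O
boundaries.

Curation mirrors how such corpora are built at scale:

* `filter_by_similarity()` guards against leakage into downstream
  validation/test splits at a 40% similarity threshold. The similarity
  tool behind published corpora is typically unstated, so two definitions
  are provided: a 3-mer containment proxy (cheap, 100% for exact
  duplicates) and exact global Needleman-Wunsch identity
  (match 1 / mismatch 0 / gap 0, normalized by query length, via
  Biostrings). The choice is a flag.
* `crop_sequence()` caps lengths at 500 by a uniformly-placed contiguous
  window, cropping any per-residue track with the same window.
* `augment_perturb()` produces perturbed sequence variants
  (segment permutation or replacement over a contiguous window covering
  `intensity` of the length). Perturbed sequences deliberately carry **no
  score**: they must be re-scored by a scorer (a trained distill model or
  the synthetic oracle), never fabricated. The exact perturbation recipe of
  large augmented corpora is unstated, so segment size and variant count
  are exposed parameters.
* `balance_filter()` thins the over-represented high-score range;
  `sampling_weights()` gives inverse-bin-frequency minibatch weights.

## The distill model

The reference architecture is deliberately small and fully hand
differentiated: windowed amino-acid composition features (half-width 4, a
9-residue window) feed a position-wise tanh hidden layer (width 24); a
per-position head emits 50-bin logits (the per-residue track) and a
sequence-level head reads the **mean-pooled** hidden state (the scalar).
The pooled readout stands in for a first-token readout of a transformer
encoder: the contract (`forward: tokens -> sequence-level logits +
per-position logits`) keeps the backbone pluggable, and a ~5k-parameter
network trains on a CPU in seconds while having exactly the capacity needed
for the planted oracle family. This is a deliberate departure from a
self-attention encoder; nothing downstream depends on the backbone's form.

Training (`sc_distill()`) minimizes **focal loss**
$-(1-p_t)^\gamma \log p_t$ over discretized labels with $\gamma = 2$ (the
focal-loss paper's default; the distillation setting names the loss but not
$\gamma$), with minibatches drawn by inverse-bin-frequency weights.
Validation uses plain cross-entropy ($\gamma = 0$) each epoch and the
best-epoch weights are kept. Runs are bit-reproducible given `seed`.

The scalar readout from 50-class logits is the softmax-weighted mean of bin
centers (`expected_score()`), which is smooth in the logits — required for
the SC gradient path — with an argmax-bin-center option for reporting. How
a released distilled model converts logits to its reported scalar is
unstated; the expectation is this package's choice and both readouts are
available.

## The SC regularizer

`combined_loss(ce, sc_scores, alpha)` assembles
$\mathcal{L} = \mathcal{L}_{CE} + \alpha \mathcal{L}_{SC}$ exactly.
`score_generated()` produces per-sample SC scores from a frozen distill
model in two modes:

* **soft** (default): per-position probability vectors are fed directly
  through the model (probability-weighted composition features), so the
  score is smooth in the generator's distributions and carries an analytic
  gradient (verified against finite differences to 1e-4 in the tests).
* **hard / straight-through**: discrete sequences forward, soft gradients
  backward.

How gradients cross the discrete generated sequence in the original
training setup is not stated anywhere we could rely on; both modes are
provided as interpretations, soft being the default. Per-residue models
are reduced to a scalar per sequence by the unweighted mean before entering
the objective, since $SC(\hat s)$ is scalar per sequence.

**CE convention (matters for the $\alpha = 1$ regime).** The per-sequence
reconstruction CE is the *sum* of per-position cross-entropies — the
standard sequence loss and the literal reading of
$\mathcal{L}_{CE} = \sum_i \mathcal{L}_{CE}(s_i, \hat s_i)$. With a
per-position *mean* instead, the SC term at $\alpha = 1$ becomes roughly
$L$ times stronger relative to CE and drags recovery down by ~10 points on
the toy task — far outside the "diversity up, recovery maintained" regime
this method occupies. The summed convention is the package's design choice
and the default.

## Synthetic generators: what they emulate, what they do not

* `make_backbone()` builds ideal helices (rise 1.5 Å, 3.6 residues/turn),
  extended chains (3.5 Å spacing) and self-avoiding random coils (3.8 Å
  steps, minimum 3.6 Å non-consecutive separation). These have realistic
  C$\alpha$ spacing and packing density but no side chains, no secondary
  structure mixture, no physical energetics.
* `perturb_backbone()` adds isotropic Gaussian noise — graded structure
  pairs whose TM/lDDT decrease in expectation with magnitude; real model
  errors are correlated along the chain, which this does not emulate.
* `make_oracle()` plants a deterministic sequence-to-score map: per-residue
  scores are a logistic of the windowed (9-wide) amino-acid composition
  under fixed random coefficients (sd 3, chosen once so that random
  sequences spread over roughly 20-30 of the 50 bins), and the scalar is
  the mean of the track — mirroring how mean-pLDDT summarizes a per-residue
  confidence track. The oracle is local by construction (a substitution
  changes scores only inside its window), unlike a real folding model's
  global couplings. Passing the parameter-recovery tests therefore shows
  the training loop works, not that a 5k-parameter model could learn real
  folding confidence.
* `make_design_task()` plants a recoverable structure-to-residue rule:
  eight classes (neighbor density at 8 Å × local compactness) map each to
  one amino acid, corrupted at rate `noise`. Features exposed to the
  designer are rotation-invariant (neighbor counts at 6/8/10 Å, local
  spans, chain position), so the task cannot be solved by coordinate
  memorization. Each record carries a contiguous masked span for the
  infilling variant. At noise 0.2 the Bayes recovery ceiling is
  $0.8 + 0.2/20 = 81\%$.

## Numerical choices

* Bin labels 0-based; edges half-open, last bin closed; boundary scores
  clamped inward by machine epsilon.
* $p_t$ clamped at $10^{-12}$ before logarithms; zero probabilities in
  perplexity clamped at $10^{-12}$ with a warning.
* Kabsch superposition forbids reflections (determinant +1 enforced via
  the SVD sign correction); fewer than 3 points error; collinear sets warn
  and return the (non-unique-rotation) minimizer.
* lDDT inclusion uses the *reference* distances only; tolerance comparison
  is strict (`<`).
* Coordinates and distances in Å; residue indexing 1-based in R APIs,
  residue ids preserved in report output.
* All stochastic operations take a `seed` and restore the caller's RNG
  state; derived seeds stay below $2^{31}$.

## Problem sizes used in the checks

The test-suite and `scripts/acceptance.R` run, as this package's chosen
desk-scale study conditions: 50 random structure pairs of up to 30 residues
for the lDDT oracle check and 5 toys of 12-15 residues for the TM oracle
check; 2,000 oracle-scored sequences of length 30-80 (3 seeds) for
distillation parameter recovery; and the toy design task at $n = 500$,
noise 0.2, 5 seeds, with 16-sample decodes for the regularization-direction
experiment. On these sizes the scalar model reaches held-out Pearson
$\ge 0.9$ and the per-residue model MAE $\le 0.1$, and $\alpha = 1$
soft-mode SC regularization raises decode diversity in at least 4 of 5
seeds while moving mean recovery by well under 2 points.

## Known limitations

* The distill backbone is a windowed-composition network: it cannot
  represent long-range sequence interactions; it is the smallest model
  that makes the pipeline exercisable, not a statement about adequate
  capacity for real confidence distillation.
* TM-score optimization is a bounded deterministic search; global
  optimality is only verified (against brute force) on small chains.
* The similarity filter's 3-mer containment proxy upper-bounds low
  similarity cheaply but is not a substitution-matrix similarity; use
  `method = "identity"` where exactness matters and lengths are short.
* Diversity requires equal-length samples (decodes for a fixed backbone);
  no alignment is attempted.
* Recovery is averaged per-sequence, then across a dataset (pooling
  positions instead is a one-line change in the caller and gives the same
  value for equal-length sets).
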