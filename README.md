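# scdistill

Structure-consistency distillation for protein sequence design, in R.

## The problem

Inverse protein folding — designing an amino-acid sequence that folds into
a target 3D backbone — is usually trained on reconstruction loss alone,
which rewards recovering the one deposited sequence and tends to produce
near-duplicate designs. A forward folding model could grade every candidate
sequence for structural plausibility during training, but folding-model
inference is far too slow for the optimization loop and is not
differentiable.

`scdistill` implements the distillation route around this: train a small,
fast, differentiable sequence-to-score model to reproduce a folding model's
confidence metrics — a global pTM-style scalar and a per-residue
pLDDT-style track, both in (0,1) — and use the frozen distilled score
SC(s) as a regularizer on the design model's objective:

    L = L_CE + alpha * L_SC,      L_SC = sum_i (1 - SC(s_hat_i)),

with `alpha = 1` as the reference setting. The package is aimed at people
building or studying structure-aware sequence design pipelines, and is
fully exercisable at desk scale: a synthetic module provides toy backbones,
graded structure pairs, a planted sequence-to-score oracle and a toy
structure-conditioned design task, so every stage runs on a laptop CPU in
seconds to minutes.

It contains:

* **Structure metrics** from Cα coordinates: TM-score
  (`TM = max over superpositions of (1/L_ref) * sum 1/(1+(d_i/d0)^2)`,
  `d0 = 1.24 (L_ref-15)^(1/3) - 1.8` Å) with a deterministic bounded
  superposition search, lDDT (four tolerances 0.5/1/2/4 Å inside a 15 Å
  inclusion radius, superposition-free), Kabsch superposition, and
  core/surface residue classes (≥ 24 / ≤ 16 Cα neighbors within 10 Å).
* **Score-dataset curation**: 50-bin discretization of (0,1), similarity
  filtering against holdout splits (40% threshold), random cropping to
  length 500, sequence-perturbation augmentation, balance filtering and
  inverse-frequency sampling weights.
* **The distill model** `sc_distill()`: a small trainable sequence model
  over a 50-bin vocabulary with focal-loss training (`gamma = 2`),
  weighted sampling, per-epoch cross-entropy validation, and the classic
  fitted-model interface (`print`, `summary`, `coef`, `predict`, `plot`,
  `residuals`, `simulate`).
* **The SC regularizer**: `combined_loss()` (exact Eq. decomposition),
  `score_generated()` with soft (differentiable, analytic gradients) and
  hard/straight-through scoring modes, and a toy designer
  (`train_designer()`) demonstrating SC-regularized training end to end.
* **Evaluation**: recovery, diversity (complement of mean pairwise
  recovery), perplexity, and per-burial-class breakdowns.

## Worked example

```r
library(scdistill)

## structure metrics on a graded synthetic pair
ref <- make_backbone(40, "random_coil", seed = 1)
mod <- perturb_backbone(ref, magnitude = 1, seed = 2)
sc  <- structure_score(mod, ref)
sprintf("TM = %.3f, lDDT = %.3f", sc$tm, sc$lddt_global)
#> "TM = 0.557, lDDT = 0.620"

## distill a sequence -> score oracle into a small model
orc   <- make_oracle(seed = 7)
train <- generate_synthetic_scored(800, as_scorer(orc), seed = 11)
fit   <- sc_distill(scored_dataset(train), target = "scalar",
                    config = distill_config(epochs = 8), seed = 1)
fit
#> <sc_distill> scalar model, 50 bins, 3028 parameters, best epoch 8 (val CE 2.3475)

s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
predict_ptm(fit, s)        # 0.796
predict(orc, s)$scalar     # 0.798  (the model tracks the oracle closely)

## the regularized objective for a generated candidate
term <- combined_loss(ce = 2.0,
                      sc_scores = score_generated(fit, list(s), mode = "hard"),
                      alpha = 1)
term
#> <sc_loss_term> total 2.20422 = ce 2 + alpha 1 * sc 0.204217 (N = 1)
```

A 1 Å-perturbed 40-mer scores TM 0.56 / lDDT 0.62 against its original —
a recognizably similar but degraded fold. The distilled model predicts the
oracle's scalar within ~0.002 on an unseen sequence, and the combined loss
shows the SC term (1 − 0.796 = 0.204) added to the task loss at
`alpha = 1`.

A command-line interface wrapping the same functions (subcommands `score`,
`curate`, `distill-train`, `distill-predict`, `train-designer`, `evaluate`,
`fixtures`) is installed at
`system.file("cli", "scdistill", package = "scdistill")`.

See `vignettes/structure-consistency-distillation.Rmd` for the models,
parameter choices, and limits of the synthetic generators.

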