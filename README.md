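# metadti

Drug–target interaction (DTI) prediction for **proteins unseen at training
time**, in R. The package implements, end to end and on one CPU core:

* a **multi-level encoder** — a convolutional protein-sequence branch and a
  graph-convolutional molecule branch, fused at every level by low-rank
  bilinear attention and consolidated by a gated selection unit into one
  interaction vector *O*;
* **stage one (inductive):** supervised training on a labeled *source*
  domain plus **category-aware domain-adversarial alignment** against an
  unlabeled *target* domain — a gradient reversal layer feeds two domain
  discriminators, one per interaction class, each conditioned on the
  model's class probability, so positive-like and negative-like pairs are
  aligned separately (`L = L_s + λ·L_d`, λ on the standard ramp);
* **stage two (associative):** 2-way *k*-shot episodes drawn from protein
  clusters; per-query **dynamic prototypes** built by SiLU affine attention
  (`A = ReLU(QKᵀ)^{∘2}`, softmax restricted to each class's supports),
  classified by cosine similarity and trained with a focal loss
  `−α(1−p)^γ log p`;
* a **virtual-screening score** `y_c² · y_r` that squares the interaction
  probability before weighting by the single-layer affinity head, plus
  top-fraction attention extraction over residues and atoms;
* a **synthetic benchmark generator** that plants protein motif families,
  fragment-assembled molecules and a lock-and-key compatibility rule shared
  across domains, with calibrated positive rate and label noise — so
  generalization and memorization are distinguishable by construction.

All tabular inputs and outputs are tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` plots. The neural core runs on
a small reverse-mode automatic-differentiation engine included in the
package and finite-difference-tested.

## Worked example

```r
library(metadti)

# a planted-rule benchmark: 6 motif families x 30 proteins, 60 fragment-
# assembled molecules, eta = 0.05 label noise, clean positive rate 0.5
bench <- prepare_benchmark(seed = 11)

# stage one: 30 epochs on 400 labeled source pairs, with adversarial
# alignment against the two held-out (shifted) families
stage1 <- run_stage_one(bench, seed = 11, cada = TRUE)

# stage two: 5-shot episodes from source clusters, evaluated on episodes
# from the held-out target clusters (no protein shared between support and
# query anywhere)
stage2 <- run_stage_two(bench, stage1$model, k = 5, seed = 13)
glance(stage2$eval)
```

With `cada = FALSE`, `run_stage_one(bench, seed = 11, cada = FALSE)$val_auroc`
prints `0.9034` — the final source-validation AUROC, against labels
carrying 5% flips (so the ceiling is 0.95). The stage-two evaluation above
prints

```
#> # A tibble: 1 × 7
#>   auroc auprc   acc auroc_sd auprc_sd acc_sd n_episodes
#>   <dbl> <dbl> <dbl>    <dbl>    <dbl>  <dbl>      <int>
#> 1 0.625 0.702  0.56    0.300    0.230  0.190         20
```

(the held-out clusters are *shifted protein families* — their motifs never
occur on the source side — so this is the hard cross-domain reading of the
few-shot task; see the methods vignette for what the benchmark can and
cannot establish).

Scoring and interpretation:

```r
hits <- screen_pairs(stage1$model, bench$target$interactions, bench$features)
attr(hits, "top_precision")     # precision among the top 10% by y_c^2 * y_r

att <- extract_attention(stage1$model,
                         bench$target$proteins$sequence[1],
                         bench$dataset$drugs$smiles[1], top_fraction = 0.2)
plot_attention(att, "atom")
```

A thin command-line wrapper over these functions (commands `synth`,
`cluster`, `train-inductive`, `train-meta`, `eval-zeroshot`, `eval-fewshot`,
`screen`, `explain`) ships as `inst/cli/metadti.R`.

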