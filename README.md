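# trustfuse

Trustworthy late fusion of multi-omics data for diagnostic classification,
with graph-attention encoders and evidential (Dirichlet) uncertainty.

## What it does

Given several omics blocks measured on the same subjects (for instance mRNA
expression, DNA methylation and miRNA), `trustfuse`:

1. **builds a co-expression network per block** on training subjects — the
   signed WGCNA-style soft adjacency `A_ij = ((1 + r_ij)/2)^beta`,
   binarized at a threshold (default 0.08) into a shared edge set;
2. **encodes every subject as a graph**: the block's edge set with the
   subject's own scaled feature values on the nodes, passed through two
   multi-head graph-attention layers (`G0 -> G1 -> G2`) whose levels are
   fused into one subject vector;
3. **reads the encoder output as evidence**: non-negative per-class
   evidence `e_k` defines a Dirichlet with concentration `alpha_k = e_k + 1`,
   belief masses `b_k = e_k / S` and an explicit uncertainty mass
   `u = K / S` (subjective logic), so every per-omics prediction carries
   its own "don't know" mass;
4. **fuses blocks by the Dempster–Shafer rule**
   `b_k^F = (b_k^1 b_k^2 + b_k^1 u^2 + b_k^2 u^1) / (1 - C)`,
   `u^F = u^1 u^2 / (1 - C)` with conflict `C = sum_{i != j} b_i^1 b_j^2`,
   so a modality with high uncertainty contributes little;
5. trains everything end to end on an **evidential objective**: Dirichlet
   expected cross-entropy `sum_k y_k (psi(S) - psi(alpha_k))` plus an
   annealed KL penalty toward the uniform Dirichlet on the off-label
   evidence, for the fused and every per-omics head, plus auxiliary
   per-omics cross-entropies;
6. ranks biomarkers by **feature ablation**: the drop in F1 (binary) or
   macro-F1 (multi-class) when one feature is zeroed at inference.

A synthetic-cohort generator (`sim_spec()` / `generate_cohort()`) plants
block-correlated modules and class signals so the full pipeline is testable
without external downloads, and a masking protocol (`mask_modality()`,
`robustness_curve()`) probes how gracefully accuracy and uncertainty react
as one modality is progressively suppressed.

## Worked example

```r
library(trustfuse)

spec   <- sim_spec(seed = 42)          # 300 subjects, 3 classes, 3 x 50 features
cohort <- generate_cohort(spec)

fit <- fit_pipeline(cohort$omics, cohort$labels, seed = 1,
                    lr = 1e-2, n_heads = 2, hidden = 4,
                    evidence_hidden = 32, epochs = 60, patience = 20)
unlist(fit$metrics)
#>         acc f1_weighted    f1_macro 
#>           1           1           1 

test  <- fit$take(fit$split$test)
preds <- predict_subjects(fit$model, test)
round(preds$probabilities[1:3, ], 3)      # fused Dirichlet-mean probabilities
#>        [,1] [,2]  [,3]
#> S0007 0.782 0.08 0.138
#> S0010 0.749 0.11 0.140
#> S0011 0.137 0.68 0.184
round(preds$fused$u[1:3], 3)              # fused uncertainty mass per subject
#> S0007 S0010 S0011 
#> 0.216 0.249 0.323 
```

Held-out accuracy is 1 here because the generator planted a 1.5-SD class
signal; the per-subject `u` is the evidential "don't know" mass left after
fusing the three blocks, and `preds$per_omics` carries each block's own
beliefs and uncertainty. Ranked biomarkers come from
`feature_importance(fit$model, test, fit$labels[fit$split$test])`, and
`top_k_report()` reports the top five ranks with reproducible down-sampling
of oversized tie groups.

## Command line

```sh
trustfuse simulate   --spec spec.yaml --out data/
trustfuse preprocess --omics data/omics_mrna.csv,data/omics_mirna.csv \
                     --labels data/labels.csv --k 200,200 --out prep/
trustfuse run        --config run.yaml --out results/
trustfuse explain    --checkpoint results/checkpoint.rds --data data/ \
                     --labels data/labels.csv
```
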