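# mmsurv — multi-modal PET/CT + clinical-text deep survival analysis

`mmsurv` is an R package for time-to-event prognosis from co-registered
PET/CT imaging and structured clinical covariates. It implements, end to end:

* **masked-autoencoder (MAE) pretraining** of per-modality vision-transformer
  encoders (75% of patches masked, standardized-patch MSE on masked
  positions), pretrained independently per modality so unpaired scans still
  contribute, then frozen;
* **cross-attention PET/CT fusion** — CT tokens provide attention queries and
  keys, PET tokens the values: `softmax(Q K' / √d_k) V` plus a residual
  feed-forward block (swapped-role, concat+FC and single-modality ablations
  included);
* **Q-Former image–text fusion** — learnable query tokens self-attend jointly
  with one embedding token per clinical field (age decade, sex, T, N, M,
  stage; never coded as ordinal numbers) and cross-attend to the fused image
  sequence;
* a **time-indexed sigmoid partial-likelihood loss**. With risk set
  R(T_i) = {j : T_j ≥ T_i} and network score N(y, t),

  ```
  l(θ) = −(1/N_events) Σ_{i: E_i = 1} [ ln σ(N(y_i, T_i))
                                        − ln Σ_{j ∈ R(T_i)} σ(N(y_j, T_i)) ]
  ```

  The baseline hazard λ0(t) cancels exactly as in the Cox partial
  likelihood; substituting the exponential link with time-invariant scores
  recovers the Cox loss to machine precision (a tested reduction). Focal and
  Breslow-tie Cox losses are available as components of a combined objective
  (default: proposed + focal);
* an **evaluation suite**: Harrell's C with subject-level percentile
  bootstrap CIs (B = 1000), median-split Kaplan–Meier curves with log-rank
  tests, and a per-subject L2 distance between `σ(N(y_i, T_i))` and the
  observed outcome;
* a **synthetic phantom-cohort generator** in which one latent risk per
  subject drives tumor size on CT, hotspot intensity on PET, the TNM/stage
  distribution, and a Weibull proportional-hazards event time with
  independent censoring — so every stage of the pipeline can be tested at
  desk scale against a known ground truth, and modality ablations have an
  expected ordering.

It is aimed at methods researchers in imaging-based survival analysis who
want a fully inspectable, dependency-light reference implementation: all
forward and backward passes are explicit (hot kernels in RcppArmadillo) and
checked against finite differences and brute-force oracles in the test
suite.

## Worked example

```r
library(mmsurv)

config <- experiment_config(seed = 1, n_subjects = 200, endpoints = "OS")
report <- run_experiment(config)
report
#> <mm_run_report>
#>   OS: C = 0.648 (0.542-0.720), log-rank p = 0.176, mean L2 = 0.417
```

What the numbers mean: 160 subjects were used to pretrain the two encoders
and fine-tune the fusion stack; on the 40 held-out subjects the fused
PET+CT+text risk score orders survival times with concordance 0.648 (0.5 is
chance; the bracket is a percentile-bootstrap 95% CI, wide at n = 40). The
log-rank p-value tests whether the median split of the predicted risk
separates the held-out Kaplan–Meier curves (at n = 20 per arm it does not
reach significance here); the mean L2 of 0.42 is the average distance
between the predicted event probability at each subject's own follow-up time
and the observed indicator (0.5 would be an uninformative constant
predictor).

Individual stages are exposed (`simulate_cohort`, `cohort_planes`,
`run_pretrain`, `run_finetune`, `run_evaluate`, `run_ablation_grid`), as are
the statistics (`proposed_loss`, `cox_loss`, `focal_loss`, `harrell_c`,
`bootstrap_ci`, `km_curve`, `log_rank`, `stratify`, `l2_event_distance`) and
building blocks (`patchify`, `plan_mask`, `mae_pretrain`,
`cross_attention_fuse`, `encode_clinical`, `qformer_fuse`, `risk_score`).
A command-line front end with `simulate` / `pretrain` / `train` / `evaluate`
/ `ablate` subcommands ships in `inst/cli/mmsurv`. The methods vignette
(`vignettes/multimodal-deep-survival.Rmd`) documents the model, the
generator, all numerical choices and the desk-scale training recipe.

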