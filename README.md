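# survnet

Multi-task neural survival analysis for right-censored tabular cohorts with
missing covariate values.

## Who this is for

Biostatisticians and clinical-ML researchers who need a per-patient
prognosis index from small, heavily censored registries (the motivating
setting is early-stage non-small-cell lung cancer: ~9 clinicopathologic
covariates, ~30% observed deaths, and most rows missing at least one
value). Dropping incomplete patients biases the cohort; this model keeps
them.

## The model

Each patient is a triplet (x, s, t): covariates (missing entries
zero-filled, with an indicator matrix R marking them), an event indicator,
and follow-up time in months. A shared trunk
`input -> 64 tanh -> batchnorm -> 32 tanh` feeds three jointly trained
heads:

- **reconstruction** — a linear decoder with the incomplete-aware loss
  `J_re = (1/2n) Σ_i ||r_i ⊙ (x*_i − x_i)||²` (masked entries get exactly
  zero gradient);
- **survival classification** — logistic head predicting survival past a
  fixed horizon T = 36 months, censoring-masked cross-entropy (patients
  censored before T carry no label);
- **Cox regression** — linear head producing the raw log-hazard `a_p`,
  gated by the classification probability into the deployed prognosis
  index `p_x = a_p · a_c`, trained with the negative mean Cox log partial
  likelihood (Breslow ties, log-sum-exp).

Total objective: `J = α·J_cox + β·J_c + γ·J_re`, defaults
`α, β, γ = 0.2, 1, 3`; RMSProp, 100 epochs, batch 64, weight decay 1e-5;
the epoch with the best validation C-index is kept. Evaluation ships with
Harrell's C, median-score dichotomization, Kaplan-Meier curves with
Greenwood bands, the two-group log-rank test, and an input-dropout
robustness experiment. A Weibull proportional-hazards simulator provides
cohorts with known ground-truth risk.

## Worked example

```r
library(survnet)

sim <- simulate_cohort(simulation_config(n = 1137, seed = 7))
mean(sim$records$event)                       # 0.2902375  (~30% events)
mean(apply(is.na(sim$records[2:10]), 1, any)) # 0.8645558  (~86% rows incomplete)

cohort <- encode_cohort(sim$records, sim$schema)
splits <- split_cohort(cohort, c(0.6, 0.2, 0.2), seed = 7)
sapply(splits, function(s) length(s$time))    # 682 / 227 / 228

fit <- train_survnet(init_model(survnet_arch(), seed = 7),
                     splits$train, splits$validation, training_config(seed = 7))
attr(fit$history, "best_val_cindex")          # 0.6193442 (selected epoch 87)

scores <- survnet_forward(fit$model, splits$test$X)$p_x
concordance_index(scores, splits$test$time, splits$test$event)
# 0.6478365 — test-set ranking accuracy (0.5 = random, 1 = perfect)

idx <- match(splits$test$ids, sim$records$id)
oracle_cindex(sim$truth[idx], splits$test$time, splits$test$event)
# 0.7606671 — ceiling achievable with the true log-hazard on this cohort

groups <- dichotomize(scores)                 # median split: 114 high / 114 low
logrank_test(groups, splits$test$time, splits$test$event)[c("statistic", "p_value")]
# statistic 12.54414, p 0.0003974515 — the two risk groups separate clearly
```

So on a simulated cohort with ~86% incomplete rows the model recovers a
C-index of 0.648 against a ground-truth ceiling of 0.761, and its median
split yields a log-rank p < 0.001.

## Command line

```sh
Rscript -e 'survnet::survnet_cli()' simulate --out cohort.csv --seed 1
Rscript -e 'survnet::survnet_cli()' train --cohort cohort.csv \
    --schema cohort.csv.schema.json --out model.json
Rscript -e 'survnet::survnet_cli()' evaluate --checkpoint model.json \
    --cohort cohort.csv --schema cohort.csv.schema.json --out report.json
```

Subcommands: `simulate`, `train`, `evaluate`, `predict`, `robustness`.
Configs are JSON; every output gets a `.manifest.json` sibling recording
command, config, seed and package version.

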