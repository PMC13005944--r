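# srps — survival-reinforced patient stratification

Transfers molecular subtype definitions from a labeled **source** cohort to an
unlabeled **target** cohort, using the target's survival follow-up to steer the
classifier through the distribution shift between cohorts.

The model is a bias-free linear softmax classifier `p_i = softmax(Θ x_i)`
trained full-batch with Adam on a combined objective

```
ω₁·l_CE + ω₂·l_RE + φ·‖Θ‖₁
```

where `l_CE` is the cross-entropy on the labeled source cohort and `l_RE` is a
REINFORCE policy-gradient loss on the target: per episode one subtype `ŷ_i` is
sampled per patient from the predicted probabilities, and the sampled
stratification is rewarded by the minimum pairwise gap in restricted mean
survival time (RMST, the area under the Kaplan–Meier curve up to 60 months)
between subtypes,

```
r = min_{a<b} (τ_a − τ_b),      l_RE = −(1/N) Σ_i q_i · log p_i(ŷ_i),
q_i = r − b_i − b_c,
```

with the advantage baseline `b_i` a small learned perceptron (plus scalar
`b_c`) fitted by a separate optimizer. The reward is positive only when every
better-labeled subtype outlives every worse-labeled one, so maximizing it
transfers the *prognostic ordering* of the subtypes, not just their feature
profile. Inference is a plain argmax — no survival data needed.

The package also provides: Kaplan–Meier / RMST / log-rank / Harrell-concordance
utilities; the proteomic preprocessing pipeline (quantile normalization, 30%
detection filter, zero imputation, per-protein z-scoring, cross-cohort protein
intersection, optional signature restriction); simulators for a 121-cell toy
grid and a 1000×1000 batch-effect benchmark with Weibull survival; supervised
DNN and adversarial (DANN) baselines behind one pluggable classifier contract;
the Δweight interpretation score for linear classifiers with ensemble
averaging and ranking-stability diagnostics; single-sample gene-set enrichment
similarity; and a repeated cross-validation harness with accuracy-map
experiments. A thin command-line wrapper lives in `inst/cli/srps.R`.

## Worked example

```r
library(srps)

# a toy source/target pair: 2 subtypes, 20 features, strong batch noise
pair <- make_toy_pair(toy_grid_spec(seed = 1), alpha = 2.4, swap = 0)

cfg <- srps_config(k = 2, d = 20, episodes = 1000, seed = 1)
fit <- srps_train(pair$source, pair$target, cfg)

accuracy(predict(fit$model, pair$target$expr), pair$target$labels)
#> [1] 0.96
dnn <- train_dnn(pair$source, dnn_config(epochs = 1000, seed = 1))
accuracy(predict(dnn, pair$target$expr), pair$target$labels)
#> [1] 0.86
```

At `alpha = 2.4` the target features are heavily distorted, and the purely
supervised DNN transfers at 0.86 accuracy; the survival-reinforced classifier
reaches 0.96 on the same cells because the target cohort's survival ordering
pulls the decision boundary back toward the true subtypes. (At `alpha = 0`
both methods sit at 1.0; averaged over the whole 11 x 11 toy grid the
survival-reinforced map is 0.037 accuracy above the DNN map, one-sided
P = 0.002 — individual cells fluctuate in both directions.)

Interpretation of a trained model:

```r
dw <- delta_weight(fit$model$theta)
rank_proteins(dw, subtype = 2, top_n = 5)
#> [1] "F12" "F11" "F19" "F14" "F15"
```

Features 11–20 are the ones elevated in subtype 2 by construction, and they
head its Δweight ranking.

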