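# riemsway

Riemannian covariance analysis of postural sway from markerless motion
capture.

`riemsway` classifies **postural-stability conditions** and **seated balance
tasks** from multivariate kinematic time series: 30 Hz skeletal joint
trajectories from a depth camera (25 Kinect-style joint centroids) paired
with 600 Hz center-of-pressure (COP) traces from a force platform.  It is
aimed at movement scientists and rehabilitation engineers who want to turn
cheap markerless capture into quantitative balance assessment, and at anyone
who needs a tested reference implementation of tangent-space classification
on the SPD manifold for multichannel time series.

## Method in brief

Each trial `X` (channels × frames) is summarised by its spatial covariance

    C = (1/Nt) (X − X̄)(X − X̄)ᵀ

and covariances are handled as points on the manifold of symmetric
positive-definite matrices under the affine-invariant metric

    δ_R(C₁, C₂) = sqrt( Σᵢ log² λᵢ ),   λᵢ eigenvalues of C₁⁻¹C₂,

which is invariant to any common invertible channel transform (camera
placement, body size).  For classification, covariances are projected into
the tangent space at the log-Euclidean mean C of the training covariances,

    Sᵢ = Log(C^{−1/2} Cᵢ C^{−1/2}),   sᵢ = upper-triangle vec with √2 off-diagonal weights,

so that ‖sᵢ‖₂ = δ_R(Cᵢ, C), and fed to ridge-penalised multinomial logistic
regression.  Tasks use one pipeline on all trials; conditions use one
pipeline per task, combined by **summing the per-task probability vectors
over a session** (one subject × one condition) and taking the argmax.
Everything is evaluated by leave-one-subject-out cross-validation with the
tangent reference refitted per fold.

A fully seeded synthetic generator produces paired camera/force-plate
datasets with per-task covariance templates, a low-dimensional
condition-dependent "sway subspace", AR(1) temporal smoothness, per-subject
affine transforms and a noisy COP read-out, so the entire pipeline is
testable without human recordings.  See the methods vignette
(`vignettes/riemannian-postural-sway.Rmd`) for the model, parameter and
design details.

## Worked example

```r
library(riemsway)
library(dplyr)

# closed-form sanity check of the metric
riemann_distance(diag(2), diag(c(4, 4)))
#> [1] 1.960516

# a paired synthetic study: 12 subjects x 6 tasks x 3 conditions
cfg    <- synthetic_config(seed = 1)
trials <- generate_dataset(cfg)
mk2    <- filter(trials, device == "MK2")

# which task is being performed? (gesture recognition)
loso_evaluate(mk2, target = "task")
#> Leave-one-subject-out task classification: 100.0% accuracy over 12 folds

# how stably was it performed? (condition classification, session-level)
cv <- loso_evaluate(mk2, target = "condition")
cv
#> Leave-one-subject-out condition classification: 77.8% accuracy over 12 folds
#> Confusion (row %):
#>      predicted
#> truth    1    2     3
#>     1 91.7  8.3   0.0
#>     2 25.0 41.7  33.3
#>     3  0.0  0.0 100.0
glance(cv)
#> # A tibble: 1 × 4
#>   target    accuracy n_folds n_units
#> 1 condition     77.8      12      36

# device agreement: mid-spine trajectory vs center of pressure
benchmark_table(benchmark_dataset(trials))[, c(1, 6, 7)]
#> # A tibble: 6 × 3
#>    task `SpineMid (X)` `SpineMid (Z)`
#> 1     1 0.99 ± 0.00    0.98 ± 0.00
#> 2     2 0.98 ± 0.00    0.98 ± 0.00
#> ...
```

Reading the output: task identity is essentially perfectly recoverable
(tasks are well-separated covariance templates), while condition accuracy at
the default effect sizes reflects the much subtler within-gesture signal —
the extreme conditions (rows 1 and 3) are recovered reliably and the
intermediate condition is hardest, exactly the pattern the confusion matrix
shows.  The near-unity SpineMid correlations confirm the synthetic COP
channel tracks the trunk trajectory it was derived from.

Plots: `autoplot(cv)` (confusion heatmap), `autoplot(benchmark_dataset(trials))`,
`autoplot(embed_2d(pairwise_distances(mk2)))`, `autoplot(learning_curve(...))`.

A thin command-line front end over the same functions ships at
`inst/cli/riemsway` (verbs: `simulate`, `features`, `evaluate`,
`learning-curve`, `benchmark`, `embed`).

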