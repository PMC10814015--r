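# pnnclass

Probabilistic nearest neighbors classification for R: a nearest-neighbor
classifier that returns genuine predictive probabilities, with an exactly
computable likelihood.

## The model

The natural probabilistic version of k-nearest-neighbor classification is a
Boltzmann-type joint model on the training labels,

$$p(y \mid x, \beta, k) \propto \exp\Big(\frac{\beta}{k} \sum_{i=1}^{n} \sum_{r=1}^{k} I\big(y_i = y_{[i]_r}\big)\Big),$$

where $[i]_r$ is the index of unit $i$'s $r$-th nearest neighbor. Its
normalizing constant sums $L^n$ terms, and computing it exactly for
arbitrary neighborhood structures is linked to the maximum-cut problem —
this package includes small-instance oracles that make that link concrete
(`cut_identity()`, `joint_coefficients_enum()`).

The classifier implemented here sidesteps the intractability by working with
*nonlocal* models, one per neighbor rank $r$, in which each unit interacts
only with its $r$-th nearest neighbor:

$$p_r(y \mid x, \beta_r) = \frac{1}{Z_r(\beta_r)} \exp\Big(\beta_r \sum_{i=1}^{n} I\big(y_i = y_{[i]_r}\big)\Big).$$

The rank-$r$ neighbor digraph has outdegree one everywhere, so each of its
components contains exactly one simple cycle, and $Z_r$ has a closed form in
the cycle-size counts $c_m(r)$:

$$Z_r(\beta_r) = \big(e^{\beta_r} + L - 1\big)^{\,n - \sum_m m\,c_m(r)} \prod_{m=2}^{n} \Big[\big(e^{\beta_r} + L - 1\big)^m + (L-1)\big(e^{\beta_r} - 1\big)^m\Big]^{c_m(r)},$$

computable in $O(n)$ per rank. Each $\beta_r$ is estimated by maximum
likelihood (the model is a one-parameter exponential family, so the
likelihood is concave), per-rank predictive distributions for a query point
are averaged over the first $k$ ranks, and $k$ is chosen by leave-one-out
cross-validation. Everything is deterministic: fixed tie rules, no sampling,
bit-identical refits.

## Worked example

```r
library(pnnclass)

sim <- ripley_like(seed = 1)           # two-class Gaussian-mixture benchmark
fit <- pnnclass(sim$train$x, sim$train$y)
fit
#> Probabilistic nearest neighbors classifier
#>   n = 250 training units, p = 2 predictors, L = 2 classes
#>   k selected by LOOCV: 32 (LOO error 0.0800); k grid 1..249

evaluate(fit, sim$test$x, sim$test$y)
#> Test error rate: 0.0840  (n = 1000)
#> Confusion matrix (rows predicted, columns observed):
#>          observed
#> predicted   0   1
#>         0 463  47
#>         1  37 453
#> AUC: 0.9647;  best threshold 0.4905 (sens 0.916, spec 0.926)

predict(fit, sim$test$x[1:3, ], type = "prob")
#>              0          1
#> [1,] 0.1711620 0.82883801
#> [2,] 0.9125882 0.08741175
#> [3,] 0.9031410 0.09685904
```

The fitted object carries the per-rank interaction strengths
(`coef(fit)`), the LOOCV error curve (`plot(fit)`), leave-one-out fitted
probabilities (`fitted(fit)`), and serializes to a documented JSON file
(`write_pnnclass()` / `read_pnnclass()`). A 8.4% test error with AUC 0.96
on this 250/1000 split matches what an optimally tuned majority-vote k-NN
achieves on the same data (7.7%), while additionally providing calibrated
class probabilities.

A formula interface is available for data frames
(`pnnclass(y ~ ., data = df)`), and a thin command-line wrapper ships in
`inst/cli/pnnclass.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pnnclass.R", package="pnnclass"))')" \
  fit --train train.csv --label-col y --model model.json
```

with `predict`, `evaluate`, `simulate`, and `oracle` subcommands.

## Using your own benchmark datasets

The synthetic generators emulate the *structure* of the classic published
benchmarks (two-class Gaussian mixtures; multiclass blobs) so that all
tests run self-contained. To evaluate on the original datasets, export them
from your own environment to CSV — e.g. the Pima diabetes training/test
tables from the `MASS` package
(`write.csv(MASS::Pima.tr, "pima_tr.csv", row.names = FALSE)`) — and run
the same `pnnclass`/`evaluate` calls (label column `type`) or the CLI
`fit`/`evaluate` subcommands on those files.

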