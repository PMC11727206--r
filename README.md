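# modexp: minimax optimal deterministic experiments

`modexp` designs two-arm experiments when pre-treatment covariates are
available for all n units before any outcome is observed — the setting of
online A/B tests, classroom studies, batch allocation in lab experiments.
It is aimed at statisticians and experimenters who want covariate balance
guarantees rather than balance on average.

## The idea

With potential outcomes `E{Y_i(t) | X} = f_t(X_i)` and the
difference-in-means estimator of the average treatment effect
`tau = mean{f_1(X_i) - f_0(X_i)}`, the worst-case mean squared error of an
assignment `T` over all mean functions in a kernel (RKHS) ball of radius
`gamma` and noise variances bounded by `sigma^2` has the closed form

    R(T) = sigma^2 (1/n1 + 1/n0) + gamma^2 * D_K(X1, X0)^2

where `D_K(X1, X0)` is the **generalized discrepancy** — the maximum mean
discrepancy between the empirical covariate distributions of the treated
and control groups, computed by kernel double sums. With the energy kernel
`K(x, y) = -||x - y||` it is the energy distance.

The variance term is minimized by any balanced split, so the **minimax
optimal deterministic experiment (MODE)** is the balanced partition of the
units minimizing `D_K(X1, X0)`. Randomized designs draw Monte Carlo
partitions whose discrepancy decays like `n^(-1/2)`; the optimized
partition behaves like a quasi-Monte Carlo point set with discrepancy
`o(n^(-1/2))`, so under fixed potential outcomes the estimator's MSE
improves from `O_p(1/n)` to `o(1/n)`.

The package provides:

* kernels and imbalance measures: `energy_kernel()`,
  `centered_l2_kernel()`, `user_kernel()`, `discrepancy_between_groups()`,
  `discrepancy_to_full()`, `mahalanobis_distance()`;
* partition optimizers: `twin_split()` (nearest-neighbour twinning for the
  energy kernel), `dds_split()` (marginal-CDF transform), `mc_search()`,
  `exchange_optimize()`, and the exhaustive oracle
  `brute_force_partition()`;
* assignment designs: `mode_assign()` (the Algorithm-style dispatcher),
  `cre_assign()` (complete randomization), `rem_assign()` /
  `rem_threshold()` (Mahalanobis re-randomization), and
  `relaxed_rerandomize()` (re-randomization on a discrepancy quantile);
* risk and estimation: `difference_in_means()`, `true_ate()`,
  `conditional_mse()`, `max_risk()`, `randomization_variance()`,
  `enumerate_assignment_moments()`, `percent_reduction()`, `va_factor()`;
* a replication engine: `gen_covariates()`, `outcome_model()`,
  `gen_outcomes()`, `ks_statistic()`, `run_study()`;
* a command-line tool (`inst/cli/modexp`) with `assign`, `balance`,
  `risk` and `simulate` subcommands over CSV/YAML files.

## Worked example

```r
library(modexp)
X <- gen_covariates(200, 5, law = "uniform", seed = 42)  # U[-3,3] covariates

trt <- mode_assign(X, energy_kernel(), seed = 1)
sum(trt)                                  # 100 treated of 200
attr(trt, "discrepancy")                  # 0.1536

cre <- cre_assign(200, 100, seed = 1)
assignment_discrepancy(X, cre, energy_kernel())   # 0.2855
mahalanobis_distance(X, trt)              # 0.065
mahalanobis_distance(X, cre)              # 3.817

max_risk(trt, X, risk_params(sigma2 = 1, gamma2 = 1))
#> <risk_report>
#>   variance component: 0.02
#>   bias component:     0.0236077
#>   total maximum risk: 0.0436077
```

The optimized assignment halves the energy distance of a random
assignment and cuts the Mahalanobis imbalance by a factor of ~60; the risk
report splits the worst-case MSE into its noise floor (`4*sigma^2/n`) and
the imbalance-driven bias bound.

A small replication study comparing designs end to end:

```r
res <- run_study(sim_config(n = 200, p = 5, model = "C1",
                            designs = list(cre = design_spec("cre"),
                                           rem = design_spec("rem"),
                                           mode = design_spec("mode")),
                            replications = 200, seed = 7))
res
#> <simulation_result: model C1, n = 200, p = 5, uniform covariates, 200 replications>
#>  design MSE x 1e4 KS x 1e2 PR vs CRE (%)
#>     cre     160.9     5.88             0
#>     rem      61.1     4.90            62
#>    mode       2.3     3.57            99
```

Each row is one design evaluated on the same paired covariate and noise
draws: the empirical MSE of the difference-in-means estimator (x 10^4),
the mean Kolmogorov–Smirnov distance between the treated-arm potential
outcome distribution and the observed treated outcomes (x 10^2), and the
percent MSE reduction relative to complete randomization. Re-randomization
helps; the deterministic minimum-discrepancy design dominates both.

The same workflow runs from a shell on any covariate CSV:

```sh
inst/cli/modexp assign --covariates X.csv --design mode --kernel energy \
    --seed 1 --out assignment.csv
inst/cli/modexp balance --covariates X.csv --assignment assignment.csv
inst/cli/modexp simulate --config inst/extdata/example-study.yaml --out study.csv
```

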