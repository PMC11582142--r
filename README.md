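# IsingMiss

Bayesian estimation of Ising networks from binary item-response data with
missing values.

## The problem

The Ising model is the standard graphical model of network psychometrics:
binary items (symptoms, survey questions) are nodes, and a symmetric
parameter matrix **S** on the log-odds scale encodes their conditional
dependence structure,

    P(Y = y | S)  ∝  exp( Σ_j s_jj y_j / 2  +  Σ_{j<k} s_jk y_j y_k ),
    y ∈ {0,1}^J.

Because the normalizing constant sums over 2^J patterns, estimation is
based on the *pseudo-likelihood* — the product over items of each item's
logistic conditional, whose linear predictor is `s_jj/2 + Σ_{k≠j} s_jk y_k`.
That objective needs complete response vectors, and questionnaire data are
rarely complete.  Worse, the usual fixes fail in predictable ways: listwise
deletion requires MCAR, and with *screening items* (respondents answering
"no" to the gate questions skip the rest) the complete-case estimate of the
edge between the screening items is pushed toward −∞ — a spurious negative
association known as Berkson's paradox — even when the true edge is
strongly positive.

`IsingMiss` implements a conditional Bayesian estimator that handles any
missing-at-random mechanism: fully-conditional-specification (chained
equations) imputation with per-item Bayesian logistic regressions is
interleaved with joint Pólya–Gamma-augmented sampling of
`vech(S)` from the pseudo-posterior.  Because the logistic conditionals are
exactly the Ising model's own conditionals, the imputation model is
compatible with the joint model and the posterior-mean estimate is
consistent under MAR.  Baseline estimators (listwise deletion, single
imputation), exact and Gibbs samplers for the model, synthetic-data
generators for MCAR / anchor-MAR / screening missingness, and a
replication harness computing per-parameter MSE and bias are included.

## Worked example

Six items, the first two acting as screening items: whenever both screening
responses are 0, items 3–6 are missing.  The true network has six positive
edges of weight 0.8, including the screening pair `s_12`.

```r
library(IsingMiss)

truth <- make_study2_truth()                  # s_12 = 0.8 > 0
full  <- sample_exact(truth, 4000, seed = 1)
data  <- apply_missingness(full, missingness_spec("screening"), seed = 2)
data
#> response_data: 4000 respondents x 6 items, 5.9% missing

fit <- fit_ising(data, method = "proposed", chains = 2,
                 iters = 1500, burnin = 500, thin = 10, seed = 3)
fit
#> ising_fit (proposed): 6 items, 2 chain(s) x 100 retained draws
#> max Gelman-Rubin R-hat: 1.019
#> edges with |estimate| > 0.5: 6
#>   item1 item2    weight
#> 6    y5    y6 0.9021426
#> 1    y1    y2 0.8795225
#> 5    y4    y6 0.8596277
#> 4    y3    y5 0.7111791
#> 3    y2    y4 0.6655194
#> 2    y1    y3 0.6209767
```

The six edges above are exactly the six true edges, each estimated near
0.8, and the screening-pair edge `y1–y2` comes out positive (0.88).  The
`max R-hat` line is the Gelman–Rubin statistic over all 21 parameters; a
value near 1 means the two chains agree.  Listwise deletion on the same
data flips the sign of that edge:

```r
listwise_estimate(data, 1500, 500, 10, seed = 3)[1, 2]
#> -3.95
```

— off by almost 5 on the log-odds scale, purely because the complete cases
exclude the (0,0) screening pattern.  The imputation-based estimator uses
the observed frequency of that pattern and gets the sign and magnitude
right.

A command-line front end with `fit`, `edges`, `simulate` and `replicate`
subcommands is installed at `inst/cli/isingmiss` (flags mirror the function
arguments; a YAML config can stand in for flags).

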