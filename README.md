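# wtpmxl

**WTP-space mixed logit analysis of rewilding choice experiments**

`wtpmxl` is an R package for analysing stated-preference discrete choice
experiments (DCEs) on landscape rewilding programs — and for validating that
analysis end to end on synthetic data.  It is aimed at environmental
economists and conservation scientists who field DCEs in which respondents
repeatedly choose between program alternatives and a zero-cost status quo,
and who want to know how willingness to pay (WTP) varies with respondent
characteristics such as political affiliation.

## The model

Utility is specified in *WTP space*, so attribute coefficients are
denominated directly in EUR:

    V_itn = alpha_n * ( beta_n0 * SQ_itn + beta_n1' log L_itn
                        + beta_n2 * LC_itn + beta_n3 * LH_itn - Cost_itn )

where `SQ` is the status-quo dummy, `log L` the log-coded landscape
attributes (forest, river, agriculture, connectivity; four ordered levels
coded 1..4), `LC`/`LH` the large-carnivore and large-herbivore presence
counts, and `alpha_n > 0` the marginal utility of money confounded with
scale.  Coefficients are heterogeneous:

    beta_nj = mu_j + lambda_j X_n + zeta_nj
    alpha_n = exp( pi + gamma X_n + eta_n )

with `(zeta_n, eta_n)` jointly normal with fully estimated covariance
`Omega` (Cholesky-parameterized).  The model is estimated by maximum
simulated likelihood with scrambled Sobol draws (2000 per respondent by
default), analytic gradients, and respondent-clustered sandwich standard
errors.  Post-estimation tools produce per-party WTP tables (baseline party
mean plus party shifts), status-quo choice shares, and a decomposition of
WTP heterogeneity into covariate-explained and residual parts with joint
Wald tests per covariate group.

## Worked example

Simulate a compact panel with known parameters (400 respondents, 12 tasks,
two parties), fit the mixed logit, and inspect the outputs:

```r
library(wtpmxl)
cfg <- recovery_config(400, seed = 7)          # true river WTP 30, shift +12
fx  <- make_fixture(cfg)
spec <- model_spec(covariates = "voting", baseline = c(voting = "gray"),
                   n_draws = 200)
fit <- fit_mxl(fx$data, fx$covariates, spec, seed = 7)
print(fit)
#> WTP-space MXL fit: 400 respondents, logLik -2311.01, 200 draws, converged
#> mu (EUR):
#>         sq      river herbivores
#>     37.299     30.809     27.398
#> exp(pi) = 0.06812
#> sd of random components:
#>         sq      river herbivores      money
#>     63.085     25.307     16.548      0.658
```

The generating values were `mu = (40, 30, 25)`, `exp(pi) = 0.06` and
random-component standard deviations `(60, 20.9, 15.8, 0.46)`: location
parameters are recovered closely at this sample size, dispersions within
sampling error.  Per-party WTP for the river attribute:

```r
subset(party_wtp_table(fit), attribute == "river")
#>   party attribute  wtp   se ci_lo ci_hi shift shift_se signif
#>    gray     river 30.8 2.23  26.4  35.2     0       NA    ***
#>   green     river 43.8 2.90  38.1  49.4    13     3.46    ***
```

The baseline ("gray") row is the estimated mean WTP; the "green" row shows
the party shift (+13 EUR, true value +12) with its own standard error.
Status-quo shares and the heterogeneity decomposition:

```r
attr(sq_share(fx$data, fx$covariates), "overall")
#> [1] 0.414
build_decomposition_table(fit, fx$covariates)
#>    attribute    voting sum explained_share
#>           sq 100.00*** 100            5.51
#>        river 100.00*** 100            6.14
#>   herbivores 100.00*** 100            2.35
#>         cost   100.00* 100            2.76
#>         mean    100.00 100            4.25
```

Each decomposition row sums to 100 across covariate groups (here a single
group, voting); `explained_share` is the percentage of each coefficient's
total variance accounted for by covariates.  The worked example's high
status-quo share reflects the compact validation design; the study-scale
generator (`default_simulation_config()`) produces shares near 17% with a
six-party electorate.

A command-line pipeline (`simulate` / `fit` / `report` / `recover`) driven
by a YAML config is available through `run_cli()` and the thin wrapper in
`inst/cli/wtpmxl.R`; see `?cmd_simulate`.

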