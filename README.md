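# zicount

Count outcomes in health-services research — hospital length of stay
(LOS), utilization counts, adverse-event tallies — are nonnegative
integers, right-skewed, usually overdispersed and sometimes zero-inflated.
Choosing among the four standard regression models for such data
(Poisson, negative binomial, zero-inflated Poisson, zero-inflated
negative binomial) is a recurring practical question, and the answer
depends on the sample size, the amount of overdispersion and the
proportion of structural zeros. `zicount` is for biostatisticians and
health-services researchers who want to make that choice with evidence:
it provides the four models as transparent maximum-likelihood fitters, a
Monte Carlo harness that measures how each model behaves when fitted to
data from each process, and a four-model comparison report for empirical
LOS-format tables.

## The models

All four share a log-linear count mean, `mu_i = exp(x_i' beta)`.

| model | pmf | conditional variance |
|---|---|---|
| Poisson | `e^{-mu} mu^y / y!` | `mu` (equidispersion) |
| NB2 | gamma–Poisson mixture, `Gamma(y + 1/alpha) / (y! Gamma(1/alpha)) * (1/(1+alpha mu))^{1/alpha} (alpha mu/(1+alpha mu))^y` | `mu (1 + alpha mu)` |
| ZIP | `phi 1{y=0} + (1-phi) Pois(y; mu)`, `phi = F(z' gamma)` | `mu(1-phi)(1 + phi mu)` |
| ZINB | `phi 1{y=0} + (1-phi) NB2(y; mu, alpha)` | `mu(1-phi)(1 + (alpha+phi) mu)` |

Poisson is nested in NB (`alpha -> 0`) and in ZIP (`phi -> 0`); ZINB
nests all three. Fits are compared by AIC (`-2l + 2k`), BIC
(`-2l + k ln n`), the Pearson dispersion statistic
(`chi^2_Pearson / (n - k)`; values above 1 flag overdispersion), the
convergence rate across Monte Carlo replications, and the mean absolute
error `MAE = sum |E(y_i|x_i) - E(yhat_i|x_i)| / n` between true and
fitted conditional means.

## Worked example

Generate an LOS-shaped table (overdispersed NB outcome, mean ~8 days,
demographic covariates), describe it, and compare the four models:

```r
library(zicount)
library(dplyr)

los <- sim_los(2167, seed = 1)
describe_counts(los, "los")
#> los: n = 2167, mean = 8.07, variance = 42.70 (SD 6.54), 5.5% zeros, range 0-39
#> variance exceeds mean: overdispersion signal (Poisson equidispersion violated)

cmp <- compare_count_models(los, "los", c("age", "sex", "insurance", "admission_type"))
cmp$fit_stats |> select(family, AIC, BIC, pearson_dispersion)
#>   family      AIC    BIC pearson_dispersion
#> 1 nb       13385. 13442.              0.967
#> 2 zinb     13390. 13498.              0.981
#> 3 zip      17413. 17515.              3.61
#> 4 poisson  18404. 18455.              5.18
```

The NB model wins on both AIC and BIC; its Pearson dispersion is near 1
(the model accounts for the overdispersion) while the Poisson statistic
of 5.18 shows the equidispersion assumption failing badly. The
coefficient table shows why the choice matters:

```r
cmp$coefficients |>
  filter(model %in% c("poisson", "nb"), part == "count", term == "age") |>
  select(model, estimate, std.error, p.value)
#>   model   estimate std.error   p.value
#> 1 poisson -0.00193  0.000364  1.12e-07
#> 2 nb      -0.00204  0.000856  0.0169
```

Same data, same covariate — but the Poisson fit understates the standard
error roughly 2.4-fold and overstates the significance of age by five
orders of magnitude. `autoplot(cmp)` draws the count-part coefficients
with 95% intervals across models.

For the simulation side, a study over the NB-generating grid:

```r
study <- run_study(study_config(families = "nb", dispersions = c(1, 5, 10),
                                replications = 200))
render_tables(study$summaries)   # wide per-family CSV-ready tables
autoplot(study)                  # mean AIC by sample size and dispersion
```

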