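# odnaseg

Quantitative tools for organelle-DNA (oDNA) heteroplasmy segregation: how
cell divisions, mtDNA/ptDNA turnover, gene conversion, subsampling and
reamplification generate the cell-to-cell heteroplasmy variance that lets
purifying selection purge mutant organelle genomes — the "genetic
bottleneck" — and how to infer which mechanisms are at work from
single-cell heteroplasmy measurements.

The package is written for quantitative and population geneticists working
on organelle genetics: germline bottleneck studies in animals, and
recombination-driven segregation in plants, fungi and basal metazoans that
never sequester a germline.

## The theory in brief

For a population of cells with mean heteroplasmy E(h) and variance V(h),
the normalised variance `V'(h) = V(h) / (E(h)(1 − E(h)))` measures progress
toward fixation (0 = identical cells, 1 = all homoplasmic), with effective
bottleneck size `N_b = 1/V'(h)`. To first order the mechanisms contribute
additively:

    V'(h) ≃ Σ_divisions n_c/n
          + Σ_cycles t_i ( (1+n_d) ν_i f_i / n_i  +  2 κ_i (1−f_i)² )
          + Σ_subsamples n_c (1/n₂ − 1/n₁)
          + Σ_amplifications (1/n₁ − 1/n₂)

where n is copy number, n_c the inherited cluster size, ν turnover rate,
f the fragmented fraction of organelles, κ the gene-conversion rate and
n_d the molecules destroyed per autophagy event. Gene conversion is the
only copy-number-independent term, which is what makes it a powerful
segregation mechanism for organisms that cannot deplete oDNA; and f tunes
the cell between turnover-driven (∝ f) and conversion-driven (∝ (1−f)²)
segregation.

Around this core the package provides:

* `variance_theory`: the per-mechanism terms, event schedules, the
  division/regrowth cascade closed form, selection theory (logistic mean,
  closed-form variance), and the founder-referenced logit transform;
* an exact Gillespie simulator (C++ core) of a cell's oDNA population
  `(W_fused, W_single, M_fused, M_single)` with copy-number feedback,
  clustered autophagy, biased gene conversion and fission–fusion;
* sampling distributions for partitioning (hypergeometric, clustered,
  perfect, binomial comparison model) and Pólya-urn reamplification, plus
  a physical partitioning toy experiment;
* the mouse female-germline schedule (29 + 7 divisions, depletion to a
  fitted minimum b, reamplification) and competing mechanism variants;
* maximum-likelihood fitting of those models to clustered single-cell
  heteroplasmy data on the transformed scale, with stratified bootstrap
  intervals and AIC/R² model comparison;
* a synthetic-data generator for the whole pipeline, with a Gaussian
  backend and a stochastic-simulation backend.

## Worked example

Generate a synthetic oocyte study (40 mothers across ages 60–365 days,
30 oocytes each, truth: bottleneck b = 670 copies, ageing turnover
νf/n = 1.4e−4 per day), then fit and bootstrap the neutral
divisions+turnover+reamplification model:

```r
library(odnaseg)

dat <- generate_heteroplasmy(generator_config(seed = 11))
fit <- fit_ml(dat, "div_turnover_amp")
fit <- bootstrap_fit(dat, fit, n_boot = 200, seed = 1)
fit
#> ML fit [div_turnover_amp]: loglik = -1080.91, AIC = 2165.82, R^2 = 0.759 (n = 1200)
#>   b            708.181   [445.319, 1144.67] 
#>   nu_f_over_n  0.000148449   [0.000118091, 0.000171862] 
```

The fitted bottleneck (708, CI 445–1145 copies) and turnover compound
(1.48e−4/day, CI 1.18–1.72e−4) recover the generative truth: the minimum
copy number reached during germline development and the rate at which
ageing oocytes keep accruing variance. The implied effective bottleneck
at the end of development:

```r
sch <- mouse_schedule(b = 670, nu_f_over_n = 1.4e-4)
predict_norm_var(sch, c(0, 100, 300))
#>   age_days   norm_var bottleneck_size transformed_mean
#> 1        0 0.02609555        38.32072                0
#> 2      100 0.05409555        18.48581                0
#> 3      300 0.11009555         9.08211                0
```

so ~10^5 mtDNA molecules behave like an effective population of only ~38
segregating units at birth, and ageing halves that again within months —
the quantitative content of the bottleneck.

Checking one theory term against the stochastic simulator (turnover at
ν = 1/day in a fully fragmented cell of 1,000 molecules; theory
2νt/n = 0.002):

```r
ens <- run_ensemble(cell_state(0, 500, 0, 500), sim_params(),
                    t_max = 1, record_times = c(0, 1), n_reps = 10000,
                    seed = 2)
ens$norm_var[2]
#> [1] 0.001958793
```

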