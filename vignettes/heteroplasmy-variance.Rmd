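---
title: "Heteroplasmy variance mechanisms: theory, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heteroplasmy variance mechanisms: theory, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odnaseg)
```

## The scientific problem

Mitochondrial and plastid DNA (collectively oDNA) exist in hundreds to
thousands of copies per cell. A cell carrying a fraction $h$ of mutant
copies is heteroplasmic, and without a mechanism that *increases*
cell-to-cell variance in $h$, purifying selection between generations has
nothing to act on: deleterious mutations accumulate (Muller's ratchet). In
several animals, a germline "bottleneck" generates this beneficial
variance by transiently depleting mtDNA copy number; most other
eukaryotes never sequester a germline and must generate variance some
other way, for example through recombination-mediated gene conversion.

`odnaseg` quantifies this picture. Its core is an additive first-order
expression for the *normalised heteroplasmy variance*

$$V'(h) = \frac{V(h)}{E(h)\,(1 - E(h))},$$

a drift-scale quantity that is 0 for identical cells and 1 at complete
fixation, with effective bottleneck size $N_b = 1/V'(h)$. Five mechanism
classes contribute:

| mechanism | contribution to $V'(h)$ |
|---|---|
| cell division (copy number $n$, cluster size $n_c$) | $n_c/n$ |
| turnover ($\nu$/day, fragmented fraction $f$, autophagy size $n_d$) | $(1+n_d)\,\nu f t/n$ |
| gene conversion (rate $\kappa$/day) | $2\kappa (1-f)^2 t$ |
| subsampling $n_1 \to n_2$ | $n_c\,(1/n_2 - 1/n_1)$ |
| reamplification $n_1 \to n_2$ | $1/n_1 - 1/n_2$ |

Two structural facts drive the package's biology. First, every term
except gene conversion is suppressed by copy number $n$, so a large
population can only be segregated by repeated application or by a
physical bottleneck — whereas gene conversion contributes $2\kappa t$
regardless of $n$. Second, the fragmentation fraction $f$ of the
organelle population pulls turnover ($\propto f$) and gene conversion
($\propto (1-f)^2$) in opposite directions, so organelle fission–fusion
state selects the segregation mechanism.

```{r terms}
division_contribution(1000)
conversion_contribution(kappa = 0.002, f = 0, t = 1)
```

## The stochastic cell model

The simulator tracks integer copy numbers $(W_f, W_s, M_f, M_s)$ —
wild-type/mutant split into fused and singleton (fragmented) organelle
pools — under Gillespie dynamics (exact waiting times, implemented in
C++ against R's RNG so that a seed fixes the trajectory bitwise):

* **Replication** at per-molecule rate
  $r(N) = \max(0, \nu + (\lambda - \nu)(1 - \alpha N))$, mutants scaled
  by $(1+\delta)$. This relaxed-replication law equals $\lambda$ at
  $N = 0$ and exactly balances degradation at the target copy number
  $1/\alpha$, so the population is regulated around $1/\alpha$ for any
  $(\lambda, \nu)$. The defaults $\lambda = 2$, $\nu = 1$,
  $\alpha = 10^{-3}$, $\kappa = 0.002$, $n_d = 1$ (all per day) are the
  standard illustrative parameterisation used throughout.
* **Autophagy** removes $n_d$ same-type *singleton* molecules per event
  at event rate $\nu \cdot \mathrm{pool}/n_d$ — only fragmented
  organelles are degraded, which is what couples turnover to $f$ and
  produces the $(1 + n_d)$ factor (one unit of variance from the
  clustered removal, one from the compensating replication).
* **Gene conversion** is mass-action in discordant *fused* pairs:
  $aA \to AA$ at $\kappa (1+\varepsilon) W_f M_f$ and $aA \to aa$ at
  $\kappa (1-\varepsilon) W_f M_f$. This is the unique rate scaling for
  which $dV'/dt = 2\kappa(1-f)^2$ independently of $N$. The bias
  convention is that $\varepsilon > 0$ favours conversion toward the
  mutant type.
* **Fission/fusion** switch molecules between pools at per-molecule
  rates, giving equilibrium $f = \alpha_s/(\alpha_s + \alpha_f)$. This
  coarse-grained representation is deliberately the simplest one with a
  testable equilibrium; results depend on it only through $f$.

Extinction ($N = 0$) is absorbing; extinct cells have no defined
heteroplasmy and are excluded from ensemble statistics (their fraction
is reported separately). Ensemble standard errors on $V'$ use
$V'\sqrt{2/(m-1)}$, the normal-theory standard error of a variance.

```{r ssa}
ens <- run_ensemble(cell_state(0, 500, 0, 500), sim_params(),
                    t_max = 1, record_times = c(0, 1), n_reps = 2000,
                    seed = 1)
ens$norm_var[2]           # simulated turnover variance after 1 day
turnover_contribution(1, 1, 1, 1000)  # theory: 2 nu f t / n
```

## Selection theory

With a scaled replicative difference $\rho$ per day between the types,
the mean follows the logistic curve whose logit moves linearly:
$\mathrm{logit}\,E(h) = \mathrm{logit}\,h_0 + \rho t$. The variance
solves the linear-noise moment equation
$dV/dt = 2\rho(1 - 2E)V + 2\nu f E(1-E)/N$, giving the closed form
(at reference $h_0 = 1/2$, $s = \rho t$)

$$V(t) = \frac{2\nu f}{N\rho}\; \frac{e^{2s}\,(2s + e^s - e^{-s})}{(1 + e^s)^4},$$

which reduces to the neutral $2\nu f t/N \cdot h_0(1-h_0)$ as
$\rho \to 0$ and collapses as the mean approaches fixation. We derived
this form ourselves and validated it against the stochastic simulator;
it is the solution consistent with the logistic mean and the neutral
diffusion, and the simulation ensembles confirm it within Monte-Carlo
error (see below for the caveats at strong selection). For founders away
from $1/2$ the normalised variance is treated as founder-invariant,
which is exactly the construction the inference uses on the transformed
scale.

Two practical caveats, both visible in simulation and documented here
deliberately:

* The analytic map from the microscopic replicative advantage $\delta$
  to $\rho$ degenerates under copy-number control (at the set point the
  control law cancels a naive $\delta(\alpha N - 1)$ factor), so $\rho$
  is treated as an *empirically calibrated* quantity: `effective_rho()`
  fits the zero-intercept linear trend of the transformed ensemble mean.
* The closed form treats $N$ as an equilibrated constant. Under
  selection the regulated population equilibrates a few percent above
  $1/\alpha$ (mutants replicate faster), and the instantaneous $\rho$
  declines slightly as $h$ grows. At $\delta = 0.05$ these first-order
  approximation errors are 2–3%, which is why the consistency checks run
  at a Monte-Carlo resolution (2,500 replicates) commensurate with them
  and compare against the simulated equilibrium copy number.

## Sampling distributions

Division and subsampling are *without replacement*: hypergeometric, so
each molecule has exactly one fate. Clustered inheritance (`n_c > 1`)
samples homoplasmic clusters as units, with remainders treated as
singletons — molecule-conserving, and converging to the $n_c/n$ theory
term as $n$ grows. The binomial division model (daughter complements
drawn *with* replacement) is provided purely for comparison: it doubles
the division term to $2/n$ precisely because molecule fates are not
exclusive, the unphysical behaviour that motivates the hypergeometric
choice. Reamplification is a Pólya urn; its added-count law is
beta-binomial by exchangeability, and the implementation draws from that
exact law (a Beta-distributed replication propensity followed by a
binomial count) rather than iterating the urn.

The first-order amplification term $1/n_1 - 1/n_2$ is the large-$n_1$
limit of the exact urn variance $(n_2-n_1)/(n_2(n_1+1))$; at $n_1 = 4$
the exact value is $4/5$ of the formula, at $n_1 = 500$ the factor is
$500/501$. Tests assert both the formula and the exact enumeration, and
the distinction matters only for pools of a few molecules.

A deliberately minimal physical toy shows why the *partition mechanism*
matters for copy number but not heteroplasmy: organelles placed
uniformly in the unit square and bisected give binomial daughter copy
numbers; adding short-range pairwise repulsion (inverse-distance forces,
reflecting boundaries, relaxed until the largest displacement falls
below $10^{-4}$ or an iteration cap) spreads them evenly and shrinks
$V(N)$ several-fold — but because genotype is independent of position,
$V'(h)$ is unchanged. No interaction potential is specified by the
biology; only this ordering and invariance are asserted.

## The mouse germline schedule

Development of the female mouse germline is modelled as 29 divisions
(7-hour period) depleting copy number geometrically from $10^5$ to a
minimum $b$ — the debated physical bottleneck size, always a free
parameter here — then 7 divisions (16-hour period) regrowing to 5,000,
then reamplification to $10^5$: 36 divisions in total. Each
division-plus-regrowth cascade has the closed form (cycle-start copy
numbers $n_i = N_0 (a/2)^i$, $a = 2(N_k/N_0)^{1/k}$)

$$V' = \frac{a\,n_c + 2(a-1)}{a N_0}\; \frac{(2/a)^k - 1}{(2/a) - 1},$$

which we *define* by, and verify to $10^{-12}$ against, the explicit
per-cycle sum of division and amplification terms; the geometric
within-phase profile is a modelling choice (the data constrain only the
endpoints). Ageing oocytes accrue variance linearly through turnover at
the compound rate $\nu f/n$ — only this product is identifiable from
oocyte data — so

$$V'(\text{age}) = V'_0(b) + (1 + n_d)\,\frac{\nu f}{n}\,\text{age}.$$

```{r mouse}
sch <- mouse_schedule(b = 670, nu_f_over_n = 1.4e-4)
predict_norm_var(sch, c(0, 100, 300))
```

Competing mechanism emphases are exposed as `model_variants()`:
divisions+turnover+reamplification, a single oogenesis subsampling event
plus reamplification, and clustered division (large $n_c$ without deep
depletion). Tuned to the same developmental variance they make identical
age-0 predictions — mechanisms compensate — which is why model
comparison needs the age profile, and why the fitted likelihood surface
shows the bottleneck size and turnover rate trading off against each
other.

## Inference

Measurements are single-cell heteroplasmies clustered by mother, each
mother carrying her own founder level $h_0$. The founder-referenced
logit transform $z = \mathrm{logit}(h) - \mathrm{logit}(h_0)$ puts all
cells on a common scale: neutral drift leaves $E(z) = 0$, selection
makes $E(z) = \rho\,t$ exactly. The likelihood is Gaussian in $z$ with
the delta-method variance
$\mathrm{Var}(z) = V'(\text{age})/(E(h)(1 - E(h)))$ — a construction
chosen over a Kimura-type distribution on raw $h$ because
it makes the selection mean exactly linear and the founder structure
exactly absorbable. Cells fixated at $h \in \{0, 1\}$ have no finite
transform; they are excluded and counted, with no censored-likelihood
correction attempted.

Fitting is Nelder–Mead (`optim`) on log-transformed positive parameters;
bootstrap confidence intervals resample records with replacement
*within* each mother by default (preserving the founder design; whole-
mother resampling is available), refit from the point estimate, and take
percentile intervals, 1,000 resamples by convention. Models are compared
by AIC ($2k - 2\ell$) and by $R^2$ between per-age observed $V'$ (the
mean of per-mother normalised variances, so founder differences between
mothers do not masquerade as segregation variance) and the model curve.

## The synthetic-data generator

The generator emulates the study design the inference assumes: mothers
split across age groups, founder heteroplasmies uniform in $(0.2, 0.8)$,
a clutch of oocytes each. The default scale — 40 mothers, 30 oocytes
each, ages 60/150/250/365 days, truth $b = 670$,
$\nu f/n = 1.4\times10^{-4}$/day, neutral — mirrors a desk-scale mouse
oocyte study spanning young to aged animals; mothers-per-age counts are
plausible stand-ins (the real study design is not fully published) and
configurable.

Two backends: `gaussian_transformed` draws $z$ from the exact inferential
model and back-transforms (so generated $h$ is always inside $(0,1)$);
`full_ssa` pushes each oocyte's molecule counts through the development
cascade by exact sampling — hypergeometric halvings and Pólya regrowth,
which *are* the simulator's division and amplification operations — and
then runs the Gillespie core for the ageing turnover epoch at a reduced
surrogate copy number (1,000) with $\nu f$ rescaled so the compound
$\nu f/n$ matches the truth; the variance accrual depends only on that
compound and time, so the surrogate is dynamically equivalent at a
fraction of the cost. The two backends agree on per-age variance within
sampling error, which is itself one of the package's tests.

What passing recovery tests do and do not show: the generator satisfies
the inferential model's assumptions by construction (Gaussianity on the
transformed scale, exact founder knowledge, no measurement error in
heteroplasmy calls, no oocyte selection or atresia). Recovery of
$b$ and $\nu f/n$ within ±30%/±25% with ≥90% bootstrap coverage
demonstrates the estimator is consistent and calibrated *under those
assumptions* — it does not validate them for any real dataset.

```{r recover}
dat <- generate_heteroplasmy(generator_config(seed = 11))
fit_ml(dat)
```

## Numerical choices and degenerate inputs

* One estimator bias is worth knowing: the per-group empirical $V'$
  computed on the raw $h$ scale carries an $O(V')$ downward bias from
  the logistic squashing (about −2% at $V' = 0.01$, −16% at
  $V' = 0.1$). The likelihood works on the transformed scale and is
  unaffected; the bias only touches the descriptive statistics and the
  $R^2$, and the tests document it explicitly.
* The additive theory is first order: totals above 0.5 are flagged, and
  above 1 (nominal fixation) strongly warned, but reported uncapped so
  the per-event breakdown stays interpretable.
* `cascade_variance` requires $a \ge 1$ (depletion no faster than
  halving per cycle); at $a = 2$ (constant copy number) the geometric
  ratio is 1 and the sum is taken exactly rather than by the ratio
  formula.
* Perfect partitioning of odd type-counts assigns remainders by fair
  coin; clustered sampling splits the final overshooting cluster to
  conserve molecules exactly.
* Fits on data with fewer than two distinct ages warn: the turnover
  slope is structurally unidentifiable from a single age.
* Monte-Carlo consistency checks in the test suite use family-wise 95%
  bands (Bonferroni over the points compared in a block), the
  appropriate joint test for a trajectory of correlated comparisons.
* Problem sizes in the standard checks — $10^4$ replicates for
  single-mechanism ensembles, 2,500 for the 10-day selection
  trajectories, 100 synthetic datasets with 150 bootstrap resamples for
  recovery — were chosen so each comparison's Monte-Carlo resolution
  matches the approximation being tested.

## Known limitations

* No de novo mutation: the model moves variance between existing types
  only, so it cannot describe systems where mutation is as fast as
  segregation.
* The first-order theory saturates near fixation; its slowing is not
  modelled.
* No spatially resolved network model, nucleoid substructure beyond
  $n_c$/$n_d$ clustering, or kiss-and-run contact kinetics beyond what
  $\kappa$ and $f$ encode; no folliculogenesis or oocyte selection in
  the germline schedule.
* The selection closed form assumes equilibrated $f$ and $N$; at strong
  selection ($\rho t \gtrsim 1$ with large $\delta$) the constant-$N$
  approximation visibly underestimates the feedback coupling, as
  quantified above.
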