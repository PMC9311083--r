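---
title: "Sex-specific plasticity, population persistence, and the meta-analytic pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific plasticity, population persistence, and the meta-analytic pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexplast)
```

`sexplast` has two halves that mirror how sexually dimorphic phenotypic
plasticity is studied: an evolutionary quantitative-genetic **theory** of
population persistence under environmental change (closed forms plus a
deterministic simulator that validates them), and a **meta-analytic
pipeline** for sex-specific thermal plasticity data (paired effect sizes, a
phylogenetic multilevel model, heterogeneity and magnitude summaries). This
vignette explains the models, their assumptions, the numerical choices, and
what the synthetic-data validation does and does not demonstrate.

## The two-sex moving-optimum model

A single quantitative trait is expressed in females and males. The
environment $\varepsilon(t)$ moves each sex's phenotypic optimum at rate
$B_s$ (trait units per environment unit, $s \in \{f, m\}$), while a fixed
sex-specific reaction norm moves the phenotype itself at rate $b_s$. What
evolution must track is only the *effective* rate of optimum change

$$K_s = B_s - b_s,$$

the shift in the optimum not absorbed by plasticity. Sexual dimorphism in
plasticity is $b_{SD} = b_f - b_m$ and the sex-averaged norm is
$\bar b = (b_f + b_m)/2$.

Assumptions, shared with the moving-optimum tradition this extends:
Gaussian stabilising selection of constant sex-specific strength $\gamma_s$
around the moving optimum; a constant G-matrix
$\begin{pmatrix} V_{A,f} & C \\ C & V_{A,m}\end{pmatrix}$ with cross-sex
covariance $C = r_{mf}\sqrt{V_{A,f} V_{A,m}}$ (many loci of small effect);
fixed reaction norms (the package models the *consequences* of dimorphic
plasticity, not its evolutionary origin); and deterministic,
density-independent demography summarised by the intrinsic growth rate,
with maximum $r_{max}$ attained by a perfectly adapted population.

Each generation the mean breeding values respond to the two sexes'
selection gradients through the two-sex breeder's equation (half the
G-weighted average of the gradients, because each sex inherits from both
parents). Under directional change $\varepsilon(t) = \eta t$ the lags reach
a steady state; solving the linear system gives the selection-scaled female
lag

$$\gamma_f L_f = \frac{2\eta\,(K_f - r_{mf} c K_m)}{V_{A,f}(1 - r_{mf}^2)},
  \qquad c = \sqrt{V_{A,f}/V_{A,m}},$$

and symmetrically for males. Each sex carries a lag load
$(\gamma_s/2)L_s^2$. Two demographic modes translate loads into growth:
under **female demographic dominance** (males contribute only gametes)
growth is reduced by the full female load; under **demographic
co-dominance** (equal parental investment) by half of each sex's load. The
female-dominance form is equivalent to
$r_{eq} = r_{max} - \tfrac{2}{\gamma_f}\left(\frac{\eta K_f}{V_{A,f}}\right)^2
\left(\frac{1 - r_{mf}\alpha}{1 - r_{mf}^2}\right)^2$ with
$\alpha = K_m\sqrt{V_{A,f}}/(K_f\sqrt{V_{A,m}})$. A population persists
while $r_{eq} > 0$.

Because $r_{eq}$ is an exact quadratic in $b_{SD}$ (at fixed $\bar b$), the
growth-maximising dimorphism $\hat b_{SD}$ has a closed form
(`optimal_bsd()`). Three consequences anchor the package's headline tests:

* Under female dominance with cost-free, adaptive-but-imperfect plasticity
  ($0 < \bar b < B_f$) and $0 < r_{mf} < 1$, the optimum is strictly
  female-biased; with equal optima rates and variances it collapses to
  $\hat b_{SD} = 2(B_f - \bar b)(1 - r_{mf})/(1 + r_{mf})$ — the female lag
  load is a perfect square that the optimal dimorphism zeroes exactly, so
  the optimised population grows at $r_{max}$.
* Under co-dominance with full symmetry between the sexes the optimum is
  exactly $0$: sex-biased plasticity only hurts when the sexes matter
  equally and nothing else distinguishes them.
* Under fast environmental cycles the cycle-averaged growth is
  $r_{max} - \tfrac{\gamma_f}{4} A K_f^2$ (female dominance) or
  $r_{max} - \tfrac{\gamma_f}{8} A K_f^2 - \tfrac{\gamma_m}{8} A K_m^2$
  (co-dominance): no premium on dimorphism per se, only on each sex
  tracking its own optimum ($b_s = B_s$).

```{r optima}
p <- figure1_params("black") # eta 0.05, b_bar 0.5, B 1, V_A 0.5, r_mf 0.5
c(female_dominance = optimal_bsd(p, 0.05, "female_dominance"),
  codominance = optimal_bsd(p, 0.05, "codominance"))
```

### Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `B_f`, `B_m` | trait / env unit | 1 | optimum sensitivity to the environment |
| `b_f`, `b_m` | trait / env unit | 0.5 | adaptive yet imperfect plasticity ($0 < b/B < 1$) |
| `V_A_f`, `V_A_m` | trait units² | 0.5 | sex-specific additive variance |
| `r_mf` | — | 0.5 | typical positive cross-sex correlation |
| `gamma_f`, `gamma_m` | 1 / trait units² | 1 | stabilising selection; cancels from cost-free optima |
| `gamma_b_f`, `gamma_b_m` | — | 0 | quadratic cost of plasticity, $(\gamma_{b,s}/2) b_s^2$ |
| `r_max` | per generation | 0.05 | growth of a perfectly adapted population |
| `eta` | env / generation | 0.05 | directional change rate |

The reference curve settings (`figure1_params()`) pin down every parameter
except the common $\gamma$, which they leave free; the package fixes
$\gamma_f = \gamma_m = 1$ since it cancels from all cost-free optima and
only scales the depth of the growth curves.

### Numerical choices

* **Cost placement.** Costs of plasticity enter as a quadratic growth
  penalty $(\gamma_{b,s}/2) b_s^2$ per sex (full female cost under female
  dominance, half of each sex's under co-dominance), routed through the
  single function `plasticity_cost()` so the placement can be revised in
  one spot. The cost-bearing closed-form optimum is re-derived under this
  placement and verified against direct numerical maximisation.
* **$r_{max}$ is net of standing loads.** Constant loads that do not
  depend on $b_{SD}$ (e.g. the standing-variance load
  $(\gamma_s/2)V_{A,s}$) are absorbed into $r_{max}$; the simulator can
  subtract them explicitly via `include_variance_load = TRUE`, which
  shifts every growth rate by the same constant.
* **Singularities.** $|r_{mf}| = 1$ makes the $(1 - r_{mf}^2)$
  denominators vanish and is rejected with an error rather than handled as
  a limit.
* **Numeric optimisation.** `optimal_bsd_numeric()` is a deterministic
  golden-section search on $b_{SD} \in [-10, 10]$ (scaled by
  $\bar B = (B_f + B_m)/2$ when $|\bar B| > 1$) to a bracket tolerance of
  `1e-8`; since the objective is an exact concave quadratic the search is
  globally valid.
* **Cyclic amplitude.** The fast-cycle load term is written with an
  amplitude constant $A$; the simulator realises
  $\varepsilon(t) = \sqrt{A}\,\sin(2\pi t/\mathrm{period})$, whose mean
  squared value $A/2$ reproduces exactly that load term, so $A$ is the
  squared sinusoid amplitude.

### The simulator as oracle

`simulate_dynamics()` iterates the infinite-population mean recursion: it
is deterministic and noise-free, so agreement with the closed forms is a
sharp test, not a statistical one. The steady-state estimator averages
growth after a burn-in of 40% of the run (convergence window 10%, both
fixed), over whole cycles in cyclic mode. The test suite checks: machine
agreement for directional change across random parameter sets; the
single-sex lag limit $2\eta K_s/(\gamma_s V_{A,s})$ when $r_{mf} = 0$; and
the fast-cycle forms to within 2% of $r_{max}$ for parameter draws inside
the fast-cycle regime ($\gamma_s V_{A,s} \cdot \mathrm{period} \lesssim
0.1$ with period 4). The fast-cycle closed forms are limits: when
selection is strong enough that evolution partially tracks the cycle
($\gamma V \cdot \mathrm{period} \sim 0.5$), the true mean growth
deviates from the limit form by several percent, which is a property of
the regime boundary, not a numerical failure.

## The meta-analytic pipeline

### Effect sizes

From group summaries (mean, SD, n for each study × experiment × treatment
level × sex), `compute_effects()` computes for every within-experiment
pair of treatment levels, per sex, the bias-corrected standardised mean
difference (Hedges' d, small-sample correction $J = 1 - 3/(4m - 1)$ on
$m = n_1 + n_2 - 2$ df, sampling variance
$(n_1 + n_2)/(n_1 n_2) + d^2/(2m)$) and the log
coefficient-of-variation ratio lnCVR with its small-sample corrections;
plus a male-vs-female lnCVR at each level (male CV in the numerator, so
positive = males more variable).

Directionality is what makes d values comparable across heterogeneous
designs: for development time, longevity, size and survival the colder
treatment is the minuend (positive d = larger trait value in the cold);
for cold resistance, heat resistance and gene expression the warmer
treatment is (positive d = larger value in the warm, the adaptive
direction for resistance under the manipulations typically applied).
Levels are ordered by their temperatures; designs that manipulate
exposure duration rather than temperature carry an explicit
`direction_override` (`a_colder` / `b_colder`), otherwise the pair is
excluded as unorderable. The other exclusion rules — zero reported SD,
pooled n below 5, zero mean (lnCVR only) — are reason-coded, and
candidate contrasts always equal effects plus exclusions.

### The multilevel model

`fit_meta()` fits, by blocked Gibbs sampling,

$$y = X\beta + u_{sp} + u_{ph} + u_{st} + u_{ex} + m + e$$

where $y$ are effect sizes, $X$ contains an intercept (female mean) and
the sex(male) deviation (plus optional moderators crossed with sex, or the
sampling standard error for the Egger-style refit); $u_{ph} \sim
N(0, \sigma^2_{ph} A)$ uses the Grafen correlation matrix $A$ built from
topology alone (node height = descendant tips − 1, scaled to depth 1,
power 1 — `grafen_correlation()`, with species and phylogeny deliberately
separate components); $u_{sp}, u_{st}, u_{ex}$ are i.i.d.; $m$ carries the
*known* sampling covariance $M$ (variances $V_i$ on the diagonal,
within-experiment correlation 0.5: `build_M()`); and the residual $e$ has
a sex-specific variance. Priors on variances are inverse-gamma(0.001,
0.001); defaults are 4 chains × 30,000 iterations (burn-in 10,000, thin
10), overridable — the worked analyses and tests use shorter, stated
settings and check split R-hat (the fit refuses to report above 1.1
unless forced).

The sampler draws $(\beta, m)$ as a block — $\beta$ from its conditional
with $m$ integrated out, then $m \mid \beta$ — because the naive
one-at-a-time scheme mixes pathologically when residual variance is small
relative to sampling variance (exactly the conjugate special case used to
validate the sampler against the closed-form inverse-variance-weighted
posterior). All per-experiment solves are closed-form and vectorised for
block sizes 1 and 2.

Downstream summaries: `heterogeneity()` partitions $I^2$ by component
($I^2_k = \sigma^2_k / (\sum_k \sigma^2_k + \sigma^2_{typ})$ with the
weight-based typical sampling variance; components sum to the total by
construction) and reports marginal/conditional $R^2$ per posterior draw;
`folded_mean()` applies the folded-normal mean
$E|X| = \sigma\sqrt{2/\pi}\,e^{-\mu^2/2\sigma^2} + \mu(1 - 2\Phi(-\mu/\sigma))$
to each draw (analyse-then-transform) to summarise the magnitude of
plasticity regardless of direction. Which variances spread the fold is
genuinely ambiguous; the package defaults to the **total** heterogeneity
(all components plus the sex's residual) with `residual_only` selectable,
and labels results accordingly.

### Synthetic data: what passing tests do and do not show

`synth_generate()` draws a Yule phylogeny, Grafen-correlated phylogenetic
effects, independent species/study/experiment effects, a sex(male)
deviation, and sex-specific per-contrast residuals; group summaries are
back-constructed so that computed Hedges' d is unbiased for the recorded
per-contrast truth, with observed means and SDs carrying exact
normal/chi-square sampling noise. Defaults emulate a cold-resistance-like
trait: true female mean d = 1.76 with sex deviation −0.8, heterogeneity
dominated by experiment and residual levels
($\sigma^2_{sp} = \sigma^2_{ph} = 0.05$, $\sigma^2_{st} = 0.2$,
$\sigma^2_{ex} = 0.3$, $\sigma^2_{res} = 0.8$ per sex), group sizes
n ~ DU(5, 50), baseline mean 100 at CV 0.3, temperatures 18 / 25 °C for
two-level designs. With more than two levels, standardised level offsets
grade linearly with temperature rank, so sub-range contrasts carry
proportionally smaller true effects.

The validation this enables is *internal*: the pipeline recovers known
truth (95% credible-interval coverage of the sex deviation sits at ~94%
over 200 replicates of 40 effects each), the variance-component ordering
is recovered, and censored funnels are detected. It does not show that
real data meet the model's assumptions — Gaussian effects, correctly
reported SDs, a within-experiment sampling correlation of exactly 0.5, or
trait classes with homogeneous direction conventions. Two behaviours of
the generator are worth knowing: because group means are shifted by
$d \cdot SD$ at constant SD, a nonzero true d mechanically induces
nonzero lnCVR between treatments ($\approx -\ln(1 + d\cdot CV)$ under the
warm-minus-cold convention) even when no variability difference is
simulated; and because the sampling variance of d contains $d^2$, an
Egger-style slope can be positive at large true effects without any
selective reporting — asymmetry tests should be judged against
effect-matched simulations, as in the package's censoring test.

### Known limitations

The theory is deterministic: no drift, demographic stochasticity, density
dependence, evolving G-matrices or evolving reaction norms, and no account
of why dimorphic plasticity evolved. The meta-model is Gaussian with known
sampling variances and a single phylogeny; measurement error in the
phylogeny, non-Gaussian effect distributions, and model selection across
random-effect structures are out of scope. Analysis problem sizes (30
species, ~180 d effects in the worked scripts; 10 species × 40 effects ×
200 replicates in the coverage study) were chosen to make the full
validation suite comfortably reproducible on a single CPU.
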