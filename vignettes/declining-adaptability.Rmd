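---
title: "Declining adaptability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declining adaptability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitdecline)
```

# The phenomenon and the estimand

In evolve-and-compare experiments, a collection of founder genotypes
with graded initial fitness is propagated in a common environment for
hundreds of generations, after which each founder's fitness gain is
compared with that of the fittest founder. The recurrent observation is
*declining adaptability*: the less fit a founder starts, the faster it
gains fitness per generation. `fitdecline` treats this quantitatively.
The estimand is the slope magnitude $\beta$ of the log-log-linear
relationship between the per-generation excess gain and the
per-generation initial deficit, both measured against the fittest
founder on the natural-log (Malthusian) scale.

# Standardization

Fitness measurements arrive on heterogeneous scales, so all values are
first mapped onto a common multiplicative scale whose natural log is a
Malthusian-parameter difference per generation:

* `relative` — already a per-generation multiplier; identity.
* `malthusian_exp` — $e^m$ for Malthusian difference $m$; identity.
* `growth_rate_ratio` — a ratio accumulated over an assay of $A$
  generations; converted by the per-generation root $v^{1/A}$. The
  conversion applied to any given dataset is declared with the data,
  because published tables rarely state it.

With reference $r$ (maximal $w_{start}$; ties broken toward the
lexicographically smallest genotype id, so the choice is deterministic)
and generation count $G$:

$$x_i = \frac{1}{G}\ln\frac{w_{i,start}}{w_{r,start}}, \qquad
  y_i = \frac{1}{G}\left[\ln\frac{w_{i,final}}{w_{i,start}}
        - \ln\frac{w_{r,final}}{w_{r,start}}\right].$$

Units: natural-log fitness per generation. Both coordinates are
invariant under multiplying every fitness in a collection by one
positive constant, and the reference lands at $(0,0)$ by construction —
two properties the test suite checks to $10^{-12}$. Generation counts
are per-record (experiments in a combined analysis differ, roughly 240
to 640 generations), with a collection-level override.

One deliberate design decision: the deficit $x$ is computed from the
*initial* fitness $w_{i,start}$. The alternative of using the final
fitness in the numerator circulates in the literature's informal
descriptions but cannot anchor the reference at the origin; it is
exposed as `standardize(x_from = "final")` for comparison only, not
endorsed.

# The adaptability regressions

`fit_loglog()` is ordinary least squares of $\ln y$ on $\ln(-x)$;
`fit_exponential()` of $\ln y$ on $x$. OLS (rather than an
errors-in-variables fit) is used because the reported statistics of this
literature — correlation coefficient, $r^2$, F-test — are those of
simple regression; measurement noise in $x$ is a known limitation noted
below.

Points that cannot enter the transform are excluded *and logged with a
reason*, never silently dropped: the reference ($x = 0$; always, in the
log-log form) and any genotype with $y \le 0$ (it gained no more than
the reference; both forms). Fewer than three eligible points is an
explicit insufficient-data error. Both $r$ and $r^2$ are reported and
labelled, since legend conventions in this literature sometimes blur
which of the two is printed. `compare_fits()` prefers the form with the
higher $r^2$, breaking exact ties toward the log-log form with a flag.

Calibration (checked by the tests at these exact sizes): on noise-free
power-law data the slope is recovered to $10^{-9}$ with $r^2 = 1$; on
synthetic collections of 64 genotypes with generating slope 0.8 and
lognormal noise of sd 0.2 on the excess gain, 200 seeded fits recover
the slope within $\pm 0.1$ in at least 95% of runs with absolute bias
below 0.02.

# Trajectory extrapolation

If the log-log law holds with slope $\beta$, each successive fitting
epoch's log-gain shrinks by the factor $(1-\beta)$, giving

$$\ln\frac{w_t}{w_0} \;=\; \ln\frac{w_1}{w_0}\,
   \frac{1-(1-\beta)^t}{\beta},$$

a geometric series whose limit — the *fitness plateau* — is
$\ln(w_1/w_0)/\beta$. We read the exponent as $(1-\beta)^t$: the
alternative product reading $(1-\beta)\,t$ yields no plateau and is
internally inconsistent with the plateau expression itself. The domain
is restricted to $\beta \in (0,2)$, where $|1-\beta| < 1$ guarantees
convergence (monotone below 1, oscillating above); $t$ counts abstract
fitting intervals — the epoch over which the first gain was measured —
not necessarily single generations. Numerically, the $\beta < 1$ branch
uses `expm1`/`log1p` for stability as $\beta \to 0$ (where the
continuous extension is $t\,\ln(w_1/w_0)$), and the $\beta > 1$ branch
evaluates the signed power directly; $t = 0$ returns exactly 0. The
per-step identity $f(t{+}1) - f(t) = \ln(w_1/w_0)(1-\beta)^t$ holds to
$10^{-12}$ in the tests. No confidence bands are produced: they would
hinge on the regression's behaviour as $x \to 0$, where experimental
resolution is genuinely limited.

# The simulator

The population is a set of *genotype classes* — fitness, abundance,
model-specific state — rather than individuals, which keeps $N = 10^6$
tractable; equivalence with a brute-force per-individual simulator at
$N = 200$ is a tested property, not an assumption. Reproduction is
discrete-generation Wright–Fisher multinomial resampling with
probabilities $p_i \propto c_i w_i$ (the standard choice for
serial-transfer experiments; a Moran scheme would change time units but
not the comparative statics studied here). Mutation draws, per class, a
binomial number of mutants at the model's per-individual rate; each
mutant founds a new class of count one. Double mutations within one
generation are ignored — at rates of order $10^{-5}$ they are of order
$10^{-10}$. $N$ is conserved exactly by every step, empty classes are
pruned, and identical seed plus configuration gives bit-identical
trajectories (replicate $r$ of founder $f$ uses seed
$s + (f-1)\,reps + r$).

For performance the mutation step draws all $k$ mutants of a class in
one batched call (vectorised exponential, normal, or site draws); the
single-event `draw_mutant()` remains the reference implementation and
the reduction and engine-equivalence tests tie the two together.

The recorded observable is the population mean fitness; the final
fitness a replicate reports is the mean at generation $T$ (a defensible
alternative — sampling one random clone — adds variance without
changing the expectations compared here). Diffusion-theory anchors are
tested directly: a neutral single copy fixes at frequency $1/N$
($N = 100$, $10^5$ replicates), and a mutant with $s = 0.05$ at
Kimura's $(1-e^{-2s})/(1-e^{-2Ns})$ ($N = 1000$, $10^4$ replicates),
both within three binomial standard errors.

# The four macroscopic-epistasis models

All four couple the supply of beneficial mutations to current fitness
$w$, through different mechanisms:

| model | rate | effects | state |
|---|---|---|---|
| diminishing effects | constant $\mu$ | $s \sim Exp(\alpha_0 w^g)$ | none |
| declining rate | $\mu_0 w^{-g}$ | $s \sim Exp(\alpha)$ | none |
| finite sites | constant $\mu$ | fixed $s_j \sim Exp(\alpha)$, one use each | mutated-site set |
| FGM | constant $\mu$ | displacement $N(0,\sigma^2 I_n)$ | phenotype $z$ |

Effects compose multiplicatively, $w \to w(1+s)$, in the first three
(beneficial-only supply); FGM fitness is the Gaussian
$w(z) = e^{-\|z\|^2/2}$ with a single optimum at the origin, naturally
producing both beneficial and deleterious mutations, none filtered. The
Gaussian decay and the isotropic kernel are the canonical FGM choices;
the decay form is a tagged option so alternatives can be added. At
$g = 0$ the first two models collapse onto identical constant-DFE
dynamics — a tested reduction. A computed rate above 1 is an error,
never clipped: silently flattening the rate law would distort exactly
the fitness-dependence under study.

Default shape parameters — $\alpha_0 = \alpha = 20$ (mean effect 0.05),
$g = 1$, $L = 100$, $n = 10$, $\sigma = 0.05$ — keep typical effect
sizes in the experimentally observed 1–10% range. They are working
defaults, not estimates of any published configuration, and are
config-exposed.

**Founder ladders.** `founder_at_fitness()` assigns the target fitness
directly (for FGM, by placing the phenotype at distance
$\sqrt{-2\ln w_0}$ along the first axis, exact to $10^{-12}$). For the
finite-sites model a subtlety matters: a founder's fitness *is* the
record of sites already exploited, so a ladder built from fresh-state
founders would give every rung the same mutational supply and no
declining adaptability could emerge. `founder_ladder()` therefore
builds finite-sites rungs by pre-mutating sites in decreasing order of
effect — mirroring the substitution order adaptation itself favours —
so fitter rungs hold correspondingly weaker residual supplies. This is
the package's reading of how such collections arise (fitter strains
are fitter *because* they already fixed the strong mutations), and it
is what makes the model's macroscopic epistasis visible without any
microscopic epistasis.

**Study conditions for the simulation experiment.** The shipped
clonal-interference configuration uses $N = 10^5$, $\mu = 10^{-4}$
(so $N\mu = 10$, matching the regime of the $N = 10^6$,
$\mu = 10^{-5}$ default at a desk-scale population), $T = 500$
generations, 100 replicates per founder, and an 8-founder ladder with
per-generation deficits of 0 plus seven log-spaced values in
$[5\times10^{-4}, 5\times10^{-3}]$. The FGM ladder tops out at
$w = 0.9$ rather than 1: at the optimum no adaptation is possible, and
the log-log law is expected to hold *away* from the optimum's
immediate vicinity. Under these conditions the tests require the excess
gain to be negatively rank-correlated with founder fitness
(Spearman, $\alpha = 0.01$) for all four models, and the FGM points to
fit the log-log form with $r^2 \ge 0.8$.

# The synthetic-data generator

`generate_collection()` inverts the standardization plus the log-log
model: deficits uniform on a range (one genotype pinned at 0 as
reference), expected gains $E[y] = c\,|x|^\beta$, lognormal measurement
noise (Gaussian on $\ln y$ — the conventional error model for
relative-fitness assays; an additive-on-$y$ reading would let noise of
any useful size swamp gains of order $10^{-3}$), then back-conversion
to initial/final fitness. With zero noise the round trip through
`standardize()` is exact to $10^{-12}$.

The presets mimic the *designs* of five published studies — founder
counts (187, 64, 64, 8, 23, 8) and generation spans within 240–640 —
not their data: per-study deficit ranges, noise levels and generating
slopes are documented working values, and the hypermutator preset
simply carries the largest generating slope. Consequently, passing
tests demonstrate that the pipeline recovers known structure under a
plausible error model; they say nothing about any study's actual
values, and real data add features the generator omits: non-uniform
deficit distributions, genotypes expelled from the local fitness peak
(loss-of-function founders with $y \le 0$, which the regression
excludes and logs), and correlated assay errors.

# Degenerate inputs and tie-breaks

* Equal-fitness founders: reference chosen lexicographically.
* `deficit_range = c(0, 0)`: generation succeeds (all genotypes at the
  reference), and the regression then raises its insufficient-data
  error — the failure surfaces where the information is.
* Finite-sites supply exhausted: mutation is a no-op, so trajectories
  flatten at $w_0 \prod_j (1+s_j)$.
* $\mu = 0$: a legal model; populations change only by drift.
* Exact $r^2$ tie between regression forms: log-log wins, flagged.

# Limitations

* No recombination, demographic bottlenecks, or deleterious DFEs for
  the first three models; bottleneck-accumulation designs are emulated
  only through low-fitness founders.
* OLS ignores noise in $x$; with noisy deficits the slope is
  attenuated toward zero.
* The extrapolation inherits the regression's blind spot near
  $x \to 0$; plateau forecasts are short-horizon statements only.
* Simulation-based checks run at $N = 10^5$ rather than $10^6$ — same
  $N\mu$ regime, chosen as a desk-scale configuration; the engine
  accepts $10^6$.
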