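---
title: "A growth-rate-driven model of phenotypic adaptation under intermittent dosing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A growth-rate-driven model of phenotypic adaptation under intermittent dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenadapt)
```

## The model

Drug resistance in BRAF-inhibitor-treated melanoma lines can arise without
mutations, by cells reversibly shifting their phenotype under drug pressure.
`phenadapt` implements a deliberately simple cell-level model of this
process, built entirely from net growth rates measured in cell-count assays.

Each cell carries a discrete phenotype state on the lattice
$x_i = i\,\Delta$, $i = 0..n{+}1$, $\Delta = 1/(n+1)$, where $x = 0$ is the
most drug-sensitive (drug-naive) state and $x = 1$ the most drug-adapted.
A fitness matrix $\mathrm{FM}(x, d)$ assigns every state a per-day net
growth rate under every dose $d$: positive entries are daily division
probabilities, negative entries daily death probabilities (hence the hard
requirement $|\mathrm{FM}| \le 1$; out-of-range rates are rejected rather
than clipped, because clipping would silently change the dynamics). Only
the two endpoint columns are measured; interior states are linearly
interpolated in $x$, and missing doses can be added by log-linear
interpolation between the two bracketing positive doses (the weight
$w = \log(d/d_{lo})/\log(d_{hi}/d_{lo})$ is log-base invariant; dose 0 can
never anchor a log interpolation).

### From counts to rates

The 72-hour challenge assay reports fold changes relative to a reference
condition (500 nM). Under exponential growth,
$\lambda_d = \log(\mathrm{FC}^{rel,d})/\Delta t + \lambda_{500}$ with
$\Delta t = 3$ days; all logs in the package are natural logs, and the
assay duration is a parameter rather than a constant. The reference rate
$\lambda_{500}$ is the slope of a log-scale least-squares regression on a
7-day count series. Records from 1–4 weeks of pre-incubation have
statistically indistinguishable dose responses and are pooled (all
replicates equally weighted) into the drug-adapted endpoint; a
mean-of-week-means alternative is exposed via
`stratify_phenotype_rates(adapted = "week_means")` for unbalanced designs.
Rates are never clamped at this stage — range enforcement happens at
matrix construction, where the error can name the offending dose.

### Phenotype update strategies

Four per-opportunity kernels describe how a cell at state $x_0$ proposes
moves to its neighbours $x_\pm$:

* **none** — no movement; resistance can only come from pre-existing
  heterogeneity;
* **unbiased** — moves up or down with probability $\rho/2$ each
  (phenotypic instability);
* **semi-biased** — proposes with probability $\rho/2$ but accepts only
  moves to strictly higher fitness (noisy gradient sensing);
* **biased** — moves to a strictly fitter neighbour with probability one
  (stress-induced directed adaptation; $\rho$ plays no role).

Mass from rejected or boundary-blocked proposals stays on the current
state, so each kernel row sums to one exactly. Two conventions are worth
stating because the defining expressions leave them open. First,
$H(0) = 0$: an equal-fitness neighbour is not "higher fitness", so ties
are rejected — this also makes "none" the exact $\rho = 0$ case of both
stochastic kernels. Second, boundary proposals are rejected, not
reflected. Linear-in-$x$ columns are monotone, so the biased kernel never
sees two improving directions; for arbitrary matrices the kernel is made
total by letting the larger fitness gain win and splitting exact ties
equally.

### The stochastic simulator

`run_simulation()` iterates a daily loop: set the day's dose from the
treatment schedule; draw $v \sim U(0,1)$ and resolve birth/death before
the phenotype updates if $v < 0.5$, after them otherwise (this
order-randomisation removes the systematic bias either fixed order would
introduce); in the birth/death pass each cell divides with probability
$g = \mathrm{FM}(x, d)$ if $g > 0$ (daughter inherits the phenotype) or
dies with probability $|g|$ if $g < 0$; in the update pass every cell
performs the day's $\eta$ opportunities consecutively. Update frequencies
may be integers $0..10$ or $1/h$ for $h = 2..10$, meaning one opportunity
every $h$-th day — the phase is unspecified in the frequency definition,
and the package fixes it as days divisible by $h$, first update on day
$h$. Day indexing is 1-based; the row for day $t$ records the population
at the start of day $t$, so `count[t+1] = count[t] + births[t] -
deaths[t]` holds exactly on uncapped days.

Because cells are exchangeable given their state, the population is
represented as a count histogram over the $S$ states, and the per-cell
loops become per-state binomial draws (births, deaths) and multinomial
draws (updates) on the counts present at entry to each pass. This realises
the same stochastic process as an explicit cell list — the snapshot rule
means daughters born in a birth/death pass are not revisited within it,
though they do participate in an update pass that follows later the same
day — while running orders of magnitude faster. A population cap (default
$10^6$) down-samples uniformly (multivariate hypergeometric across states)
and tracks a multiplicative scale factor, so reported counts remain
unbiased; capped days are flagged. One root seed drives everything;
replicate ensembles derive per-run seeds from the root so summaries are
reproducible and replicate-order invariant.

Initial conditions: everyone at $x = 0$ or $x = 1$, a deterministic
stratified uniform spread, an explicit histogram, or a burn-in — uniform
seeding followed by 28 drug-free days under the configured strategy, then
sampling $n_0$ cells from the resulting distribution. The burn-in is
drug-free by default (the natural reading of a pre-treatment expansion);
its duration and the choice are configurable.

## Calibration

At the 500 nM dose no 72-hour fold changes exist, so four parameters are
fitted per strategy: the endpoint rates $\mathrm{FM}(0, 500)$ and
$\mathrm{FM}(1, 500)$ — bounded by the measured 300 and 1000 nM columns,
with 10 linearly spaced candidates each — and the update frequencies
$\eta_{on}, \eta_{off}$ over the 20-value set $\{1/h\} \cup \{0..10\}$.
`fit_parameters()` exhaustively evaluates the sum of squared distances
between ensemble-mean normalised counts and the data at four comparison
days under the continuous and the 7-on/7-off intermittent 500 nM schedule
simultaneously. The comparison days default to weekly ($7, 14, 21, 28$,
normalised to day 1): the in vitro curves are weekly but the exact
sampling days are not printed. All candidates share one root seed (common
random numbers): the objective surface is then deterministic given the
seed, the generating candidate of a synthetic dataset scores exactly
zero, and ties break by grid row order. Whether the original analysis
shared seeds across candidates is unknown, which is one reason exact
reproduction of previously reported optima is not attempted; the package's
recovery tests instead demonstrate that the machinery finds a known
generating candidate on a reduced $5^4$ grid. $\rho$ is fixed at 1 by
default; sweeps over $\rho$ and $n$ are plain configuration.

## Effective growth rates in closed form

Under the biased strategy a homogeneous population stays homogeneous, so
in the continuum limit its phenotype follows a clipped sawtooth:
$\dot x = +\omega$ on drug (until $x = 1$), $-\omega$ off drug (until
$x = 0$), with $\omega = \eta \Delta$. Over one period $\tau = t_{on} +
t_{off}$ of the limit cycle, counts satisfy $N(s+\tau) =
N(s)e^{\lambda_{eff}\tau}$ with $\lambda_{eff}$ the cycle average of
$\mathrm{FM}$ along the trajectory. `lambda_eff_numeric()` computes this
by exact segment-wise quadrature of the piecewise-linear integrand;
`lambda_eff_closed_form()` evaluates the six-case closed form (anchored at
$x = 1$ when the off-interval is the shorter one, at $x = 0$ otherwise,
with dedicated equal-interval expressions; at $t_{on} = t_{off} = 1/\omega$
the rate is exactly the mean of the four fitness corners). The two agree
to $10^{-8}$ over randomised sweeps — the quadrature is deliberately
structured so it shares no algebra with the closed form.

Two numerical facts deserve emphasis. The printed form of the
$t_{off} < t_{on} \le 1/\omega$ case is implemented with
$\Delta\mathrm{FM}(D)$ alongside $\Delta\mathrm{FM}(0)$; re-deriving that
limit cycle (rise from $1 - \omega t_{off}$ to 1, plateau, symmetric
descent) confirms this is the dimensionally and symmetrically consistent
coefficient, and the quadrature oracle agrees. And $\lambda_{eff}$ is
*not* continuous everywhere: approaching equal intervals from
$t_{on} > t_{off}$ with $T\omega < 1$, the limit cycle anchors at $x = 1$,
while at exact equality every starting phenotype is periodic and the
convention $x(0) = 0$ selects the bottom-anchored cycle — a genuine
one-sided jump. Continuity holds from the $t_{on} < t_{off}$ side
everywhere and from both sides once both intervals exceed the traversal
time $1/\omega$.

Continuous treatment is compared through its long-term rate
$\mathrm{FM}(1, D)$ (the $t_{off} \to 0$ limit). For 1:1 schedules with
the usual gradient signs ($\Delta\mathrm{FM}(D) > 0 >
\Delta\mathrm{FM}(0)$), $\lambda_{eff}$ is non-decreasing in $T$, so
intermittent dosing wins exactly below a critical interval:
$T\omega = (\Delta\mathrm{FM}(0) - \Delta\mathrm{FM}(D)) /
(2(\mathrm{FM}(1,D) - \mathrm{FM}(0,0)))$ on the $T \ge 1/\omega$ branch,
otherwise found by root-finding on the quadrature oracle;
`critical_schedule()` also classifies the no-crossing regimes
(`always_better` / `always_worse`). `schedule_heatmap()` maps
$\lambda_{eff}$ over $(\eta, T)$ grids in ODE or IBM mode with a shared
output schema; the ODE classification calls $|\lambda_{eff} -
\mathrm{FM}(1,D)| \le 10^{-10}$ a tie, the IBM mode uses a
2-standard-error band.

### What the stochastic and deterministic descriptions can agree on

The fitness matrix is read as *daily probabilities* by the simulator and
as *instantaneous rates* by the ODE: a day at rate $g$ multiplies expected
counts by $1+g$ in the IBM but by $e^g$ in the theory. The per-day order
randomisation makes the simulator's expected log-growth a trapezoid
evaluation of the fitness along the day's phenotype step, which matches
the continuum integral exactly for linear columns — so the residual gap
is the $\log(1+g) - g = O(g^2)$ term. Quantitative IBM-to-ODE agreement
is therefore a small-$|g|$ statement; the convergence experiments use
corners of magnitude $\le 0.012$ per day, where that bias sits below the
Monte-Carlo resolution of 50-run ensembles, and lattice refinement
($n = 19 \to 39$ at fixed $\omega$) is checked to not degrade the
agreement. At data-scale rates (up to 0.5 per day in magnitude) the two
descriptions agree qualitatively but not within Monte-Carlo error — a
limitation inherited from interpreting three-day net growth as daily
event probabilities, not a software artifact.

The per-run re-challenge analysis has a related caveat. When dosing
resumes after a holiday, death events spike because cells have
re-sensitised, and the ensemble-mean deaths-per-cell series peaks on the
re-challenge day under both directed strategies at their fitted optima. A
*per-run* argmax is less clean: in the quarter of runs that happen to
take updates-first on the re-challenge day and birth/death-first on the
following day, both days draw deaths at the same phenotype state, and the
larger of the two is a coin flip. Roughly one run in eight therefore
peaks one day late; this is a structural property of the
order-randomised daily loop, not noise that more cells would remove.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth:
Hill-type dose-response curves for the naive and adapted endpoints on the
twelve-dose grid (0 to 10000 nM), constrained at construction to the
crossing structure that drives the whole analysis — naive fitter off
drug, adapted fitter at and above the 500 nM pre-incubation dose, all
rates within $[-1, 1]$, so the fitness gradient changes sign across the
grid. The default curve parameters (naive top 0.30, bottom −0.55 per day,
midpoint 80 nM; adapted top 0.05, bottom −0.10 per day, midpoint
1500 nM) were chosen once to resemble the reported dose-response structure of the measured system:
endpoint rates of a few tenths per day, a naive IC50 well below the
pre-incubation dose, an adapted curve with compressed span and shifted
midpoint. The reference rate defaults to the reported 0.1059 per day.
Fold changes are back-computed by inverting the rate equation, and noise
is multiplicative lognormal (keeping fold changes positive; the assay's
true noise model is not stated), with $\sigma = 0.05$ and quadruplicate
replicates as defaults. Week 1–4 records share the adapted curve; week 0
records the naive curve.

What passing on synthetic data does *not* show: the generator has no
plating variation, confluence effects, or week-to-week drift in the
adapted stratum, and its noise is exactly the lognormal form the
estimators invert. Recovery results bound estimator correctness, not
robustness to real assay artifacts.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: $10^3$ randomised
schedules for the closed-form/oracle comparison; 200-run ensembles of
1000 cells for the branching-process checks; 50-run ensembles of $10^4$
cells on 8-week horizons for IBM-to-ODE convergence; a $5^4$ reduced grid
with 50-run ensembles (common random numbers) for parameter recovery; and
100-run ensembles for the re-challenge analysis — sizes chosen so each
property is resolved with comfortable margin at interactive runtimes.
Other conventions: the limit cycle is found by iterating the cycle map
from $x(0) = 0$ to a $10^{-14}$ fixed-point tolerance; root-finding uses
bisection to $10^{-12}$ on the quadrature oracle; extinction is recorded
and extinct runs are excluded from ensemble rate averages (the extinct
fraction is reported alongside); and the 500 nM column inserted during
fitting re-interpolates interior states so column linearity is preserved
exactly.

## Known limitations

The adapted endpoint is anchored to 500 nM pre-incubation only, so at
doses above 500 nM the true adapted rates may exceed the matrix values —
the interpolation cannot see adaptation beyond the three-day assay.
Non-1:1 closed forms and dose-dependent adaptation speeds are supported
numerically (the quadrature handles arbitrary $t_{on}$:$t_{off}$) but no
new closed forms are derived. There is no spatial structure, no
competition, no pharmacokinetics, and events resolve on a daily grid.
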