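# phenadapt

Growth-rate-driven modelling of phenotypic adaptation in drug-treated
cancer cell populations.

Targeted therapy against BRAF-mutant melanoma reliably selects for
resistance, and a growing share of that resistance is non-genetic: cells
shift phenotype under drug pressure and shift back during drug holidays.
`phenadapt` is for modellers and quantitative biologists who want to work
with this process using nothing more than cell-count data. It turns
72-hour fold-change assays into per-day net growth rates, organises them
into a phenotype-by-dose **fitness matrix**, simulates a stochastic
individual-based model of cells moving on a bounded phenotype lattice
under four candidate update strategies, calibrates the model's free
parameters against treatment-response curves, and — for the directed
strategy — provides closed-form long-term growth rates that say exactly
when intermittent dosing beats continuous dosing.

## The model in brief

Each cell occupies a state on the lattice `x_i = i/(n+1)`, `i = 0..n+1`,
from drug-naive (`x = 0`) to drug-adapted (`x = 1`). The fitness matrix
`FM(x, d)` gives the per-day net growth rate of state `x` under dose `d`;
positive entries act as daily division probabilities, negative entries as
daily death probabilities. Endpoint columns come from data via

```
lambda_d = log(FC_rel_d) / 3 + lambda_ref        (per day, natural log)
```

and interior states are linear in `x`. Per update opportunity a cell
moves to a neighbouring state under one of four kernels — `none`,
`unbiased` (rho/2 each way), `semibiased` (rho/2, accepted only uphill in
fitness), `biased` (uphill whenever possible) — and the simulator
resolves division/death and updates in random daily order. For the
biased strategy the population stays homogeneous and its phenotype
follows a clipped sawtooth `dx/dt = ±omega`; averaging `FM` over the
resulting limit cycle yields a six-case closed form for the effective
growth rate `lambda_eff(t_on, t_off, omega)`, the critical 1:1 interval

```
T * omega = (dFM(0) - dFM(D)) / (2 * (FM(1,D) - FM(0,0)))
```

at which intermittent and continuous schedules tie, and `(eta, T)`
classification heatmaps.

## Worked example

Everything below runs from generated data with known ground truth — no
downloads. Recover rates from a synthetic assay, build the matrix,
interpolate the 500 nM column, and compare schedules:

```r
library(phenadapt)

assay  <- synth_foldchange_dataset(synth_params(sigma = 0.05), seed = 11)
series <- synth_count_series(rate = 0.1059, sigma = 0.05, seed = 11)

lambda_ref <- estimate_reference_rate(series)   # 0.1173792 per day
rates <- stratify_phenotype_rates(assay$records, lambda_ref)
fm500 <- add_dose_loglinear(build_fitness_matrix(rates, n = 9), 500)

gradient_direction(fm500, c(0, 500))
#>   dose_nM delta_fm direction
#> 1       0   -0.239        -1
#> 2     500    0.501         1
```

The gradient sign flips across the grid: off drug, fitness increases
towards the naive state; at 500 nM, towards the adapted state. That is
the engine of the whole analysis. Now the schedule comparison, first in
closed form (adaptation speed `omega = eta * Delta = 0.1`/day, weekly
1:1 intervals):

```r
inp <- eg_inputs_from_fm(fm500, 500, omega = 0.1, t_on = 7, t_off = 7)
lambda_eff_closed_form(inp)   # -0.0413 per day  (intermittent)
continuous_rate(inp)          # +0.0299 per day  (continuous, long-term)
critical_schedule(inp)
#>   T_crit T_omega T_eta   status
#> 1   13.9    1.39  13.9 crossing
```

Weekly intermittent dosing turns net growth negative while continuous
dosing cannot (its long-term rate is the adapted cell's +0.03/day), and
the tie sits at intervals of ~14 days: shorter holidays than that keep
winning. The stochastic model, started from a drug-free burn-in as in
the calibration experiments, agrees over a four-week horizon:

```r
cfg <- simulation_config(fm500, update_strategy("biased"),
                         eta_on = 1, eta_off = 1, n0 = 100,
                         init = "burn_in")
glance(run_replicates(cfg, schedule_intermittent(500, 7, 7, 28),
                      n_runs = 100, seed = 11))
#>   final_mean_norm lambda_eff extinct_fraction
#> 1          0.0909    -0.0874             0.18
glance(run_replicates(cfg, schedule_continuous(500, 28),
                      n_runs = 100, seed = 11))
#>   final_mean_norm lambda_eff extinct_fraction
#> 1           0.109    -0.0826                0
```

Counts are normalised to day 1; the continuous arm also shrinks over
this short horizon because the burn-in population is drug-naive and dies
while it adapts — the closed-form `continuous_rate()` deliberately
describes the post-adaptation long run.

Calibration against treatment curves (`fit_parameters()`), simulated
`(eta, T)` heatmaps (`schedule_heatmap()`), and per-result `tidy()` /
`glance()` / `autoplot()` methods are covered in the methods vignette
(`vignettes/phenotype-adaptation-model.Rmd`).

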