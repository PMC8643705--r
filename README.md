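# adaswitch

Stochastic single-cell simulation and analysis of the *Escherichia
coli* adaptive response to DNA alkylation damage.

## The problem

The adaptive response (the *ada-alkB* operon, *alkA*, and *aidB*)
protects *E. coli* against alkylating agents such as methyl
methanesulfonate (MMS). Its regulator Ada is present at roughly one
molecule per cell before stress; methylation of a single Ada molecule
converts it into the transcriptional activator of its own operon,
closing a positive feedback loop. Cells that happen to hold zero Ada
copies when stress begins cannot fire the switch until basal expression
produces one, so an isogenic population splits into an early
"Activated" majority and a "Delayed" minority that lacks the entire
repair regulon for an extended time. Delayed cells accumulate DNA
mismatches (visible as fluorescent MutL foci) and fixed mutations, yet
many survive by activating the response late — making them a viable
hypermutable subpopulation that disproportionately feeds genetic
variation into the population.

The package is for quantitative biologists who want a fully generative,
testable model of this system together with the complete analysis
pipeline used on such single-cell data:

* `simulate_population()` / `simulate_cell()` — mother-machine cells
  under a step or pulse dose profile `m(t)`: birth–death basal
  expression, per-molecule switch hazard `k_m s(t)` with a lagged
  damage-sensing signal, positive-feedback amplification to ~1000
  copies modulated by a shared Ornstein–Uhlenbeck fluctuation, three
  lesion pools with saturable basal repair, mismatch formation
  `r0 + r_mut sat(L_o6meg) + r_tox sat(L_tox)`, mutation fixation, and
  a distress-gated death hazard. One vectorised engine serves both
  trace-level runs (hundreds of cells with per-frame fluorescence) and
  event-level runs (10^6 cells for sorting experiments).
* Trace analysis — `baseline_subtract()`,
  `detect_activation_delay()` (threshold = baseline + 5 SD sustained 3
  frames), `delay_fit()`, `population_mean_curve()`,
  `steady_state_crosscorr()` with shuffled-cell and
  constitutive-marker null controls.
* Molecule counting — `snapshot_molecule_counts()` with the >8
  counting limit, `summarize_counts()`, censoring-aware
  `fit_poisson()` with Fano factor and goodness of fit.
* Damage dynamics — `dedup_foci()`, `mismatch_rate_curve()`,
  `smooth_curve()` (30-min moving average), `survival_curve()`
  (product-limit with lysed/arrested/escaped fate accounting).
* FACS — `define_gates()` (Delayed gate on the untreated mode,
  Activated gate of identical width on the treated mode),
  `apply_gates()`, `colony_assay()`, `mutant_frequency()`,
  `plasticity_share()`, and the end-to-end
  `run_facs_experiment()`.

The calibrated model reproduces the study's headline numbers: ada
activation delays of 63 ± 19 min at 1 mM with the alkA reporter offset
by ~8 min at slope ~1; basal abundances (AlkA ~2.6 molecules/cell with
~5% of cells beyond the counting limit, ~20% of cells with exactly one
AlkB, AidB absent, Fano factors near 1); <10% survival of
ΔalkA/ΔalkB/Δada-alkB after 4 h of 1 mM MMS versus ~90% for the
repair-dead but regulation-competent *ada^C321A*; and
Delayed:Activated rifampicin-resistance frequency ratios near 1.5 / 5 /
4 at 1 / 3 / 10 mM, with the ~15% Delayed gate at 3 mM contributing
about half of all viable mutants.

## Worked example

Simulate a dual-reporter wild-type population under a 1 mM step and
call activation delays on both reporters:

```r
library(adaswitch)

pop <- simulate_population(139, sim_params(),
                           mms_profile(1, onset = 21), horizon = 150,
                           seed = 1, channels = c("ada", "alkA"))
tr <- baseline_subtract(as_trace_set(pop), "ada")
tr <- baseline_subtract(tr, "alkA")
fit <- delay_fit(detect_activation_delay(tr, "ada"),
                 detect_activation_delay(tr, "alkA"))
fit
#> <delay_fit> n = 117 (excluded 22)
#>   A: 60.4 +/- 16.0 min; B: 68.5 +/- 15.9 min
#>   Pearson r = 0.996; B = 0.990 * A + 8.6 min (paired diff 8.1 min)
```

Cells called in both channels activate after 60.4 ± 16.0 min (ada) and
68.5 min (alkA) in this draw (63 ± 19 min averaged over seeds); the
regression says the alkA delay is the ada delay plus ~8 min — the
fluctuation-propagation signature. The 22 excluded cells either died
before a call or stayed Delayed past the window.

A full sort-and-plate mutation experiment at 3 mM (event-level, 10^6
cells; ~2 min):

```r
ex <- run_facs_experiment(3, n_cells = 1e6, seed = 1)
a <- ex$assay
a$frequency[a$subpopulation == "Delayed"] /
  a$frequency[a$subpopulation == "Activated"]
#> [1] 5.751592
ex$sort$fractions
#>   Delayed Activated
#> 0.1595054 0.8138194
ex$share
#>   subpopulation   weight share_pct
#> 1       Delayed 43210.01  52.99182
#> 2     Activated 38330.89  47.00818
```

The Delayed gate holds ~16% of events, its rifampicin-resistant mutant
frequency is ~5-fold the Activated gate's (5.75 in this single draw,
5.2 averaged over seeds), and the
counts-times-percentage accounting attributes about half of all viable
mutants to it.

The numbered drivers under `analysis/` run the whole study:
`01_simulate.R` (datasets), `02_activation_delays.R`,
`03_fluctuations_and_counts.R` (cross-correlation with null controls,
basal counting), `04_mismatch_and_survival.R` (genotype panel),
`05_facs_mutation.R` (dose series). Each writes tables under
`results/`.

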