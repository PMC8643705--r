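---
title: "A stochastic single-cell model of the E. coli adaptive response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic single-cell model of the E. coli adaptive response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaswitch)
```

## The biology being modelled

The *E. coli* adaptive response protects cells against DNA alkylation
damage. Its master regulator Ada is a bifunctional protein: it repairs
methyl-phosphotriester and O^6^-methylguanine lesions by irreversible
methyl transfer, and the methylated form activates transcription of its
own operon (*ada-alkB*) and of *alkA*, closing a positive feedback loop.
Basal Ada expression is extremely low (about one molecule per cell), so
a substantial fraction of cells carries zero copies at the moment
alkylation stress begins. Those cells cannot trigger the feedback until
basal expression produces a molecule, which splits an isogenic
population into an early-activating majority ("Activated") and a
minority that stays off for a long time ("Delayed"). Because AlkB and
AlkA are also essentially absent before induction, Delayed cells lack
the whole repair arsenal: they accumulate replication errors — visible
as fluorescently labelled MutL foci at nascent mismatches — and fixed
mutations, yet many of them survive if they activate the response
eventually. The package simulates this system at the level of single
mother-machine cells and implements every analysis stage used to
quantify it: activation-delay calling, dual-reporter correlation,
censored molecule-count statistics, mismatch-rate and survival curves,
and flow-sorting with mutant-frequency accounting.

## Model structure

`simulate_population()` advances all cells together in fixed steps of
`dt = 0.5` min, with per-step event probabilities `1 - exp(-rate * dt)`.
A fixed-step scheme was chosen over an exact event-driven simulation
because every per-molecule rate is far below `1/dt` (the fastest, the
per-molecule methylation hazard at 10 mM, is ~0.1 min^-1), so the
discretisation error on the critical 0-to-1 molecule transition is of
order `(rate * dt)^2 ~ 1e-4`, while vectorising across cells is what
makes million-cell sorting experiments tractable on one CPU.

**Expression.** Each gene's OFF state is a birth–death process with
stationary mean equal to the measured basal abundance (Ada 1.0, AlkB
0.25, AlkA 2.6, AidB 0.05 molecules/cell) and dilution rate
`log(2)/30 min`. The basal *alkA* law carries a 5% subpopulation drawn
from Poisson(15): a pure Poisson(2.6) puts only 0.15% of cells above
the single-molecule counting limit of 8, whereas ~5% of cells are
reported as uncountable; a small basal-elevated fraction reproduces
both the 2.6 average and the censored tail. After the switch, copy
number relaxes towards `N_ss * d(t)` with a 35-min timescale, where
`d(t)` is a per-cell Ornstein–Uhlenbeck fluctuation (mean 1, SD 0.2,
correlation time 30 min) shared by *ada* and *alkB* and read by *alkA*
with an 8-min lag — the minimal structure that produces positive
dual-reporter cross-correlation over ±1 h with an offset peak, while
the constitutive marker fluctuates independently.

**The switch.** Each Ada molecule is methylated at rate `k_m * s(t)`,
where the sensing signal `s` lags the extracellular dose with a 33-min
time constant (`ds/dt = beta_s (m - s)`). The lag stands for the
accumulation of the methyl-phosphotriester lesions that actually
methylate Ada; it also lets cells keep switching for a while after the
drug is washed out, which is what allows Delayed cells to rescue
themselves during post-sort outgrowth. A first-order lag rather than a
direct `k_m * m` hazard is also what concentrates the called delay
distribution: with a constant hazard the delays would be exponential
(coefficient of variation 1), incompatible with the observed 63 ± 19
min. Cells with zero Ada cannot switch; while unswitched, their *ada*
birth rate is divided by `1 + (m/2.35)^5`, a cooperative dose-dependent
suppression representing transcription/replication blocking by damage.
This term is what makes the Delayed subpopulation grow with dose: at
1 mM it is mild (factor ~0.99), at 3 mM most zero-copy cells are
trapped until wash-out.

**Lesions.** Three pools with influx `alpha * m(t)`: `meA` (3meA;
substrate of AlkA, with saturable basal repair by Tag), `meC`
(3meC/1meA; AlkB substrate, no basal enzyme) and `o6meg` (O^6^meG; Ada
C321 substrate, with saturable basal repair by the low-abundance,
high-affinity suicide methyltransferase Ogt). Basal repair is
Michaelis–Menten with capacities that saturate between 1 and 3 mM,
encoding the physiological observation that alternative repair
pathways cope at low dose and are overwhelmed above it; this is the
source of every superlinear dose effect in the model. Once the
response is on (a 3-min expression lag after the switch, plus the
*alkA* induction lag for 3meA), induced repair removes lesions in
first order; O^6^meG removal by the abundant activated Ada pool is
effectively immediate (8 min^-1). Genotypes knock out their terms:
`delta_alkA` and `delta_alkB` lose one induced pathway each,
`delta_ada_alkB` never switches at all, and `ada_C321A` switches with
wild-type kinetics (its slightly elevated basal expression is not
modelled by default; an override exists) but never repairs O^6^meG,
giving the sustained, intermediate mismatch elevation with near-normal
survival. After wash-out an extra first-order clearance (0.08 min^-1)
represents resumed growth, replication-coupled dilution and excision in
fresh medium.

**Mismatches and mutations.** The MutL-focus rate per cell is
`r0 + r_mut * sat(L_o6meg) + r_tox * sat(L_meA + L_meC)` with
`sat(L) = L/(1 + L/10)`: conversion of lesions into replication errors
is capped by replication throughput, which is why the mutagenic burden
saturates between 3 and 10 mM while lesion load keeps rising. Foci per
frame are Poisson draws; a focus becomes a fixed mutation with
`p_fix = 0.01` (the canonical fraction of mismatches that escape
mismatch repair), and a fixed mutation confers rifampicin resistance
with `p_rif = 0.4`. That last number is deliberately a scaled
effective probability, not the per-locus value (~1e-5): it sets only
the absolute colony counts, and every reported quantity built from
them (frequency ratios, plasticity shares) is invariant to it, while
desk-scale sorts of 10^5–10^6 cells then yield hundreds of colonies and
tight Monte-Carlo error instead of single-digit counts.

**Death.** A distress variable `D` relaxes towards 1 with a 30-min
time constant while the replication-blocking load `meA + meC` exceeds a
lethal threshold (150 lesions) and decays with a 10-min constant below
it; the hazard is `h_max * D` with `h_max = 0.025 min^-1`. The
threshold-plus-saturating form encodes "beyond a certain level of
blocking lesions, tolerance pathways cannot compensate": a hazard
linear in load cannot simultaneously let wild type survive 1 mM almost
untouched, kill the repair deletions within 4 h at the same dose, and
leave a sortable Delayed population alive after 90 min at 3 mM,
because tripling the dose would triple the hazard rather than merely
advance the threshold crossing. Fates of dying cells (lysis, growth
arrest, filament escape) are drawn 0.5/0.4/0.1; escaping filaments are
right-censored in the survival analysis by default since they leave the
field of view without confirmed death.

**Observation.** Reporter fluorescence is `scale * n(t - maturation) +
background` plus Gaussian frame noise, sampled every 3 min; the 34-min
`maturation` parameter lumps transcription, translation and fluorophore
maturation of the slow CFP/YFP reporters into one expression-to-signal
lag. Channel scales differ (the mYPet
channel is acquired at longer exposure, so its a.u./molecule scale is
higher), equalising the early post-switch rise rates of the two
reporters in intensity units. The cytometer sees the same quantity
through a log-normal spread (CV 0.25). Single-molecule counting snapshots draw from the basal laws
and censor counts above 8, as in the fixed-cell assay.

## Analysis conventions and numerical choices

* Delay calling: threshold = pre-stress baseline + 5 baseline-SD,
  sustained for 3 consecutive frames (9 min). Both knobs are exposed;
  the rule is deliberately simple and translation-equivariant. Cells
  crossing after 120 min (or never, within the window) are labelled
  Delayed; traces that end in death before the window is exhausted give
  NoCall.
* The published "AlkA delay = Ada delay + 8 min" line is reported both
  as the free-slope least-squares intercept (slope is expected near 1)
  and as the paired mean difference, since the original fit's
  constraint is not documented.
* Cross-correlation: per-cell segments are centred on their full-window
  means; per-lag normalisation uses the overlapping segments' variances
  about those means, which keeps every value in [-1, 1] by
  Cauchy–Schwarz while remaining exactly 1 at lag 0 for identical
  traces. Positive lag means the second channel lags the first. The
  steady-state window defaults to 3 h after onset. The shuffled
  control permutes cells with fixed points displaced, so no cell is
  ever paired with itself.
* Mismatch rates: foci persisting over consecutive frames count once,
  at their first frame; the per-frame rate divides by the cells still
  alive and observed at that frame (per-frame denominators are the
  default; the fixed initial-count alternative is a flag away via
  `at_risk`). The 30-min moving average uses the exact 11-frame
  centred kernel at 3-min sampling, shrinking symmetrically at the
  edges.
* The censored Poisson fit maximises the likelihood in which censored
  cells contribute `P(X > 8)`; the goodness-of-fit chi-square pools
  bins to expected counts of at least 5. The headline mean is computed
  over countable cells (the published average excludes cells beyond the
  counting limit); the truncated MLE is reported alongside.
* Gates: the Delayed gate is centred on the kernel-density mode
  (Gaussian kernel, Silverman bandwidth) of the untreated log10
  intensity with half-width 3 untreated-SD; the Activated gate has the
  identical width at the treated global mode. Bounds are closed-open.
  Overlapping gates are an error, not a warning.
* The plasticity share is the literal counts-times-percentage rule,
  which requires an equal number of sorted cells per gate and is
  enforced as such.

## The simulated sorting experiment at desk scale

`run_facs_experiment()` treats 10^6 event-level cells for 90 min,
snapshots the cytometer, defines gates against an untreated culture,
sorts an identical number of cells per gate (capped by the smaller
gate population, ~1.5 x 10^5 Delayed events at 3 mM), continues the
simulation for 180 min of post-sort outgrowth without drug, and plates.
The original experiments sort 10^6 cells per gate from an effectively
unlimited culture; sorting equal numbers is what the share formula
requires, and colony counts simply scale with the sorted number. Cells
that were lethally damaged but still intensity-positive at the sorter
fail to form colonies during the outgrowth window — this survivorship
is what caps the Delayed mutant frequency at 10 mM below its 3 mM
ratio, and it is also why the never-activating operon deletion loses
colony-forming ability at high dose while Delayed wild-type cells,
which can still switch on the response after wash-out, do not.

## Calibration

The default constants live in
`inst/extdata/default_calibration.yaml` — they are data, not code — and
were produced by the staged search in `scripts/calibrate.R` against the
published summary statistics: basal abundances and censored fractions
(counting assay), the 63 ± 19 min ada delay and 8-min alkA offset at
1 mM, genotype survival at 4 h of 1 mM, the ~15% Delayed gate fraction
at 3 mM, and the 1.5/5/4-fold Delayed:Activated mutant-frequency
ratios at 1/3/10 mM. The stages decouple: expression means come
directly from the counting statistics; the switch and observation lags
are fit to the delay distribution; lesion influx, threshold and hazard
to the survival panel; mismatch-rate constants and wash-out clearance
to the frequency ratios. Problem sizes in the shipped analyses (139
trace cells as in the dual-reporter dataset, 500 cells per survival
genotype, 10^6-cell event-level sorts, three replicate seeds) keep
every run within minutes on one CPU.

## What the generator does and does not emulate

The simulator reproduces the joint behaviour the analyses measure:
delay heterogeneity and its propagation across the regulon, basal
copy-number statistics with the counting limit, transient-vs-sustained
mismatch kinetics by genotype, dose-dependent survival, and the
subpopulation mutation-frequency arithmetic. It does not model cell
geometry or image formation, lineage branching (mother cells only),
division-time variability, photobleaching, plasmid copy-number noise in
the reporter, or the genetics of rifampicin resistance beyond a single
effective probability. Passing tests therefore validate the analysis
operations and the internal consistency of the model's mechanism — not
pixel-level behaviour of real microscopy data. Absolute fluorescence
units, colony counts and the basal focus rate are scale conventions;
the dimensionless and ratio quantities are the calibrated science.

## Known limitations

* The Delayed gate fraction is not monotone in dose (about 19% at 1 mM,
  16% at 3 mM, 19% at 10 mM): with delays of 63 ± 19 min at 1 mM, a
  90-min snapshot necessarily leaves a tail of still-dim slow switchers
  in the Delayed gate, so a much smaller 1 mM Delayed fraction would
  contradict the delay distribution within this model's observation
  conventions. The dose dependence of the *trapped* (never-switching)
  subpopulation is monotone; the gate fraction convolves it with the
  late-switcher tail and with gate-time survival.
* `ada_C321A` uses wild-type activation kinetics; its documented
  spontaneous basal activation is available only via a parameter
  override.
* The fixed-step engine returns event times quantised to within one
  0.5-min step (switch times carry sub-step jitter).
* Basal copy-number fluctuations of *alkB*, *alkA* and *aidB* are
  frozen at their initial draw within a trace (only *ada*'s basal
  birth–death is simulated frame to frame); their basal contribution to
  trace dynamics is far below the measurement noise.
```
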