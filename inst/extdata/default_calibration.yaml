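# Default calibration of the adaptive-response simulator.
# Produced by the search documented in scripts/calibrate.R against the
# published single-cell summary statistics (activation-delay mean/SD,
# basal copy-number statistics, genotype survival at 4 h / 1 mM,
# Delayed-gate fraction and Delayed:Activated mutant-frequency ratios).
# Units: time min, dose mM, copy numbers molecules/cell, lesions
# lesions/cell, fluorescence a.u.
expression:
  basal_mean: {ada: 1.0, alkB: 0.25, alkA: 2.6, aidB: 0.05, constitutive: 150.0}
  alka_high_frac: 0.05        # minority basal-elevated alkA subpopulation
  alka_high_mean: 15.0
  dilution_rate: 0.0231       # min^-1; log(2) / 30-min generation time
  activated_ss: {ada: 1000.0, alkB: 250.0, alkA: 600.0}
  rise_time: 35.0             # min, post-switch relaxation to steady state
  alka_lag: 8.0               # min, alkA induction lag behind ada
  maturation: 34.0            # min, expression + fluorophore maturation lag
  fluct_theta: 0.0333         # min^-1, OU mean reversion of expression noise
  fluct_sd: 0.20              # stationary SD of the shared fluctuation
switch:
  k_m: 0.14                  # min^-1 mM^-1 per Ada molecule (at full sensing)
  sensing_rate: 0.030         # min^-1, lag of intracellular methylation signal
  supp_K: 2.35                 # dose (mM) halving unswitched ada expression
  supp_hill: 5.0              # cooperativity of the expression suppression
lesions:
  lesion_alpha: {meA: 1.9, meC: 1.65, o6meg: 0.40}     # lesions min^-1 mM^-1
  basal_vmax: {meA: 0.30, meC: 0.0, o6meg: 0.4225}      # saturable basal repair
  basal_km: {meA: 1.0, meC: 1.0, o6meg: 0.03}
  basal_decay: {meA: 0.002, meC: 0.003, o6meg: 0.002} # dilution/turnover
  induced_rate: {meA: 0.25, meC: 0.25, o6meg: 8.0}   # min^-1 once induced
  repair_lag: 3.0            # min from switch to effective induced repair
  wash_dilution: 0.08         # min^-1 extra clearance once MMS is removed
mismatch:
  r0: 0.0012                   # basal foci rate, foci cell^-1 min^-1
  r_mut: 0.016                # foci min^-1 per mutagenic (O6meG) lesion
  r_tox: 0.00005               # foci min^-1 per replication-blocking lesion
  l_half: 10.0                # lesions at which mismatch conversion half-saturates
  p_fix: 0.01                 # fraction of mismatches fixed as mutations
  p_rif: 0.40                 # fixed mutation confers rifampicin resistance
death:
  h_max: 0.025                # min^-1, saturated death hazard
  lethal_thresh: 150.0         # blocking-lesion load above which distress builds
  tau_up: 30.0                # min, distress build-up time constant
  tau_down: 10.0              # min, distress decay once load is repaired
fluorescence:
  fluor_scale: {ada: 1.0, alkB: 1.0, alkA: 1.7, aidB: 1.0, constitutive: 1.0}
  fluor_bg: 100.0             # a.u.
  fluor_sd: 3.0               # a.u., per-frame measurement noise
  facs_cv: 0.25               # log-normal spread of cytometer intensities
observation:
  frame_interval: 3.0         # min
  dt: 0.5                     # min, simulation step
fate_probs: {lysed: 0.5, arrested: 0.4, escaped: 0.1}
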