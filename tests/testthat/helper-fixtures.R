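# Shared fixtures: small constructed trace sets and populations.

# A trace set with one channel built from a matrix of intensities.
make_traces <- function(mat, times = seq(0, by = 3,
                                         length.out = ncol(mat)),
                        onset = times[ceiling(length(times) / 3)],
                        channel = "ada") {
  chans <- list()
  chans[[channel]] <- mat
  trace_set(times, chans, onset)
}

# A noiseless step trace: value `lo` before `t_step`, `hi` after.
step_trace <- function(lo, hi, t_step, times) {
  ifelse(times < t_step, lo, hi)
}

# Small simulated population reused across tests (1 mM step, traces on).
cached_pop <- local({
  pop <- NULL
  function() {
    if (is.null(pop)) {
      pop <<- simulate_population(150, sim_params(),
                                  mms_profile(1, onset = 21),
                                  horizon = 150, seed = 42,
                                  channels = c("ada", "alkA",
                                               "constitutive"))
    }
    pop
  }
})
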