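test_that("OFF-state copy numbers follow the birth-death stationary law", {
  # with k_b/gamma = 1 the stationary law is Poisson(1)
  snap <- snapshot_molecule_counts("ada", 10000, sim_params(), seed = 7)
  x <- snap$counts[!snap$censored]
  expect_equal(mean(x == 0), exp(-1), tolerance = 0.05)
  obs <- tabulate(pmin(x, 5) + 1L, nbins = 6L)
  pr <- c(dpois(0:4, 1), ppois(4, 1, lower.tail = FALSE))
  expect_gt(chisq.test(obs, p = pr)$p.value, 0.01)
})

test_that("an unstressed population never switches, dies, or exceeds r0", {
  p <- sim_params()
  pop <- simulate_population(400, p, mms_profile(0), horizon = 120,
                             seed = 11, channels = "ada")
  expect_true(all(is.na(pop$cells$t_on)))
  expect_true(all(pop$cells$fate == "alive"))
  expect_true(all(is.na(pop$cells$death_time)))
  # foci-rate estimator recovers r0 within 3 Monte-Carlo SE
  tot <- sum(pop$cells$n_mismatches)
  expect_gt(tot, 0)
  r_hat <- tot / (400 * 120)
  se <- sqrt(tot) / (400 * 120)
  expect_lt(abs(r_hat - p$mismatch$r0), 3 * se)
})

test_that("identical master seeds give identical datasets", {
  p <- sim_params()
  a <- simulate_population(3, p, mms_profile(1), horizon = 60, seed = 5)
  b <- simulate_population(3, p, mms_profile(1), horizon = 60, seed = 5)
  expect_identical(a$cells, b$cells)
  expect_identical(a$traces, b$traces)
  expect_identical(a$foci, b$foci)
  c2 <- simulate_population(3, p, mms_profile(1), horizon = 60, seed = 6)
  expect_false(identical(a$cells, c2$cells))
})

test_that("switch times decrease stochastically with dose and with k_m", {
  mean_ton <- function(dose, k_m) {
    p <- sim_params(switch = list(k_m = k_m))
    pop <- simulate_population(800, p, mms_profile(dose), horizon = 150,
                               seed = 13, keep_traces = FALSE)
    mean(pop$cells$t_on, na.rm = TRUE)
  }
  by_dose <- vapply(c(1, 3, 10), mean_ton, numeric(1),
                    k_m = sim_params()$switch$k_m)
  expect_true(all(diff(by_dose) < 0))
  by_km <- vapply(c(0.05, 0.14, 0.4), function(k) mean_ton(1, k),
                  numeric(1))
  expect_true(all(diff(by_km) < 0))
})

test_that("zero-Ada cells cannot switch before producing a molecule", {
  p <- sim_params(switch = list(k_m = 1e3))  # switch instantly once possible
  pop <- simulate_population(300, p, mms_profile(1), horizon = 60,
                             seed = 17, keep_traces = FALSE)
  z <- pop$cells$n0_ada == 0
  expect_gt(sum(z), 50)
  # cells born with Ada fire immediately; zero-copy cells wait for a birth
  expect_lt(max(pop$cells$t_on[!z], na.rm = TRUE), 5)
  expect_gt(min(pop$cells$t_on[z], na.rm = TRUE), 1)
})

test_that("ON-state amplification reaches two orders of magnitude", {
  pop <- cached_pop()
  tr <- pop$traces
  on <- which(!is.na(pop$cells$t_on) & pop$cells$t_on < 60 &
                is.na(pop$cells$death_time))
  expect_gt(length(on), 20)
  late <- tr$channels$ada[on, tr$times > 140, drop = FALSE]
  bg <- pop$params$fluorescence$fluor_bg
  mean_on <- mean(late, na.rm = TRUE) - bg
  expect_gt(mean_on / pop$params$expression$basal_mean$ada, 100)
})

test_that("cell records satisfy their structural invariants", {
  pop <- cached_pop()
  cl <- pop$cells
  expect_false(any(duplicated(cl$cell_id)))
  expect_true(all(is.na(cl$death_time) == (cl$fate == "alive")))
  expect_true(all(cl$t_on >= 0, na.rm = TRUE))
  expect_true(all(pop$foci$frame_index %in%
                    (seq_along(pop$traces$times) - 1L)))
  expect_true(all(pop$foci$cell_id %in% cl$cell_id))
  # traces terminate at death
  dead <- which(!is.na(cl$death_time))
  expect_gt(length(dead), 0)
  for (i in dead[seq_len(min(5, length(dead)))]) {
    gone <- pop$traces$times > cl$death_time[i]
    expect_true(all(is.na(pop$traces$channels$ada[i, gone])))
  }
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(simulate_population(0, sim_params(), mms_profile(1),
                                   horizon = 60), "n must be")
  expect_error(simulate_population(5, sim_params(), mms_profile(1),
                                   horizon = 1), "at least one frame")
  expect_error(simulate_population(5, sim_params(), mms_profile(1),
                                   horizon = 60, facs_time = 90),
               "within the simulated horizon")
})

test_that("colony assay is a thinned count of viable resistant cells", {
  cells <- data.frame(death_time = c(NA, NA, 50, NA),
                      rif_resistant = c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(colony_assay(cells, 1, seed = 1), 2L)
  expect_identical(colony_assay(cells[0, ], 1, seed = 1), 0L)
  none <- data.frame(death_time = NA, rif_resistant = FALSE)
  expect_identical(colony_assay(none, 1, seed = 1), 0L)
  expect_error(colony_assay(cells, 0), "plating_efficiency")
  # binomial mean/variance oracle at large n
  big <- data.frame(death_time = rep(NA_real_, 50000),
                    rif_resistant = rep(TRUE, 50000))
  draws <- vapply(1:20, function(s) colony_assay(big, 0.2, seed = s),
                  integer(1))
  expect_lt(abs(mean(draws) - 10000), 3 * sqrt(50000 * 0.2 * 0.8 / 20))
})
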