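sim_events <- function(logc, sd, n, seed = 1) {
  set.seed(seed)
  ev <- data.frame(cell_id = sprintf("e%d_%05d", seed, seq_len(n)),
                   gfp_au = 10^rnorm(n, logc, sd),
                   mkate_au = 10^rnorm(n, 2.5, sd))
  class(ev) <- c("facs_events", "data.frame")
  ev
}

test_that("gates are built around the untreated mode with equal widths", {
  unt <- sim_events(2.0, 0.1, 20000)
  trt <- sim_events(3.0, 0.1, 20000, seed = 2)
  g <- define_gates(unt, trt, width_sigmas = 3)
  expect_equal(g$Delayed$lower, 1.7, tolerance = 0.02)
  expect_equal(g$Delayed$upper, 2.3, tolerance = 0.02)
  expect_equal(g$Activated$lower, 2.7, tolerance = 0.03)
  expect_equal(g$Activated$upper, 3.3, tolerance = 0.03)
  expect_equal(g$Activated$upper - g$Activated$lower,
               g$Delayed$upper - g$Delayed$lower)
})

test_that("indistinguishable populations give an overlap error", {
  unt <- sim_events(2.0, 0.1, 5000)
  expect_error(define_gates(unt, sim_events(2.0, 0.1, 5000, seed = 3)),
               "overlap")
  expect_error(define_gates(unt[0, ], unt), "non-empty")
})

test_that("gate membership partitions events and reports fractions", {
  unt <- sim_events(2.0, 0.1, 10000)
  trt <- rbind(sim_events(2.0, 0.1, 1500, seed = 4),
               sim_events(3.0, 0.1, 8500, seed = 5))
  class(trt) <- c("facs_events", "data.frame")
  g <- define_gates(unt, trt)
  s <- apply_gates(trt, g)
  expect_equal(s$fractions[["Delayed"]], 0.15, tolerance = 0.1)
  expect_equal(sum(vapply(s$members, length, integer(1))) / s$n_events +
                 s$excluded_fraction, 1)
  expect_false(any(s$members$Delayed %in% s$members$Activated))

  all_del <- apply_gates(sim_events(2.0, 0.05, 500, seed = 6), g)
  expect_gt(all_del$fractions[["Delayed"]], 0.99)
  expect_equal(all_del$fractions[["Activated"]], 0)
})

test_that("mutant frequency is the exact colony ratio", {
  f <- mutant_frequency(25, 1e6)
  expect_identical(as.numeric(f), 2.5e-5)
  expect_identical(attr(f, "rational"), c(25, 1e6))
  expect_identical(as.numeric(mutant_frequency(0, 1000)), 0)
  expect_identical(as.numeric(mutant_frequency(50, 2e6)),
                   as.numeric(mutant_frequency(25, 1e6)))
  expect_equal(as.numeric(mutant_frequency(125, 1e6)) /
                 as.numeric(mutant_frequency(25, 1e6)), 5)
  expect_error(mutant_frequency(5, 0), "n_sorted")
})

test_that("plasticity shares follow the counts-times-percentage rule exactly", {
  assay <- data.frame(subpopulation = c("Delayed", "Activated"),
                      n_sorted = c(1e6, 1e6),
                      colonies = c(20, 50),
                      pct_sorted = c(15, 85))
  sh <- plasticity_share(assay)
  expect_identical(sh$weight, c(300, 4250))
  expect_equal(sh$share_pct, 100 * c(300, 4250) / 4550)
  expect_equal(sh$share_pct[1], 6.593, tolerance = 1e-3)
  expect_equal(sum(sh$share_pct), 100)

  eq <- plasticity_share(data.frame(
    subpopulation = c("a", "b"), n_sorted = c(10, 10),
    colonies = c(7, 7), pct_sorted = c(40, 40)))
  expect_equal(eq$share_pct, c(50, 50))

  set.seed(12)
  for (i in 1:10) {
    a <- data.frame(subpopulation = c("a", "b", "c"), n_sorted = 100,
                    colonies = rpois(3, 20), pct_sorted = runif(3, 5, 60))
    if (sum(a$colonies) == 0) next
    expect_equal(sum(plasticity_share(a)$share_pct), 100)
  }
  expect_error(plasticity_share(assay[1, ]), "at least 2")
  expect_error(plasticity_share(transform(assay, n_sorted = c(1, 2))),
               "equal number")
  expect_error(plasticity_share(transform(assay, colonies = c(0, 0))),
               "no mutants")
})

test_that("cytometry snapshots exclude dead cells and are seed-stable", {
  p <- sim_params()
  pop <- simulate_population(5000, p, mms_profile(3), horizon = 90,
                             seed = 31, keep_traces = FALSE, facs_time = 90)
  ev1 <- facs_snapshot(pop, seed = 4)
  ev2 <- facs_snapshot(pop, seed = 4)
  expect_identical(ev1, ev2)
  expect_equal(nrow(ev1), sum(pop$cells$alive_at_facs))
  expect_true(all(ev1$gfp_au > 0))

  basal <- simulate_population(5000, p, mms_profile(0), horizon = 90,
                               seed = 32, keep_traces = FALSE,
                               facs_time = 90)
  evb <- facs_snapshot(basal, seed = 5)
  # unimodal at the basal mode: (almost) nothing near the activated level
  expect_gt(mean(abs(log10(evb$gfp_au) - 2) < 0.4), 0.99)
})
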