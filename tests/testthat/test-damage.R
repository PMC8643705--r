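test_that("foci deduplication keeps the first frame of each run", {
  expect_equal(dedup_foci(c(10, 11, 12, 20, 21)), c(10L, 20L))
  expect_equal(dedup_foci(integer(0)), integer(0))
  expect_equal(dedup_foci(c(5, 7, 9)), c(5L, 7L, 9L))
  expect_error(dedup_foci(c(3, 3, 4)), "sorted")
})

test_that("deduplication is idempotent on random foci sets", {
  set.seed(8)
  for (i in 1:25) {
    f <- sort(sample(0:60, sample(0:25, 1)))
    once <- dedup_foci(f)
    expect_identical(dedup_foci(once), once)
    expect_true(all(once %in% f))
    expect_false(any(diff(once) == 1 &
                       !(once[-length(once)] + 1) %in% setdiff(f, once)))
  }
})

test_that("table-level dedup equals per-cell dedup", {
  foci <- data.frame(cell_id = c("a", "a", "a", "b", "b"),
                     frame_index = c(4, 5, 9, 2, 3))
  ev <- dedup_foci_table(foci)
  expect_equal(ev$frame_index[ev$cell_id == "a"], c(4, 9))
  expect_equal(ev$frame_index[ev$cell_id == "b"], 2)
})

test_that("the rate formula and its conservation identity hold exactly", {
  times <- seq(0, 30, by = 3)
  ev <- data.frame(cell_id = rep("c1", 6), frame_index = rep(5L, 6))
  rc <- mismatch_rate_curve(ev, at_risk = rep(100L, 11), times = times)
  expect_identical(rc$rate[6], 6 / (3 * 100))
  expect_identical(sum(rc$rate * 3 * rc$n_at_risk), 6)

  none <- mismatch_rate_curve(ev[0, ], rep(10L, 11), times)
  expect_true(all(none$rate == 0))

  set.seed(9)
  for (i in 1:10) {
    n_ev <- sample(1:40, 1)
    ev2 <- data.frame(cell_id = "x",
                      frame_index = sample(0:10, n_ev, replace = TRUE))
    ar <- sample(5:50, 11, replace = TRUE)
    rc2 <- mismatch_rate_curve(ev2, ar, times)
    expect_equal(sum(rc2$rate * 3 * rc2$n_at_risk), n_ev)
  }
  expect_error(mismatch_rate_curve(ev, c(rep(100L, 5), 0L, rep(100L, 5)),
                                   times), "no cells at risk")
})

test_that("moving-average smoothing has the exact 11-frame interior kernel", {
  times <- seq(0, 120, by = 3)
  n <- length(times)
  const <- mismatch_rate_curve(
    data.frame(cell_id = character(0), frame_index = integer(0)),
    rep(10L, n), times)
  const$rate <- rep(0.02, n)
  expect_equal(smooth_curve(const, 30)$rate, rep(0.02, n))

  imp <- const
  imp$rate <- rep(0, n)
  imp$rate[21] <- 1
  sm <- smooth_curve(imp, 30)
  expect_equal(sm$rate[21], 1 / 11)
  expect_equal(sm$rate[16], 1 / 11)  # edge of the +/- 15 min span
  expect_equal(sm$rate[15], 0)
  # a curve supported away from the edges has its mean preserved exactly
  rnd <- const
  set.seed(10)
  rnd$rate <- c(rep(0, 10), runif(n - 20), rep(0, 10))
  sm2 <- smooth_curve(rnd, 30)
  expect_equal(mean(sm2$rate), mean(rnd$rate))
  expect_error(smooth_curve(const, 1), "at least one frame")
  expect_error(smooth_curve(const, 10), "multiple")
})

test_that("survival curve matches a hand-worked product-limit table", {
  fates <- data.frame(
    fate = c("lysed", "arrested", "alive", "alive"),
    death_time = c(60, 120, NA, NA))
  sc <- survival_curve(fates, horizon = 240)
  expect_equal(surv_at(sc, 240), 0.5)
  expect_equal(surv_at(sc, 59), 1)
  expect_equal(surv_at(sc, 60), 0.75)

  all_alive <- data.frame(fate = rep("alive", 5), death_time = NA_real_)
  expect_true(all(survival_curve(all_alive, 100)$surv == 1))

  # censoring before the first death: KM table by hand
  # n=4; censor at 50, deaths at 100 and 200:
  # S(100) = 1 * (1 - 1/3) = 2/3;  S(200) = 2/3 * (1 - 1/2) = 1/3
  cen <- data.frame(fate = c("escaped", "lysed", "lysed", "alive"),
                    death_time = c(50, 100, 200, NA))
  sc2 <- survival_curve(cen, horizon = 240, escape_policy = "censor")
  expect_equal(surv_at(sc2, 150), 2 / 3)
  expect_equal(surv_at(sc2, 240), 1 / 3)
  # escapes counted as deaths instead
  sc3 <- survival_curve(cen, horizon = 240, escape_policy = "death")
  expect_equal(surv_at(sc3, 75), 0.75)
  expect_error(survival_curve(data.frame(fate = "vanished",
                                         death_time = 1), 10),
               "unknown fate")
})

test_that("survival curves are non-increasing and match the ECDF when uncensored", {
  set.seed(11)
  dt <- sort(runif(40, 0, 200))
  fates <- data.frame(fate = c(rep("lysed", 40), rep("alive", 10)),
                      death_time = c(dt, rep(NA, 10)))
  sc <- survival_curve(fates, 240)
  expect_true(all(diff(sc$surv) <= 1e-12))
  expect_equal(surv_at(sc, 240), 10 / 50)
  expect_equal(surv_at(sc, 100), mean(c(dt, rep(Inf, 10)) > 100))
})

test_that("simulated genotype rate curves separate transient from sustained", {
  run_curve <- function(genotype, n = 250, seed = 21) {
    p <- sim_params(genotype = genotype)
    pop <- simulate_population(n, p, mms_profile(1, onset = 21),
                               horizon = 201, seed = seed,
                               channels = "ada")
    ev <- dedup_foci_table(pop$foci)
    ar <- at_risk_per_frame(pop$cells, pop$traces$times)
    sm <- smooth_curve(mismatch_rate_curve(ev, ar, pop$traces$times), 30)
    post <- sm$time_min > 21 & sm$time_min <= 180
    list(peak = max(sm$rate[post]),
         final = mean(sm$rate[sm$time_min > 141 & sm$time_min <= 201]))
  }
  wt <- run_curve("wild_type")
  expect_lt(wt$final, 0.5 * wt$peak)        # transient burst, then recovery
  ko <- run_curve("delta_ada_alkB")
  expect_gt(ko$final, 0.8 * ko$peak)        # sustained, non-recovering
  expect_gt(ko$final, wt$final)
})
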