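test_that("baseline subtraction removes the pre-onset mean", {
  times <- seq(0, 60, by = 3)
  tr <- make_traces(matrix(100, 2, length(times)), times, onset = 30)
  tr <- baseline_subtract(tr, "ada")
  expect_true(all(tr$channels$ada == 0))
  expect_equal(unname(tr$baseline$ada$mean), c(100, 100))

  stepm <- rbind(step_trace(100, 600, 30, times),
                 step_trace(100, 600, 30, times))
  tr2 <- baseline_subtract(make_traces(stepm, times, onset = 30), "ada")
  expect_equal(unique(as.vector(tr2$channels$ada[, times >= 30])), 500)
})

test_that("baseline statistics recover the noise moments", {
  set.seed(99)
  sigma <- 4
  times <- seq(0, 300, by = 3)
  m <- matrix(rnorm(60 * length(times), 0, sigma), 60)
  tr <- baseline_subtract(make_traces(m, times, onset = 150), "ada")
  post <- tr$channels$ada[, times >= 150]
  expect_lt(abs(mean(post)), 3 * sigma / sqrt(length(post)))
  expect_equal(mean(tr$baseline$ada$sd), sigma, tolerance = 0.1)
})

test_that("too few pre-onset frames is an error naming the cells", {
  times <- seq(0, 30, by = 3)
  tr <- make_traces(matrix(1, 1, length(times)), times, onset = 3)
  expect_error(baseline_subtract(tr, "ada"), "pre-onset")
})

test_that("population mean curve averages and normalizes correctly", {
  times <- 0:10 * 3
  base <- matrix(rep(times / 3, each = 2), nrow = 2, byrow = FALSE)
  tr <- make_traces(rbind(times / 3, 3 * times / 3), times, onset = 0)
  cv <- population_mean_curve(tr, "ada")
  expect_equal(cv$mean_intensity, 2 * times / 3)
  cvn <- population_mean_curve(tr, "ada", normalize = TRUE)
  expect_equal(cvn$mean_intensity, (2 * times / 3) / 20)
  expect_equal(max(cvn$mean_intensity), 1)
  two <- make_traces(rbind(times, times), times, onset = 0)
  expect_equal(population_mean_curve(two, "ada")$mean_intensity,
               as.numeric(times))
  zero <- make_traces(matrix(0, 2, length(times)), times, onset = 0)
  expect_error(population_mean_curve(zero, "ada", normalize = TRUE),
               "normalize")
})

make_called <- function(delays, sd_noise = 0, times = seq(0, 240, by = 3),
                        onset = 30, amp = 50) {
  m <- t(vapply(delays, function(d) {
    x <- step_trace(0, amp, onset + d, times)
    x + rnorm(length(times), 0, max(sd_noise, 1e-9))
  }, numeric(length(times))))
  baseline_subtract(make_traces(m + 100, times, onset = onset), "ada")
}

test_that("activation delays are called at the sustained threshold crossing", {
  set.seed(1)
  tr <- make_called(c(63, 12), sd_noise = 1)
  calls <- detect_activation_delay(tr, "ada", k_sigma = 5, min_frames = 3)
  expect_equal(calls$delay_min, c(63, 12))
  expect_equal(calls$label, c("Activated", "Activated"))

  flat <- baseline_subtract(
    make_traces(matrix(100, 1, 81), seq(0, 240, by = 3), onset = 30), "ada")
  c2 <- detect_activation_delay(flat, "ada")
  expect_true(is.na(c2$delay_min))
  expect_equal(c2$label, "Delayed")
})

test_that("a trace truncated by death before the window gives NoCall", {
  set.seed(2)
  tr <- make_called(1000, sd_noise = 1)   # never crosses
  tr$channels$ada[1, tr$times > 90] <- NA  # death at 90 min
  cl <- detect_activation_delay(tr, "ada")
  expect_equal(cl$label, "NoCall")
})

test_that("delay calling is invariant to time translation", {
  set.seed(3)
  times <- seq(0, 240, by = 3)
  d0 <- detect_activation_delay(make_called(60, 2), "ada")$delay_min
  # same trace shifted by 30 min together with its onset
  m <- matrix(step_trace(0, 50, 90 + 30, times) + 100 +
                rnorm(length(times), 0, 2), 1)
  tr <- baseline_subtract(make_traces(m, times, onset = 60), "ada")
  d1 <- detect_activation_delay(tr, "ada")$delay_min
  expect_equal(d0, 60)
  expect_equal(d1, d0)
})

test_that("raising k_sigma never shortens a called delay", {
  set.seed(4)
  tr <- make_called(seq(10, 90, by = 10), sd_noise = 4, amp = 40)
  prev <- rep(-Inf, 9)
  for (k in c(2, 4, 6, 8)) {
    d <- detect_activation_delay(tr, "ada", k_sigma = k)$delay_min
    d[is.na(d)] <- Inf
    expect_true(all(d >= prev))
    prev <- d
  }
})

test_that("delay regression recovers exact linear relations and nulls", {
  ca <- data.frame(cell_id = sprintf("c%02d", 1:30), channel = "ada",
                   delay_min = seq(20, 110, length.out = 30))
  cb <- ca
  cb$delay_min <- ca$delay_min + 8
  f <- delay_fit(ca, cb)
  expect_equal(f$r, 1)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 8)
  expect_equal(f$mean_diff, 8)
  self <- delay_fit(ca, ca)
  expect_equal(c(self$r, self$slope, self$intercept), c(1, 1, 0))
  set.seed(5)
  cp <- cb
  cp$delay_min <- sample(cb$delay_min)
  expect_lt(abs(delay_fit(ca, cp)$r), 2 / sqrt(30 - 3))
  expect_error(delay_fit(ca[1, ], cb[1, ]), "at least 2")
})

test_that("cells missing a call in either channel are excluded and counted", {
  ca <- data.frame(cell_id = c("a", "b", "c"), channel = "ada",
                   delay_min = c(10, NA, 30))
  cb <- data.frame(cell_id = c("a", "b", "c"), channel = "alkA",
                   delay_min = c(18, 25, 38))
  f <- delay_fit(ca, cb)
  expect_equal(f$n, 2)
  expect_equal(f$n_excluded, 1)
})

ou_traces <- function(n = 40, nf = 160, lag_frames = 0, seed = 10) {
  set.seed(seed)
  a <- exp(-0.1)
  base <- matrix(0, n, nf + lag_frames)
  for (j in 2:(nf + lag_frames)) {
    base[, j] <- base[, j - 1] * a + rnorm(n, 0, sqrt(1 - a^2))
  }
  list(A = base[, (1 + lag_frames):(nf + lag_frames)],
       B = base[, 1:nf])
}

test_that("cross-correlation identities: self at lag 0, shifts at their lag", {
  ou <- ou_traces()
  times <- seq(0, by = 3, length.out = ncol(ou$A))
  tr <- trace_set(times, list(ada = ou$A, alkA = ou$A), onset = 0)
  cc <- steady_state_crosscorr(tr, "ada", "alkA", window_start = 0,
                               max_lag = 30)
  expect_equal(cc$mean_corr[cc$lag_min == 0], 1)
  expect_true(all(abs(cc$mean_corr) <= 1 + 1e-12))

  sh <- ou_traces(lag_frames = 3)  # B lags A by 9 min
  tr2 <- trace_set(times, list(ada = sh$A, alkA = sh$B), onset = 0)
  cc2 <- steady_state_crosscorr(tr2, "ada", "alkA", window_start = 0,
                                max_lag = 30)
  expect_equal(cc2$lag_min[which.max(cc2$mean_corr)], 9)
})

test_that("shuffled control sits inside its permutation-null envelope", {
  ou <- ou_traces(n = 60, seed = 12)
  times <- seq(0, by = 3, length.out = ncol(ou$A))
  tr <- trace_set(times, list(ada = ou$A, alkA = ou$A), onset = 0)
  cc <- steady_state_crosscorr(tr, "ada", "alkA", window_start = 0,
                               max_lag = 30, mode = "shuffled", seed = 2)
  # per-lag null SE ~ 1/sqrt(effective samples per cell) / sqrt(cells)
  se <- 1 / sqrt(0.5 * ncol(ou$A)) / sqrt(60)
  expect_true(all(abs(cc$mean_corr) < 4 * se))
})

test_that("window shorter than twice the lag span is rejected", {
  ou <- ou_traces(n = 5)
  times <- seq(0, by = 3, length.out = ncol(ou$A))
  tr <- trace_set(times, list(ada = ou$A, alkA = ou$A), onset = 0)
  expect_error(steady_state_crosscorr(tr, "ada", "alkA",
                                      window_start = max(times) - 30,
                                      max_lag = 30), "shorter than")
})
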