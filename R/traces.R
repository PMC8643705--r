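#' Trace set from a simulated population
#'
#' Collects the per-frame fluorescence matrices of a `population_dataset`
#' into the container the trace-analysis operations work on.
#'
#' @param pop a `population_dataset` simulated with `keep_traces = TRUE`.
#' @return object of class `trace_set`: list with `times` (min), `onset`
#'   (stress onset, min), `cell_ids`, `channels` (named list of cells x
#'   frames intensity matrices, a.u.) and `baseline` (filled by
#'   [baseline_subtract()]).
#' @export
as_trace_set <- function(pop) {
  stopifnot(inherits(pop, "population_dataset"))
  if (is.null(pop$traces)) {
    stop("population was simulated without traces (keep_traces = FALSE)")
  }
  structure(list(times = pop$traces$times, onset = pop$traces$onset,
                 cell_ids = pop$cells$cell_id,
                 channels = pop$traces$channels,
                 baseline = list()),
            class = "trace_set")
}

#' Construct a trace set from matrices
#'
#' @param times frame times (min), strictly increasing, evenly spaced.
#' @param channels named list of intensity matrices (cells x frames).
#' @param onset stress onset time (min), on the frame grid.
#' @param cell_ids optional cell identifiers.
#' @return a `trace_set`.
#' @export
trace_set <- function(times, channels, onset, cell_ids = NULL) {
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (max(abs(diff(diff(times)))) > 1e-8) {
    stop("times must be evenly spaced")
  }
  if (!any(abs(times - onset) < 1e-8)) {
    stop("onset must lie on the frame grid")
  }
  if (!is.list(channels) || is.null(names(channels))) {
    stop("channels must be a named list of matrices")
  }
  nr <- unique(vapply(channels, nrow, integer(1)))
  if (length(nr) != 1) stop("all channel matrices must have the same cells")
  for (ch in names(channels)) {
    if (ncol(channels[[ch]]) != length(times)) {
      stop("channel ", ch, " is not aligned to the frame grid")
    }
  }
  if (is.null(cell_ids)) cell_ids <- sprintf("c%06d", seq_len(nr))
  structure(list(times = times, onset = onset, cell_ids = cell_ids,
                 channels = channels, baseline = list()),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set>", length(x$cell_ids), "cells x", length(x$times),
      "frames; onset", x$onset, "min\n  channels:",
      paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Subtract the pre-stress baseline from a channel
#'
#' For every cell, the mean intensity over the frames before stress onset
#' is subtracted from the whole series. The per-cell baseline mean and SD
#' are stored on the trace set for use as the detection threshold scale.
#'
#' @param traces a `trace_set`.
#' @param channel channel name.
#' @return the `trace_set` with the channel baseline-corrected and
#'   `baseline[[channel]]` holding per-cell `mean` and `sd`.
#' @export
baseline_subtract <- function(traces, channel) {
  stopifnot(inherits(traces, "trace_set"))
  ch <- get_channel(traces, channel)
  pre <- which(traces$times < traces$onset)
  if (length(pre) < 3) {
    stop("need at least 3 pre-onset frames (have ", length(pre),
         ") for cells ", paste(utils::head(traces$cell_ids, 3),
                               collapse = ", "))
  }
  bl <- rowMeans(ch[, pre, drop = FALSE], na.rm = TRUE)
  bsd <- apply(ch[, pre, drop = FALSE], 1, stats::sd, na.rm = TRUE)
  traces$channels[[channel]] <- ch - bl
  traces$baseline[[channel]] <- list(mean = bl, sd = bsd)
  traces
}

get_channel <- function(traces, channel) {
  if (!channel %in% names(traces$channels)) {
    stop("no channel `", channel, "` in trace set (have: ",
         paste(names(traces$channels), collapse = ", "), ")")
  }
  traces$channels[[channel]]
}

#' Population-average intensity curve
#'
#' Pointwise mean across cells of the baseline-subtracted traces of one
#' channel, optionally divided by the curve maximum.
#'
#' @param traces a `trace_set` after [baseline_subtract()].
#' @param channel channel name.
#' @param normalize divide by the curve's maximum (must be > 0).
#' @return data.frame with `time_min`, `mean_intensity`, `n_cells`.
#' @export
population_mean_curve <- function(traces, channel, normalize = FALSE) {
  stopifnot(inherits(traces, "trace_set"))
  ch <- get_channel(traces, channel)
  cv <- colMeans(ch, na.rm = TRUE)
  n_at <- colSums(!is.na(ch))
  if (normalize) {
    mx <- max(cv, na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) {
      stop("cannot normalize: curve maximum is not positive")
    }
    cv <- cv / mx
  }
  data.frame(time_min = traces$times, mean_intensity = cv, n_cells = n_at)
}

#' Call the activation delay of a reporter
#'
#' A cell is called activated at the first post-onset frame where the
#' baseline-subtracted intensity exceeds `k_sigma` times its baseline SD
#' for at least `min_frames` consecutive frames; the delay is that frame's
#' time minus the stress onset. Cells crossing later than `delay_cutoff`
#' (or never, within the observation window) are labelled `Delayed`;
#' cells whose trace ends (death) before the window is exhausted and that
#' never cross are `NoCall`.
#'
#' @param traces a `trace_set` after [baseline_subtract()] on `channel`.
#' @param channel channel name.
#' @param k_sigma threshold in baseline SDs (default 5).
#' @param min_frames consecutive frames required above threshold
#'   (default 3, i.e. 9 min at 3-min sampling).
#' @param window observation window after onset (min); defaults to the
#'   remaining trace length, truncated with a warning if longer.
#' @param delay_cutoff delay (min) separating Activated from Delayed.
#' @return data.frame with one row per cell: `cell_id`, `channel`,
#'   `delay_min` (NA when no crossing), `label` (`Activated`/`Delayed`/
#'   `NoCall`), `threshold_au` (absolute threshold, a.u.).
#' @export
detect_activation_delay <- function(traces, channel, k_sigma = 5,
                                    min_frames = 3, window = NULL,
                                    delay_cutoff = 120) {
  stopifnot(inherits(traces, "trace_set"))
  if (is.null(traces$baseline[[channel]])) {
    stop("run baseline_subtract() on channel `", channel, "` first")
  }
  ch <- get_channel(traces, channel)
  bl <- traces$baseline[[channel]]
  tmax <- max(traces$times)
  if (is.null(window)) window <- tmax - traces$onset
  if (traces$onset + window > tmax + 1e-9) {
    warning("window extends past the trace end; truncated to ",
            tmax - traces$onset, " min (NoCall possible)")
    window <- tmax - traces$onset
  }
  post <- which(traces$times >= traces$onset &
                  traces$times <= traces$onset + window + 1e-9)
  n <- nrow(ch)
  delay <- rep(NA_real_, n)
  label <- rep(NA_character_, n)
  thr <- k_sigma * bl$sd
  for (i in seq_len(n)) {
    x <- ch[i, post]
    above <- !is.na(x) & x > thr[i]
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_frames)
    if (length(hit)) {
      j <- post[starts[hit[1]]]
      delay[i] <- traces$times[j] - traces$onset
      label[i] <- if (delay[i] <= delay_cutoff) "Activated" else "Delayed"
    } else {
      # no crossing: Delayed if observed to the end of the window,
      # NoCall if the trace terminated early (death)
      ok <- !is.na(x)
      label[i] <- if (all(ok)) "Delayed" else "NoCall"
    }
  }
  data.frame(cell_id = traces$cell_ids, channel = channel,
             delay_min = delay, label = label,
             threshold_au = bl$mean + thr,
             stringsAsFactors = FALSE)
}

#' Paired delay regression between two reporters
#'
#' Pairs activation calls by cell, and reports the Pearson correlation,
#' the ordinary least-squares fit of channel B's delay on channel A's
#' (free slope), the paired mean difference, and per-channel delay
#' summaries. Cells lacking a called delay in either channel are excluded
#' and counted.
#'
#' @param calls_A,calls_B data.frames from [detect_activation_delay()].
#' @return object of class `delay_fit`: list with `r`, `slope`,
#'   `intercept` (min), `mean_diff` (min), per-channel `mean`/`sd`,
#'   `n` (complete pairs), `n_excluded`.
#' @export
delay_fit <- function(calls_A, calls_B) {
  m <- merge(calls_A[, c("cell_id", "delay_min")],
             calls_B[, c("cell_id", "delay_min")],
             by = "cell_id", suffixes = c("_a", "_b"))
  total <- length(union(calls_A$cell_id, calls_B$cell_id))
  ok <- stats::complete.cases(m$delay_min_a, m$delay_min_b)
  m <- m[ok, ]
  if (nrow(m) < 2) stop("need at least 2 cells with delays in both channels")
  a <- m$delay_min_a
  b <- m$delay_min_b
  fit <- stats::lm(b ~ a)
  structure(list(
    r = stats::cor(a, b),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    mean_diff = mean(b - a),
    mean_a = mean(a), sd_a = stats::sd(a),
    mean_b = mean(b), sd_b = stats::sd(b),
    n = nrow(m), n_excluded = total - nrow(m)
  ), class = "delay_fit")
}

#' @export
print.delay_fit <- function(x, ...) {
  cat(sprintf(
    "<delay_fit> n = %d (excluded %d)\n  A: %.1f +/- %.1f min; B: %.1f +/- %.1f min\n  Pearson r = %.3f; B = %.3f * A + %.1f min (paired diff %.1f min)\n",
    x$n, x$n_excluded, x$mean_a, x$sd_a, x$mean_b, x$sd_b,
    x$r, x$slope, x$intercept, x$mean_diff))
  invisible(x)
}

#' Steady-state cross-correlation between two channels
#'
#' For each cell, the two channel segments inside the steady-state window
#' are centred on their full-window means and the correlation computed at
#' every lag (positive lag means channel B lags channel A); per-lag
#' normalisation uses the overlapping segments' variances about those
#' means, keeping every value in [-1, 1]. Curves are then averaged across
#' cells. Control modes replace channel B by the same channel from a
#' random other cell (`shuffled`, seeded) or by the constitutive marker of
#' the same cell (`constitutive`).
#'
#' @param traces a `trace_set`.
#' @param channel_A,channel_B channel names.
#' @param window_start start of the steady-state window (min, absolute
#'   time); the window runs to the trace end.
#' @param max_lag maximum lag (min); must not exceed half the window.
#' @param mode `"paired"`, `"shuffled"` or `"constitutive"`.
#' @param seed seed for the shuffled control.
#' @return data.frame with `lag_min`, `mean_corr`, `n_cells`, `mode`;
#'   attribute `n_skipped` counts cells dropped for missing data or zero
#'   variance.
#' @export
steady_state_crosscorr <- function(traces, channel_A, channel_B,
                                   window_start, max_lag = 60,
                                   mode = c("paired", "shuffled",
                                            "constitutive"),
                                   seed = 1L) {
  stopifnot(inherits(traces, "trace_set"))
  mode <- match.arg(mode)
  fi <- diff(traces$times[1:2])
  win <- which(traces$times >= window_start)
  if (length(win) * fi < 2 * max_lag) {
    stop("steady-state window (", length(win) * fi,
         " min) is shorter than 2 * max_lag")
  }
  A <- get_channel(traces, channel_A)[, win, drop = FALSE]
  B <- switch(mode,
    paired = get_channel(traces, channel_B)[, win, drop = FALSE],
    constitutive = get_channel(traces, "constitutive")[, win, drop = FALSE],
    shuffled = {
      set.seed(as.integer(seed))
      Bm <- get_channel(traces, channel_B)[, win, drop = FALSE]
      perm <- sample(nrow(Bm))
      fix <- which(perm == seq_along(perm))
      if (length(fix)) {   # displace fixed points so no cell pairs itself
        perm[c(fix, fix[1])] <- perm[c(fix[length(fix)], fix)][-1]
        if (length(fix) == 1 && nrow(Bm) > 1) {
          swap <- if (fix[1] == 1L) 2L else 1L
          perm[c(fix, swap)] <- perm[c(swap, fix)]
        }
      }
      Bm[perm, , drop = FALSE]
    })
  nlag <- round(max_lag / fi)
  lags <- (-nlag):nlag
  n <- nrow(A)
  acc <- numeric(length(lags))
  used <- 0L
  skipped <- 0L
  for (i in seq_len(n)) {
    a <- A[i, ]
    b <- B[i, ]
    if (anyNA(a) || anyNA(b)) { skipped <- skipped + 1L; next }
    a <- a - mean(a)
    b <- b - mean(b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      skipped <- skipped + 1L; next
    }
    cc <- vapply(lags, function(k) {
      if (k >= 0) {
        ai <- a[seq_len(length(a) - k)]
        bi <- b[seq_len(length(b) - k) + k]
      } else {
        ai <- a[seq_len(length(a) + k) - k]
        bi <- b[seq_len(length(b) + k)]
      }
      den <- sqrt(mean(ai^2) * mean(bi^2))
      if (den == 0) return(0)
      mean(ai * bi) / den
    }, numeric(1))
    acc <- acc + cc
    used <- used + 1L
  }
  if (used == 0) stop("no usable cells in the steady-state window")
  out <- data.frame(lag_min = lags * fi, mean_corr = acc / used,
                    n_cells = used, mode = mode)
  attr(out, "n_skipped") <- skipped
  out
}
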