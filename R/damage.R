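#' Deduplicate persistent foci into mismatch events
#'
#' A focus persisting over several consecutive frames is one mismatch:
#' each maximal run of consecutive focus-positive frames contributes only
#' its first frame as an event.
#'
#' @param frames sorted integer frame indices at which a focus is present
#'   in one cell.
#' @return integer frame indices of the deduplicated events.
#' @export
dedup_foci <- function(frames) {
  if (!length(frames)) return(integer(0))
  frames <- as.integer(frames)
  if (is.unsorted(frames, strictly = TRUE)) {
    stop("foci frames must be sorted and unique")
  }
  frames[c(TRUE, diff(frames) > 1L)]
}

#' Deduplicate a per-cell foci table
#'
#' @param foci data.frame with `cell_id` and `frame_index` (and optionally
#'   `time_min`).
#' @return data.frame of the same shape keeping only event frames.
#' @export
dedup_foci_table <- function(foci) {
  if (!all(c("cell_id", "frame_index") %in% names(foci))) {
    stop("foci table needs columns cell_id, frame_index")
  }
  if (nrow(foci) == 0) return(foci)
  keep <- unlist(lapply(split(seq_len(nrow(foci)), foci$cell_id),
                        function(ix) {
    ix <- ix[order(foci$frame_index[ix])]
    ix[c(TRUE, diff(foci$frame_index[ix]) > 1L)]
  }), use.names = FALSE)
  out <- foci[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Population mismatch-rate curve
#'
#' Rate per frame = events at that frame / (frame interval x cells at
#' risk), in foci per cell per minute. Cells at risk are those still alive
#' and observed at the frame.
#'
#' @param events data.frame of deduplicated events (`cell_id`,
#'   `frame_index`).
#' @param at_risk integer vector: cells at risk at each frame.
#' @param times frame times (min), same length as `at_risk`.
#' @param interval frame interval (min).
#' @return object of class `rate_curve`: data.frame with `time_min`,
#'   `rate`, `n_at_risk`; attribute `smoothing_min` (NA if unsmoothed).
#' @export
mismatch_rate_curve <- function(events, at_risk, times,
                                interval = diff(times[1:2])) {
  if (interval <= 0) stop("interval must be > 0")
  if (length(at_risk) != length(times)) {
    stop("at_risk and times must align")
  }
  nf <- length(times)
  cnt <- tabulate(events$frame_index + 1L, nbins = nf)
  bad <- which(cnt > 0 & at_risk == 0)
  if (length(bad)) {
    stop("events recorded at frames with no cells at risk (frame ",
         bad[1] - 1L, "); inconsistent input")
  }
  rate <- ifelse(at_risk > 0, cnt / (interval * at_risk), 0)
  out <- data.frame(time_min = times, rate = rate, n_at_risk = at_risk)
  attr(out, "smoothing_min") <- NA_real_
  class(out) <- c("rate_curve", "data.frame")
  out
}

#' Cells at risk per frame
#'
#' @param cells `population_dataset$cells` data.frame.
#' @param times frame times (min).
#' @return integer vector: cells alive and observed at each frame.
#' @export
at_risk_per_frame <- function(cells, times) {
  dt <- cells$death_time
  vapply(times, function(t) sum(is.na(dt) | dt > t), integer(1))
}

#' Moving-average smoothing of a rate curve
#'
#' Centred moving average spanning `window` minutes (11 frames at 3-min
#' sampling for a 30-min window, i.e. +/- 15 min); near the edges the
#' window shrinks symmetrically. Cells-at-risk counts are untouched.
#'
#' @param curve a `rate_curve`.
#' @param window smoothing span (min); a positive multiple of the frame
#'   interval.
#' @return the smoothed `rate_curve` (attribute `smoothing_min` set).
#' @export
smooth_curve <- function(curve, window = 30) {
  stopifnot(inherits(curve, "rate_curve"))
  fi <- diff(curve$time_min[1:2])
  if (window < fi) stop("window must span at least one frame interval")
  if (abs(window / fi - round(window / fi)) > 1e-8) {
    stop("window must be a multiple of the frame interval (", fi, " min)")
  }
  half <- round(window / fi / 2)
  n <- nrow(curve)
  sm <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(curve$rate[(i - h):(i + h)])
  }, numeric(1))
  out <- curve
  out$rate <- sm
  attr(out, "smoothing_min") <- window
  out
}

#' Survival curve with fate accounting
#'
#' Product-limit (Kaplan-Meier) estimate of the fraction of cells
#' surviving over time. Lysed and arrested cells are deaths at their
#' recorded times; escaped cells (filamentation out of the channel) are
#' right-censored at their escape time under the default policy, or
#' treated as deaths under `escape_policy = "death"`. Cells alive at the
#' horizon are right-censored there.
#'
#' @param fates data.frame with `fate` (`alive`, `lysed`, `arrested`,
#'   `escaped`) and `death_time` (min; the escape time for escaped cells).
#' @param horizon end of observation (min).
#' @param escape_policy `"censor"` (default) or `"death"`.
#' @return object of class `survival_curve`: data.frame with `time_min`,
#'   `surv`, `n_risk`, `n_event`; attributes `counts` (per-fate totals)
#'   and `escape_policy`.
#' @export
survival_curve <- function(fates, horizon,
                           escape_policy = c("censor", "death")) {
  escape_policy <- match.arg(escape_policy)
  known <- c("alive", "lysed", "arrested", "escaped")
  bad <- setdiff(unique(fates$fate), known)
  if (length(bad)) stop("unknown fate label(s): ", paste(bad, collapse = ", "))
  if (any(!is.na(fates$death_time) & fates$death_time > horizon + 1e-9)) {
    stop("death_time after the horizon")
  }
  time <- ifelse(is.na(fates$death_time), horizon, fates$death_time)
  status <- fates$fate %in% c("lysed", "arrested") |
    (escape_policy == "death" & fates$fate == "escaped")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  out <- data.frame(time_min = c(0, fit$time),
                    surv = c(1, fit$surv),
                    n_risk = c(length(time), fit$n.risk),
                    n_event = c(0, fit$n.event))
  attr(out, "counts") <- table(factor(fates$fate, levels = known))
  attr(out, "escape_policy") <- escape_policy
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Survival fraction at a time point
#'
#' @param curve a `survival_curve`.
#' @param t time (min).
#' @return the step-function value S(t).
#' @export
surv_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  i <- findInterval(t + 1e-9, curve$time_min)
  curve$surv[max(i, 1L)]
}
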