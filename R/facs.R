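#' Construct Delayed and Activated sorting gates
#'
#' The Delayed gate is centred on the mode of the untreated population's
#' log10 reporter intensity with half-width `width_sigmas` times the
#' untreated SD; the Activated gate has the identical width and is centred
#' on the global kernel-density maximum of the treated distribution
#' (Gaussian kernel, Silverman bandwidth). Events between or outside the
#' gates belong to neither.
#'
#' @param untreated,treated `facs_events` (or data.frames with `gfp_au`).
#' @param width_sigmas gate half-width in untreated-SD units (default 3).
#' @return object of class `facs_gates`: list of two gates (`Delayed`,
#'   `Activated`), each with `lower` and `upper` bounds on log10
#'   intensity, plus the construction constants.
#' @export
define_gates <- function(untreated, treated, width_sigmas = 3) {
  if (nrow(untreated) == 0 || nrow(treated) == 0) {
    stop("both event sets must be non-empty")
  }
  lu <- log10(untreated$gfp_au)
  lt <- log10(treated$gfp_au)
  if (any(!is.finite(lu)) || any(!is.finite(lt))) {
    stop("intensities must be positive for log-scale gating")
  }
  half <- width_sigmas * stats::sd(lu)
  c_del <- density_mode(lu)
  c_act <- density_mode(lt)
  del <- c(lower = c_del - half, upper = c_del + half)
  act <- c(lower = c_act - half, upper = c_act + half)
  if (del[["upper"]] > act[["lower"]]) {
    stop("Delayed and Activated gates overlap (peak separation ",
         sprintf("%.2f", c_act - c_del), " log10 units); use a smaller ",
         "width_sigmas or check that the treated population activated")
  }
  structure(list(Delayed = as.list(del), Activated = as.list(act),
                 width_sigmas = width_sigmas, untreated_sd = stats::sd(lu),
                 centers = c(Delayed = c_del, Activated = c_act)),
            class = "facs_gates")
}

density_mode <- function(x) {
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' @export
print.facs_gates <- function(x, ...) {
  cat(sprintf(
    "<facs_gates> log10 intensity gates (width %.2f):\n  Delayed   [%.3f, %.3f)\n  Activated [%.3f, %.3f)\n",
    x$Delayed$upper - x$Delayed$lower,
    x$Delayed$lower, x$Delayed$upper,
    x$Activated$lower, x$Activated$upper))
  invisible(x)
}

#' Sort events into gates
#'
#' Assigns each event to the Delayed or Activated gate by its log10
#' reporter intensity (closed-open bounds `[lower, upper)`); events in
#' neither gate are excluded from sorting but counted.
#'
#' @param events `facs_events`.
#' @param gates a `facs_gates`.
#' @return list with `members` (named list of cell_id vectors per gate),
#'   `fractions` (per-gate fraction of all events), `excluded_fraction`,
#'   `n_events`.
#' @export
apply_gates <- function(events, gates) {
  stopifnot(inherits(gates, "facs_gates"))
  lx <- log10(events$gfp_au)
  members <- lapply(gates[c("Delayed", "Activated")], function(g) {
    events$cell_id[lx >= g$lower & lx < g$upper]
  })
  n <- nrow(events)
  fr <- vapply(members, length, integer(1)) / n
  list(members = members, fractions = fr,
       excluded_fraction = 1 - sum(fr), n_events = n)
}

#' Mutant frequency
#'
#' @param colonies resistant colony count.
#' @param n_sorted number of cells sorted and plated (>= 1).
#' @return frequency (colonies per sorted cell), with the exact fraction
#'   in attribute `rational` (c(colonies, n_sorted)).
#' @export
mutant_frequency <- function(colonies, n_sorted) {
  if (n_sorted < 1) stop("n_sorted must be >= 1")
  if (colonies < 0) stop("colonies must be >= 0")
  structure(colonies / n_sorted, rational = c(colonies, n_sorted))
}

#' Share of total viable mutants per subpopulation
#'
#' Each subpopulation's weight is its colony count times the percentage of
#' cells it comprises (valid when an identical number of cells is sorted
#' per gate); shares are weights normalised to 100%.
#'
#' @param assay data.frame with one row per subpopulation: columns
#'   `subpopulation`, `n_sorted`, `colonies`, `pct_sorted`.
#' @return object of class `plasticity_share`: data.frame with
#'   `subpopulation`, `weight`, `share_pct`.
#' @export
plasticity_share <- function(assay) {
  need <- c("subpopulation", "n_sorted", "colonies", "pct_sorted")
  if (!all(need %in% names(assay))) {
    stop("assay needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(assay) < 2) stop("need at least 2 subpopulations")
  if (length(unique(assay$n_sorted)) != 1) {
    stop("the counts-times-percentage accounting requires an equal number ",
         "of sorted cells per subpopulation")
  }
  w <- assay$colonies * assay$pct_sorted
  if (sum(w) == 0) stop("no mutants in any subpopulation; share undefined")
  out <- data.frame(subpopulation = assay$subpopulation, weight = w,
                    share_pct = 100 * w / sum(w),
                    stringsAsFactors = FALSE)
  class(out) <- c("plasticity_share", "data.frame")
  out
}
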