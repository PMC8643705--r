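#' Single-molecule counting snapshot of basal expression
#'
#' Draws per-cell molecule counts of one adaptive-response protein from
#' its basal (unstressed) stationary law and applies the counting limit of
#' the single-molecule assay: cells with more than `limit` molecules are
#' only recorded as ">limit" (censored). The basal laws are Poisson with
#' the calibrated means; alkA additionally carries a small basal-elevated
#' subpopulation (`alka_high_frac`) giving the overdispersed right tail.
#'
#' @param gene one of `"ada"`, `"alkB"`, `"alkA"`, `"aidB"`.
#' @param n number of cells.
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @param limit counting limit (default 8 molecules).
#' @return an object of class `count_snapshot`: list with `counts`
#'   (observed counts, capped at `limit` where censored), `censored`
#'   (logical), `limit`, `gene`.
#' @export
snapshot_molecule_counts <- function(gene, n, params = sim_params(),
                                     seed = 1L, limit = 8L) {
  gene <- match.arg(gene, c("ada", "alkB", "alkA", "aidB"))
  stopifnot(n >= 1, limit >= 1)
  set.seed(as.integer(seed))
  p <- params
  x <- if (gene == "alkA") {
    hi <- stats::runif(n) < p$expression$alka_high_frac
    ifelse(hi, stats::rpois(n, p$expression$alka_high_mean),
           stats::rpois(n, p$expression$basal_mean$alkA))
  } else {
    stats::rpois(n, p$expression$basal_mean[[gene]])
  }
  count_snapshot(x, limit = limit, gene = gene)
}

#' Build a count snapshot from raw counts
#'
#' @param x integer counts (the true values; censoring is applied here).
#' @param limit counting limit.
#' @param gene gene label.
#' @return a `count_snapshot`.
#' @export
count_snapshot <- function(x, limit = 8L, gene = "unknown") {
  if (length(x) < 1) stop("need at least one cell")
  if (any(x < 0)) stop("counts must be non-negative")
  cen <- x > limit
  structure(list(counts = as.integer(pmin(x, limit)), censored = cen,
                 limit = as.integer(limit), gene = gene),
            class = "count_snapshot")
}

#' @export
print.count_snapshot <- function(x, ...) {
  cat("<count_snapshot>", x$gene, ":", length(x$counts), "cells,",
      sum(x$censored), sprintf("censored (>%d)", x$limit), "\n")
  invisible(x)
}

#' Cytometry snapshot of a simulated population
#'
#' Emits one event per cell alive at the sampling time, with the
#' adaptive-response reporter intensity (ada channel) and the constitutive
#' marker intensity, each blurred by the cytometer's log-normal
#' measurement spread (`facs_cv`). Dead cells are excluded.
#'
#' @param pop a `population_dataset` simulated with `facs_time` set (or
#'   with traces covering `t_sample`).
#' @param t_sample sampling time (min); must match the captured snapshot.
#' @param seed integer seed for the measurement noise.
#' @return object of class `facs_events`: data.frame with `cell_id`,
#'   `gfp_au`, `mkate_au`.
#' @export
facs_snapshot <- function(pop, t_sample = pop$facs_time, seed = 1L) {
  stopifnot(inherits(pop, "population_dataset"))
  if (is.null(pop$facs_time) || is.null(pop$cells$facs_gfp)) {
    stop("population was simulated without a cytometry snapshot; ",
         "pass facs_time to simulate_population()")
  }
  if (!isTRUE(all.equal(t_sample, pop$facs_time))) {
    stop("t_sample does not match the captured snapshot time (",
         pop$facs_time, " min)")
  }
  set.seed(as.integer(seed))
  keep <- pop$cells$alive_at_facs
  if (!any(keep)) {
    warning("no live cells at the sampling time; empty event set")
  }
  cv <- pop$params$fluorescence$facs_cv
  n <- sum(keep)
  ev <- data.frame(
    cell_id = pop$cells$cell_id[keep],
    gfp_au = pop$cells$facs_gfp[keep] *
      stats::rlnorm(n, -cv^2 / 2, cv),
    mkate_au = pop$cells$facs_mkate[keep] *
      stats::rlnorm(n, -cv^2 / 2, cv),
    stringsAsFactors = FALSE
  )
  class(ev) <- c("facs_events", "data.frame")
  ev
}

#' Rifampicin-resistance colony assay
#'
#' Plates a set of sorted cells and counts resistant colonies: a binomial
#' draw over the sorted cells that are both colony-forming (never died in
#' the simulated window, including any post-sort recovery) and carry a
#' rifampicin-resistance mutation.
#'
#' @param sorted_cells data.frame of `population_dataset$cells` rows.
#' @param plating_efficiency probability a viable resistant cell forms a
#'   colony; in (0, 1].
#' @param seed integer seed.
#' @return integer colony count.
#' @export
colony_assay <- function(sorted_cells, plating_efficiency = 1, seed = 1L) {
  if (plating_efficiency <= 0 || plating_efficiency > 1) {
    stop("plating_efficiency must be in (0, 1]")
  }
  if (is.null(sorted_cells) || nrow(sorted_cells) == 0) return(0L)
  set.seed(as.integer(seed))
  viable <- is.na(sorted_cells$death_time) & sorted_cells$rif_resistant
  stats::rbinom(1L, sum(viable), plating_efficiency)
}

#' Simulate a full sort-and-plate mutation experiment
#'
#' Runs the complete protocol behind the subpopulation mutation-frequency
#' measurements: treat a population for `treat_min` minutes at `dose` mM,
#' take a cytometry snapshot, define Delayed/Activated gates against an
#' untreated culture, sort an identical number of cells from each gate,
#' plate on rifampicin and compute per-gate mutant frequencies and the
#' plasticity share. Cells continue to be simulated for `recovery_min`
#' after the (washed) treatment, so lethally damaged cells sorted while
#' still intensity-positive fail to form colonies.
#'
#' @param dose MMS concentration (mM).
#' @param n_cells treated population size.
#' @param n_untreated untreated reference population size.
#' @param n_sort target cells sorted per gate (capped at the smallest gate
#'   population; equal numbers are sorted from each gate).
#' @param treat_min treatment duration before sorting (min).
#' @param recovery_min simulated post-sort outgrowth (min).
#' @param params a [sim_params()] object.
#' @param width_sigmas gate half-width in units of the untreated SD.
#' @param seed integer seed.
#' @return list with `events`, `gates`, `sort` (the [apply_gates()]
#'   result), `assay` (per-gate n sorted, colonies, frequency, percentage
#'   of events) and `share` (the [plasticity_share()] result).
#' @export
run_facs_experiment <- function(dose, n_cells = 1e6, n_untreated = 1e5,
                                n_sort = 1e6, treat_min = 90,
                                recovery_min = 180,
                                params = sim_params(),
                                width_sigmas = 3, seed = 1L) {
  seed <- as.integer(seed)
  pop <- simulate_population(
    n_cells, params = params,
    mms = mms_profile(c(dose, 0), breakpoints = treat_min),
    horizon = treat_min + recovery_min, seed = seed,
    keep_traces = FALSE, facs_time = treat_min
  )
  ref <- simulate_population(
    n_untreated, params = params, mms = mms_profile(0),
    horizon = treat_min, seed = seed + 1L,
    keep_traces = FALSE, facs_time = treat_min
  )
  ev_treated <- facs_snapshot(pop, seed = seed + 2L)
  ev_untreated <- facs_snapshot(ref, seed = seed + 3L)
  gates <- define_gates(ev_untreated, ev_treated,
                        width_sigmas = width_sigmas)
  srt <- apply_gates(ev_treated, gates)
  n_avail <- min(vapply(srt$members, length, integer(1)))
  if (n_avail < 1) stop("a sorting gate is empty; cannot sort")
  n_sort <- min(n_sort, n_avail)
  set.seed(seed + 4L)
  assay <- do.call(rbind, lapply(names(srt$members), function(g) {
    ids <- sample(srt$members[[g]], n_sort)
    sc <- pop$cells[match(ids, pop$cells$cell_id), ]
    col <- colony_assay(sc, seed = seed + 5L + match(g, names(srt$members)))
    data.frame(subpopulation = g, n_sorted = n_sort, colonies = col,
               frequency = mutant_frequency(col, n_sort),
               pct_sorted = 100 * srt$fractions[[g]],
               stringsAsFactors = FALSE)
  }))
  share <- plasticity_share(assay)
  list(events = ev_treated, gates = gates, sort = srt, assay = assay,
       share = share)
}
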