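#' Simulate a population of mother-machine cells
#'
#' Runs the stochastic adaptive-response model for `n` independent cells
#' on a common frame grid. The OFF state is a birth-death process for the
#' Ada copy number; the switch is the first methylation of any Ada
#' molecule (per-molecule rate `k_m * s(t)` with `s` the lagged
#' intracellular sensing signal); the ON state relaxes towards the
#' activated steady state modulated by a per-cell Ornstein-Uhlenbeck
#' fluctuation shared across the regulon. Three lesion pools with
#' saturable basal repair drive mismatch (MutL focus) formation, ada
#' expression suppression in unswitched cells, and a distress-gated death
#' hazard. All cells are advanced together in fixed steps of
#' `params$observation$dt` minutes with per-step Bernoulli event
#' probabilities `1 - exp(-rate * dt)`.
#'
#' @param n number of cells (>= 1).
#' @param params a [sim_params()] object.
#' @param mms an [mms_profile()] dose profile.
#' @param horizon simulated duration (min); must cover at least one frame.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param keep_traces if `TRUE`, per-frame fluorescence traces and foci
#'   tables are materialised (use for up to ~1e4 cells); if `FALSE` only
#'   per-cell event-level outcomes are kept, allowing ~1e6-cell runs.
#' @param facs_time optional time (min) at which a cytometry snapshot of
#'   reporter and constitutive intensities is captured.
#' @param channels trace channels to materialise when `keep_traces`.
#' @return an object of class `population_dataset`: a list with elements
#'   `cells` (one row per cell: `cell_id`, `n0_ada`, `t_on`, `fate`,
#'   `death_time`, `n_mismatches`, `n_mutations`, `rif_resistant`, and
#'   FACS columns when requested), `traces`, `foci`, `params`, `mms`,
#'   `horizon`, `seed`.
#' @export
simulate_population <- function(n, params = sim_params(),
                                mms = mms_profile(1), horizon,
                                seed = 1L, keep_traces = TRUE,
                                facs_time = NULL,
                                channels = c("ada", "alkB", "alkA", "aidB",
                                             "constitutive")) {
  stopifnot(inherits(params, "sim_params"), inherits(mms, "mms_profile"))
  if (n < 1) stop("n must be >= 1")
  p <- params
  fi <- p$observation$frame_interval
  if (!is.finite(horizon) || horizon < fi) {
    stop("horizon must cover at least one frame (", fi, " min)")
  }
  if (!is.null(facs_time) && (facs_time < 0 || facs_time > horizon)) {
    stop("facs_time must lie within the simulated horizon")
  }
  channels <- match.arg(channels, several.ok = TRUE)
  set.seed(as.integer(seed))

  if (all(mms$doses == 0) && !keep_traces) {
    return(simulate_basal_population(n, p, mms, horizon, seed, facs_time))
  }

  dt <- p$observation$dt
  nstep <- ceiling(horizon / dt)
  tgrid <- (seq_len(nstep) - 1L) * dt       # step start times
  gamma <- p$expression$dilution_rate

  geno <- p$genotype
  ada_present <- geno != "delta_ada_alkB"
  rep_on_gene <- c(meA = geno != "delta_alkA",
                   meC = !geno %in% c("delta_alkB", "delta_ada_alkB"),
                   o6meg = geno %in% c("wild_type", "delta_alkA",
                                       "delta_alkB"))

  # dose and sensing signal paths (identical for all cells)
  m_path <- dose_at(mms, tgrid)
  s_path <- numeric(nstep)
  es <- exp(-p$switch$sensing_rate * dt)
  s <- 0
  for (k in seq_len(nstep)) {
    s <- m_path[k] + (s - m_path[k]) * es
    s_path[k] <- s
  }

  al <- p$lesions$lesion_alpha
  vmax <- p$lesions$basal_vmax
  km <- p$lesions$basal_km
  dec <- p$lesions$basal_decay
  ind <- p$lesions$induced_rate
  repair_lag <- p$lesions$repair_lag
  alka_lag <- p$expression$alka_lag

  kb_ada <- p$expression$basal_mean$ada * gamma
  n_ada <- if (ada_present) stats::rpois(n, p$expression$basal_mean$ada)
           else integer(n)
  n0_ada <- n_ada

  LA <- LC <- LO <- numeric(n)
  D <- numeric(n)
  cumhaz <- numeric(n)
  Ethr <- stats::rexp(n)
  alive <- rep(TRUE, n)
  death_time <- rep(NA_real_, n)
  switched <- rep(FALSE, n)
  t_on <- rep(NA_real_, n)
  n_on <- rep(NA_real_, n)
  mm_cum <- numeric(n)

  frames <- seq(0, horizon, by = fi)
  nf <- length(frames)
  mat <- p$expression$maturation
  if (keep_traces) {
    mm_frame <- numeric(n)
    foci_counts <- numeric(n)
    foci_cell <- integer(0)
    foci_frame <- integer(0)
    N_pre <- matrix(rep(n_ada, nf), nrow = n, ncol = nf)
    samp_t <- pmax(frames - mat, 0)
    rec_step <- pmin(pmax(floor(samp_t / dt) + 1L, 1L), nstep)
    # frame j's foci are drawn at the step covering its time (frame > 0)
    frame_step <- pmin(ceiling(frames[-1] / dt), nstep)
  }
  facs_step <- if (!is.null(facs_time)) {
    max(1L, min(nstep, floor(facs_time / dt) + 1L))
  } else NA_integer_
  facs_n_ada <- NULL
  facs_alive <- NULL

  r0 <- p$mismatch$r0
  r_mut <- p$mismatch$r_mut
  r_tox <- p$mismatch$r_tox
  l_half <- p$mismatch$l_half
  supp_K <- p$switch$supp_K
  supp_h <- p$switch$supp_hill
  k_m <- p$switch$k_m
  h_max <- p$death$h_max
  Lc <- p$death$lethal_thresh
  e_up <- exp(-dt / p$death$tau_up)
  e_dn <- exp(-dt / p$death$tau_down)
  wash <- p$lesions$wash_dilution
  onset_t <- stress_onset(mms)

  unsw <- if (ada_present) seq_len(n) else integer(0) # alive & unswitched

  t_rep_A <- rep(Inf, n)   # induced repair onset per cell (set at switch)
  t_rep <- rep(Inf, n)
  for (k in seq_len(nstep)) {
    t <- tgrid[k]
    m <- m_path[k]
    s <- s_path[k]

    # lesion pools, semi-implicit update (stable for stiff repair rates);
    # full-vector arithmetic, dead cells masked where it matters
    on_A <- rep_on_gene[["meA"]] & t >= t_rep_A
    on_C <- rep_on_gene[["meC"]] & t >= t_rep
    on_O <- rep_on_gene[["o6meg"]] & t >= t_rep
    # wash-out: once MMS is removed, resumed growth and excision add an
    # extra first-order clearance of all adducts
    w <- if (m == 0 && t > onset_t) wash else 0
    LA <- (LA + dt * al$meA * m) /
      (1 + dt * (vmax$meA / (km$meA + LA) + dec$meA + w + ind$meA * on_A))
    LC <- (LC + dt * al$meC * m) /
      (1 + dt * (vmax$meC / (km$meC + LC) + dec$meC + w + ind$meC * on_C))
    LO <- (LO + dt * al$o6meg * m) /
      (1 + dt * (vmax$o6meg / (km$o6meg + LO) + dec$o6meg + w +
                   ind$o6meg * on_O))

    Ltox <- LA + LC
    above <- Ltox > Lc
    D <- D * (e_dn + (e_up - e_dn) * above) + (1 - e_up) * above

    # mismatch conversion saturates with load (replication throughput)
    rate <- (r0 + r_mut * LO / (1 + LO / l_half) +
               r_tox * Ltox / (1 + Ltox / l_half)) * alive
    mm_cum <- mm_cum + rate * dt
    if (keep_traces) mm_frame <- mm_frame + rate * dt

    cumhaz <- cumhaz + (h_max * dt) * D * alive
    if (any(dd <- alive & cumhaz >= Ethr)) {
      dead_now <- which(dd)
      h_here <- h_max * D[dead_now] * dt
      over <- pmin(pmax((cumhaz[dead_now] - Ethr[dead_now]) / h_here, 0), 1)
      death_time[dead_now] <- t + dt * (1 - over)
      alive[dead_now] <- FALSE
    }

    if (length(unsw)) {
      unsw <- unsw[alive[unsw]]
    }
    if (length(unsw)) {
      nu <- n_ada[unsw]
      # switch: first methylation of any Ada molecule
      psw <- -expm1(-nu * k_m * s * dt)
      hit <- stats::runif(length(unsw)) < psw
      if (any(hit)) {
        id <- unsw[hit]
        t_on[id] <- t + stats::runif(length(id)) * dt
        n_on[id] <- n_ada[id]
        switched[id] <- TRUE
        t_rep[id] <- t_on[id] + repair_lag
        t_rep_A[id] <- t_on[id] + alka_lag + repair_lag
      }
      rest <- unsw[!hit]
      if (length(rest)) {
        # dose-dependent suppression of expression in unswitched cells
        # (replication/transcription blocking); scalar per step
        kb_eff <- kb_ada / (1 + (m / supp_K)^supp_h)
        born <- stats::runif(length(rest)) < -expm1(-kb_eff * dt)
        n_ada[rest] <- n_ada[rest] + born
        die <- stats::runif(length(rest)) <
          -expm1(-n_ada[rest] * gamma * dt)
        n_ada[rest] <- n_ada[rest] - (die & n_ada[rest] > 0L)
      }
      unsw <- unsw[!hit]
    }

    if (keep_traces) {
      jj <- which(rec_step == k)
      if (length(jj)) N_pre[, jj] <- n_ada
      ff <- which(frame_step == k)
      if (length(ff)) {
        cnt <- stats::rpois(n, mm_frame * alive)
        foci_counts <- foci_counts + cnt
        pos <- which(cnt > 0)
        if (length(pos)) {
          foci_cell <- c(foci_cell, pos)
          foci_frame <- c(foci_frame, rep.int(ff[1], length(pos)))
        }
        mm_frame[] <- 0
      }
    }
    if (!is.na(facs_step) && k == facs_step) {
      facs_n_ada <- n_ada
      facs_alive <- alive
    }
  }

  # mutation outcomes
  M <- if (keep_traces) foci_counts else stats::rpois(n, mm_cum)
  fixed <- stats::rbinom(n, M, p$mismatch$p_fix)
  rif <- fixed > 0 &
    stats::runif(n) < -expm1(fixed * log1p(-p$mismatch$p_rif))

  fate <- rep("alive", n)
  dead <- !alive
  if (any(dead)) {
    fp <- unlist(p$fate_probs)
    fate[dead] <- sample(names(fp), sum(dead), replace = TRUE, prob = fp)
  }

  cells <- data.frame(
    cell_id = sprintf("c%06d", seq_len(n)),
    n0_ada = n0_ada,
    t_on = t_on,
    fate = fate,
    death_time = death_time,
    n_mismatches = M,
    n_mutations = fixed,
    rif_resistant = rif,
    stringsAsFactors = FALSE
  )

  if (!is.null(facs_time)) {
    fl <- facs_intensity(p, facs_time, facs_n_ada, switched, t_on, n_on)
    cells$facs_gfp <- fl$gfp
    cells$facs_mkate <- fl$mkate
    cells$alive_at_facs <- facs_alive
  }

  traces <- NULL
  foci <- data.frame(cell_id = character(0), frame_index = integer(0),
                     time_min = numeric(0))
  if (keep_traces) {
    traces <- build_traces(p, frames, channels, n, N_pre, switched, t_on,
                           n_on, death_time, horizon, stress_onset(mms))
    if (length(foci_cell)) {
      o <- order(foci_cell, foci_frame)
      foci <- data.frame(cell_id = cells$cell_id[foci_cell[o]],
                         frame_index = foci_frame[o],
                         time_min = frames[foci_frame[o] + 1L],
                         stringsAsFactors = FALSE)
    }
  }

  structure(list(cells = cells, traces = traces, foci = foci,
                 params = p, mms = mms, horizon = horizon,
                 seed = as.integer(seed), facs_time = facs_time),
            class = "population_dataset")
}

# Stationary shortcut for an unstressed population without traces: no cell
# switches, no lesions accumulate and the hazard is zero, so per-cell
# outcomes can be drawn from the stationary laws directly.
simulate_basal_population <- function(n, p, mms, horizon, seed, facs_time) {
  ada_present <- p$genotype != "delta_ada_alkB"
  n_ada <- if (ada_present) stats::rpois(n, p$expression$basal_mean$ada)
           else integer(n)
  M <- stats::rpois(n, p$mismatch$r0 * horizon)
  fixed <- stats::rbinom(n, M, p$mismatch$p_fix)
  rif <- fixed > 0 &
    stats::runif(n) < -expm1(fixed * log1p(-p$mismatch$p_rif))
  cells <- data.frame(
    cell_id = sprintf("c%06d", seq_len(n)),
    n0_ada = n_ada,
    t_on = NA_real_,
    fate = "alive",
    death_time = NA_real_,
    n_mismatches = M,
    n_mutations = fixed,
    rif_resistant = rif,
    stringsAsFactors = FALSE
  )
  if (!is.null(facs_time)) {
    fl <- facs_intensity(p, facs_time, n_ada, rep(FALSE, n),
                         rep(NA_real_, n), rep(NA_real_, n))
    cells$facs_gfp <- fl$gfp
    cells$facs_mkate <- fl$mkate
    cells$alive_at_facs <- TRUE
  }
  structure(list(cells = cells, traces = NULL,
                 foci = data.frame(cell_id = character(0),
                                   frame_index = integer(0),
                                   time_min = numeric(0)),
                 params = p, mms = mms, horizon = horizon,
                 seed = as.integer(seed), facs_time = facs_time),
            class = "population_dataset")
}

# Noiseless reporter and constitutive intensities at the cytometry sample
# time. Switched cells use the deterministic ON-state relaxation with a
# stationary draw of the expression fluctuation; unswitched cells carry
# their basal copy number.
facs_intensity <- function(p, facs_time, n_ada, switched, t_on, n_on) {
  n <- length(n_ada)
  gamma <- p$expression$dilution_rate
  tau <- facs_time - p$expression$maturation
  nn <- as.numeric(n_ada)
  sw <- which(switched & t_on <= facs_time)
  if (length(sw)) {
    d <- 1 + stats::rnorm(length(sw), 0, p$expression$fluct_sd)
    dl <- pmax(tau - t_on[sw], 0)
    nn[sw] <- n_on[sw] * exp(-gamma * dl) +
      p$expression$activated_ss$ada * pmax(d, 0) * -expm1(-dl / p$expression$rise_time)
  }
  gfp <- p$fluorescence$fluor_scale$ada * nn + p$fluorescence$fluor_bg
  nc <- p$expression$basal_mean$constitutive *
    (1 + stats::rnorm(n, 0, p$expression$fluct_sd))
  mkate <- p$fluorescence$fluor_scale$constitutive * pmax(nc, 0) +
    p$fluorescence$fluor_bg
  list(gfp = gfp, mkate = mkate)
}

# Materialise per-frame fluorescence matrices for every requested channel.
build_traces <- function(p, frames, channels, n, N_pre, switched, t_on,
                         n_on, death_time, horizon, onset) {
  nf <- length(frames)
  gamma <- p$expression$dilution_rate
  mat <- p$expression$maturation
  tau <- pmax(frames - mat, 0)
  theta <- p$expression$fluct_theta
  sdd <- p$expression$fluct_sd
  need_d <- any(c("ada", "alkB", "alkA") %in% channels) && any(switched)
  dgrid <- NULL
  if (need_d || "constitutive" %in% channels) {
    tg <- seq(0, ceiling(horizon), by = 1)
    a <- exp(-theta)
    sz <- sdd * sqrt(1 - a^2)
    mk_ou <- function() {
      m <- matrix(0, n, length(tg))
      x <- stats::rnorm(n, 0, sdd)
      m[, 1] <- x
      for (j in 2:length(tg)) {
        x <- x * a + stats::rnorm(n, 0, sz)
        m[, j] <- x
      }
      1 + m
    }
    dgrid <- list(times = tg)
    if (need_d) dgrid$shared <- mk_ou()
    if ("constitutive" %in% channels) dgrid$indep <- mk_ou()
  }
  ou_at <- function(mat_ou, tq) {
    # tq: per-cell vector of query times (may be NA); returns fluctuation
    j <- pmin(pmax(round(tq) + 1L, 1L), ncol(mat_ou))
    v <- mat_ou[cbind(seq_len(n), j)]
    v[is.na(tq)] <- 1
    v
  }

  basal_static <- list(
    alkB = if (p$genotype == "delta_ada_alkB") numeric(n)
           else stats::rpois(n, p$expression$basal_mean$alkB),
    alkA = {
      hi <- stats::runif(n) < p$expression$alka_high_frac
      ifelse(hi, stats::rpois(n, p$expression$alka_high_mean),
             stats::rpois(n, p$expression$basal_mean$alkA))
    },
    aidB = stats::rpois(n, p$expression$basal_mean$aidB)
  )
  can_induce_alkA <- p$genotype != "delta_ada_alkB"

  out <- list()
  for (ch in channels) {
    sc <- p$fluorescence$fluor_scale[[ch]]
    Fm <- matrix(0, n, nf)
    for (j in seq_len(nf)) {
      tq <- tau[j]
      nn <- switch(ch,
        ada = {
          v <- as.numeric(N_pre[, j])
          sw <- which(switched & t_on < tq)
          if (length(sw)) {
            dl <- tq - t_on[sw]
            d <- pmax(ou_at(dgrid$shared, rep(tq, n))[sw], 0)
            v[sw] <- n_on[sw] * exp(-gamma * dl) +
              p$expression$activated_ss$ada * d * -expm1(-dl / p$expression$rise_time)
          }
          v
        },
        alkB = {
          v <- as.numeric(basal_static$alkB)
          sw <- which(switched & t_on < tq)
          if (length(sw)) {
            dl <- tq - t_on[sw]
            d <- pmax(ou_at(dgrid$shared, rep(tq, n))[sw], 0)
            v[sw] <- v[sw] * exp(-gamma * dl) +
              p$expression$activated_ss$alkB * d * -expm1(-dl / p$expression$rise_time)
          }
          v
        },
        alkA = {
          v <- as.numeric(basal_static$alkA)
          lag <- p$expression$alka_lag
          sw <- if (can_induce_alkA) which(switched & (t_on + lag) < tq)
                else integer(0)
          if (length(sw)) {
            dl <- tq - t_on[sw] - lag
            d <- pmax(ou_at(dgrid$shared, rep(tq - lag, n))[sw], 0)
            v[sw] <- v[sw] * exp(-gamma * dl) +
              p$expression$activated_ss$alkA * d * -expm1(-dl / p$expression$rise_time)
          }
          v
        },
        aidB = as.numeric(basal_static$aidB),
        constitutive = p$expression$basal_mean$constitutive *
          pmax(ou_at(dgrid$indep, rep(tq, n)), 0)
      )
      Fm[, j] <- sc * nn + p$fluorescence$fluor_bg
    }
    Fm <- Fm + stats::rnorm(n * nf, 0, p$fluorescence$fluor_sd)
    # traces terminate at death
    dd <- which(!is.na(death_time))
    for (i in dd) Fm[i, frames > death_time[i]] <- NA_real_
    rownames(Fm) <- sprintf("c%06d", seq_len(n))
    out[[ch]] <- Fm
  }
  list(times = frames, onset = onset, channels = out)
}

#' Simulate a single cell
#'
#' Convenience wrapper around [simulate_population()] with `n = 1`.
#'
#' @inheritParams simulate_population
#' @return a `population_dataset` holding one cell.
#' @export
simulate_cell <- function(params = sim_params(), mms = mms_profile(1),
                          horizon, seed = 1L, keep_traces = TRUE) {
  simulate_population(1L, params = params, mms = mms, horizon = horizon,
                      seed = seed, keep_traces = keep_traces)
}

#' @export
print.population_dataset <- function(x, ...) {
  cat("<population_dataset>", nrow(x$cells), "cells,", x$params$genotype,
      "\n  dose profile:")
  print(x$mms)
  cat("  horizon:", x$horizon, "min; seed:", x$seed, "\n")
  cat("  switched:", sum(!is.na(x$cells$t_on)),
      "; dead:", sum(!is.na(x$cells$death_time)), "\n")
  if (!is.null(x$traces)) {
    cat("  traces:", paste(names(x$traces$channels), collapse = ", "),
        "on", length(x$traces$times), "frames\n")
  }
  invisible(x)
}
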