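#' Simulator parameters
#'
#' Construct the full parameter set of the adaptive-response simulator.
#' Defaults come from the shipped calibration
#' (`inst/extdata/default_calibration.yaml`), which was fitted against the
#' published single-cell summary statistics (see `scripts/calibrate.R`).
#' Any field can be overridden by name; unknown names are rejected.
#'
#' The model components and their parameters:
#' \describe{
#'   \item{expression}{Basal expression is a birth-death process per gene
#'     with stationary mean `basal_mean` (molecules/cell) and per-molecule
#'     dilution rate `dilution_rate` (min^-1). `alka_high_frac` of cells
#'     draw their basal alkA count from a `Poisson(alka_high_mean)`
#'     component instead, giving the overdispersed right tail seen in
#'     single-molecule counting. After the switch, copy numbers relax
#'     towards `activated_ss * d(t)` with timescale `rise_time`, where
#'     `d(t)` is a per-cell Ornstein-Uhlenbeck fluctuation with mean 1,
#'     reversion rate `fluct_theta` and stationary SD `fluct_sd`, shared
#'     between ada and alkB and read by alkA with lag `alka_lag`.}
#'   \item{switch}{Each Ada molecule is methylated (activating the
#'     positive feedback) at rate `k_m * s(t)` where the sensing signal
#'     `s(t)` follows the extracellular dose with first-order rate
#'     `sensing_rate` (methyl-phosphotriester lesions must accumulate
#'     before Ada can be methylated, and persist after wash-out). Cells
#'     with zero Ada molecules cannot switch until basal expression
#'     produces one; in unswitched cells the ada birth rate is divided by
#'     `1 + (s/supp_K)^supp_hill`, the dose-dependent suppression of
#'     expression by replication/transcription-blocking damage that traps
#'     zero-copy cells in the Delayed state at high dose.}
#'   \item{lesions}{Three lesion pools: `meA` (3meA, AlkA substrate, basal
#'     Tag repair), `meC` (3meC/1meA, AlkB substrate, no basal enzyme) and
#'     `o6meg` (O6meG, Ada-C321 substrate, basal Ogt repair). Each obeys
#'     `dL/dt = alpha * m(t) - vmax * L/(km + L) - decay * L -
#'     induced * L * [induced repair active]`; the Michaelis-Menten basal
#'     term encodes the finite capacity of the constitutive enzymes, which
#'     saturates between 1 and 3 mM. After wash-out an extra first-order
#'     `wash_dilution` models resumed growth and excision in fresh
#'     medium.}
#'   \item{mismatch}{MutL focus rate per cell is
#'     `r0 + r_mut * sat(L_o6meg) + r_tox * sat(L_meA + L_meC)` with
#'     `sat(L) = L / (1 + L/l_half)` (conversion of lesions to mismatches
#'     is capped by replication throughput); each focus fixes a mutation
#'     with probability `p_fix` and a fixed mutation confers rifampicin
#'     resistance with probability `p_rif`.}
#'   \item{death}{A distress variable `D` builds towards 1 (time constant
#'     `tau_up`) while the replication-blocking load `L_meA + L_meC`
#'     exceeds `lethal_thresh` and decays (time constant `tau_down`) below
#'     it; the death hazard is `h_max * D`.}
#'   \item{fluorescence}{Reporter intensity is
#'     `fluor_scale * n(t - maturation) + fluor_bg` plus Gaussian noise
#'     `fluor_sd`, sampled every `frame_interval` minutes. `facs_cv` is
#'     the extra log-normal spread of cytometer measurements.}
#' }
#'
#' @param ... named overrides of calibration fields (nested lists are
#'   merged by name, e.g. `mismatch = list(r0 = 0.02)`).
#' @param genotype one of `"wild_type"`, `"delta_alkB"`, `"delta_alkA"`,
#'   `"delta_ada_alkB"`, `"ada_C321A"`. `delta_ada_alkB` removes the ada
#'   gene entirely (never switches) and AlkB repair; the single deletions
#'   remove the corresponding induced repair term; `ada_C321A` switches
#'   with wild-type kinetics but lacks induced O6meG repair.
#' @param calibration optional calibration list or path to a YAML file in
#'   the schema of `default_calibration()`.
#' @return an object of class `sim_params` (a validated nested list).
#' @export
sim_params <- function(..., genotype = "wild_type", calibration = NULL) {
  base <- if (is.null(calibration)) {
    default_calibration()
  } else if (is.character(calibration)) {
    read_calibration(calibration)
  } else {
    calibration
  }
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all overrides to sim_params() must be named")
  }
  p <- modify_by_name(base, over)
  p$genotype <- match.arg(genotype, genotypes())
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> genotype:", x$genotype, "\n")
  cat("  basal means:",
      paste(sprintf("%s=%g", names(x$expression$basal_mean),
                    unlist(x$expression$basal_mean)), collapse = ", "), "\n")
  cat("  switch: k_m =", x$switch$k_m,
      " sensing_rate =", x$switch$sensing_rate, "\n")
  cat("  frame_interval =", x$observation$frame_interval,
      "min, dt =", x$observation$dt, "min\n")
  invisible(x)
}

#' Genotype labels understood by the simulator
#' @return character vector of genotype names.
#' @export
genotypes <- function() {
  c("wild_type", "delta_alkB", "delta_alkA", "delta_ada_alkB", "ada_C321A")
}

#' Shipped default calibration
#'
#' Reads the packaged calibration file. The constants are data, not code:
#' they were produced by the documented search in `scripts/calibrate.R`.
#' @return nested list of calibration constants.
#' @export
default_calibration <- function() {
  path <- system.file("extdata", "default_calibration.yaml",
                      package = "adaswitch", mustWork = TRUE)
  read_calibration(path)
}

#' Read a calibration YAML file
#' @param path file path.
#' @return nested list of calibration constants.
#' @export
read_calibration <- function(path) {
  cal <- yaml::read_yaml(path)
  expected <- c("expression", "switch", "lesions", "mismatch", "death",
                "fluorescence", "observation", "fate_probs")
  unknown <- setdiff(names(cal), expected)
  if (length(unknown)) {
    stop("unknown calibration sections: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(expected, names(cal))
  if (length(missing)) {
    stop("calibration file lacks sections: ", paste(missing, collapse = ", "))
  }
  cal
}

# Recursive merge of named overrides into a nested list; unknown keys at
# any depth are an error so config typos cannot silently pass through.
modify_by_name <- function(base, over, path = character()) {
  for (nm in names(over)) {
    here <- paste(c(path, nm), collapse = "$")
    if (!nm %in% names(base)) {
      stop("unknown parameter: ", here)
    }
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- modify_by_name(base[[nm]], over[[nm]], c(path, nm))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

validate_sim_params <- function(p) {
  chk_num <- function(x, what, lo = 0, hi = Inf) {
    v <- unlist(x)
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop("parameter `", what, "` must be finite numeric")
    }
    if (any(v < lo) || any(v > hi)) {
      stop("parameter `", what, "` out of range [", lo, ", ", hi, "]")
    }
    invisible(TRUE)
  }
  chk_num(p$expression$basal_mean, "expression$basal_mean")
  chk_num(p$expression$dilution_rate, "expression$dilution_rate")
  chk_num(p$expression$alka_high_frac, "expression$alka_high_frac", 0, 1)
  chk_num(p$expression$rise_time, "expression$rise_time")
  chk_num(p$switch$k_m, "switch$k_m")
  chk_num(p$switch$sensing_rate, "switch$sensing_rate")
  chk_num(unlist(p$lesions), "lesions")
  chk_num(p$mismatch$r0, "mismatch$r0")
  chk_num(p$mismatch$p_fix, "mismatch$p_fix", 0, 1)
  chk_num(p$mismatch$p_rif, "mismatch$p_rif", 0, 1)
  chk_num(p$death$h_max, "death$h_max")
  chk_num(p$observation$frame_interval, "observation$frame_interval")
  if (p$observation$frame_interval <= 0) {
    stop("parameter `observation$frame_interval` must be > 0")
  }
  if (p$observation$dt <= 0) stop("parameter `observation$dt` must be > 0")
  pools <- c("meA", "meC", "o6meg")
  for (f in c("lesion_alpha", "basal_vmax", "basal_km", "basal_decay",
              "induced_rate")) {
    if (!all(pools %in% names(p$lesions[[f]]))) {
      stop("lesions$", f, " must name pools ", paste(pools, collapse = ", "))
    }
  }
  fp <- unlist(p$fate_probs)
  if (abs(sum(fp) - 1) > 1e-6) stop("fate_probs must sum to 1")
  invisible(p)
}

#' Piecewise-constant MMS dose profile
#'
#' Defines the extracellular methyl methanesulfonate concentration m(t) as
#' a step function. The canonical treatments are a constant step
#' (`mms_profile(1)`) and a pulse followed by wash-out
#' (`mms_profile(c(3, 0), breakpoints = 90)`).
#'
#' @param doses dose level (mM) on each segment; length = number of
#'   breakpoints + 1.
#' @param breakpoints strictly increasing times (min) at which the dose
#'   changes; empty for a constant profile.
#' @param onset time (min) at which the first non-zero segment starts; a
#'   shorthand that prepends a zero-dose segment, e.g.
#'   `mms_profile(1, onset = 21)`.
#' @return object of class `mms_profile`.
#' @export
mms_profile <- function(doses = 1, breakpoints = numeric(0), onset = NULL) {
  if (!is.null(onset)) {
    if (length(breakpoints)) stop("give either `onset` or `breakpoints`")
    breakpoints <- onset
    doses <- c(0, doses)
  }
  if (length(doses) != length(breakpoints) + 1) {
    stop("need length(doses) == length(breakpoints) + 1")
  }
  if (any(doses < 0)) stop("doses must be >= 0")
  if (length(breakpoints) && any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be strictly increasing")
  }
  structure(list(doses = as.numeric(doses),
                 breakpoints = as.numeric(breakpoints)),
            class = "mms_profile")
}

#' Evaluate a dose profile
#' @param mms an `mms_profile`.
#' @param t times (min).
#' @return dose (mM) at each time.
#' @export
dose_at <- function(mms, t) {
  stopifnot(inherits(mms, "mms_profile"))
  mms$doses[findInterval(t, mms$breakpoints) + 1L]
}

#' Time of stress onset
#' @param mms an `mms_profile`.
#' @return first time (min) with a positive dose, or `Inf` if none.
#' @export
stress_onset <- function(mms) {
  stopifnot(inherits(mms, "mms_profile"))
  pos <- which(mms$doses > 0)
  if (!length(pos)) return(Inf)
  if (pos[1] == 1L) 0 else mms$breakpoints[pos[1] - 1L]
}

#' @export
print.mms_profile <- function(x, ...) {
  if (!length(x$breakpoints)) {
    cat("<mms_profile> constant", x$doses, "mM\n")
  } else {
    cat("<mms_profile> doses", paste(x$doses, collapse = " / "),
        "mM at breakpoints", paste(x$breakpoints, collapse = ", "), "min\n")
  }
  invisible(x)
}
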