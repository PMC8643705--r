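#' Summarise a molecule-count snapshot
#'
#' Histogram and headline statistics of a censored counting snapshot. The
#' mean is computed over uncensored (countable) cells, matching how
#' single-molecule counting assays report averages when some cells exceed
#' the counting limit. Fractions are reported against both denominators
#' (all cells, and uncensored cells only), since published histograms do
#' not always state which is used.
#'
#' @param snapshot a `count_snapshot`.
#' @return list with `histogram` (data.frame `count` 0..limit plus
#'   `">limit"`, `n`, `frac_all`, `frac_uncensored`), `mean_uncensored`,
#'   `frac_zero`, `frac_one`, `frac_ge1`, `frac_censored`, `n`,
#'   `n_censored`, `limit`, `gene`.
#' @export
summarize_counts <- function(snapshot) {
  stopifnot(inherits(snapshot, "count_snapshot"))
  x <- snapshot$counts
  cen <- snapshot$censored
  lim <- snapshot$limit
  n <- length(x)
  unc <- x[!cen]
  tab <- tabulate(unc + 1L, nbins = lim + 1L)
  hist <- data.frame(
    count = c(as.character(0:lim), paste0(">", lim)),
    n = c(tab, sum(cen)),
    stringsAsFactors = FALSE
  )
  hist$frac_all <- hist$n / n
  hist$frac_uncensored <- c(tab / max(length(unc), 1L), NA_real_)
  list(histogram = hist,
       mean_uncensored = if (length(unc)) mean(unc) else NA_real_,
       frac_zero = sum(unc == 0) / n,
       frac_one = sum(unc == 1) / n,
       frac_ge1 = (sum(unc >= 1) + sum(cen)) / n,
       frac_censored = mean(cen),
       n = n, n_censored = sum(cen), limit = lim, gene = snapshot$gene)
}

#' Fit a Poisson law to a censored count snapshot
#'
#' Maximum-likelihood estimate of the Poisson rate under right censoring
#' at the counting limit: uncensored cells contribute their Poisson mass,
#' censored cells contribute `P(X > limit)`. The Fano factor
#' (variance/mean, sample variance with n-1 denominator) is computed from
#' the uncensored cells, and goodness of fit is assessed by a chi-square
#' test on bins pooled to an expected count of at least 5.
#'
#' @param snapshot a `count_snapshot`.
#' @return object of class `poisson_fit`: list with `lambda` (MLE),
#'   `lambda_naive` (uncensored mean), `fano`, `gof_p`, `gof_df`, `n`,
#'   `n_censored`, `degenerate` flag.
#' @export
fit_poisson <- function(snapshot) {
  stopifnot(inherits(snapshot, "count_snapshot"))
  x <- snapshot$counts
  cen <- snapshot$censored
  lim <- snapshot$limit
  unc <- x[!cen]
  if (length(unc) < 10) stop("need at least 10 uncensored cells")
  if (all(cen)) stop("all cells censored; rate not identifiable")
  nc <- sum(cen)
  degenerate <- all(unc == 0) && nc == 0
  if (degenerate) {
    return(structure(list(lambda = 0, lambda_naive = 0, fano = 0,
                          gof_p = NA_real_, gof_df = NA_integer_,
                          n = length(x), n_censored = 0L,
                          degenerate = TRUE),
                     class = "poisson_fit"))
  }
  lambda <- if (nc == 0) {
    mean(unc)
  } else {
    nll <- function(lam) {
      -(sum(stats::dpois(unc, lam, log = TRUE)) +
          nc * stats::ppois(lim, lam, lower.tail = FALSE, log.p = TRUE))
    }
    stats::optimize(nll, c(1e-8, 5 * (mean(unc) + lim)))$minimum
  }
  fano <- if (mean(unc) > 0) stats::var(unc) / mean(unc) else 0
  # chi-square GOF on 0..limit plus censored bin, pooled to expected >= 5
  obs <- c(tabulate(unc + 1L, nbins = lim + 1L), nc)
  pr <- c(stats::dpois(0:lim, lambda),
          stats::ppois(lim, lambda, lower.tail = FALSE))
  expd <- length(x) * pr
  grp <- pool_bins(expd, 5)
  obs_p <- as.numeric(tapply(obs, grp, sum))
  exp_p <- as.numeric(tapply(expd, grp, sum))
  gof_p <- NA_real_
  gof_df <- NA_integer_
  if (length(obs_p) >= 3) {
    stat <- sum((obs_p - exp_p)^2 / exp_p)
    gof_df <- length(obs_p) - 2L   # one fitted parameter
    gof_p <- stats::pchisq(stat, gof_df, lower.tail = FALSE)
  }
  structure(list(lambda = lambda, lambda_naive = mean(unc), fano = fano,
                 gof_p = gof_p, gof_df = gof_df, n = length(x),
                 n_censored = nc, degenerate = FALSE),
            class = "poisson_fit")
}

# Greedy left-to-right pooling of adjacent bins until each group's
# expected count reaches the floor; a trailing short group is merged back.
pool_bins <- function(expd, floor_n) {
  grp <- integer(length(expd))
  g <- 1L
  acc <- 0
  for (i in seq_along(expd)) {
    grp[i] <- g
    acc <- acc + expd[i]
    if (acc >= floor_n && i < length(expd)) {
      g <- g + 1L
      acc <- 0
    }
  }
  if (acc < floor_n && g > 1L) grp[grp == g] <- g - 1L
  grp
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf(
    "<poisson_fit> lambda = %.3f (uncensored mean %.3f), Fano = %.3f\n  n = %d (%d censored); GOF p = %s\n",
    x$lambda, x$lambda_naive, x$fano, x$n, x$n_censored,
    ifelse(is.na(x$gof_p), "NA", sprintf("%.3f", x$gof_p))))
  invisible(x)
}
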