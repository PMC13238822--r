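#' Steady-state outcome metrics over the final analysis window
#'
#' Computes the three long-term prey outcomes over the last `window` years
#' of each replicate:
#' \describe{
#'   \item{mean spawning biomass}{time-mean SSB per replicate, averaged
#'     across replicates;}
#'   \item{stability}{the inverse of the mean coefficient of variation —
#'     the temporal CV (population SD / mean) is computed per replicate,
#'     averaged across replicates, then inverted. A constant series has
#'     CV 0 and stability is reported as `NA` (infinite);}
#'   \item{plus-group proportion}{time-mean of plus-group numbers over total
#'     numbers (a numbers, not biomass, basis), averaged across replicates.}
#' }
#'
#' @param ssb replicate x year matrix (or single-series vector) of annual
#'   spawning biomass.
#' @param n_tot,n_plus matching matrices of total and plus-group numbers;
#'   optional (plus-group proportion reported as `NA` when absent).
#' @param window number of final years to analyze; must not exceed the
#'   trajectory length.
#' @return list with `mean_ssb`, `stability`, `mean_cv`, `plus_prop`, and
#'   the per-replicate vectors `rep_mean`, `rep_cv`, `rep_plus_prop`.
#' @export
steady_state_metrics <- function(ssb, n_tot = NULL, n_plus = NULL,
                                 window = 150) {
  if (is.vector(ssb)) ssb <- matrix(ssb, nrow = 1)
  ny <- ncol(ssb)
  if (window > ny) stop("'window' exceeds the trajectory length")
  idx <- (ny - window + 1L):ny
  w <- ssb[, idx, drop = FALSE]
  rep_mean <- rowMeans(w)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  rep_cv <- apply(w, 1, pop_sd) / rep_mean
  mean_cv <- mean(rep_cv)
  stability <- if (mean_cv > 0) 1 / mean_cv else NA_real_
  rep_plus <- NULL
  plus_prop <- NA_real_
  if (!is.null(n_tot) && !is.null(n_plus)) {
    if (is.vector(n_tot)) n_tot <- matrix(n_tot, nrow = 1)
    if (is.vector(n_plus)) n_plus <- matrix(n_plus, nrow = 1)
    rep_plus <- rowMeans(n_plus[, idx, drop = FALSE] /
                         n_tot[, idx, drop = FALSE])
    plus_prop <- mean(rep_plus)
  }
  list(mean_ssb = mean(rep_mean), stability = stability, mean_cv = mean_cv,
       plus_prop = plus_prop, rep_mean = rep_mean, rep_cv = rep_cv,
       rep_plus_prop = rep_plus)
}

#' Rebuilding time to a fraction of unfished spawning biomass
#'
#' For each replicate, the first rebuilding-phase year (counted from the
#' start of rebuilding) in which spawning biomass reaches
#' `threshold * S0`. Replicates that never reach the benchmark within the
#' phase are censored at the phase length; censored replicates are excluded
#' from the mean and SD but counted and reported.
#'
#' @param ssb replicate x year matrix (or vector) of rebuilding-phase annual
#'   spawning biomass.
#' @param S0 unfished spawning biomass of the scenario (kg).
#' @param threshold rebuilding benchmark as a fraction of `S0` (default
#'   0.4).
#' @return list with per-replicate `times` (years; `NA` when censored),
#'   `censored` logical vector, `n_censored`, `mean`, and `sd` (sample SD
#'   across non-censored replicates).
#' @export
rebuilding_time <- function(ssb, S0, threshold = 0.4) {
  if (is.vector(ssb)) ssb <- matrix(ssb, nrow = 1)
  target <- threshold * S0
  times <- apply(ssb, 1, function(x) {
    hit <- which(x >= target)
    if (length(hit)) hit[1] else NA_integer_
  })
  censored <- is.na(times)
  ok <- times[!censored]
  list(times = times, censored = censored, n_censored = sum(censored),
       mean = if (length(ok)) mean(ok) else NA_real_,
       sd = if (length(ok) > 1) stats::sd(ok) else NA_real_)
}

#' Percent change of a metric relative to a baseline
#'
#' `100 * (scenario - baseline) / baseline`; a decrease is negative.
#'
#' @param metric_scenario scenario value(s).
#' @param metric_baseline baseline value(s); must be nonzero.
#' @return Percent change.
#' @export
relative_change <- function(metric_scenario, metric_baseline) {
  if (any(metric_baseline == 0)) stop("baseline must be nonzero")
  100 * (metric_scenario - metric_baseline) / metric_baseline
}
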