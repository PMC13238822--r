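#' von Bertalanffy length at age
#'
#' Length grows toward the asymptote `Linf` as
#' `Linf * (1 - exp(-k * age))`, with the age-at-length-zero intercept fixed
#' at t0 = 0.
#'
#' @param age age in years (>= 0); vectorized.
#' @param k growth coefficient (yr^-1), > 0.
#' @param Linf asymptotic length (cm), > 0.
#' @return Length in cm, bounded above by `Linf`.
#' @export
length_at_age <- function(age, k, Linf) {
  if (k <= 0 || Linf <= 0) stop("'k' and 'Linf' must be positive")
  if (any(age < 0)) stop("'age' must be >= 0")
  Linf * (1 - exp(-k * age))
}

#' Allometric weight at length
#'
#' @param length length in cm (>= 0); vectorized.
#' @param a_w power-law intercept (kg cm^-b_w).
#' @param b_w power-law exponent.
#' @return Weight in kg, `a_w * length^b_w`.
#' @export
weight_at_age <- function(length, a_w, b_w) {
  if (any(length < 0)) stop("'length' must be >= 0")
  a_w * length^b_w
}

#' Knife-edge vulnerability to the fishery
#'
#' Fish are either fully vulnerable (1) or invulnerable (0); the boundary is
#' inclusive: a fish exactly at the minimum landed length is vulnerable.
#'
#' @param length length in cm; vectorized.
#' @param L_min minimum length caught by the fishery (cm).
#' @return 0/1 numeric vector.
#' @export
vulnerability_at_age <- function(length, L_min) {
  as.numeric(length >= L_min)
}

#' Logistic maturity at age
#'
#' @param age age in years; vectorized.
#' @param a50 age at 50% maturity (yr).
#' @param slope logistic slope (yr^-1), > 0.
#' @return Proportion mature in \[0, 1\]; exactly 0.5 at `a50`.
#' @export
maturity_at_age <- function(age, a50, slope) {
  if (slope <= 0) stop("'slope' must be > 0")
  1 / (1 + exp(-slope * (age - a50)))
}

#' Per-age life-history schedules for a species
#'
#' Assembles length, weight, maturity, and fishery vulnerability for every
#' tracked age class (and sex, where the species is sex-structured) from the
#' species constants. The final age is the plus group; within it growth has
#' saturated, so its schedule values stand for all older fish.
#'
#' @param p a [species_params()] list.
#' @return A data.frame with columns `age`, `sex` (`"F"`/`"M"`, or `"A"` for
#'   a sex-aggregated species), `length`, `weight`, `maturity`, `vuln`.
#' @export
#' @examples
#' sched <- build_schedules(default_parameters()$yelloweye)
#' head(sched)
build_schedules <- function(p) {
  sexes <- if (p$sex_structured) c("F", "M") else "A"
  ages <- seq_len(p$plus_age)
  out <- do.call(rbind, lapply(seq_along(sexes), function(si) {
    idx <- if (p$sex_structured) sexes[si] else 1L
    len <- length_at_age(ages, p$k[[idx]], p$Linf[[idx]])
    data.frame(
      age = ages,
      sex = sexes[si],
      length = len,
      weight = weight_at_age(len, p$a_w[[idx]], p$b_w[[idx]]),
      maturity = maturity_at_age(ages, p$mat_a50[[idx]], p$mat_slope[[idx]]),
      vuln = vulnerability_at_age(len, p$L_min)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Spawning biomass per recruit
#'
#' Expected lifetime mature-female biomass produced by one age-1 recruit
#' under natural mortality plus (optionally) fishing, with the plus group
#' closed by the geometric series of continued survival. Two timing
#' conventions are supported:
#' \describe{
#'   \item{`"pre_pulse"` (default)}{survivorship to age a is `exp(-Z * a)` —
#'     the state at the end of the year, just before the recruitment/aging
#'     pulse. This matches where the simulator evaluates spawning biomass, so
#'     the unfished equilibrium satisfies S0 = R0 * phi exactly and the
#'     steepness identities hold in simulation.}
#'   \item{`"post_pulse"`}{survivorship `exp(-Z * (a - 1))` (1 at age 1), the
#'     start-of-year state.}
#' }
#' For a sex-structured species the calculation runs over the female schedule
#' and is multiplied by the 0.5 birth sex ratio, i.e. phi is female spawning
#' biomass per recruit of unknown sex.
#'
#' @param sched schedules from [build_schedules()].
#' @param M natural mortality (yr^-1); for a sex-structured species the
#'   female rate, > 0.
#' @param F fishing mortality (yr^-1) applied to vulnerable ages; default 0.
#' @param sex_structured apply the female-only, half-sex-ratio convention?
#' @param timing survivorship convention; see Details.
#' @return phi in kg per recruit.
#' @export
spawning_biomass_per_recruit <- function(sched, M, F = 0,
                                         sex_structured = FALSE,
                                         timing = c("pre_pulse",
                                                    "post_pulse")) {
  timing <- match.arg(timing)
  if (M <= 0) stop("'M' must be > 0")
  if (F < 0) stop("'F' must be >= 0")
  s <- if (sex_structured) sched[sched$sex == "F", ] else sched
  s <- s[order(s$age), ]
  A <- nrow(s)
  Z <- M + s$vuln * F
  # cumulative survival through each completed year
  surv_through <- exp(-cumsum(Z))
  ell <- switch(timing,
    pre_pulse = surv_through,                    # ell_a = exp(-sum_{1..a} Z)
    post_pulse = c(1, surv_through[-A])          # ell_1 = 1
  )
  phi <- sum(ell * s$weight * s$maturity)
  # plus group: survivors beyond the terminal age keep W_A, m_A and Z_A
  sA <- exp(-Z[A])
  phi <- phi + ell[A] * sA / (1 - sA) * s$weight[A] * s$maturity[A]
  if (sex_structured) phi <- 0.5 * phi
  phi
}

#' Beverton-Holt parameters from steepness
#'
#' Converts the steepness parameterization (h, R0, phi) into the
#' density-independent productivity `alpha` and density-dependence strength
#' `beta` of the Beverton-Holt curve `R(S) = alpha * S / (1 + beta * S)`:
#' `alpha = 4h / ((1 - h) * phi)`, `beta = (5h - 1) / ((1 - h) * phi * R0)`.
#' By construction `R(R0 * phi) = R0` and `R(0.2 * R0 * phi) = h * R0`.
#'
#' @param h steepness, 0.2 < h < 1. `h = 1` (recruitment independent of
#'   spawning biomass) is signalled as unsupported: alpha is infinite.
#' @param R0 unfished recruitment, > 0.
#' @param phi unfished spawning biomass per recruit, > 0.
#' @return list with `alpha` (recruits per kg at low biomass) and `beta`
#'   (kg^-1).
#' @export
#' @examples
#' bh <- bh_parameters(0.8, 4848, 1)
#' bh$alpha  # 16
bh_parameters <- function(h, R0, phi) {
  if (phi <= 0 || R0 <= 0) stop("'R0' and 'phi' must be > 0")
  if (h <= 0.2) stop("steepness 'h' must be > 0.2")
  if (h >= 1)
    stop("h = 1 implies constant recruitment (infinite alpha); ",
         "not supported by the stock-recruit parameterization")
  list(
    alpha = 4 * h / ((1 - h) * phi),
    beta = (5 * h - 1) / ((1 - h) * phi * R0)
  )
}
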