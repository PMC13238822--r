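#' Unfished no-predation stable age distribution
#'
#' Deterministic start-of-year (post-pulse) equilibrium numbers-at-age under
#' natural mortality only: `R0` recruits at age 1, geometric survival with
#' the plus group absorbing all older fish. For a sex-structured species each
#' sex receives `0.5 * R0` recruits and its own mortality.
#'
#' @param p a [species_params()] list.
#' @param scale multiplier on the distribution (e.g. 1.5 for the
#'   high-biomass initial condition).
#' @return Numbers-at-age: a vector for a sex-aggregated species, or a
#'   `plus_age x 2` matrix with columns `F`, `M`.
#' @export
unfished_sad <- function(p, scale = 1) {
  sad1 <- function(M, R) {
    A <- p$plus_age
    n <- R * exp(-M * (seq_len(A) - 1))
    n[A] <- n[A] / (1 - exp(-M))
    n
  }
  if (p$sex_structured) {
    out <- cbind(F = sad1(p$M[["F"]], 0.5 * p$R0),
                 M = sad1(p$M[["M"]], 0.5 * p$R0))
    out * scale
  } else {
    sad1(p$M, p$R0) * scale
  }
}

#' Autocorrelated recruitment deviations
#'
#' Draws an AR(1) series of log-scale recruitment deviations with stationary
#' marginal `N(0, sigma^2)` and lag-1 autocorrelation `rho`:
#' `eps_k = rho * eps_{k-1} + N(0, sigma^2 * (1 - rho^2))`, with `eps_1`
#' drawn from the stationary distribution.
#'
#' @param rho autocorrelation, |rho| < 1.
#' @param sigma stationary SD, >= 0 (0 gives an all-zero series).
#' @param n_years series length.
#' @param seed optional integer seed.
#' @return Numeric vector of length `n_years`.
#' @export
ar1_deviates <- function(rho, sigma, n_years, seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(numeric(n_years))
  eps <- numeric(n_years)
  innov_sd <- sigma * sqrt(1 - rho^2)
  eps[1] <- stats::rnorm(1, 0, sigma)
  if (n_years > 1) {
    z <- stats::rnorm(n_years - 1, 0, innov_sd)
    for (k in 2:n_years) eps[k] <- rho * eps[k - 1] + z[k - 1]
  }
  eps
}

#' Beverton-Holt recruitment pulse
#'
#' Recruitment entering at age 1 from spawning biomass `S`:
#' `alpha * S / (1 + beta * S)`, optionally multiplied by the lognormal
#' deviate `exp(eps - 0.5 * sigma^2)` whose `-0.5 sigma^2` bias correction
#' makes the multiplier mean-one. Deterministic mode applies multiplier 1
#' (no deviate and no bias term), targeting the mean-recruitment equilibrium.
#' For a sex-structured species each sex receives half the recruits.
#'
#' @param S spawning biomass (kg), >= 0.
#' @param alpha,beta Beverton-Holt parameters ([bh_parameters()]).
#' @param eps log-scale recruitment deviate for this year.
#' @param sigma stationary SD of the deviates (bias-correction term).
#' @param stochastic apply the lognormal multiplier?
#' @param sex_structured split recruits 50:50 by sex?
#' @return Recruits at age 1: a scalar, or a named `c(F =, M =)` pair.
#' @export
recruitment_pulse <- function(S, alpha, beta, eps = 0, sigma = 0,
                              stochastic = FALSE, sex_structured = FALSE) {
  if (S < 0) stop("'S' must be >= 0")
  R <- alpha * S / (1 + beta * S)
  if (stochastic) R <- R * exp(eps - 0.5 * sigma^2)
  if (sex_structured) c(F = 0.5 * R, M = 0.5 * R) else R
}

#' Annual aging pulse
#'
#' Shifts every cohort up one age class: age a + 1 receives age a, the plus
#' group receives its own survivors plus the penultimate class, and age 1
#' receives the new recruits. Apart from the added recruits, total numbers
#' are conserved.
#'
#' @param N end-of-year numbers: a vector, or an ages x 2 matrix for a
#'   sex-structured species.
#' @param recruits recruits at age 1 (scalar, or length-2 for a matrix `N`),
#'   >= 0.
#' @return Post-pulse numbers with the same shape as `N`.
#' @export
age_advance <- function(N, recruits) {
  if (any(recruits < 0)) stop("'recruits' must be >= 0")
  shift1 <- function(n, r) {
    A <- length(n)
    c(r, n[1:(A - 2)], n[A - 1] + n[A])
  }
  if (is.matrix(N)) {
    out <- N
    for (j in seq_len(ncol(N))) out[, j] <- shift1(N[, j], recruits[j])
    out
  } else {
    shift1(N, recruits)
  }
}

#' Spawning biomass of a population state
#'
#' Mature biomass: for a sex-structured species, mature female biomass only;
#' for a sex-aggregated species, mature biomass over all fish.
#'
#' @param state numbers-at-age (vector, or ages x 2 matrix with a female
#'   column `F`).
#' @param sched schedules from [build_schedules()].
#' @param sex_structured females-only accounting?
#' @return Spawning biomass in kg.
#' @export
spawning_biomass <- function(state, sched, sex_structured = FALSE) {
  if (sex_structured) {
    s <- sched[sched$sex == "F", ]
    n <- state[, "F"]
  } else {
    s <- sched
    n <- state
  }
  s <- s[order(s$age), ]
  sum(n * s$weight * s$maturity)
}

# Pack the parameter vector consumed by the compiled RHS (src/ye_rhs.c).
pack_ye_parms <- function(kernel, zy, L0, ZL) {
  c(kernel$delta, kernel$q, zy, as.numeric(L0), as.numeric(ZL),
    as.numeric(kernel$a))
}

# Advance the prey vector across one year with lsoda and the compiled RHS.
# L0/ZL are the predator start-of-year numbers and total mortality rates in
# kernel column order (females then males).
ye_integrate_year <- function(Y, parms, rtol, atol) {
  out <- deSolve::lsoda(y = Y, times = c(0, 1), func = "ye_deriv",
                        parms = parms, dllname = "rebuildsim",
                        initfunc = "ye_init", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("lsoda failed to integrate the year")
  yend <- out[2, -1]
  neg <- yend < 0
  if (any(yend < -100 * atol))
    stop("integrator produced a negative abundance beyond tolerance")
  yend[neg] <- 0
  unname(yend)
}

# Pure-R right-hand side, used as the independent cross-check of the
# compiled RHS in tests.
ye_rhs_r <- function(t, Y, ctx) {
  L_t <- ctx$L0 * exp(-ctx$ZL * t)
  rate <- predation_mortality(Y, L_t, ctx$kernel)
  list(-(ctx$zy + rate) * Y)
}

#' Advance the model state across one year of continuous mortality
#'
#' The within-year dynamics of the semi-discrete model: the predator decays
#' by the exact exponential `L(1) = L(0) * exp(-(M_s + nu * F))` (its
#' dynamics are linear and autonomous), while the prey is integrated through
#' `dY_i/dt = -(M + nu_i * f) * Y_i - predation_mortality(Y(t), L(t)) * Y_i`
#' with the predator trajectory substituted in closed form. Integration uses
#' `lsoda` (adaptive, stiffness-switching) at the stated tolerances; when the
#' kernel is identically zero the prey solution is the exact exponential.
#'
#' @param state list with `Y` (prey numbers, length 65) and `L` (predator
#'   numbers, 20 x 2 matrix with columns `F`, `M`).
#' @param F predator fishing mortality (yr^-1).
#' @param b bycatch proportionality; the prey fishing rate is `b * F` on
#'   vulnerable ages. Use `f_prey` to set a direct prey rate instead.
#' @param kernel a [build_kernel()] object (or `NULL` for no predation).
#' @param model a [build_model()] object supplying mortality and
#'   vulnerability schedules.
#' @param f_prey optional direct prey fishing rate overriding `b * F`.
#' @param rtol,atol integrator tolerances.
#' @return The state at the end of the year (t = 1^-), same shape as `state`.
#' @export
within_year_step <- function(state, F, b, kernel, model, f_prey = NULL,
                             rtol = 1e-6, atol = 1e-8) {
  if (F < 0 || b < 0) stop("'F' and 'b' must be >= 0")
  if (any(state$Y < 0) || any(state$L < 0)) stop("abundances must be >= 0")
  fy <- if (is.null(f_prey)) b * F else f_prey
  ZL <- model$ZL_base + model$vuln_L * F
  Lend <- state$L * exp(-ZL)
  zy <- model$ye$M + model$vuln_Y * fy
  if (is.null(kernel) || all(kernel$a == 0)) {
    Yend <- state$Y * exp(-zy)
  } else {
    parms <- pack_ye_parms(kernel, zy, c(state$L[, "F"], state$L[, "M"]),
                           c(ZL[, "F"], ZL[, "M"]))
    Yend <- ye_integrate_year(state$Y, parms, rtol, atol)
  }
  list(Y = Yend, L = Lend)
}

#' Assemble a predator-prey model object
#'
#' Bundles the species parameters, per-age schedules, steepness-derived
#' stock-recruit parameters, and the predation kernel for a given prey
#' specialization into the single object consumed by the simulator and the
#' calibration routines.
#'
#' @param params parameter set from [default_parameters()] (possibly
#'   modified).
#' @param gamma prey specialization (proportion of predator consumption that
#'   is the focal prey).
#' @param delta handling time; defaults to the predator's value.
#' @param q_scale multiplier on the auto-calibrated alternate-prey scale
#'   ([calibrate_q_scale()]); default 1 applies the calibrated baseline.
#' @param allocation kernel demand-allocation rule; see [build_kernel()].
#' @param q_calibration the calibrated alternate-prey multiplier; computed
#'   with [calibrate_q_scale()] for this model's parameters when `NULL`.
#'   Sensitivity analyses that perturb `delta` or `Y95` around the baseline
#'   should pass the baseline calibration explicitly so the perturbation is
#'   not normalized away.
#' @return A list of class `rebuild_model` with elements `ling`, `ye`
#'   (parameters), `sched_L`, `sched_Y`, `phi_L`, `phi_Y`, `bh_L`, `bh_Y`,
#'   `kernel`, `gamma`, plus cached mortality/vulnerability/biomass vectors
#'   used by the simulation engine.
#' @export
#' @examples
#' m <- build_model(gamma = 0.05)
#' m$bh_Y$alpha
build_model <- function(params = default_parameters(), gamma = 0,
                        delta = NULL, q_scale = 1,
                        allocation = c("biomass", "uniform"),
                        q_calibration = NULL) {
  allocation <- match.arg(allocation)
  ling <- params$lingcod
  ye <- params$yelloweye
  if (is.null(delta)) delta <- ling$delta
  q_auto <- if (gamma > 0) {
    if (is.null(q_calibration)) calibrate_q_scale(params, delta = delta)
    else q_calibration
  } else 1
  sched_L <- build_schedules(ling)
  sched_Y <- build_schedules(ye)
  phi_L <- spawning_biomass_per_recruit(sched_L, ling$M[["F"]],
                                        sex_structured = TRUE)
  phi_Y <- spawning_biomass_per_recruit(sched_Y, ye$M)
  ref_Y <- unfished_sad(ye)
  kernel <- build_kernel(sched_L, sched_Y, gamma, delta, ref_Y, ling,
                         allocation = allocation,
                         q_scale = q_auto * q_scale)
  sl_F <- sched_L[sched_L$sex == "F", ]
  sl_F <- sl_F[order(sl_F$age), ]
  sl_M <- sched_L[sched_L$sex == "M", ]
  sl_M <- sl_M[order(sl_M$age), ]
  sy <- sched_Y[order(sched_Y$age), ]
  structure(list(
    ling = ling, ye = ye,
    sched_L = sched_L, sched_Y = sched_Y,
    phi_L = phi_L, phi_Y = phi_Y,
    bh_L = bh_parameters(ling$h, ling$R0, phi_L),
    bh_Y = bh_parameters(ye$h, ye$R0, phi_Y),
    kernel = kernel, gamma = gamma,
    ZL_base = cbind(F = rep(ling$M[["F"]], ling$plus_age),
                    M = rep(ling$M[["M"]], ling$plus_age)),
    vuln_L = cbind(F = sl_F$vuln, M = sl_M$vuln),
    vuln_Y = sy$vuln,
    wm_LF = sl_F$weight * sl_F$maturity,
    wm_Y = sy$weight * sy$maturity,
    ref_Y = ref_Y
  ), class = "rebuild_model")
}

#' Simulate the semi-discrete dynamics for a span of years
#'
#' Runs the annual cycle — continuous within-year mortality, then the
#' recruitment-and-aging pulse — for `n_years`, recording the pre-pulse
#' (end-of-year) spawning biomass of both species, prey total and plus-group
#' numbers, and the realized recruits. Spawning biomass for the recruitment
#' pulse is the pre-pulse value of the same year.
#'
#' @param model a [build_model()] object.
#' @param init initial state list (`Y`, `L`); default the unfished
#'   no-predation stable age distributions scaled by 1.5 (the high-biomass
#'   start).
#' @param n_years number of annual cycles.
#' @param F predator fishing mortality (yr^-1), constant over the span.
#' @param b bycatch proportionality (prey rate `b * F`).
#' @param f_prey optional direct prey fishing rate overriding `b * F` (used
#'   for historical-depletion calibration).
#' @param stochastic draw lognormal recruitment deviates? Deterministic runs
#'   use multiplier 1.
#' @param eps_L,eps_Y optional pre-drawn deviate series (length `n_years`);
#'   drawn internally when `NULL` and `stochastic` is TRUE.
#' @param seed optional seed used when drawing deviates internally.
#' @param rtol,atol integrator tolerances.
#' @return A list of class `rebuild_sim`: `ssb_Y`, `ssb_L`, `n_tot_Y`,
#'   `n_plus_Y`, `rec_Y`, `rec_L` (per-year vectors), `state` (final
#'   post-pulse state), `eps_L`, `eps_Y`.
#' @export
simulate_population <- function(model, init = NULL, n_years, F = 0, b = 0,
                                f_prey = NULL, stochastic = FALSE,
                                eps_L = NULL, eps_Y = NULL, seed = NULL,
                                rtol = 1e-6, atol = 1e-8) {
  if (is.null(init))
    init <- list(Y = unfished_sad(model$ye, 1.5),
                 L = unfished_sad(model$ling, 1.5))
  if (stochastic) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(eps_L))
      eps_L <- ar1_deviates(model$ling$rho, model$ling$sigma, n_years)
    if (is.null(eps_Y))
      eps_Y <- ar1_deviates(model$ye$rho, model$ye$sigma, n_years)
  } else {
    eps_L <- eps_Y <- numeric(n_years)
  }
  fy <- if (is.null(f_prey)) b * F else f_prey
  ZL <- model$ZL_base + model$vuln_L * F
  survL <- exp(-ZL)
  zy <- model$ye$M + model$vuln_Y * fy
  survY <- exp(-zy)
  kernel <- model$kernel
  predation_on <- !is.null(kernel) && any(kernel$a > 0)
  if (predation_on) {
    parms <- pack_ye_parms(kernel, zy, numeric(length(model$vuln_L)),
                           c(ZL[, "F"], ZL[, "M"]))
    i_l0 <- 2 + length(zy) + seq_along(model$vuln_L)
  }
  A_Y <- model$ye$plus_age
  Y <- init$Y
  L <- init$L
  ssb_Y <- ssb_L <- n_tot <- n_plus <- rec_Y <- rec_L <- numeric(n_years)
  for (k in seq_len(n_years)) {
    Lend <- L * survL
    if (predation_on) {
      parms[i_l0] <- c(L[, "F"], L[, "M"])
      Yend <- ye_integrate_year(Y, parms, rtol, atol)
    } else {
      Yend <- Y * survY
    }
    S_L <- sum(Lend[, "F"] * model$wm_LF)
    S_Y <- sum(Yend * model$wm_Y)
    RL <- recruitment_pulse(S_L, model$bh_L$alpha, model$bh_L$beta,
                            eps_L[k], model$ling$sigma,
                            stochastic = stochastic, sex_structured = TRUE)
    RY <- recruitment_pulse(S_Y, model$bh_Y$alpha, model$bh_Y$beta,
                            eps_Y[k], model$ye$sigma,
                            stochastic = stochastic)
    ssb_Y[k] <- S_Y
    ssb_L[k] <- S_L
    n_tot[k] <- sum(Yend)
    n_plus[k] <- Yend[A_Y]
    rec_Y[k] <- RY
    rec_L[k] <- sum(RL)
    L <- age_advance(Lend, RL)
    Y <- age_advance(Yend, RY)
  }
  structure(list(ssb_Y = ssb_Y, ssb_L = ssb_L, n_tot_Y = n_tot,
                 n_plus_Y = n_plus, rec_Y = rec_Y, rec_L = rec_L,
                 state = list(Y = Y, L = L),
                 eps_L = eps_L, eps_Y = eps_Y),
            class = "rebuild_sim")
}
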