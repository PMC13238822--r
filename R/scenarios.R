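# Deterministic predator-only simulation (analytic within-year decay); the
# predator is independent of the prey, so calibration of its fishing rates
# never needs the ODE integrator.
sim_lingcod <- function(model, F, n_years, init = NULL) {
  if (is.null(init)) init <- unfished_sad(model$ling, 1.5)
  surv <- exp(-(model$ZL_base + model$vuln_L * F))
  L <- init
  ssb <- numeric(n_years)
  for (k in seq_len(n_years)) {
    Lend <- L * surv
    S <- sum(Lend[, "F"] * model$wm_LF)
    ssb[k] <- S
    RL <- recruitment_pulse(S, model$bh_L$alpha, model$bh_L$beta,
                            sex_structured = TRUE)
    L <- age_advance(Lend, RL)
  }
  list(ssb = ssb, state = L)
}

#' Closed-form equilibrium predator spawning biomass at a fishing rate
#'
#' Per-recruit equilibrium of the pulsed Beverton-Holt system:
#' `S_eq(F) = (alpha * phi(F) - 1) / beta` when positive (else 0), with
#' `phi(F)` the spawning biomass per recruit under fishing. At `F = 0` this
#' reduces to `R0 * phi`.
#'
#' @param model a [build_model()] object.
#' @param F fishing mortality (yr^-1).
#' @return Equilibrium spawning biomass (kg).
#' @export
lingcod_equilibrium_ssb <- function(model, F) {
  phi_F <- spawning_biomass_per_recruit(model$sched_L, model$ling$M[["F"]],
                                        F = F, sex_structured = TRUE)
  max(0, (model$bh_L$alpha * phi_F - 1) / model$bh_L$beta)
}

#' Deterministic unfished equilibria of both species
#'
#' Runs the deterministic model at `F = 0` (recruitment multiplier 1) until
#' successive-year spawning biomasses change by less than `tol` relatively,
#' and returns the unfished spawning biomass of each species. The predator
#' equilibrium is independent of prey specialization; the prey equilibrium is
#' depressed below `R0 * phi` whenever predation is active.
#'
#' @param model a [build_model()] object.
#' @param tol relative convergence tolerance between successive years.
#' @param max_years cap on simulated years before declaring non-convergence.
#' @return list with `S0_L`, `S0_Y`, the converged post-pulse `state`, and
#'   `years` run.
#' @export
unfished_equilibrium <- function(model, tol = 1e-8, max_years = 2000) {
  state <- list(Y = unfished_sad(model$ye, 1.5),
                L = unfished_sad(model$ling, 1.5))
  chunk <- 50L
  years <- 0L
  prev <- c(NA_real_, NA_real_)
  repeat {
    sim <- simulate_population(model, init = state, n_years = chunk, F = 0)
    state <- sim$state
    years <- years + chunk
    last <- c(sim$ssb_L[chunk], sim$ssb_Y[chunk])
    pen <- c(sim$ssb_L[chunk - 1L], sim$ssb_Y[chunk - 1L])
    if (all(abs(last - pen) <= tol * abs(last))) {
      return(list(S0_L = last[1], S0_Y = last[2], state = state,
                  years = years))
    }
    if (!any(is.na(prev)) && years >= max_years)
      stop("unfished equilibrium did not converge within ", max_years,
           " years")
    prev <- last
  }
}

#' Solve the predator management target F40
#'
#' The fishing rate at which equilibrium predator spawning biomass equals
#' 40% of its unfished level, found by bracketed root finding on the
#' closed-form per-recruit equilibrium (the predator is independent of the
#' prey, so the equilibrium is exact).
#'
#' @param model a [build_model()] object.
#' @param bracket search interval for F (yr^-1).
#' @param tol root tolerance in F.
#' @return F40 (yr^-1).
#' @export
solve_F40 <- function(model, bracket = c(0, 0.4), tol = 1e-5) {
  S0 <- lingcod_equilibrium_ssb(model, 0)
  f <- function(F) lingcod_equilibrium_ssb(model, F) / S0 - 0.4
  if (f(bracket[1]) * f(bracket[2]) > 0)
    stop("no sign change in the F40 bracket [",
         bracket[1], ", ", bracket[2], "]")
  stats::uniroot(f, bracket, tol = tol)$root
}

#' Solve the historical fishing rates producing 22% depletion
#'
#' The burn-in phase fishes both species deterministically for
#' `burn_years` years from the high-biomass start until each sits at the
#' target fraction (default 22%) of its own unfished spawning biomass. The
#' two rates are solved independently: a direct rate on the predator, and a
#' direct rate on vulnerable prey ages (historical prey fishing, distinct
#' from rebuilding-phase bycatch). Because predation changes prey
#' productivity, the prey rate depends on the prey-specialization scenario.
#'
#' @param model a [build_model()] object.
#' @param S0_L,S0_Y unfished spawning biomasses (from
#'   [unfished_equilibrium()]).
#' @param target depletion target (fraction of S0 at the end of burn-in).
#' @param burn_years burn-in length in years.
#' @param bracket_L,bracket_Y search intervals for the two rates.
#' @return list with `F_hist_L`, `F_hist_Y`, and the achieved depletions.
#' @export
solve_historical_F <- function(model, S0_L, S0_Y, target = 0.22,
                               burn_years = 100,
                               bracket_L = c(0, 3), bracket_Y = c(0, 2)) {
  gL <- function(F)
    sim_lingcod(model, F, burn_years)$ssb[burn_years] / S0_L - target
  if (gL(bracket_L[1]) * gL(bracket_L[2]) > 0)
    stop("predator historical depletion target unreachable in bracket")
  F_hist_L <- stats::uniroot(gL, bracket_L, tol = 1e-6)$root

  gY <- function(f) {
    sim <- simulate_population(model, n_years = burn_years, F = F_hist_L,
                               f_prey = f)
    sim$ssb_Y[burn_years] / S0_Y - target
  }
  if (gY(bracket_Y[1]) * gY(bracket_Y[2]) > 0)
    stop("prey historical depletion target unreachable in bracket")
  F_hist_Y <- stats::uniroot(gY, bracket_Y, tol = 1e-6)$root

  list(F_hist_L = F_hist_L, F_hist_Y = F_hist_Y,
       depletion_L = gL(F_hist_L) + target,
       depletion_Y = gY(F_hist_Y) + target)
}

#' Calibrate reference points for a prey-specialization scenario
#'
#' Computes, for one model (one gamma): the unfished spawning biomasses, the
#' predator management target F40, the historical fishing rates hitting 22%
#' depletion after the deterministic burn-in, and the shared burn-in end
#' state from which every stochastic rebuilding replicate starts.
#'
#' @param model a [build_model()] object.
#' @param target historical depletion (default 0.22).
#' @param burn_years deterministic burn-in length (default 100).
#' @return list of class `reference_points`: `S0_L`, `S0_Y`, `F40`,
#'   `F_hist_L`, `F_hist_Y`, `depletion_L`, `depletion_Y`, `burn_state`,
#'   `burn_years`, `gamma`.
#' @export
calibrate_model <- function(model, target = 0.22, burn_years = 100) {
  eq <- unfished_equilibrium(model)
  F40 <- solve_F40(model)
  hist <- solve_historical_F(model, eq$S0_L, eq$S0_Y, target = target,
                             burn_years = burn_years)
  burn <- simulate_population(model, n_years = burn_years,
                              F = hist$F_hist_L, f_prey = hist$F_hist_Y)
  structure(list(
    S0_L = eq$S0_L, S0_Y = eq$S0_Y, F40 = F40,
    F_hist_L = hist$F_hist_L, F_hist_Y = hist$F_hist_Y,
    depletion_L = burn$ssb_L[burn_years] / eq$S0_L,
    depletion_Y = burn$ssb_Y[burn_years] / eq$S0_Y,
    burn_state = burn$state, burn_years = burn_years, gamma = model$gamma
  ), class = "reference_points")
}

#' Deterministic per-replicate seed for a scenario cell
#'
#' Mixes the master seed with the scenario coordinates and replicate index
#' through a Lehmer-style modular recurrence so that every (gamma, F, b,
#' replicate) combination gets an independent, reproducible stream, with all
#' intermediate values kept below 2^31.
#'
#' @param master_seed integer master seed.
#' @param gamma,F,b scenario coordinates.
#' @param r replicate index.
#' @return Integer seed in \[1, 2^31 - 1].
#' @export
scenario_seed <- function(master_seed, gamma, F, b, r) {
  m <- 2147483647
  mix <- function(s, v) ((s * 48271) %% m + v) %% m
  s <- master_seed %% m
  s <- mix(s, round(gamma * 1e7))
  s <- mix(s, round(F * 1e7))
  s <- mix(s, round(b * 1e7))
  s <- mix(s, r)
  as.integer(s + 1)
}

#' Run one rebuilding scenario
#'
#' Starting from the calibrated deterministic burn-in end state (22%
#' depletion), simulates `n_reps` stochastic rebuilding replicates of
#' `rebuild_years` years at predator fishing rate `F` with prey bycatch rate
#' `b * F`, and collects the annual prey spawning biomass, total and
#' plus-group numbers per replicate.
#'
#' @param model a [build_model()] object.
#' @param refpts [calibrate_model()] output for the same model.
#' @param F predator fishing mortality during rebuilding (yr^-1).
#' @param b bycatch proportionality (default 0.05).
#' @param n_reps number of stochastic replicates.
#' @param rebuild_years rebuilding-phase length (years).
#' @param master_seed integer master seed; replicate seeds come from
#'   [scenario_seed()].
#' @return list of class `scenario_output`: matrices `ssb_Y`, `n_tot_Y`,
#'   `n_plus_Y`, `ssb_L` (replicates x years) plus the scenario metadata.
#' @export
run_scenario <- function(model, refpts, F, b = 0.05, n_reps = 150,
                         rebuild_years = 350, master_seed = 1) {
  ssb_Y <- matrix(0, n_reps, rebuild_years)
  ssb_L <- matrix(0, n_reps, rebuild_years)
  n_tot <- matrix(0, n_reps, rebuild_years)
  n_plus <- matrix(0, n_reps, rebuild_years)
  for (r in seq_len(n_reps)) {
    sd_r <- scenario_seed(master_seed, model$gamma, F, b, r)
    sim <- simulate_population(model, init = refpts$burn_state,
                               n_years = rebuild_years, F = F, b = b,
                               stochastic = TRUE, seed = sd_r)
    ssb_Y[r, ] <- sim$ssb_Y
    ssb_L[r, ] <- sim$ssb_L
    n_tot[r, ] <- sim$n_tot_Y
    n_plus[r, ] <- sim$n_plus_Y
  }
  structure(list(ssb_Y = ssb_Y, ssb_L = ssb_L, n_tot_Y = n_tot,
                 n_plus_Y = n_plus,
                 gamma = model$gamma, F = F, b = b, n_reps = n_reps,
                 rebuild_years = rebuild_years, master_seed = master_seed,
                 S0_Y = refpts$S0_Y, S0_L = refpts$S0_L, F40 = refpts$F40),
            class = "scenario_output")
}

#' Run a grid of prey-specialization x fishing x bycatch scenarios
#'
#' Calibrates each prey-specialization level once, runs every (gamma, F, b)
#' cell, and returns one tidy row of steady-state and rebuilding metrics per
#' cell.
#'
#' @param params parameter set ([default_parameters()]).
#' @param gamma_set prey-specialization levels.
#' @param F_set predator fishing rates.
#' @param b_set bycatch proportionalities.
#' @param n_reps replicates per cell.
#' @param rebuild_years rebuilding-phase length.
#' @param master_seed master seed.
#' @param window steady-state analysis window (final years).
#' @return data.frame keyed by (`gamma`, `F`, `b`) with columns `mean_ssb`,
#'   `stability`, `plus_prop`, `rebuild_mean`, `rebuild_sd`,
#'   `rebuild_censored`, `S0_Y`, `F40`.
#' @export
run_scenario_grid <- function(params = default_parameters(),
                              gamma_set = c(0.001, 0.05),
                              F_set = c(0, 0.1, 0.2), b_set = 0.05,
                              n_reps = 150, rebuild_years = 350,
                              master_seed = 1, window = 150) {
  rows <- list()
  for (g in gamma_set) {
    model <- build_model(params, gamma = g)
    refpts <- calibrate_model(model)
    for (F in F_set) for (b in b_set) {
      out <- run_scenario(model, refpts, F = F, b = b, n_reps = n_reps,
                          rebuild_years = rebuild_years,
                          master_seed = master_seed)
      ss <- steady_state_metrics(out$ssb_Y, out$n_tot_Y, out$n_plus_Y,
                                 window = window)
      rb <- rebuilding_time(out$ssb_Y, refpts$S0_Y)
      rows[[length(rows) + 1L]] <- data.frame(
        gamma = g, F = F, b = b,
        mean_ssb = ss$mean_ssb, stability = ss$stability,
        plus_prop = ss$plus_prop,
        rebuild_mean = rb$mean, rebuild_sd = rb$sd,
        rebuild_censored = rb$n_censored,
        S0_Y = refpts$S0_Y, F40 = refpts$F40
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
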