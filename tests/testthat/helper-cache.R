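# Shared cache for expensive fixtures (calibrations, scenario runs). Helpers
# are loaded once per test run, so objects computed here are reused across
# test files.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

default_params <- function() cached("params", default_parameters())

# models and reference points per prey-specialization level
model_for <- function(gamma) {
  cached(paste0("model_", gamma), build_model(default_params(), gamma = gamma))
}
refpts_for <- function(gamma) {
  cached(paste0("refpts_", gamma), calibrate_model(model_for(gamma)))
}
f40 <- function() cached("F40", solve_F40(model_for(0.001)))

# one rebuilding scenario (150 stochastic replicates, 350 years)
scenario_for <- function(gamma, F, b = 0.05, n_reps = 150) {
  key <- sprintf("run_%g_%g_%g_%d", gamma, F, b, n_reps)
  cached(key, run_scenario(model_for(gamma), refpts_for(gamma), F = F, b = b,
                           n_reps = n_reps, master_seed = 1))
}

summaries_for <- function(gamma, F, b = 0.05, n_reps = 150) {
  out <- scenario_for(gamma, F, b, n_reps)
  list(ss = steady_state_metrics(out$ssb_Y, out$n_tot_Y, out$n_plus_Y),
       rb = rebuilding_time(out$ssb_Y, out$S0_Y))
}

gsa_result <- function() {
  cached("gsa", run_gsa(n = 300, seed = 7, ntree = 300))
}

# minimal single-entry kernel for hand-evaluated functional-response checks
toy_kernel <- function(a, delta = 0.3, q = 0) {
  structure(list(a = matrix(a, 1, 1), pi = matrix(1, 1, 1), delta = delta,
                 q = q, gamma = NA_real_, sexes = "F", pred_ages = 1L,
                 allocation = "biomass", q_scale = 1),
            class = "predation_kernel")
}
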