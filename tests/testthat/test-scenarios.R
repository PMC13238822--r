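test_that("unfished equilibria obey the per-recruit identities and gamma ordering", {
  m0 <- model_for(0)
  rp0 <- refpts_for(0)
  expect_equal(rp0$S0_L, m0$ling$R0 * m0$phi_L, tolerance = 1e-3)
  expect_equal(rp0$S0_Y, m0$ye$R0 * m0$phi_Y, tolerance = 1e-3)
  # prey unfished biomass shrinks as the predator specializes on it;
  # the predator's is untouched
  s0 <- c(rp0$S0_Y, refpts_for(0.001)$S0_Y, refpts_for(0.014)$S0_Y,
          refpts_for(0.05)$S0_Y)
  expect_true(all(diff(s0) < 0))
  expect_equal(refpts_for(0.05)$S0_L, rp0$S0_L, tolerance = 1e-8)
})

test_that("F40 yields 40% predator depletion, confirmed by forward simulation", {
  m <- model_for(0.001)
  F40 <- f40()
  expect_gt(F40, 0)
  expect_lt(F40, 0.4)
  S0 <- lingcod_equilibrium_ssb(m, 0)
  # closed-form and simulated equilibria agree across the bracket
  for (F in seq(0, 0.4, length.out = 5)) {
    expect_equal(rebuildsim:::sim_lingcod(m, F, 500)$ssb[500],
                 lingcod_equilibrium_ssb(m, F), tolerance = 1e-3)
  }
  grid <- vapply(seq(0, 0.4, length.out = 9),
                 function(F) lingcod_equilibrium_ssb(m, F), numeric(1))
  expect_true(all(diff(grid) < 0))
  sim_depl <- rebuildsim:::sim_lingcod(m, F40, 500)$ssb[500] / S0
  expect_equal(sim_depl, 0.400, tolerance = 0.001 / 0.4)
})

test_that("historical rates hit the 22% depletion target for both species", {
  for (g in c(0, 0.05)) {
    rp <- refpts_for(g)
    expect_equal(rp$depletion_L, 0.22, tolerance = 0.005 / 0.22)
    expect_equal(rp$depletion_Y, 0.22, tolerance = 0.005 / 0.22)
  }
  # stronger depletion targets need harder fishing
  m <- model_for(0)
  rp <- refpts_for(0)
  h30 <- solve_historical_F(m, rp$S0_L, rp$S0_Y, target = 0.3)
  expect_lt(h30$F_hist_L, rp$F_hist_L)
  expect_lt(h30$F_hist_Y, rp$F_hist_Y)
})

test_that("prey historical rate responds to the specialization scenario", {
  expect_false(isTRUE(all.equal(refpts_for(0)$F_hist_Y,
                                refpts_for(0.05)$F_hist_Y)))
})

test_that("the replicate seed scheme is deterministic, bounded, and mixing", {
  s1 <- scenario_seed(1, 0.05, 0.12, 0.05, 7)
  expect_identical(s1, scenario_seed(1, 0.05, 0.12, 0.05, 7))
  expect_true(s1 >= 1 && s1 <= 2^31 - 1)
  seeds <- vapply(1:200, function(r) scenario_seed(1, 0.05, 0.12, 0.05, r),
                  integer(1))
  expect_equal(length(unique(seeds)), 200)
  expect_false(scenario_seed(1, 0.001, 0.12, 0.05, 7) == s1)
})

test_that("scenario runs are reproducible and bycatch vanishes at F = 0", {
  m <- model_for(0)
  rp <- refpts_for(0)
  a <- run_scenario(m, rp, F = 0, b = 0.05, n_reps = 3, rebuild_years = 40,
                    master_seed = 5)
  b_ <- run_scenario(m, rp, F = 0, b = 0.05, n_reps = 3, rebuild_years = 40,
                     master_seed = 5)
  expect_identical(a$ssb_Y, b_$ssb_Y)
  expect_equal(dim(a$ssb_Y), c(3, 40))
  # with F = 0 the bycatch rate b * F is exactly zero: under a common seed
  # stream the prey trajectory is invariant to b
  s_lo <- simulate_population(m, init = rp$burn_state, n_years = 40, F = 0,
                              b = 0.05, stochastic = TRUE, seed = 11)
  s_hi <- simulate_population(m, init = rp$burn_state, n_years = 40, F = 0,
                              b = 0.9, stochastic = TRUE, seed = 11)
  expect_identical(s_lo$ssb_Y, s_hi$ssb_Y)
})

test_that("replicate streams are effectively independent", {
  out <- scenario_for(0.001, 0)
  rep_means <- rowMeans(out$ssb_Y)
  n <- length(rep_means)
  lag1 <- stats::cor(rep_means[-1], rep_means[-n])
  expect_lt(abs(lag1), 3 / sqrt(n))
})

test_that("a small scenario grid is bookkept completely", {
  grid <- run_scenario_grid(default_params(), gamma_set = 0,
                            F_set = c(0, 0.1), b_set = 0.05, n_reps = 3,
                            rebuild_years = 160, master_seed = 2,
                            window = 150)
  expect_equal(nrow(grid), 2)
  expect_true(all(is.finite(grid$mean_ssb)))
  expect_true(all(grid$rebuild_censored == 0))
  grid2 <- run_scenario_grid(default_params(), gamma_set = 0,
                             F_set = c(0, 0.1), b_set = 0.05, n_reps = 3,
                             rebuild_years = 160, master_seed = 2,
                             window = 150)
  expect_identical(grid, grid2)
})
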