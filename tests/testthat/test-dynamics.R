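test_that("AR(1) recruitment deviations have the stated stationary moments", {
  expect_identical(ar1_deviates(0.5, 0, 100), numeric(100))
  set.seed(1)
  iid <- ar1_deviates(0, 0.5, 2e4)
  expect_lt(abs(stats::cor(iid[-1], iid[-length(iid)])), 3 / sqrt(2e4))
  eps <- ar1_deviates(0.23, 0.5, 1e5, seed = 4)
  expect_equal(stats::var(eps), 0.25, tolerance = 3 * sqrt(2 / 1e5))
  expect_equal(stats::cor(eps[-1], eps[-1e5]), 0.23,
               tolerance = 3 / sqrt(1e5))
  expect_error(ar1_deviates(1, 0.5, 10), "rho")
  expect_identical(ar1_deviates(0.23, 0.5, 50, seed = 9),
                   ar1_deviates(0.23, 0.5, 50, seed = 9))
})

test_that("recruitment pulse honors the stock-recruit curve and bias correction", {
  expect_equal(recruitment_pulse(0, 16, 0.01), 0)
  # mean-one lognormal multiplier
  set.seed(2)
  sigma <- 0.5
  eps <- stats::rnorm(1e6, 0, sigma)
  mult <- exp(eps - 0.5 * sigma^2)
  se <- stats::sd(mult) / sqrt(1e6)
  expect_equal(mean(mult), 1, tolerance = 3 * se)
  # deterministic recruitment at S0 returns exactly R0, halved per sex
  m <- model_for(0)
  S0_Y <- m$ye$R0 * m$phi_Y
  expect_equal(recruitment_pulse(S0_Y, m$bh_Y$alpha, m$bh_Y$beta),
               m$ye$R0, tolerance = 1e-10)
  S0_L <- m$ling$R0 * m$phi_L
  rl <- recruitment_pulse(S0_L, m$bh_L$alpha, m$bh_L$beta,
                          sex_structured = TRUE)
  expect_equal(unname(rl), rep(0.5 * m$ling$R0, 2), tolerance = 1e-10)
})

test_that("aging pulse conserves numbers and routes cohorts into the plus group", {
  n <- c(10, 20, 30, 40, 50)
  out <- age_advance(n, 0)
  expect_equal(sum(out), sum(n))
  expect_equal(out, c(0, 10, 20, 30, 90))
  # all fish already in the plus group stay there
  solo <- c(0, 0, 0, 0, 7)
  expect_equal(age_advance(solo, 0), solo)
  # a pulse of recruits reaches the plus group after exactly A - 1 pulses
  A <- 65
  x <- numeric(A)
  x <- age_advance(x, 100)
  for (k in seq_len(A - 2)) {
    x <- age_advance(x, 0)
    expect_equal(x[A], 0)
  }
  x <- age_advance(x, 0)
  expect_equal(x[A], 100)
  # sex-structured form
  mat <- cbind(F = c(1, 2, 3), M = c(4, 5, 6))
  adv <- age_advance(mat, c(F = 10, M = 20))
  expect_equal(adv[, "F"], c(10, 1, 5), ignore_attr = TRUE)
  expect_equal(adv[, "M"], c(20, 4, 11), ignore_attr = TRUE)
  expect_error(age_advance(n, -1), ">= 0")
})

test_that("spawning biomass sums mature (female) biomass linearly", {
  sched <- data.frame(age = 1:3, sex = "A", length = 1, weight = 2,
                      maturity = c(0, 1, 1), vuln = 0)
  expect_equal(spawning_biomass(c(5, 0, 0), sched), 0)
  expect_equal(spawning_biomass(c(0, 10, 0), sched), 20)
  expect_equal(spawning_biomass(2 * c(1, 2, 3), sched),
               2 * spawning_biomass(c(1, 2, 3), sched))
})

test_that("within-year decay matches the exact exponentials without predation", {
  m <- model_for(0)
  state <- list(Y = unfished_sad(m$ye), L = unfished_sad(m$ling))
  out <- within_year_step(state, F = 0, b = 0.05, kernel = m$kernel,
                          model = m)
  expect_equal(out$Y / state$Y, rep(exp(-0.044), 65), tolerance = 1e-12)
  expect_equal(out$L[, "F"] / state$L[, "F"], rep(exp(-0.18), 20),
               tolerance = 1e-12)
  expect_equal(out$L[, "M"] / state$L[, "M"], rep(exp(-0.32), 20),
               tolerance = 1e-12)
  # fishing adds nu * F to vulnerable lingcod ages only
  outF <- within_year_step(state, F = 0.2, b = 0, kernel = NULL, model = m)
  expect_equal(outF$L[, "F"] / state$L[, "F"],
               exp(-(0.18 + m$vuln_L[, "F"] * 0.2)), ignore_attr = TRUE)
})

test_that("compiled RHS agrees with the pure-R functional response", {
  m <- model_for(0.05)
  set.seed(5)
  Y0 <- unfished_sad(m$ye) * stats::runif(65, 0.3, 1.5)
  L0 <- unfished_sad(m$ling) * 0.8
  state <- list(Y = Y0, L = L0)
  stepped <- within_year_step(state, F = 0.1, b = 0.05, kernel = m$kernel,
                              model = m, rtol = 1e-10, atol = 1e-12)
  ZL <- m$ZL_base + m$vuln_L * 0.1
  ctx <- list(L0 = c(L0[, "F"], L0[, "M"]), ZL = c(ZL[, "F"], ZL[, "M"]),
              zy = m$ye$M + m$vuln_Y * 0.05 * 0.1, kernel = m$kernel)
  ref <- deSolve::lsoda(Y0, c(0, 1), rebuildsim:::ye_rhs_r, ctx,
                        rtol = 1e-10, atol = 1e-12)[2, -1]
  expect_equal(stepped$Y, unname(ref), tolerance = 1e-7)
})

test_that("the decoupled deterministic system settles on its unfished equilibria", {
  m <- model_for(0)
  sim <- simulate_population(m, n_years = 500, F = 0)
  S0_L <- m$ling$R0 * m$phi_L
  S0_Y <- m$ye$R0 * m$phi_Y
  last50_L <- sim$ssb_L[451:500]
  expect_lt(max(abs(diff(last50_L))), 1e-6 * S0_L)
  expect_equal(sim$ssb_L[500], S0_L, tolerance = 1e-3)
  expect_equal(sim$ssb_Y[500], S0_Y, tolerance = 1e-3)
  expect_true(all(is.finite(sim$ssb_Y)) && all(sim$ssb_Y >= 0))
})

test_that("deterministic fished predator equilibrium matches the per-recruit closed form", {
  m <- model_for(0)
  for (F in c(0.05, 0.125, 0.3)) {
    sim <- rebuildsim:::sim_lingcod(m, F, 500)
    expect_equal(sim$ssb[500], lingcod_equilibrium_ssb(m, F),
                 tolerance = 1e-3)
  }
})

test_that("prey trajectories without predation are invariant to predator shocks", {
  p <- default_params()
  m <- model_for(0)
  p2 <- p
  p2$lingcod$R0 <- 2 * p$lingcod$R0
  p2$lingcod$sigma <- 0.9
  m2 <- build_model(p2, gamma = 0)
  s1 <- simulate_population(m, n_years = 60, F = 0.2, b = 0.05)
  s2 <- simulate_population(m2, n_years = 60, F = 0.2, b = 0.05)
  expect_equal(s1$ssb_Y, s2$ssb_Y, tolerance = 1e-12)
})

test_that("simulation output is reproducible under a fixed seed", {
  m <- model_for(0.05)
  s1 <- simulate_population(m, n_years = 40, F = 0.1, b = 0.05,
                            stochastic = TRUE, seed = 123)
  s2 <- simulate_population(m, n_years = 40, F = 0.1, b = 0.05,
                            stochastic = TRUE, seed = 123)
  expect_identical(s1$ssb_Y, s2$ssb_Y)
  expect_identical(s1$eps_L, s2$eps_L)
  expect_true(all(is.finite(s1$ssb_Y)) && all(s1$ssb_Y >= 0))
})
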