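test_that("size-preference window is a hard, inclusive ratio band", {
  expect_equal(size_preference(29, 100, 0.05, 0.29), 1)
  expect_equal(size_preference(5, 100, 0.05, 0.29), 1)
  expect_equal(size_preference(30, 100, 0.05, 0.29), 0)
  expect_equal(size_preference(4.9, 100, 0.05, 0.29), 0)
  expect_error(size_preference(10, 100, 0.3, 0.29), "Y5")
})

test_that("consumption allometry reproduces the unit-weight intercepts", {
  expect_equal(annual_consumption(1, 3.01, 0.77), 3.01)
  expect_equal(annual_consumption(1, 3.31, 0.71), 3.31)
  expect_equal(annual_consumption(2, 3.31, 0.71),
               annual_consumption(1, 3.31, 0.71) * 2^0.71)
  expect_error(annual_consumption(0, 3.01, 0.77), "> 0")
})

test_that("kernel construction honors the specialization structure", {
  p <- default_params()
  sl <- build_schedules(p$lingcod)
  sy <- build_schedules(p$yelloweye)
  ref <- unfished_sad(p$yelloweye)

  k0 <- build_kernel(sl, sy, gamma = 0, delta = 0.3, ref, p$lingcod)
  expect_true(all(k0$a == 0))
  expect_equal(k0$q, 0)

  k1 <- build_kernel(sl, sy, gamma = 0.001, delta = 0.3, ref, p$lingcod)
  k50 <- build_kernel(sl, sy, gamma = 0.05, delta = 0.3, ref, p$lingcod)
  expect_true(all(k1$a >= 0))
  expect_true(all(k1$a[k1$pi == 0] == 0))
  # attack rates scale linearly with gamma in the small-p limit
  small <- k50$a > 0 & k50$a < 0.02
  expect_true(any(small))
  expect_equal(k50$a[small] / k1$a[small], rep(50, sum(small)),
               tolerance = 0.01)
  # gape limitation: the largest prey ages escape predation entirely
  gape_free <- sy$length > p$lingcod$Y95 * max(p$lingcod$Linf)
  expect_true(any(gape_free))
  expect_true(all(rowSums(k50$a)[gape_free] == 0))
  expect_true(any(rowSums(k50$a)[!gape_free] > 0))
  # demand exceeding reference prey biomass is an error
  expect_error(build_kernel(sl, sy, gamma = 0.9, delta = 0.3, ref,
                            p$lingcod), "smaller")
})

test_that("realized first-year intake equals the diet-share demand when handling is free", {
  # two prey ages, one predator (a single female; male class empty): with
  # delta = 0 and no other mortality, integrating one year must consume
  # exactly gamma * C of prey biomass -- the -log(1 - p) conversion undoes
  # within-year prey depletion.
  p <- default_params()
  ling_sched <- data.frame(age = c(1, 1), sex = c("F", "M"),
                           length = 100, weight = 2,
                           maturity = 1, vuln = 0)
  prey_sched <- data.frame(age = 1:2, sex = "A", length = c(10, 20),
                           weight = c(0.01, 0.08), maturity = 0, vuln = 0)
  ref <- c(500, 400)
  gamma <- 0.05
  k <- build_kernel(ling_sched, prey_sched, gamma = gamma, delta = 0,
                    ref_state = ref, ling_params = p$lingcod)
  demand <- gamma * annual_consumption(2, p$lingcod$a_c[["F"]],
                                       p$lingcod$b_c[["F"]])
  L <- c(1, 0)  # one female predator, no males
  traj <- deSolve::lsoda(
    y = ref, times = c(0, 1),
    func = function(t, Y, parms) list(-predation_mortality(Y, L, k) * Y),
    parms = NULL, rtol = 1e-10, atol = 1e-12
  )
  consumed <- sum((ref - traj[2, -1]) * prey_sched$weight)
  expect_equal(consumed, demand, tolerance = 0.01)
})

test_that("type-II predation mortality matches hand evaluation and its monotonicities", {
  # 1 predator, 1 prey age: a = 2, delta = 0.3, q = 0, Y = L = 1
  expect_equal(predation_mortality(1, 1, toy_kernel(2)), 2 / 1.6)
  # mass action when handling time vanishes
  expect_equal(predation_mortality(1, 3, toy_kernel(2, delta = 0)), 6)
  # saturation: per-predator intake approaches 1/delta as prey grows
  Y_big <- 1e8
  intake <- predation_mortality(Y_big, 1, toy_kernel(2)) * Y_big
  expect_equal(intake, 1 / 0.3, tolerance = 1e-6)
  # non-increasing in q and delta, non-decreasing in predator abundance
  r_q <- vapply(c(0, 1, 5, 50),
                function(q) predation_mortality(1, 1, toy_kernel(2, q = q)),
                numeric(1))
  expect_true(all(diff(r_q) < 0))
  r_d <- vapply(c(0, 0.1, 0.3, 1),
                function(d) predation_mortality(1, 1, toy_kernel(2, delta = d)),
                numeric(1))
  expect_true(all(diff(r_d) < 0))
  r_L <- vapply(c(0, 1, 2, 4),
                function(L) predation_mortality(1, L, toy_kernel(2)),
                numeric(1))
  expect_true(all(diff(r_L) > 0))
  expect_error(predation_mortality(-1, 1, toy_kernel(2)), ">= 0")
})

test_that("alternate-prey calibration pins mean reference predation at baseline M", {
  p <- default_params()
  k_cal <- calibrate_q_scale(p)
  expect_gt(k_cal, 1)
  sl <- build_schedules(p$lingcod)
  sy <- build_schedules(p$yelloweye)
  ref_Y <- unfished_sad(p$yelloweye)
  ref_L <- unfished_sad(p$lingcod)
  ker <- build_kernel(sl, sy, gamma = 0.05, delta = p$lingcod$delta, ref_Y,
                      p$lingcod, q_scale = k_cal)
  r <- predation_mortality(ref_Y, ref_L, ker)
  on <- r > 0
  expect_equal(sum(r[on] * ref_Y[on]) / sum(ref_Y[on]), p$yelloweye$M,
               tolerance = 1e-6)
})

test_that("kernel exports as a tidy long table", {
  m <- model_for(0.05)
  tab <- kernel_as_table(m$kernel)
  expect_equal(nrow(tab), 65 * 40)
  expect_equal(sort(unique(tab$pred_sex)), c("F", "M"))
  expect_equal(sum(tab$a > 0), sum(m$kernel$a > 0))
})
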