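# shared runs (reused across blocks to keep the suite fast)
traj_bomb <- simulate_scenario(defaults, bomb_short(horizon = 120),
                               init = "analytic")
traj_sus <- simulate_scenario(defaults, sustained_short(horizon = 600),
                              init = "analytic")

test_that("burn-in reaches the analytic no-hydrolysis steady state", {
  y <- burn_in(defaults, 3000)
  ref <- analytic_baseline(defaults)
  expect_equal(y[["iaa"]], ref$iaa, tolerance = 1e-3)
  expect_identical(y[["ian"]], 0)     # nothing produces IAN at alpha = 0
  expect_identical(y[["ant"]], 0)
  expect_equal(y[["tir1_iaa"]], ref$tir1_iaa, tolerance = 1e-3)

  p0 <- defaults
  p0$theta <- 0
  y0 <- burn_in(p0, 3000)
  expect_true(all(abs(y0) < 1e-12))

  # a decay rate too slow for the burn-in window is a convergence error
  pslow <- defaults
  pslow$tau_iaa <- 1e-5
  expect_error(burn_in(pslow, 100), "converge")
})

test_that("pulse kinetics follow the closed-form production/decay solution", {
  # during the 1-min pulse from baseline (ian = ant = 0), sequestration by
  # the ~1e-5 uM receptor pool is negligible, so
  # ant(t) = P/tau * (1 - exp(-tau t)) with P = (1-beta) * F_MYR
  flux <- mm_rate(defaults$myr, defaults$i3g)
  pulse <- traj_bomb[traj_bomb$time > 0 & traj_bomb$time <= 1, ]
  ant_oracle <- (1 - 0.8) * flux / 0.125 * (1 - exp(-0.125 * pulse$time))
  ian_oracle <- 0.8 * flux / 0.1 * (1 - exp(-0.1 * pulse$time))
  expect_equal(pulse$ant, ant_oracle, tolerance = 1e-3)
  expect_equal(pulse$ian, ian_oracle, tolerance = 1e-3)
  # spot value at the end of the pulse (~0.2460 uM antagonist)
  a1 <- traj_bomb$ant[traj_bomb$time == 1]
  expect_equal(a1, 0.2 * flux * (1 - exp(-0.125)) / 0.125, tolerance = 1e-3)
  # after the pulse the antagonist decays exponentially with tau_ant
  relax <- traj_bomb[traj_bomb$time >= 1 & traj_bomb$time <= 40, ]
  expect_equal(relax$ant, a1 * exp(-0.125 * (relax$time - 1)),
               tolerance = 1e-3)
})

test_that("sustained hydrolysis balances production against decay", {
  flux <- mm_rate(defaults$myr, defaults$i3g)
  ant_inf <- 0.2 * flux / 0.125   # ~2.0934 uM
  ian_inf <- 0.8 * flux / 0.1     # ~10.467 uM
  last <- traj_sus[nrow(traj_sus), ]
  expect_equal(last$ant, ant_inf, tolerance = 1e-3)
  expect_equal(last$ian, ian_inf, tolerance = 1e-3)
})

test_that("beta = 1 routes everything to the nitrile branch", {
  p <- defaults
  p$beta <- 1
  tr <- simulate_scenario(p, bomb_short(horizon = 30), init = "analytic")
  expect_true(all(tr$ant == 0))
  expect_true(all(tr$tir1_ant == 0))
  expect_gt(max(tr$ian), 0)
})

test_that("receptor conservation and non-negativity hold along trajectories", {
  for (tr in list(traj_bomb, traj_sus,
                  simulate_scenario(scale_parameter(defaults, "myr", 100),
                                    bomb_short(horizon = 60),
                                    init = "analytic"))) {
    total <- tr$tir1_iaa + tr$tir1_ant
    expect_true(all(total <= defaults$tir1_total + 1e-15))
    expect_true(all(as.matrix(tr[, c("ian", "ant", "iaa",
                                     "tir1_iaa", "tir1_ant")]) >= -1e-15))
  }
})

test_that("simulated complexes track the quasi-equilibrium occupancy", {
  # binding relaxes within ~1e-3 min (koff ~ 1.25e3/min), so for t >= 1 min
  # the complexes must sit on the competitive-binding isotherm
  sub <- traj_sus[traj_sus$time >= 1, ]
  occ <- equilibrium_occupancy(sub$iaa, sub$ant, defaults)
  expect_equal(sub$tir1_iaa, occ$tir1_iaa, tolerance = 1e-3)
  expect_equal(sub$tir1_ant, occ$tir1_ant, tolerance = 1e-3)
})

test_that("halving solver tolerances leaves TIR1:IAA unchanged to 0.01%", {
  sc <- bomb_short(horizon = 60, step = 0.5)
  t1 <- simulate_scenario(defaults, sc, init = "analytic")
  t2 <- simulate_scenario(defaults, sc, init = "analytic",
                          rtol = 5e-9, atol = 5e-17)
  rel <- abs(t1$tir1_iaa - t2$tir1_iaa) / t1$tir1_iaa
  expect_lt(max(rel), 1e-4)
})

test_that("refining the output grid leaves interpolated metrics unchanged to 0.1%", {
  m1 <- compute_metrics(simulate_scenario(defaults,
                                          bomb_short(horizon = 60, step = 0.1),
                                          init = "analytic"))
  m2 <- compute_metrics(simulate_scenario(defaults,
                                          bomb_short(horizon = 60, step = 0.02),
                                          init = "analytic"))
  expect_equal(m1$min_value, m2$min_value, tolerance = 1e-3)
  expect_equal(m1$recovery_time, m2$recovery_time, tolerance = 1e-3)
  expect_equal(m1$fold_decrease, m2$fold_decrease, tolerance = 1e-3)
})

test_that("bomb trajectories fall back to the pre-attack steady state by 24 h", {
  tr <- simulate_scenario(defaults, hydrolysis_scenario("bomb", output_step = 1),
                          init = "analytic")
  base <- attr(tr, "baseline")
  last <- tr[nrow(tr), ]
  expect_equal(last$time, 1440)
  expect_equal(last$iaa, base[["iaa"]], tolerance = 0.01)
  expect_equal(last$tir1_iaa, base[["tir1_iaa"]], tolerance = 0.01)
  expect_lt(last$ant, 1e-12)
  expect_lt(last$ian, 1e-12)

  # at 1000x MYR the overshoot decays with tau_IAA: still relaxing at 24 h,
  # monotonically back toward baseline
  tr2 <- simulate_scenario(scale_parameter(defaults, "myr", 1000),
                           hydrolysis_scenario("bomb", output_step = 1),
                           init = "analytic")
  late <- tr2$tir1_iaa[tr2$time >= 200]
  expect_true(all(diff(late) < 0))
  expect_lt(abs(tr2$tir1_iaa[nrow(tr2)] / base[["tir1_iaa"]] - 1), 0.05)
})

test_that("sustained trajectories settle: last 10% varies < 0.1% in TIR1:IAA", {
  tr <- simulate_scenario(defaults,
                          hydrolysis_scenario("sustained", output_step = 1),
                          init = "analytic")
  tail10 <- tr$tir1_iaa[tr$time >= 0.9 * 5000]
  expect_lt(diff(range(tail10)) / mean(tail10), 1e-3)
})

test_that("steady_state agrees with the analytic oracles for both switch states", {
  y0 <- steady_state(defaults, alpha = 0)
  ref <- analytic_baseline(defaults)
  expect_equal(y0[["iaa"]], ref$iaa, tolerance = 1e-3)
  expect_equal(y0[["tir1_iaa"]], ref$tir1_iaa, tolerance = 1e-3)

  y1 <- steady_state(defaults, alpha = 1)
  flux <- mm_rate(defaults$myr, defaults$i3g)
  ian_ss <- 0.8 * flux / 0.1
  iaa_ss <- (defaults$theta + mm_rate(defaults$nit, ian_ss)) / defaults$tau_iaa
  expect_equal(y1[["ian"]], ian_ss, tolerance = 1e-6)
  expect_equal(y1[["iaa"]], iaa_ss, tolerance = 1e-6)

  p0 <- defaults
  p0$theta <- 0
  expect_true(all(abs(steady_state(p0, alpha = 0)) < 1e-12))
})

test_that("trajectory bookkeeping: grid, baseline, burn-in reporting", {
  sc <- bomb_short(horizon = 10)
  tr <- simulate_scenario(defaults, sc, init = "analytic")
  expect_true(all(diff(tr$time) > 0))
  expect_equal(tr$time[1], 0)
  expect_true(1 %in% tr$time)  # the alpha switch sits on the grid
  base <- attr(tr, "baseline")
  expect_equal(unname(base[["tir1_iaa"]]), tr$tir1_iaa[1])

  trb <- simulate_scenario(defaults,
                           hydrolysis_scenario("bomb", burn_in = 50,
                                               horizon = 10, output_step = 0.5),
                           keep_burn_in = TRUE)
  expect_equal(min(trb$time), -50)
  expect_true(all(trb$ant[trb$time < 0] == 0))
})
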