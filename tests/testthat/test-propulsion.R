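test_that("BDF2 update matches its closed forms", {
  expect_equal(bdf2_velocity_update(0, 0, 0, m = 1, dt = 0.1), 0)
  expect_error(bdf2_velocity_update(0, 0, 0, m = -1, dt = 0.1), "positive")
  expect_error(bdf2_velocity_update(0, 0, 0, m = 1, dt = 0), "positive")
  # first step falls back to backward Euler
  expect_equal(bdf2_velocity_update(0, NA, 2, m = 1, dt = 0.5), 1)
})

test_that("BDF2 is exact on the linear solution u = F t / m", {
  m <- 0.0026; F <- m          # du/dt = 1, u(t) = t
  dt <- 0.01
  u <- c(0, dt)                # seeded exactly on the solution
  for (n in 2:100) {
    u_new <- bdf2_velocity_update(u[n], u[n - 1], F, m, dt)
    u <- c(u, u_new)
  }
  t_grid <- (0:100) * dt
  expect_equal(u, t_grid, tolerance = 1e-13)
})

test_that("BDF2 converges at 2nd order on sinusoidal forcing", {
  # F = sin(t), m = 1: u(t) = 1 - cos(t)
  err_at <- function(dt) {
    n <- round(1 / dt)
    u_nm1 <- 0
    u_n <- 1 - cos(dt)         # second value seeded from the closed form
    for (k in 2:n) {
      u_np1 <- bdf2_velocity_update(u_n, u_nm1, sin(k * dt), 1, dt)
      u_nm1 <- u_n; u_n <- u_np1
    }
    abs(u_n - (1 - cos(1)))
  }
  errs <- sapply(c(1e-2, 5e-3, 2.5e-3), err_at)
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 3 & ratios < 5))   # ~4x per halving
})

test_that("time to speed interpolates crossings and reports misses", {
  s <- data.frame(t = seq(0, 1, by = 0.1), u_a = seq(0, 1, by = 0.1))
  expect_equal(time_to_speed(s, 0.5)$t0, 0.5)
  miss <- time_to_speed(s, 2)
  expect_false(miss$reached)
  expect_true(is.na(miss$t0))
  expect_equal(miss$u_max, 1)
  # sampled exponential approach: target 1 - exp(-1) crossed at t = 1
  t <- seq(0, 3, by = 0.05)
  se <- data.frame(t = t, u_a = 1 - exp(-t))
  expect_equal(time_to_speed(se, 1 - exp(-1))$t0, 1, tolerance = 1e-3)
  expect_error(time_to_speed(se[0, ], 1), "empty")
})

test_that("caudal cut law: opening shortens the chord and offsets the lobes", {
  cc <- sapply(c(5, 30, 60, 100), function(phi)
    caudal_cut(span = 0.25, root_chord = 0.14, z_cut = 0.1, phi)$chord)
  expect_true(all(diff(cc) < 0))
  off <- sapply(c(5, 100), function(phi)
    caudal_cut(0.25, 0.14, 0.1, phi)$offset)
  expect_lt(off[1], 0.01)
  expect_gt(off[2], 0.1)
  # plane beyond the lobe: chord collapses to zero
  expect_equal(caudal_cut(0.25, 0.14, 0.24, 100)$chord, 0)
})

test_that("zero fin motion from rest stays exactly at rest", {
  cfg <- small_case(n_cycles = 0.2, nx = 64, ny = 32, steps_per_cycle = 25)
  cfg$analogue$fin_height <- 0     # no fin displacement at all
  s <- run_self_propelled(cfg)
  expect_true(all(s$u_a == 0))
  expect_true(all(s$F == 0))
})

test_that("identical configurations give bitwise-identical series", {
  cfg <- small_case(n_cycles = 0.3, nx = 64, ny = 32, steps_per_cycle = 50)
  s1 <- run_self_propelled(cfg)
  s2 <- run_self_propelled(cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("the swimmer accelerates forward from rest", {
  cfg <- small_case(n_cycles = 4, nx = 96, ny = 48, steps_per_cycle = 100)
  s <- run_self_propelled(cfg)
  expect_true(all(is.finite(s$u_a)))
  cyc <- ceiling(s$cycle - 1e-9)
  cyc_mean <- tapply(s$u_a, cyc, mean)
  # forward swimming builds up over the first cycles and stays positive
  expect_gt(cyc_mean[2], cyc_mean[1])
  expect_true(all(cyc_mean > 0))
  expect_gt(s$u_a[nrow(s)], 0)
})

test_that("the Picard loop reduces the force/velocity mismatch", {
  cfg <- small_case(n_cycles = 0.5, nx = 64, ny = 32, steps_per_cycle = 50)
  cfg$timestepping$picard_iters <- 1
  s1 <- run_self_propelled(cfg)
  cfg$timestepping$picard_iters <- 3
  cfg$timestepping$picard_tol <- 0
  s3 <- run_self_propelled(cfg)
  g1 <- mean(attr(s1, "picard_gap")[-(1:5)])
  g3 <- mean(attr(s3, "picard_gap")[-(1:5)])
  expect_lt(g3, g1)
})
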