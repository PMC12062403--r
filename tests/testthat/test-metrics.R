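test_that("average acceleration reproduces the observed worked values", {
  # closed caudal fin at 10 Hz: u_e = 0.73 BL/s reached in 11.4 cycles
  expect_equal(round(average_acceleration(0.73, 11.4 / 10), 2), 0.64)
  # full-open: 14.9 cycles
  expect_equal(round(average_acceleration(0.73, 14.9 / 10), 2), 0.49)
  expect_equal(average_acceleration(0, 3), 0)
  expect_error(average_acceleration(1, 0), "positive")
})

test_that("Reynolds number is the standard u L / nu", {
  expect_equal(reynolds(0, 0.057, 9.5818e-7), 0)
  expect_equal(reynolds(0.1, 0.057, 9.5818e-7), 0.1 * 0.057 / 9.5818e-7)
  expect_equal(reynolds(0.2, 0.057, 9.5818e-7),
               2 * reynolds(0.1, 0.057, 9.5818e-7))
  expect_error(reynolds(1, 1, 0), "positive")
})

test_that("power expenditure integrates force dot velocity", {
  t <- seq(0, 2, by = 0.01)
  n <- length(t)
  # all velocities zero -> no power
  pz <- power_expenditure(matrix(1, n, 3), matrix(0, n, 3), time = t)
  expect_equal(pz$total, 0)
  # single element, constant f_x = 1 N at 1 m/s for 2 s -> 2 J, 1 W
  pc <- power_expenditure(matrix(1, n, 1), matrix(1, n, 1), time = t)
  expect_equal(pc$total, 2)
  expect_equal(pc$average, 1)
  # in-phase sinusoids: window average A*B/2
  A <- 0.3; B <- 1.7
  tt <- seq(0, 2 * pi, length.out = 2001)
  ps <- power_expenditure(matrix(A * sin(tt)), matrix(B * sin(tt)),
                          time = tt)
  expect_equal(ps$average, A * B / 2, tolerance = 1e-5)
  expect_error(power_expenditure(matrix(1, 5, 2), matrix(1, 5, 3),
                                 time = 1:5), "misaligned")
})

test_that("Froude efficiency and cost of transport follow their definitions", {
  expect_equal(froude_efficiency(0, 1, 0.5), 0)
  expect_equal(froude_efficiency(0.2, 0.3, 0.2 * 0.3), 1)
  expect_equal(froude_efficiency(0.01, 0.1, 0.002), 0.5)
  expect_error(froude_efficiency(1, 1, 0), "positive")
  expect_equal(cost_of_transport(1, 1, 1), 1)
  expect_equal(cost_of_transport(0.002, 0.1, 0.0026), 0.002 / (0.1 * 0.0026))
  expect_equal(cost_of_transport(1, 2, 1), cost_of_transport(1, 1, 1) / 2)
  expect_error(cost_of_transport(1, 0, 1), "positive")
})

test_that("drag coefficient conventions differ by exactly U_a", {
  expect_equal(as.numeric(drag_coefficient(1, 2, 1, 1, "standard")), 1)
  expect_equal(as.numeric(drag_coefficient(0, 2, 1, 1, "standard")), 0)
  D <- 0.37; rho <- 1023.6881; U <- 0.73 * 0.057; s <- 2.47e-3
  cd_std <- drag_coefficient(D, rho, U, s, "standard")
  cd_prt <- drag_coefficient(D, rho, U, s, "as_printed")
  expect_equal(as.numeric(cd_prt) / as.numeric(cd_std), U)
  expect_identical(attr(cd_prt, "convention"), "as_printed")
  expect_error(drag_coefficient(1, 1, 0, 1), "mask")
})

test_that("thrust-drag split satisfies the net-force identity exactly", {
  rec <- list(fx = c(2, -0.5))
  sp <- thrust_drag_split(rec, 1)
  expect_equal(sp$T_f, 2); expect_equal(sp$D, 0.5); expect_equal(sp$F, 1.5)
  all_opp <- thrust_drag_split(list(fx = c(-1, -2)), 1)
  expect_equal(all_opp$T_f, 0)
  expect_equal(all_opp$F, -all_opp$D)
  # identity on random records
  set.seed(7)
  for (i in 1:20) {
    fx <- rnorm(50)
    sp <- thrust_drag_split(list(fx = fx), sample(c(-1, 1), 1))
    expect_equal(sp$F, sp$T_f - sp$D, tolerance = 1e-15)
  }
})

test_that("run summary reproduces hand-computed values on a synthetic series", {
  cfg <- gen_paper_case("closed", f = 10, scale = "reduced", n_cycles = 5,
                        nx = 64, ny = 32)
  n <- 500
  t <- seq(0.01, 5, by = 0.01)
  s <- data.frame(t = t, u_a = pmin(0.1 * t, 0.4), F = 0.02,
                  T_f = 0.05, D = 0.03, P_surf = 0.004, cycle = t)
  attr(s, "config") <- cfg
  class(s) <- c("propulsion_series", "data.frame")
  # mask boundary placed between samples so the kept set is unambiguous
  sm <- summarize_run(s, u_e_target = 0.3, window_cycles = 5,
                      mask_start_cycle = 0.095)
  expect_equal(sm$T_f, 0.05); expect_equal(sm$D, 0.03)
  expect_equal(sm$F, 0.02); expect_equal(sm$P_e, 0.004)
  # u_a ramps at 0.1/s to 0.4 at t = 4: trapezoid mean over [0.1, 5]
  u_mean <- (0.5 * (0.01 + 0.4) * 3.9 + 0.4 * 1) / 4.9
  expect_equal(sm$u_a_avg, u_mean, tolerance = 1e-4)
  # alpha * t_0 = u_e identity (u_e_target in BL/s, L = 1)
  expect_equal(sm$alpha * sm$t_0, sm$u_e, tolerance = 1e-12)
  expect_equal(sm$t_0, 3, tolerance = 1e-6)    # 0.1 t = 0.3 at t = 3
  expect_equal(sm$eta, froude_efficiency(0.05, u_mean, 0.004),
               tolerance = 1e-4)
  expect_equal(sm$cot, cost_of_transport(0.004, u_mean, cfg$geometry$mass),
               tolerance = 1e-4)
  # determinism: identical summaries from identical series
  expect_identical(sm, summarize_run(s, u_e_target = 0.3, window_cycles = 5,
                                     mask_start_cycle = 0.095))
})
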