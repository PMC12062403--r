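test_that("ramp coefficient matches its closed forms and is continuous", {
  T <- 0.1
  expect_equal(ramp_coefficient(T, T, "as_printed"), 1.0)
  expect_equal(ramp_coefficient(T, T, "monotone"), 1.0)
  expect_equal(ramp_coefficient(0, T, "as_printed"), 2.0)  # published quartic
  expect_equal(ramp_coefficient(0, T, "monotone"), 0.0)
  # continuity at t = T in both modes
  eps <- 1e-9 * T
  for (mode in c("as_printed", "monotone")) {
    expect_equal(ramp_coefficient(T - eps, T, mode),
                 ramp_coefficient(T + eps, T, mode), tolerance = 1e-12)
  }
  expect_error(ramp_coefficient(0.1, -1, "monotone"), "invalid")
})

test_that("fin angle follows the ramped traveling wave", {
  p <- fin_wave_params(theta_max = 30, lambda = 1, f = 2,
                       ramp_mode = "as_printed")
  # sine zeros wherever x/lambda + f t is an integer
  expect_equal(fin_angle(0.5, t = 0.75, params = p), 0, tolerance = 1e-12)
  # after the ramp, phase 0.25 gives the peak amplitude
  expect_equal(fin_angle(0.25, t = 1, params = p), 30)
  # at t = 0 the printed ramp doubles the excursion
  expect_equal(fin_angle(0.25, t = 0, params = p), 60)
  # monotone ramp starts from rest
  pm <- fin_wave_params(theta_max = 30, lambda = 1, f = 2)
  expect_equal(fin_angle(0.25, t = 0, params = pm), 0)
})

test_that("point deformation is length-preserving with the stated values", {
  d0 <- deform_point(0.3, 0.2, 0)
  expect_equal(d0$y_prime, 0.3)
  expect_equal(d0$z_prime, 0.2)
  expect_equal(d0$dz, 0)
  d90 <- deform_point(0, 1, 90)
  expect_equal(d90$y_prime, 1)
  expect_equal(d90$z_prime, 0, tolerance = 1e-15)
  d30 <- deform_point(0, 1, 30)
  expect_equal(d30$y_prime, 0.5)
  expect_equal(d30$z_prime, 0.86603, tolerance = 1e-5)
  expect_equal(d30$y_prime^2 + d30$z_prime^2, 1, tolerance = 1e-12)
})

test_that("fin-ray length is preserved over 1e5 random samples", {
  set.seed(42)
  n <- 1e5
  y <- runif(n, -1, 1); z <- runif(n, 1e-3, 2); th <- runif(n, -89, 89)
  d <- deform_point(y, z, th)
  err <- abs((d$y_prime - y)^2 + d$z_prime^2 - z^2)
  expect_true(all(err <= 1e-12 * z^2))
})

test_that("fin edge displacement peaks at H sin(theta_max)", {
  p <- fin_wave_params(theta_max = 30, lambda = 1, f = 1)
  expect_equal(fin_edge_displacement(0.5, t = 2, params = p, H = 0.01), 0,
               tolerance = 1e-12)
  expect_equal(fin_edge_displacement(0.25, t = 2, params = p, H = 0.010),
               0.005)
  expect_error(fin_edge_displacement(0, 0, p, H = -1), "positive")
})

test_that("surface deformation is rigid at rest, pinned at the base line, and periodic", {
  g <- build_swimmer_geometry(open_angle = 5, resolution = 2)
  p <- fin_wave_params(theta_max = 30, lambda = 0.03, f = 10)
  d0 <- deform_surface(g, t = 0, params = p)   # monotone ramp: beta(0) = 0
  expect_equal(d0$mesh$vertices, g$vertices)
  expect_true(all(is.finite(d0$velocity)))
  # fin base vertices are unmoved at any time
  dt1 <- deform_surface(g, t = 0.23, params = p)
  base <- which(g$vertex_region == "dorsal_fin" &
                  abs(g$vertices[, 3] - g$fin_base_z) < 1e-12)
  expect_gt(length(base), 0)
  expect_equal(dt1$mesh$vertices[base, ], g$vertices[base, ],
               tolerance = 1e-12)
  # body and caudal vertices are rigid
  rigid <- g$vertex_region %in% c("body", "caudal_fin")
  expect_equal(dt1$mesh$vertices[rigid, ], g$vertices[rigid, ])
  # periodicity after the ramp: t and t + T agree
  T <- p$T
  da <- deform_surface(g, t = 1.3 * T, params = p)
  db <- deform_surface(g, t = 2.3 * T, params = p)
  expect_equal(da$mesh$vertices, db$mesh$vertices, tolerance = 1e-12)
})

test_that("finite-difference surface velocities converge to the chain rule at 2nd order", {
  g <- build_swimmer_geometry(open_angle = 5, resolution = 2)
  p <- fin_wave_params(theta_max = 30, lambda = 0.03, f = 10)
  t <- 0.37                                  # past the ramp
  va <- deform_surface(g, t, p, velocity = "analytic")$velocity
  errs <- sapply(c(1e-3, 5e-4, 2.5e-4) * p$T, function(hh) {
    vf <- deform_surface(g, t, p, velocity = "finite_diff",
                         fd_step = hh)$velocity
    max(abs(vf - va))
  })
  orders <- log(errs[-3] / errs[-1]) / log(2)
  expect_true(all(orders > 1.7 & orders < 2.3))
})
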