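test_that("flow initialisation validates and produces divergence-free fields", {
  expect_error(init_flow(8, 8, 1, 1, nu = 1e-3), "invalid grid")
  expect_error(init_flow(32, 32, 1, 1, nu = -1), "invalid grid")
  st <- init_flow(32, 32, 1, 1, nu = 1e-3)
  expect_true(all(st$u == 0) && all(st$v == 0))
  stu <- init_flow(32, 32, 1, 1, nu = 1e-3, u_in = -0.5, init = "uniform")
  expect_true(all(stu$u == -0.5))
  tg <- init_flow(32, 32, 2 * pi, 2 * pi, nu = 1e-3, bc = "periodic",
                  init = "taylor_green")
  expect_lt(max_divergence(tg), 1e-12)
})

test_that("uniform flow is an exact steady solution", {
  st <- init_flow(32, 32, 1, 1, nu = 1e-3, u_in = -0.4, init = "uniform")
  for (i in 1:10) st <- flow_step(st, NULL, dt = 0.005)
  expect_lt(max(abs(st$u - (-0.4))), 1e-10)
  expect_lt(max(abs(st$v)), 1e-10)
})

test_that("Taylor-Green kinetic energy decays at the analytic rate", {
  nu <- 0.02
  st <- init_flow(64, 64, 2 * pi, 2 * pi, nu = nu, bc = "periodic",
                  init = "taylor_green")
  e0 <- kinetic_energy(st)
  dt <- 0.2 * st$h
  nstep <- ceiling(2 * pi / dt); dt <- 2 * pi / nstep
  divs <- numeric(nstep)
  for (i in seq_len(nstep)) {
    st <- flow_step(st, NULL, dt)
    divs[i] <- st$last$max_div
  }
  ratio <- kinetic_energy(st) / e0
  expect_equal(ratio, exp(-4 * nu * st$t), tolerance = 0.02)
  # post-projection divergence bounded at every step
  umax <- max(abs(st$u), abs(st$v))
  expect_true(all(divs <= 1e-8 * (1 + umax) / st$h))
})

test_that("Taylor-Green error decreases at close to 2nd order", {
  errs <- sapply(c(32, 64, 128), function(n) {
    st <- init_flow(n, n, 2 * pi, 2 * pi, nu = 0.02, bc = "periodic",
                    init = "taylor_green")
    e0 <- kinetic_energy(st)
    dt0 <- 0.2 * st$h
    ns <- ceiling(pi / dt0); dt <- pi / ns
    for (i in seq_len(ns)) st <- flow_step(st, NULL, dt)
    abs(kinetic_energy(st) / e0 / exp(-4 * 0.02 * st$t) - 1)
  })
  orders <- log(errs[-3] / errs[-1]) / log(2)
  expect_true(all(orders > 1.5))
})

test_that("time step limits are enforced with informative errors", {
  st <- init_flow(32, 32, 1, 1, nu = 1e-3, u_in = -1, init = "uniform")
  expect_error(flow_step(st, NULL, dt = 1), "CFL violation")
  st2 <- init_flow(32, 32, 1, 1, nu = 0.5)
  expect_error(flow_step(st2, NULL, dt = 0.01), "diffusive stability")
})

test_that("vorticity and Q-criterion match closed forms", {
  # rigid-body rotation at rate w0: vorticity 2 w0, Q = w0^2 > 0
  w0 <- 0.7
  st <- init_flow(32, 32, 1, 1, nu = 1e-3)
  xc <- 0.5; yc <- 0.5; h <- st$h
  xu <- (0:st$nx) * h; yu <- ((1:st$ny) - 0.5) * h
  xv <- ((1:st$nx) - 0.5) * h; yv <- (0:st$ny) * h
  st$u <- -w0 * outer(rep(1, st$nx + 1), yu - yc)
  st$v <- w0 * outer(xv - xc, rep(1, st$ny + 1))
  om <- vorticity(st); qc <- q_criterion(st)
  inner <- 5:28
  expect_equal(max(abs(om[inner, inner] - 2 * w0)), 0, tolerance = 1e-12)
  expect_equal(max(abs(qc[inner, inner] - w0^2)), 0, tolerance = 1e-10)
  # pure planar strain: vorticity 0, Q = -a^2 < 0
  a <- 1.3
  st$u <- a * outer(xu, rep(1, st$ny))
  st$v <- -a * outer(rep(1, st$nx), yv)
  om <- vorticity(st); qc <- q_criterion(st)
  expect_equal(max(abs(om[inner, inner])), 0, tolerance = 1e-12)
  expect_equal(max(abs(qc[inner, inner] + a^2)), 0, tolerance = 1e-10)
})

test_that("Q-criterion on Taylor-Green matches the analytic gradients", {
  st <- init_flow(64, 64, 2 * pi, 2 * pi, nu = 0.01, bc = "periodic",
                  init = "taylor_green")
  qc <- q_criterion(st)
  h <- st$h
  xc <- ((1:st$nx) - 0.5) * h; yc <- ((1:st$ny) - 0.5) * h
  # u = cos x sin y, v = -sin x cos y: S12 = 0, Q = (dudy^2 cancel) ...
  dudx <- outer(-sin(xc), sin(yc))
  dudy <- outer(cos(xc), cos(yc))
  dvdx <- outer(-cos(xc), cos(yc))
  dvdy <- outer(sin(xc), sin(yc))
  s12 <- (dudy + dvdx) / 2; o12 <- (dudy - dvdx) / 2
  q_exact <- (2 * o12^2 - (dudx^2 + dvdy^2 + 2 * s12^2)) / 2
  inner <- 5:60
  expect_equal(qc[inner, inner], q_exact[inner, inner], tolerance = 0.01)
})

test_that("no-slip is enforced at markers and forces are consistent", {
  # static plate in a uniform stream
  st <- init_flow(64, 32, 2, 1, nu = 2e-3, u_in = -0.5, init = "uniform")
  xs <- seq(0.9, 1.1, by = 0.5 * st$h)
  bd <- immersed_boundary(xs, rep(0.5, length(xs)), 0, 0, ds = 0.5 * st$h,
                          h = st$h)
  dt <- 0.4 * st$h / 0.6
  for (i in 1:60) st <- flow_step(st, bd, dt, n_forcing = 4)
  fr <- surface_forces(st, bd)
  # additivity: net force equals the per-element sum exactly
  expect_equal(fr$F, sum(fr$fx), tolerance = 1e-12)
  # a plate aligned with the stream at rest feels drag (force toward -x
  # on the body, i.e. along the stream direction)
  expect_lt(fr$F, 0)
  # no-slip: kernel-interpolated fluid velocity at the interior markers is a
  # small fraction of the free-stream speed, and the forcing loop tightens it
  slip <- boundary_slip(st, bd)
  inner <- 3:(nrow(bd) - 2)
  expect_lt(max(abs(slip$du[inner]), abs(slip$dv[inner])), 0.04 * 0.5)
  st1 <- init_flow(64, 32, 2, 1, nu = 2e-3, u_in = -0.5, init = "uniform")
  for (i in 1:60) st1 <- flow_step(st1, bd, dt, n_forcing = 1)
  slip1 <- boundary_slip(st1, bd)
  expect_lt(mean(abs(slip$du)), mean(abs(slip1$du)))
})

test_that("symmetric boundary at rest in quiescent fluid feels no force", {
  st <- init_flow(32, 32, 1, 1, nu = 1e-3)
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  bd <- immersed_boundary(0.5 + 0.15 * cos(th), 0.5 + 0.15 * sin(th), 0, 0,
                          ds = 2 * pi * 0.15 / 39)
  st <- flow_step(st, bd, dt = 0.01)
  fr <- surface_forces(st, bd)
  expect_equal(fr$F, 0, tolerance = 1e-12)
})

test_that("momentum budget closes on a periodic forced case", {
  st <- init_flow(64, 64, 2 * pi, 2 * pi, nu = 0.01, bc = "periodic",
                  init = "taylor_green")
  xs <- seq(2.5, 3.5, by = 0.5 * st$h)
  dt <- 0.2 * st$h
  for (i in 1:5) {
    bd <- immersed_boundary(xs, rep(pi, length(xs)),
                            uvel = 0.3, vvel = 0, ds = 0.5 * st$h)
    old <- st
    st <- flow_step(st, bd, dt, n_forcing = 1)
    mb <- momentum_budget(old, st, sum(st$last$fx), dt)
    # relative closure within 1% of the impulse scale
    scale <- max(abs(mb$impulse_x), 1e-12)
    expect_lt(abs(mb$d_momentum_x - mb$impulse_x) / scale, 0.01)
  }
})

test_that("towed cylinder at Re 40 gives the classical steady drag", {
  D <- 0.25; U <- 0.5; Re <- 40
  nu <- U * D / Re
  st <- init_flow(192, 96, 6, 3, nu = nu, u_in = -U, init = "uniform")
  nmark <- 48
  th <- seq(0, 2 * pi, length.out = nmark + 1)[-(nmark + 1)]
  bd <- immersed_boundary(4 + D / 2 * cos(th), 1.5 + D / 2 * sin(th), 0, 0,
                          ds = pi * D / nmark, h = st$h)
  dt <- 0.8 * 0.5 * st$h / (1.6 * U)
  drag <- c()
  nstep <- ceiling(60 * D / U / dt)
  for (i in seq_len(nstep)) {
    st <- flow_step(st, bd, dt, n_forcing = 2)
    if (i > 0.7 * nstep)
      drag <- c(drag, -sum(st$last$fx) * st$rho)
  }
  cd <- mean(drag) / (0.5 * st$rho * U^2 * D)
  expect_gt(cd, 1.2)
  expect_lt(cd, 1.9)
})
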