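#' Second-order backward-difference velocity update
#'
#' Discretises `m du/dt = F` with the BDF2 scheme
#' `(3 u^{n+1} - 4 u^n + u^{n-1}) / (2 dt) = F^{n+1} / m`, i.e.
#' `u^{n+1} = (4 u^n - u^{n-1} + 2 dt F^{n+1} / m) / 3`. The scheme is exact
#' for linear-in-time solutions and second-order accurate otherwise. The very
#' first step, where `u^{n-1}` is undefined, uses backward Euler
#' `u^1 = u^0 + dt F^1 / m`.
#'
#' @param u_n Velocity at step n, m/s.
#' @param u_nm1 Velocity at step n-1, m/s, or `NULL`/`NA` on the first step.
#' @param F_np1 Force at step n+1, N.
#' @param m Mass, kg (> 0).
#' @param dt Time step, s (> 0).
#' @return `u^{n+1}` in m/s.
#' @examples
#' bdf2_velocity_update(0, 0, 0, m = 0.0026, dt = 1e-3)  # rest stays at rest
#' @export
bdf2_velocity_update <- function(u_n, u_nm1, F_np1, m, dt) {
  if (m <= 0) stop("'m' must be positive")
  if (dt <= 0) stop("'dt' must be positive")
  if (is.null(u_nm1) || is.na(u_nm1))
    return(u_n + dt * F_np1 / m)
  (4 * u_n - u_nm1 + 2 * dt * F_np1 / m) / 3
}

#' Build the 2-D immersed-boundary outline of the swimmer
#'
#' Lays out the swimmer's cut-plane analogue as marker chains in the solver
#' domain (head toward +x, tail toward -x, so the fish swims in +x while its
#' wake convects out through the -x outflow face): a rigid centreline from
#' head to peduncle carrying the undulating-fin lateral displacement over the
#' fin span, and the caudal-fin cut — one slender chord when closed, two
#' laterally offset chords when the lobes are folded open.
#'
#' @param config A run configuration from [gen_paper_case()].
#' @param t Time, s.
#' @param h Grid spacing, m (markers are spaced at `0.5 h` in x).
#' @return A list: `boundary` (an [immersed_boundary()]) plus the static
#'   layout (`x_head`, caudal chord/offset).
#' @export
swimmer_boundary_2d <- function(config, t, h) {
  geo <- config$geometry; an <- config$analogue
  L <- geo$length
  wave <- fin_wave_params(theta_max = config$wave$theta_max,
                          lambda = config$wave$lambda, f = config$wave$f,
                          ramp_mode = config$wave$ramp_mode)
  x_head <- an$x_head
  y_mid <- an$y_mid
  dsx <- 0.5 * h
  # centreline: body coordinate xi from head (0) to peduncle
  x_ped <- an$x_peduncle
  xi <- seq(0, x_ped, by = dsx)
  span <- an$fin_span
  env <- .span_envelope(xi, span, 0.08 * L)
  th <- fin_angle(xi - span[1], t, wave, direction = -1)
  disp <- env * an$fin_height * sin(th * pi / 180)
  vel <- env * fin_edge_velocity(xi - span[1], t, wave, an$fin_height,
                                 direction = -1)
  bx <- x_head - xi
  by <- y_mid + disp
  breg <- ifelse(xi >= span[1] & xi <= span[2], "dorsal_fin", "body")
  bu <- rep(0, length(xi)); bv <- vel
  # caudal cut: chord(s) from the folded-lobe law
  cd <- caudal_cut(an$caudal_span, an$caudal_root_chord, an$z_cut,
                   geo$open_angle)
  if (cd$chord > 0) {
    xc <- seq(x_ped, x_ped + cd$chord, by = dsx)
    offs <- if (cd$offset < 0.5 * h) 0 else c(-cd$offset, cd$offset)
    for (o in offs) {
      bx <- c(bx, x_head - xc)
      by <- c(by, rep(y_mid + o, length(xc)))
      bu <- c(bu, rep(0, length(xc)))
      bv <- c(bv, rep(0, length(xc)))
      breg <- c(breg, rep("caudal_fin", length(xc)))
    }
  }
  list(boundary = immersed_boundary(bx, by, bu, bv, ds = dsx,
                                    region = breg),
       x_head = x_head, caudal = cd)
}

#' In-plane caudal-fin cut from the folded-lobe law
#'
#' At cut height `z_cut` a lobe folded by `phi/2` from the vertical is sampled
#' a distance `s = z_cut / cos(phi/2)` from the peduncle axis; the rounded
#' lobe outline gives chord `c0 * sqrt(1 - (s/R)^2)` (floored at 15% of the
#' root chord until the plane leaves the lobe entirely) at lateral offset
#' `z_cut * tan(phi/2)`.
#'
#' @param span Lobe half-span R, m.
#' @param root_chord Root chord c0, m.
#' @param z_cut Cut height, m.
#' @param open_angle Opening angle phi, degrees.
#' @return List with `chord` (0 when the plane misses the lobe) and `offset`.
#' @export
caudal_cut <- function(span, root_chord, z_cut, open_angle) {
  phi2 <- open_angle / 2 * pi / 180
  s <- z_cut / cos(phi2)
  if (s > span) return(list(chord = 0, offset = z_cut * tan(phi2)))
  chord <- root_chord * sqrt(max(1 - (s / span)^2, 0.15^2))
  list(chord = chord, offset = z_cut * tan(phi2))
}

.span_envelope <- function(xi, span, ramp) {
  env <- numeric(length(xi))
  inside <- xi >= span[1] & xi <= span[2]
  env[inside] <- 1
  d1 <- xi - span[1]; d2 <- span[2] - xi
  lo <- inside & d1 < ramp
  hi <- inside & d2 < ramp
  env[lo] <- 0.5 * (1 - cos(pi * d1[lo] / ramp))
  env[hi] <- pmin(env[hi], 0.5 * (1 - cos(pi * d2[hi] / ramp)))
  env
}

#' Run a self-propelled swimming simulation
#'
#' Couples the flow solver to the x-only body dynamics in the body frame:
#' each step (1) deforms the fin boundary at `t^{n+1}`, (2) sets the
#' far-field inflow to minus the extrapolated body speed
#' `2 u^n - u^{n-1}`, (3) advances the flow, (4) integrates the surface
#' force, (5) updates the body speed with [bdf2_velocity_update()]; steps
#' (2)-(5) are repeated in a short Picard loop so the force and velocity are
#' mutually consistent.
#'
#' @param config A run configuration from [gen_paper_case()] (or compatible).
#' @param quiet Suppress the per-cycle log line.
#' @param snapshot_every Write a VTK snapshot every this many steps into
#'   `snapshot_dir` (0 disables).
#' @param snapshot_dir Directory for snapshots.
#' @return An object of class `propulsion_series`: data.frame with columns
#'   `t`, `u_a` (m/s), `F`, `T_f`, `D` (N per unit span), `P_surf` (W per
#'   unit span), `cycle`, plus attributes `config`, `picard_gap` (final
#'   force/velocity mismatch per step) and `final_state`.
#' @export
run_self_propelled <- function(config, quiet = TRUE, snapshot_every = 0,
                               snapshot_dir = tempdir()) {
  ts <- config$timestepping
  fl <- config$fluid
  gr <- config$grid
  L <- config$geometry$length
  f <- config$wave$f
  Tc <- 1 / f
  dt <- Tc / ts$steps_per_cycle
  n_steps <- round(ts$n_cycles * ts$steps_per_cycle)
  st <- init_flow(gr$nx, gr$ny, Lx = gr$domain_length_bl * L,
                  Ly = gr$domain_width_bl * L, nu = fl$nu, rho = fl$rho,
                  bc = "channel", u_in = 0, init = "quiescent",
                  advection = gr$advection %||% "quick")
  m <- config$geometry$mass
  u_n <- 0; u_nm1 <- NA_real_
  rec <- vector("list", n_steps)
  picard_gap <- numeric(n_steps)
  for (n in seq_len(n_steps)) {
    t_np1 <- n * dt
    bd <- swimmer_boundary_2d(config, t_np1, st$h)$boundary
    u_tilde <- if (is.na(u_nm1)) u_n else 2 * u_n - u_nm1
    st_new <- NULL; F_np1 <- 0; u_np1 <- u_n; gap <- 0
    for (k in seq_len(max(1L, ts$picard_iters))) {
      st_try <- st
      st_try$u_in <- -u_tilde
      st_try <- flow_step(st_try, bd, dt,
                          n_forcing = ts$n_forcing %||% 2,
                          cg_tol = ts$cg_tol %||% 1e-10)
      F_np1 <- sum(st_try$last$fx) * fl$rho
      u_np1 <- bdf2_velocity_update(u_n, u_nm1, F_np1, m, dt)
      gap <- abs(u_np1 - u_tilde)
      st_new <- st_try
      if (gap <= (ts$picard_tol %||% 1e-6) * max(abs(u_np1), 1e-12)) break
      u_tilde <- u_np1
    }
    picard_gap[n] <- gap
    if (!is.finite(u_np1))
      stop(sprintf("non-finite body velocity at step %d (t = %g s)", n, t_np1))
    st <- st_new
    fx <- st$last$fx * fl$rho
    fy <- st$last$fy * fl$rho
    T_f <- sum(fx[fx > 0])
    D <- -sum(fx[fx < 0])
    # rate of work done by the surface on the fluid, with tank-frame surface
    # velocities (deformation plus the body's x-translation)
    P_surf <- -sum(fx * (bd$u + u_np1) + fy * bd$v)
    rec[[n]] <- c(t = t_np1, u_a = u_np1, F = F_np1, T_f = T_f, D = D,
                  P_surf = P_surf, cycle = t_np1 / Tc)
    u_nm1 <- u_n; u_n <- u_np1
    if (!quiet && n %% ts$steps_per_cycle == 0)
      message(sprintf("cycle %.0f: u_a = %.4g m/s, F = %.4g", t_np1 / Tc,
                      u_np1, F_np1))
    if (snapshot_every > 0 && n %% snapshot_every == 0)
      write_vtk_field(st, file.path(snapshot_dir,
                                    sprintf("flow_%06d.vtk", n)))
  }
  out <- as.data.frame(do.call(rbind, rec))
  attr(out, "config") <- config
  attr(out, "picard_gap") <- picard_gap
  attr(out, "final_state") <- st
  class(out) <- c("propulsion_series", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time to reach a target speed
#'
#' First crossing time of `u_target` in a propulsion series, with linear
#' interpolation between samples.
#'
#' @param series A `propulsion_series` (or data.frame with `t`, `u_a`).
#' @param u_target Target speed, m/s.
#' @return List with `reached` (logical), `t0` (s, `NA` if never reached)
#'   and `u_max` (largest speed seen).
#' @export
time_to_speed <- function(series, u_target) {
  if (!nrow(series)) stop("empty series")
  u <- series$u_a; t <- series$t
  u_max <- max(u)
  idx <- which(u >= u_target)
  if (!length(idx))
    return(list(reached = FALSE, t0 = NA_real_, u_max = u_max))
  i <- idx[1]
  if (i == 1) {
    # crossing before the first sample: interpolate from rest at t = 0
    t0 <- if (u[1] > 0) t[1] * u_target / u[1] else t[1]
    return(list(reached = TRUE, t0 = t0, u_max = u_max))
  }
  w <- (u_target - u[i - 1]) / (u[i] - u[i - 1])
  list(reached = TRUE, t0 = t[i - 1] + w * (t[i] - t[i - 1]), u_max = u_max)
}

#' @export
print.propulsion_series <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "propulsion series: %d steps, %.3g cycles, final u_a = %.4g m/s\n",
    nrow(x), max(x$cycle), x$u_a[nrow(x)]))
  if (!is.null(cfg))
    cat(sprintf("  caudal fin %g deg open, f = %g Hz\n",
                cfg$geometry$open_angle, cfg$wave$f))
  invisible(x)
}
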