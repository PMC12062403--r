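#' Initialise a 2-D incompressible flow state
#'
#' Creates the staggered-grid (MAC) flow state used by the immersed-boundary
#' solver: x-velocity on vertical cell faces, y-velocity on horizontal faces,
#' kinematic pressure (pressure over density) at cell centres.
#'
#' Boundary conditions: `"channel"` has a Dirichlet inflow on the right face
#' (`u = u_in`, typically negative so the far field streams tailward past the
#' swimmer), a convective outflow on the left face, and free-slip lateral
#' walls; `"periodic"` wraps both directions (used by analytic validation
#' cases).
#'
#' @param nx,ny Number of cells in x and y (each >= 16).
#' @param Lx,Ly Domain extents, m. Cells must be square (`Lx/nx == Ly/ny`).
#' @param nu Kinematic viscosity, m^2/s (> 0).
#' @param rho Fluid density, kg/m^3 (used only to convert kinematic forces to
#'   Newtons).
#' @param bc `"channel"` or `"periodic"`.
#' @param u_in Far-field/inflow x-velocity, m/s (channel only).
#' @param init `"quiescent"`, `"uniform"` (fills the field with `u_in`), or
#'   `"taylor_green"` (requires `periodic`; see `taylor_green`).
#' @param tg_k Taylor-Green wavenumber (integer modes across the domain).
#' @param tg_U0 Taylor-Green amplitude, m/s.
#' @param div_tol Base divergence tolerance; the asserted bound is
#'   `div_tol * (1 + max|u|) / h` per step.
#' @param advection Advective flux scheme: `"central"` (2nd-order,
#'   energy-conserving; default) or `"quick"` (upwind-biased, more robust for
#'   boundary-dominated flows at higher cell Peclet numbers).
#' @return An object of class `flow_state`.
#' @export
init_flow <- function(nx, ny, Lx, Ly, nu, rho = 1000,
                      bc = c("channel", "periodic"), u_in = 0,
                      init = c("quiescent", "uniform", "taylor_green"),
                      tg_k = 1, tg_U0 = 1, div_tol = 1e-8,
                      advection = c("central", "quick")) {
  bc <- match.arg(bc); init <- match.arg(init)
  advection <- match.arg(advection)
  if (nx < 16 || ny < 16)
    stop("invalid grid spec: nx and ny must both be >= 16")
  if (nu <= 0) stop("invalid grid spec: 'nu' must be positive")
  h <- Lx / nx
  if (abs(Ly / ny - h) > 1e-12 * h)
    stop("invalid grid spec: cells must be square (Lx/nx == Ly/ny)")
  st <- structure(
    list(u = matrix(0, nx + 1, ny), v = matrix(0, nx, ny + 1),
         p = matrix(0, nx, ny), t = 0,
         nx = nx, ny = ny, h = h, Lx = Lx, Ly = Ly,
         nu = nu, rho = rho, bc = bc, u_in = u_in, div_tol = div_tol,
         advection = advection, last = NULL),
    class = "flow_state")
  if (init == "uniform") {
    st$u[] <- u_in
  } else if (init == "taylor_green") {
    if (bc != "periodic") stop("taylor_green init requires periodic bc")
    st <- set_taylor_green(st, t = 0, k = tg_k, U0 = tg_U0)
  }
  st
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("flow state: %d x %d cells (h = %g m), t = %g s, bc = %s\n",
              x$nx, x$ny, x$h, x$t, x$bc))
  cat(sprintf("  nu = %g m^2/s, max |u| = %.4g m/s, KE = %.4g\n",
              x$nu, max(abs(x$u), abs(x$v)), kinetic_energy(x)))
  invisible(x)
}

#' Sample the decaying Taylor-Green vortex onto a flow state
#'
#' `u = U0 cos(kx) sin(ky) exp(-2 nu k^2 t)`,
#' `v = -U0 sin(kx) cos(ky) exp(-2 nu k^2 t)` with `k` in rad/m chosen as
#' `2*pi*k_modes/Lx`. Sampled on the staggered points; the discrete
#' divergence of the sampled field vanishes identically.
#'
#' @param state A `flow_state` (periodic).
#' @param t Evaluation time, s.
#' @param k Number of vortex modes across the domain.
#' @param U0 Amplitude, m/s.
#' @return The state with fields replaced.
#' @export
set_taylor_green <- function(state, t = 0, k = 1, U0 = 1) {
  kk <- 2 * pi * k / state$Lx
  dec <- exp(-2 * state$nu * kk^2 * t)
  h <- state$h
  xu <- (0:state$nx) * h;        yu <- ((1:state$ny) - 0.5) * h
  xv <- ((1:state$nx) - 0.5) * h; yv <- (0:state$ny) * h
  state$u <- U0 * dec * outer(cos(kk * xu), sin(kk * yu))
  state$v <- -U0 * dec * outer(sin(kk * xv), cos(kk * yv))
  state$t <- t
  attr(state, "tg") <- list(k = kk, U0 = U0)
  state
}

#' Immersed-boundary marker set
#'
#' A set of Lagrangian marker points carrying position, prescribed velocity,
#' segment length and a region tag; used by [flow_step()] to impose a moving
#' no-slip boundary by direct forcing.
#'
#' @param x,y Marker positions, m.
#' @param uvel,vvel Prescribed marker velocities, m/s (recycled).
#' @param ds Segment length per marker, m (recycled; default spacing of the
#'   chain).
#' @param region Character region tags (recycled).
#' @param h Grid spacing to validate marker spacing against (optional): `ds`
#'   must lie within `[0.5 h, 1.5 h]` for forcing stability.
#' @return An object of class `immersed_boundary` (data.frame-backed).
#' @export
immersed_boundary <- function(x, y, uvel = 0, vvel = 0, ds = NULL,
                              region = "body", h = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 1)
  if (is.null(ds)) {
    if (n > 1) {
      seg <- sqrt(diff(x)^2 + diff(y)^2)
      ds <- c(seg[1], (seg[-1] + seg[-length(seg)]) / 2, seg[length(seg)])
      ds <- ds[seq_len(n)]
    } else ds <- 1
  }
  b <- data.frame(x = x, y = y, u = rep_len(uvel, n), v = rep_len(vvel, n),
                  ds = rep_len(ds, n), region = rep_len(region, n),
                  stringsAsFactors = FALSE)
  if (!is.null(h)) {
    bad <- b$ds < 0.5 * h | b$ds > 1.5 * h
    if (any(bad))
      stop(sprintf(
        "marker spacing outside [0.5h, 1.5h] for %d markers (h = %g)",
        sum(bad), h))
  }
  class(b) <- c("immersed_boundary", "data.frame")
  b
}

#' Advance the flow by one time step
#'
#' Fractional-step update: SSP-RK3 integration of advection (QUICK
#' upwind-biased fluxes) and explicit diffusion, direct-forcing immersed
#' boundary with a 3-point regularized delta, global mass-balance correction,
#' conjugate-gradient pressure Poisson solve (warm-started from the previous
#' pressure), and projection. The post-projection divergence is asserted
#' against the state's tolerance.
#'
#' @param state A `flow_state`.
#' @param boundary An [immersed_boundary()] or `NULL`.
#' @param dt Time step, s. Must satisfy the advective CFL bound
#'   (`dt <= cfl_max * h / max|u|`) and the explicit diffusion bound
#'   (`dt <= h^2 / (4 nu)`); violations raise an error naming the admissible
#'   step.
#' @param n_forcing Direct-forcing iterations (more iterations tighten the
#'   no-slip residual).
#' @param cg_tol Relative tolerance of the pressure solve.
#' @param cg_maxit Maximum CG iterations.
#' @param check_div If `TRUE`, error when post-projection divergence exceeds
#'   tolerance.
#' @return The advanced `flow_state`; element `last` holds per-marker body
#'   forces (kinematic, per unit span), CG diagnostics and the max
#'   divergence.
#' @export
flow_step <- function(state, boundary = NULL, dt, n_forcing = 1,
                      cg_tol = 1e-10, cg_maxit = 20000, check_div = TRUE) {
  stopifnot(inherits(state, "flow_state"))
  umax <- max(abs(state$u), abs(state$v), abs(state$u_in), 1e-12)
  cfl_max <- 0.5
  dt_adv <- cfl_max * state$h / umax
  if (dt > dt_adv * (1 + 1e-9))
    stop(sprintf("CFL violation: dt = %g exceeds admissible dt = %g s",
                 dt, dt_adv))
  dt_diff <- state$h^2 / (4 * state$nu)
  if (dt > dt_diff)
    stop(sprintf(
      "diffusive stability violation: dt = %g exceeds admissible dt = %g s",
      dt, dt_diff))
  if (is.null(boundary)) {
    mx <- numeric(0); my <- numeric(0); mu <- numeric(0); mv <- numeric(0)
    mds <- numeric(0)
  } else {
    mx <- boundary$x; my <- boundary$y; mu <- boundary$u; mv <- boundary$v
    mds <- boundary$ds
  }
  out <- cpp_flow_step(state$u, state$v, state$p,
                       state$h, dt, state$nu, state$bc == "periodic",
                       state$u_in, mx, my, mu, mv, mds,
                       as.integer(n_forcing), cg_tol, as.integer(cg_maxit),
                       if (identical(state$advection, "quick")) 1L else 0L)
  if (out$cg_iters >= cg_maxit && out$cg_resid > cg_tol * 10)
    stop(sprintf("pressure solve failed to converge: relative residual %g",
                 out$cg_resid))
  st <- state
  st$u <- out$u; st$v <- out$v; st$p <- out$p
  st$t <- state$t + dt
  if (any(!is.finite(st$u)) || any(!is.finite(st$v)))
    stop("non-finite velocity field after step")
  umax2 <- max(abs(st$u), abs(st$v), 1e-12)
  tol <- state$div_tol * (1 + umax2) / state$h
  if (check_div && out$max_div > tol)
    stop(sprintf("post-projection divergence %g exceeds tolerance %g",
                 out$max_div, tol))
  st$last <- list(fx = out$fx, fy = out$fy,
                  region = if (is.null(boundary)) character(0)
                           else boundary$region,
                  cg_iters = out$cg_iters, max_div = out$max_div, dt = dt)
  st
}

#' Surface forces from the immersed-boundary momentum exchange
#'
#' Net and per-element forces on the body, taken as the sign-reversed sum of
#' the direct-forcing momentum exchange recorded during the last
#' [flow_step()]. A pressure/viscous split is estimated diagnostically by
#' sampling the pressure on both sides of each marker along the local normal;
#' the remainder is attributed to viscous stress.
#'
#' @param state A `flow_state` advanced past at least one step with markers.
#' @param boundary The [immersed_boundary()] used in that step (for geometry
#'   and tags).
#' @return An object of class `force_record`: list with net `F` (x-force, N
#'   per unit span), `fx`, `fy` per element, `pressure_x`, `viscous_x`
#'   components, `region`, `t`.
#' @export
surface_forces <- function(state, boundary = NULL) {
  stopifnot(inherits(state, "flow_state"))
  if (is.null(boundary) || nrow(boundary) == 0 || is.null(state$last) ||
      !length(state$last$fx)) {
    warning("empty boundary: zero-force record")
    return(structure(list(F = 0, fx = numeric(0), fy = numeric(0),
                          pressure_x = 0, viscous_x = 0,
                          region = character(0), t = state$t),
                     class = "force_record"))
  }
  rho <- state$rho
  fx <- state$last$fx * rho
  fy <- state$last$fy * rho
  # diagnostic pressure split: p jump across the filament along normals
  n <- nrow(boundary)
  tx <- numeric(n); ty <- numeric(n)
  if (n > 1) {
    dx <- c(diff(boundary$x), 0) + c(0, diff(boundary$x))
    dy <- c(diff(boundary$y), 0) + c(0, diff(boundary$y))
    L <- sqrt(dx^2 + dy^2); L[L == 0] <- 1
    tx <- dx / L; ty <- dy / L
  }
  nxv <- -ty; nyv <- tx
  off <- 1.2 * state$h
  pp <- .sample_pressure(state, boundary$x + off * nxv, boundary$y + off * nyv)
  pm <- .sample_pressure(state, boundary$x - off * nxv, boundary$y - off * nyv)
  press_x <- sum((pm - pp) * nxv * boundary$ds) * rho
  structure(list(F = sum(fx), fx = fx, fy = fy,
                 pressure_x = press_x, viscous_x = sum(fx) - press_x,
                 region = boundary$region, t = state$t),
            class = "force_record")
}

#' @export
print.force_record <- function(x, ...) {
  cat(sprintf(
    "force record at t = %g s: F = %.4g (pressure %.4g, viscous %.4g)\n",
    x$t, x$F, x$pressure_x, x$viscous_x))
  invisible(x)
}

.sample_pressure <- function(state, x, y) {
  h <- state$h
  gx <- pmin(pmax(x / h - 0.5, 0), state$nx - 1)
  gy <- pmin(pmax(y / h - 0.5, 0), state$ny - 1)
  i0 <- pmin(floor(gx), state$nx - 2); j0 <- pmin(floor(gy), state$ny - 2)
  fx <- gx - i0; fy <- gy - j0
  p <- state$p
  (1 - fx) * (1 - fy) * p[cbind(i0 + 1, j0 + 1)] +
    fx * (1 - fy) * p[cbind(i0 + 2, j0 + 1)] +
    (1 - fx) * fy * p[cbind(i0 + 1, j0 + 2)] +
    fx * fy * p[cbind(i0 + 2, j0 + 2)]
}

#' Vorticity field
#'
#' `omega = dv/dx - du/dy`, evaluated at cell corners by compact staggered
#' differences and averaged to cell centres.
#'
#' @param state A `flow_state`.
#' @return `nx x ny` matrix, 1/s.
#' @export
vorticity <- function(state) {
  h <- state$h; nx <- state$nx; ny <- state$ny
  u <- state$u; v <- state$v
  # corner values (nx+1) x (ny+1), interior corners only; replicate edges
  dvdx <- (v[c(2:nx, nx), ] - v[c(1, 1:(nx - 1)), ]) / (2 * h)  # at v pts
  dudy <- (u[, c(2:ny, ny)] - u[, c(1, 1:(ny - 1))]) / (2 * h)  # at u pts
  # average to centres
  dvdx_c <- (dvdx[, 1:ny] + dvdx[, 2:(ny + 1)]) / 2
  dudy_c <- (dudy[1:nx, ] + dudy[2:(nx + 1), ]) / 2
  dvdx_c - dudy_c
}

#' Q-criterion field
#'
#' `Q = (||Omega||^2 - ||S||^2) / 2` from the velocity-gradient tensor
#' (Frobenius norms of the antisymmetric and symmetric parts), central
#' differences at cell centres. Positive where rotation dominates strain.
#'
#' @param state A `flow_state`.
#' @return `nx x ny` matrix, 1/s^2.
#' @export
q_criterion <- function(state) {
  h <- state$h; nx <- state$nx; ny <- state$ny
  u <- state$u; v <- state$v
  dudx <- (u[2:(nx + 1), ] - u[1:nx, ]) / h                     # at centres
  dvdy <- (v[, 2:(ny + 1)] - v[, 1:ny]) / h
  uc <- (u[1:nx, ] + u[2:(nx + 1), ]) / 2
  vc <- (v[, 1:ny] + v[, 2:(ny + 1)]) / 2
  dudy <- (uc[, c(2:ny, ny)] - uc[, c(1, 1:(ny - 1))]) / (2 * h)
  dudy[, 1] <- (uc[, 2] - uc[, 1]) / h
  dudy[, ny] <- (uc[, ny] - uc[, ny - 1]) / h
  dvdx <- (vc[c(2:nx, nx), ] - vc[c(1, 1:(nx - 1)), ]) / (2 * h)
  dvdx[1, ] <- (vc[2, ] - vc[1, ]) / h
  dvdx[nx, ] <- (vc[nx, ] - vc[nx - 1, ]) / h
  s12 <- (dudy + dvdx) / 2
  o12 <- (dudy - dvdx) / 2
  omega2 <- 2 * o12^2
  s2 <- dudx^2 + dvdy^2 + 2 * s12^2
  (omega2 - s2) / 2
}

#' Maximum absolute discrete divergence
#' @param state A `flow_state`.
#' @return max |div u| over cells, 1/s.
#' @export
max_divergence <- function(state) {
  h <- state$h; nx <- state$nx; ny <- state$ny
  div <- (state$u[2:(nx + 1), ] - state$u[1:nx, ] +
            state$v[, 2:(ny + 1)] - state$v[, 1:ny]) / h
  max(abs(div))
}

#' Total kinetic energy of the resolved field
#' @param state A `flow_state`.
#' @return `0.5 * sum(u^2 + v^2) * h^2` (per unit density and span).
#' @export
kinetic_energy <- function(state) {
  nx <- state$nx; ny <- state$ny
  uc <- (state$u[1:nx, ] + state$u[2:(nx + 1), ]) / 2
  vc <- (state$v[, 1:ny] + state$v[, 2:(ny + 1)]) / 2
  0.5 * sum(uc^2 + vc^2) * state$h^2
}

#' Residual slip at immersed-boundary markers
#'
#' Kernel-interpolated fluid velocity at the markers minus the prescribed
#' marker velocity, evaluated on the current (post-projection) fields with
#' the same 3-point regularized delta the forcing uses. The forcing loop
#' drives the pre-projection slip toward zero; the projection reintroduces a
#' small residual.
#'
#' @param state A `flow_state`.
#' @param boundary An [immersed_boundary()].
#' @return Data.frame with per-marker `du`, `dv` and the interpolated
#'   velocities.
#' @export
boundary_slip <- function(state, boundary) {
  h <- state$h
  interp <- function(q, ox, oy, x, y) {
    roma <- function(r) {
      a <- abs(r)
      w <- numeric(length(a))
      i1 <- a <= 0.5
      w[i1] <- (1 + sqrt(pmax(1 - 3 * a[i1]^2, 0))) / 3
      i2 <- a > 0.5 & a <= 1.5
      w[i2] <- (5 - 3 * a[i2] - sqrt(pmax(1 - 3 * (1 - a[i2])^2, 0))) / 6
      w
    }
    sapply(seq_along(x), function(l) {
      gx <- x[l] / h - ox; gy <- y[l] / h - oy
      ic <- floor(gx + 0.5); jc <- floor(gy + 0.5)
      s <- 0
      for (dj in -1:1) for (di in -1:1) {
        i <- ic + di; j <- jc + dj
        w <- roma(gx - i) * roma(gy - j)
        i <- min(max(i, 0), nrow(q) - 1)
        j <- min(max(j, 0), ncol(q) - 1)
        s <- s + w * q[i + 1, j + 1]
      }
      s
    })
  }
  ui <- interp(state$u, 0, 0.5, boundary$x, boundary$y)
  vi <- interp(state$v, 0.5, 0, boundary$x, boundary$y)
  data.frame(du = ui - boundary$u, dv = vi - boundary$v, u = ui, v = vi)
}

#' Domain momentum budget terms (periodic domains)
#'
#' For a periodic domain the change of total fluid momentum over a step must
#' equal the immersed-boundary forcing impulse (boundary fluxes cancel);
#' returns both sides so the closure can be checked.
#'
#' @param state_old,state_new Flow states before/after [flow_step()].
#' @param body_force_x Net x-force on the body for that step (kinematic, as
#'   in `state_new$last`).
#' @param dt Step size, s.
#' @return List with `d_momentum_x` and `impulse_x` (both per unit density).
#' @export
momentum_budget <- function(state_old, state_new, body_force_x, dt) {
  stopifnot(state_old$bc == "periodic")
  h2 <- state_old$h^2
  nx <- state_old$nx
  mom <- function(s) sum(s$u[1:nx, ]) * h2
  list(d_momentum_x = mom(state_new) - mom(state_old),
       impulse_x = -body_force_x * dt)
}

#' Write a flow snapshot as legacy ASCII VTK (rectilinear grid)
#'
#' Cell-centred velocity, pressure, vorticity and Q-criterion fields.
#'
#' @param state A `flow_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(state, path) {
  nx <- state$nx; ny <- state$ny; h <- state$h
  uc <- (state$u[1:nx, ] + state$u[2:(nx + 1), ]) / 2
  vc <- (state$v[, 1:ny] + state$v[, 2:(ny + 1)]) / 2
  om <- vorticity(state); qc <- q_criterion(state)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("flow t=%g", state$t), "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("X_COORDINATES %d double", nx)), con)
  writeLines(paste(sprintf("%e", ((1:nx) - 0.5) * h), collapse = " "), con)
  writeLines(sprintf("Y_COORDINATES %d double", ny), con)
  writeLines(paste(sprintf("%e", ((1:ny) - 0.5) * h), collapse = " "), con)
  writeLines(c("Z_COORDINATES 1 double", "0"), con)
  writeLines(sprintf("POINT_DATA %d", nx * ny), con)
  wr <- function(name, m) {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%e", as.vector(m)), con)
  }
  wr("u", uc); wr("v", vc); wr("p", state$p)
  wr("vorticity", om); wr("q_criterion", qc)
  invisible(path)
}
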