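#' Traveling-wave parameters for median-fin undulation
#'
#' Bundles the parameters of the sinusoidal traveling wave applied to the
#' dorsal and anal fin rays: peak angular amplitude, wavelength, frequency,
#' and the startup-ramp variant used during the first cycle.
#'
#' @param theta_max Peak angular excursion of a fin ray, degrees. Must lie in
#'   (0, 90).
#' @param lambda Wavelength of the traveling wave along the fin base, m.
#' @param f Undulation frequency, Hz. The cycle period is `T = 1/f`.
#' @param ramp_mode Startup ramp applied during the first cycle, one of
#'   `"monotone"` (ramp rises 0 to 1) or `"as_printed"` (the published
#'   quartic, which starts at 2 and falls to 1; see [ramp_coefficient()]).
#'
#' @return An object of class `fin_wave_params`: a list with elements
#'   `theta_max`, `lambda`, `f`, `T`, `ramp_mode`, `wave_direction`.
#' @examples
#' fin_wave_params(theta_max = 30, lambda = 0.0285, f = 10)
#' @export
fin_wave_params <- function(theta_max = 30, lambda, f,
                            ramp_mode = c("monotone", "as_printed")) {
  ramp_mode <- match.arg(ramp_mode)
  if (!is.numeric(f) || length(f) != 1L || f <= 0)
    stop("invalid wave spec: 'f' must be a positive scalar frequency [Hz]")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("invalid wave spec: 'lambda' must be a positive scalar [m]")
  if (!is.numeric(theta_max) || length(theta_max) != 1L ||
      theta_max <= 0 || theta_max >= 90)
    stop("invalid wave spec: 'theta_max' must lie in (0, 90) degrees")
  structure(
    list(theta_max = theta_max, lambda = lambda, f = f, T = 1 / f,
         ramp_mode = ramp_mode, wave_direction = "+x"),
    class = "fin_wave_params"
  )
}

#' @export
print.fin_wave_params <- function(x, ...) {
  cat(sprintf(
    "fin wave: theta_max = %g deg, lambda = %g m, f = %g Hz (T = %g s), ramp = %s\n",
    x$theta_max, x$lambda, x$f, x$T, x$ramp_mode))
  invisible(x)
}

#' Startup ramp coefficient for the first undulation cycle
#'
#' The fin wave is multiplied by a ramp coefficient during the first cycle so
#' the boundary does not start impulsively. Two variants are provided:
#'
#' * `"as_printed"`: `beta(t) = ((t - T)^4 + T^4) / T^4` for `t <= T`, and 1
#'   afterwards. Note this expression starts at `beta(0) = 2` and *falls* to 1,
#'   i.e. it doubles rather than softens the first-cycle excursion; it is kept
#'   so the published motion can be reproduced verbatim.
#' * `"monotone"`: `beta(t) = 1 - ((T - t)/T)^4` for `t <= T`, and 1
#'   afterwards, which rises smoothly from rest (`beta(0) = 0`) and serves the
#'   stated purpose of a startup ramp. This is the default for swimming runs.
#'
#' Both variants are continuous (value 1) at `t = T`.
#'
#' @param t Time, s (vectorised). Must be `>= 0`.
#' @param T Cycle period, s.
#' @param mode `"as_printed"` or `"monotone"`.
#' @return Dimensionless ramp coefficient, same length as `t`.
#' @examples
#' ramp_coefficient(0, T = 0.1, mode = "monotone")    # 0
#' ramp_coefficient(0, T = 0.1, mode = "as_printed")  # 2
#' ramp_coefficient(0.1, T = 0.1, mode = "monotone")  # 1
#' @export
ramp_coefficient <- function(t, T, mode = c("monotone", "as_printed")) {
  mode <- match.arg(mode)
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("invalid wave spec: period 'T' must be a positive scalar [s]")
  if (any(t < 0)) stop("'t' must be non-negative")
  beta <- rep(1, length(t))
  early <- t <= T
  if (mode == "as_printed") {
    beta[early] <- ((t[early] - T)^4 + T^4) / T^4
  } else {
    beta[early] <- 1 - ((T - t[early]) / T)^4
  }
  beta
}

#' Fin-ray angular excursion of the traveling wave
#'
#' Evaluates the traveling-wave fin angle
#' `theta(x, t) = beta(t) * theta_max * sin(2*pi*(x/lambda + f*t))`
#' (degrees), with the ramp `beta` active during the first cycle only.
#'
#' With the printed `+f*t` phase the wave crests move toward decreasing `x`;
#' `direction = -1` flips the sign of the time term so the wave travels toward
#' increasing `x` (head-to-tail under the head-at-origin body frame), which is
#' the propagation sense used by the swimming simulations.
#'
#' @param x Position along the fin base, m (vectorised).
#' @param t Time, s (scalar).
#' @param params A [fin_wave_params()] object.
#' @param direction `+1` (printed phase) or `-1` (tailward propagation).
#' @return Fin angle theta in degrees, same length as `x`.
#' @examples
#' p <- fin_wave_params(theta_max = 30, lambda = 1, f = 1)
#' fin_angle(0.25, t = 2, params = p)   # sin peak after the ramp: 30 degrees
#' @export
fin_angle <- function(x, t, params, direction = 1) {
  stopifnot(inherits(params, "fin_wave_params"), length(t) == 1L, t >= 0)
  if (!direction %in% c(-1, 1)) stop("'direction' must be +1 or -1")
  beta <- ramp_coefficient(t, params$T, params$ramp_mode)
  phase <- 2 * pi * (x / params$lambda + direction * params$f * t)
  beta * params$theta_max * sin(phase)
}

#' Length-preserving deformation of a fin-ray point
#'
#' Rotates a point at height `z` above the fin base line through the angle
#' `theta` while keeping the fin-ray length constant: the lateral displacement
#' is `y' = z*sin(theta) + y` and the height correction is
#' `dz = 2*z*cos((pi - theta)/2)*sin(theta/2)`, `z' = z - dz`, which is
#' algebraically `z' = z*cos(theta)` so that `(y' - y)^2 + z'^2 = z^2`.
#'
#' @param y Lateral coordinate before deformation, m (vectorised).
#' @param z Height above the fin base line, m (vectorised).
#' @param theta Angular excursion, degrees (vectorised).
#' @return A data.frame with columns `y_prime`, `z_prime`, `dz`, `theta`.
#' @examples
#' deform_point(0, 1, 30)  # y' = 0.5, z' = cos(30 deg)
#' @export
deform_point <- function(y, z, theta) {
  th <- theta * pi / 180
  dz <- 2 * z * cos((pi - th) / 2) * sin(th / 2)
  data.frame(y_prime = z * sin(th) + y,
             z_prime = z - dz,
             dz = dz,
             theta = theta)
}

#' Lateral displacement of the free fin edge
#'
#' Displacement of the undulating fin's free edge at height `H` above the base
#' line: `H * sin(theta(x, t))`. This is the quantity that drives the
#' two-dimensional solver analogue of the fin.
#'
#' @inheritParams fin_angle
#' @param H Fin height (base line to free edge), m. Must be positive.
#' @return Lateral displacement in m, bounded by `H*sin(theta_max*beta_max)`.
#' @export
fin_edge_displacement <- function(x, t, params, H, direction = 1) {
  if (!is.numeric(H) || length(H) != 1L || H <= 0)
    stop("'H' must be a positive scalar [m]")
  H * sin(fin_angle(x, t, params, direction) * pi / 180)
}

#' Analytic time derivative of the fin-edge displacement
#'
#' Chain-rule velocity of [fin_edge_displacement()]; used to prescribe marker
#' velocities without finite differencing. Only exact after the startup ramp
#' or under the `monotone` ramp (whose derivative is included).
#'
#' @inheritParams fin_edge_displacement
#' @return Lateral velocity in m/s.
#' @keywords internal
fin_edge_velocity <- function(x, t, params, H, direction = 1) {
  th <- fin_angle(x, t, params, direction) * pi / 180
  # d(theta)/dt in radians/s: product rule over ramp and sine
  Tc <- params$T
  phase <- 2 * pi * (x / params$lambda + direction * params$f * t)
  beta <- ramp_coefficient(t, Tc, params$ramp_mode)
  dbeta <- 0
  if (t <= Tc) {
    dbeta <- if (params$ramp_mode == "as_printed")
      4 * (t - Tc)^3 / Tc^4 else 4 * (Tc - t)^3 / Tc^4
  }
  thmax <- params$theta_max * pi / 180
  dth <- thmax * (dbeta * sin(phase) +
                    beta * cos(phase) * 2 * pi * direction * params$f)
  H * cos(th) * dth
}

#' Deform the swimmer surface mesh at time t
#'
#' Applies the traveling-wave, length-preserving fin-ray deformation to the
#' dorsal- and anal-fin vertices of a swimmer mesh (body and caudal-fin
#' vertices stay rigid) and returns the deformed mesh together with
#' per-vertex velocities.
#'
#' The fin rays rotate about their base line (the attachment height stored in
#' the geometry); the anal fin mirrors the dorsal fin so both receive the
#' same motion, as observed for the undulating median fins.
#'
#' @param mesh A `swimmer_geometry` object from [build_swimmer_geometry()].
#' @param t Time, s.
#' @param params A [fin_wave_params()] object.
#' @param direction Wave propagation sign passed to [fin_angle()].
#' @param velocity How to compute per-vertex velocities: `"finite_diff"`
#'   (central difference of position with step `T/1000`) or `"analytic"`
#'   (chain rule).
#' @param fd_step Finite-difference half-step, s; default `params$T/1000`.
#' @return A list with `mesh` (deformed copy) and `velocity` (n x 3 matrix,
#'   m/s).
#' @export
deform_surface <- function(mesh, t, params, direction = 1,
                           velocity = c("finite_diff", "analytic"),
                           fd_step = params$T / 1000) {
  velocity <- match.arg(velocity)
  stopifnot(inherits(mesh, "swimmer_geometry"))
  pos <- function(tt) .deform_vertices(mesh, tt, params, direction)
  v1 <- pos(t)
  vel <- matrix(0, nrow(mesh$vertices), 3)
  if (velocity == "finite_diff") {
    h <- fd_step
    tm <- max(t - h, 0)
    vel <- (pos(t + h) - pos(tm)) / (t + h - tm)
  } else {
    # analytic chain rule on the rotating fin rays
    vel <- .deform_vertex_velocity(mesh, t, params, direction)
  }
  out <- mesh
  out$vertices <- v1
  list(mesh = out, velocity = vel)
}

# rotate fin vertices about their base lines; body/caudal rigid
.deform_vertices <- function(mesh, t, params, direction) {
  v <- mesh$vertices
  out <- v
  for (fin in c("dorsal_fin", "anal_fin")) {
    idx <- which(mesh$vertex_region == fin)
    if (!length(idx)) next
    zb <- if (fin == "dorsal_fin") mesh$fin_base_z else -mesh$fin_base_z
    x <- v[idx, 1]; y <- v[idx, 2]; z <- v[idx, 3]
    zloc <- if (fin == "dorsal_fin") z - zb else zb - z
    th <- fin_angle(x, t, params, direction)
    d <- deform_point(y, zloc, th)
    out[idx, 2] <- d$y_prime
    out[idx, 3] <- if (fin == "dorsal_fin") zb + d$z_prime else zb - d$z_prime
  }
  out
}

.deform_vertex_velocity <- function(mesh, t, params, direction) {
  v <- mesh$vertices
  vel <- matrix(0, nrow(v), 3)
  Tc <- params$T
  beta <- ramp_coefficient(t, Tc, params$ramp_mode)
  dbeta <- 0
  if (t <= Tc) {
    dbeta <- if (params$ramp_mode == "as_printed")
      4 * (t - Tc)^3 / Tc^4 else 4 * (Tc - t)^3 / Tc^4
  }
  thmax <- params$theta_max * pi / 180
  for (fin in c("dorsal_fin", "anal_fin")) {
    idx <- which(mesh$vertex_region == fin)
    if (!length(idx)) next
    zb <- if (fin == "dorsal_fin") mesh$fin_base_z else -mesh$fin_base_z
    x <- v[idx, 1]; z <- v[idx, 3]
    zloc <- if (fin == "dorsal_fin") z - zb else zb - z
    phase <- 2 * pi * (x / params$lambda + direction * params$f * t)
    th <- beta * thmax * sin(phase)
    dth <- thmax * (dbeta * sin(phase) +
                      beta * cos(phase) * 2 * pi * direction * params$f)
    vel[idx, 2] <- zloc * cos(th) * dth
    dzdt <- -zloc * sin(th) * dth            # d/dt of zloc*cos(theta)
    vel[idx, 3] <- if (fin == "dorsal_fin") dzdt else -dzdt
  }
  vel
}
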