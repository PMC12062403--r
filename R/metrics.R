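#' Average acceleration from target speed and time to reach it
#'
#' `alpha = u_e / t_0`, the acceleration index used to compare caudal-fin
#' configurations: the experimentally measured swimming speed divided by the
#' simulated time needed to reach it.
#'
#' @param u_e Swimming speed, BL/s.
#' @param t_0 Time required to reach `u_e`, s (> 0).
#' @return Average acceleration, BL/s^2.
#' @examples
#' average_acceleration(0.73, 11.4 / 10)  # closed caudal fin, 10 Hz
#' average_acceleration(0.73, 14.9 / 10)  # full-open caudal fin, 10 Hz
#' @export
average_acceleration <- function(u_e, t_0) {
  if (any(t_0 <= 0)) stop("invalid input: 't_0' must be positive")
  u_e / t_0
}

#' Reynolds number of the swimmer
#'
#' `Re = u_e * L_D / nu` with the body length as the length scale.
#'
#' @param u_e Swimming speed, m/s.
#' @param L_D Body (model) length, m.
#' @param nu Kinematic viscosity, m^2/s (> 0).
#' @return Reynolds number (dimensionless).
#' @export
reynolds <- function(u_e, L_D, nu) {
  if (any(nu <= 0)) stop("invalid input: 'nu' must be positive")
  u_e * L_D / nu
}

#' Hydrodynamic energy expenditure over a window
#'
#' Trapezoidal time integral of the total rate of work done by the body
#' surface on the fluid, `sum_elements(f_x dx/dt + f_y dy/dt [+ f_z dz/dt])`,
#' over the averaging window (canonically 20 undulation cycles). Accepts
#' per-element force and velocity series; the z-terms are simply omitted by
#' passing `NULL` (the planar analogue).
#'
#' @param f_x,f_y,f_z Matrices (n_steps x n_elements) of surface forces, N.
#'   `f_z` may be `NULL`.
#' @param v_x,v_y,v_z Matching surface-velocity matrices, m/s.
#' @param time Time stamps, s (length n_steps).
#' @param window Integration window `c(t_start, t_end)`, s; default the full
#'   series.
#' @return List with `total` (J) and `average` (W) over the window.
#' @export
power_expenditure <- function(f_x, v_x, f_y = NULL, v_y = NULL,
                              f_z = NULL, v_z = NULL, time,
                              window = range(time)) {
  f_x <- as.matrix(f_x); v_x <- as.matrix(v_x)
  if (!all(dim(f_x) == dim(v_x)))
    stop("invalid input: force and velocity series are misaligned")
  if (nrow(f_x) != length(time))
    stop("invalid input: series length does not match 'time'")
  pw <- rowSums(f_x * v_x)
  for (pair in list(list(f_y, v_y), list(f_z, v_z))) {
    if (!is.null(pair[[1]])) {
      a <- as.matrix(pair[[1]]); b <- as.matrix(pair[[2]])
      if (!all(dim(a) == dim(f_x)))
        stop("invalid input: force and velocity series are misaligned")
      pw <- pw + rowSums(a * b)
    }
  }
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 2) stop("window contains fewer than 2 samples")
  tt <- time[keep]; pp <- pw[keep]
  total <- sum(diff(tt) * (pp[-1] + pp[-length(pp)]) / 2)
  list(total = total, average = total / (tt[length(tt)] - tt[1]))
}

#' Froude efficiency
#'
#' `eta = T_f * u_a / P_e`: useful propulsive power (thrust times swimming
#' speed) over total hydrodynamic power, from cycle-averaged inputs taken
#' over the same window.
#'
#' @param T_f_avg Cycle-averaged thrust, N.
#' @param u_a_avg Cycle-averaged swimming speed, m/s.
#' @param P_e_avg Cycle-averaged power expenditure, W (> 0).
#' @return Dimensionless efficiency.
#' @export
froude_efficiency <- function(T_f_avg, u_a_avg, P_e_avg) {
  if (any(P_e_avg <= 0))
    stop("undefined efficiency: 'P_e_avg' must be positive")
  T_f_avg * u_a_avg / P_e_avg
}

#' Cost of transport
#'
#' `Omega = P_e / (u_a * m)`: energy spent per unit mass per unit distance.
#'
#' @param P_e_avg Cycle-averaged power expenditure, W.
#' @param u_a_avg Cycle-averaged swimming speed, m/s (> 0).
#' @param m Body mass, kg (> 0).
#' @return Cost of transport, J/(kg m).
#' @export
cost_of_transport <- function(P_e_avg, u_a_avg, m) {
  if (any(u_a_avg <= 0))
    stop("undefined cost: 'u_a_avg' must be positive")
  if (any(m <= 0)) stop("undefined cost: 'm' must be positive")
  P_e_avg / (u_a_avg * m)
}

#' Drag coefficient
#'
#' Two conventions are supported. `"standard"` is the usual
#' `C_d = D / (0.5 rho U_a^2 s)`. `"as_printed"` is
#' `C_d = D / (0.5 rho U_a s)` with the speed to the first power (the form
#' in which the quantity was published for this system; note it is not
#' dimensionless). The two differ by exactly a factor `U_a`.
#'
#' @param D Drag, N.
#' @param rho Fluid density, kg/m^3 (> 0).
#' @param U_a Body speed, m/s (> 0; zero-speed start-of-run records must be
#'   masked before calling).
#' @param s Reference (total surface) area, m^2 (> 0).
#' @param convention `"standard"` or `"as_printed"`.
#' @return The drag coefficient, with the convention recorded as an
#'   attribute.
#' @export
drag_coefficient <- function(D, rho, U_a, s,
                             convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  if (any(rho <= 0) || any(s <= 0))
    stop("invalid input: 'rho' and 's' must be positive")
  if (any(U_a <= 0))
    stop("undefined coefficient: 'U_a' must be positive (mask rest records)")
  cd <- if (convention == "standard") D / (0.5 * rho * U_a^2 * s)
        else D / (0.5 * rho * U_a * s)
  structure(cd, convention = convention)
}

#' Thrust-drag decomposition of a force record
#'
#' Splits the per-element x-forces by sign relative to the swimming
#' direction: thrust `T_f` is the sum of aligned components, drag `D` the
#' magnitude of the opposing sum, so the net force identity `F = T_f - D`
#' holds exactly by construction.
#'
#' @param record A `force_record` from [surface_forces()], or any list with
#'   per-element `fx`.
#' @param swim_direction `+1` or `-1`: sign of the swimming direction along
#'   x.
#' @return List with `T_f`, `D`, `F` (N).
#' @export
thrust_drag_split <- function(record, swim_direction = 1) {
  if (!swim_direction %in% c(-1, 1))
    stop("'swim_direction' must be +1 or -1")
  fx <- record$fx * swim_direction
  T_f <- sum(fx[fx > 0])
  D <- -sum(fx[fx < 0])
  list(T_f = T_f, D = D, F = T_f - D)
}

#' Summarise a self-propulsion run
#'
#' Cycle-averaged hydrodynamic performance over the configured window
#' (default from cycle 0.1 — masking the impulsive start — to cycle 20, or
#' to the last complete cycle if the series is shorter): thrust, drag, net
#' force, power, Froude efficiency, cost of transport, Reynolds number, drag
#' coefficient, and the average acceleration against a target speed.
#'
#' @param series A `propulsion_series` from [run_self_propelled()].
#' @param u_e_target Target speed for the acceleration index, BL/s. Default
#'   92.5% of the plateau (top-decile mean) speed of this series.
#' @param window_cycles Averaging window length in cycles.
#' @param mask_start_cycle Start of the averaging window, cycles.
#' @param cd_convention Drag-coefficient convention, see
#'   [drag_coefficient()].
#' @param reference_area Area `s` for the drag coefficient; default the body
#'   length times fin height of the configuration (per unit span analogue).
#' @return An object of class `performance_summary`.
#' @export
summarize_run <- function(series, u_e_target = NULL, window_cycles = 20,
                          mask_start_cycle = 0.1,
                          cd_convention = c("standard", "as_printed"),
                          reference_area = NULL) {
  cd_convention <- match.arg(cd_convention)
  cfg <- attr(series, "config")
  if (nrow(series) < 2 || max(series$cycle) < 1)
    stop("need at least one full cycle of data")
  L <- cfg$geometry$length
  m <- cfg$geometry$mass
  rho <- cfg$fluid$rho
  nu <- cfg$fluid$nu
  f <- cfg$wave$f
  w_end <- min(window_cycles, floor(max(series$cycle)))
  if (w_end < window_cycles)
    warning(sprintf("window truncated to %g complete cycles", w_end))
  keep <- series$cycle >= mask_start_cycle & series$cycle <= w_end
  sub <- series[keep, , drop = FALSE]
  tmean <- function(x) {          # trapezoidal time average
    tt <- sub$t
    sum(diff(tt) * (x[-1] + x[-length(x)]) / 2) / (tt[length(tt)] - tt[1])
  }
  T_f_avg <- tmean(sub$T_f); D_avg <- tmean(sub$D); F_avg <- tmean(sub$F)
  P_avg <- tmean(sub$P_surf); u_avg <- tmean(sub$u_a)
  u_bl <- series$u_a / L
  if (is.null(u_e_target)) {
    plateau <- mean(sort(u_bl, decreasing = TRUE)[
      seq_len(max(1, floor(0.1 * length(u_bl))))])
    u_e_target <- 0.925 * plateau
  }
  tts <- time_to_speed(series, u_e_target * L)
  alpha <- if (tts$reached) average_acceleration(u_e_target, tts$t0)
           else NA_real_
  if (is.null(reference_area)) reference_area <- L * cfg$analogue$fin_height
  cd <- if (u_avg > 0)
    drag_coefficient(D_avg, rho, u_avg, reference_area, cd_convention)
  else NA_real_
  structure(
    list(alpha = alpha, u_e = u_e_target, t_0 = tts$t0,
         Re = reynolds(u_avg, L, nu),
         eta = if (P_avg > 0) froude_efficiency(T_f_avg, u_avg, P_avg)
               else NA_real_,
         cot = if (u_avg > 0) cost_of_transport(P_avg, u_avg, m)
               else NA_real_,
         P_e = P_avg, C_d = cd, cd_convention = cd_convention,
         T_f = T_f_avg, D = D_avg, F = F_avg, u_a_avg = u_avg,
         u_a_final = series$u_a[nrow(series)],
         window = c(mask_start_cycle, w_end), f = f, L_D = L, rho = rho,
         mass = m),
    class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("hydrodynamic performance summary\n")
  cat(sprintf("  window: cycles %g-%g at f = %g Hz\n",
              x$window[1], x$window[2], x$f))
  cat(sprintf("  u_a (cycle avg) = %.4g m/s (final %.4g), Re = %.4g\n",
              x$u_a_avg, x$u_a_final, x$Re))
  cat(sprintf("  alpha = %.4g BL/s^2 (u_e = %.4g BL/s, t_0 = %.4g s)\n",
              x$alpha, x$u_e, x$t_0))
  cat(sprintf("  T_f = %.4g, D = %.4g, F = %.4g N; P_e = %.4g W\n",
              x$T_f, x$D, x$F, x$P_e))
  cat(sprintf("  eta = %.4g, cost of transport = %.4g J/(kg m), C_d = %.4g (%s)\n",
              x$eta, x$cot, as.numeric(x$C_d), x$cd_convention))
  invisible(x)
}
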