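#' Behavioural and numerical parameters of the movement model
#'
#' Bundles the four behavioural parameters of the persistent turning walker
#' with homing, together with flight speed and the integration step.  The two
#' equivalent parameterizations of the angular-speed process are
#' interconvertible and kept consistent: the noise amplitude `sigma` and the
#' stationary angular-speed variance `omega_var` are related by
#' `omega_var = sigma^2 / (2 * gamma)`, and the mean exploration duration
#' `alpha` is the reciprocal of the per-second switch probability `p_return`.
#' Supply either member of each pair; supplying both is allowed only when they
#' agree to within 1e-12 relative tolerance.
#'
#' Defaults are the values calibrated against harmonic-radar recordings of
#' exploring bumblebees: `gamma = 1` 1/s, `sigma = 0.37` (so
#' `omega_var = 0.07` rad^2/s^2 to two decimals), `p_return = 1/30` 1/s
#' (`alpha = 30` s) and `eta_star = 0.2` 1/s.  The flight speed is not
#' constrained by the calibration observables (which are shape-based); the
#' default of 5 m/s is a plausible bumblebee ground speed, and all absolute
#' spatial scales produced by the simulator scale with it.
#'
#' @param gamma autocorrelation coefficient of the angular-speed process, 1/s.
#' @param sigma noise amplitude of the angular-speed process.
#' @param omega_var stationary variance of the angular speed, rad^2/s^2.
#' @param p_return probability per unit time of switching from the exploration
#'   phase to the return phase, 1/s.
#' @param alpha mean duration of the exploration phase, s (`1/p_return`).
#' @param eta_star homing attraction strength during the return phase, 1/s.
#' @param speed constant flight speed, m/s.
#' @param dt integration time step, s.
#' @param nest_radius radius around the nest that terminates a loop, m.
#' @param max_loop_duration censoring cap on a single loop, s.
#' @return An object of class `bee_params`: a named list with all ten fields,
#'   both parameterizations filled in.
#' @examples
#' p <- model_params()
#' p$omega_var            # 0.37^2 / 2
#' model_params(omega_var = 0.07, alpha = 30)$sigma
#' @export
model_params <- function(gamma = 1.0, sigma = NULL, omega_var = NULL,
                         p_return = NULL, alpha = NULL, eta_star = 0.2,
                         speed = 5, dt = 0.01, nest_radius = 13,
                         max_loop_duration = 3600) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a positive scalar")
  if (is.null(sigma) && is.null(omega_var)) sigma <- 0.37
  if (!is.null(sigma) && !is.null(omega_var)) {
    if (abs(omega_var - sigma^2 / (2 * gamma)) >
        1e-12 * max(1, abs(omega_var)))
      stop("`sigma` and `omega_var` are inconsistent: omega_var must equal ",
           "sigma^2 / (2 * gamma)")
  }
  if (is.null(omega_var)) omega_var <- sigma^2 / (2 * gamma)
  if (is.null(sigma)) sigma <- sqrt(2 * gamma * omega_var)

  if (is.null(p_return) && is.null(alpha)) p_return <- 1 / 30
  if (!is.null(p_return) && !is.null(alpha)) {
    if (abs(alpha - 1 / p_return) > 1e-12 * max(1, abs(alpha)))
      stop("`alpha` and `p_return` are inconsistent: alpha must equal ",
           "1 / p_return")
  }
  if (is.null(p_return)) p_return <- 1 / alpha
  if (is.null(alpha)) alpha <- 1 / p_return

  if (sigma < 0) stop("`sigma` must be non-negative")
  if (eta_star < 0) stop("`eta_star` must be non-negative")
  if (speed <= 0) stop("`speed` must be positive")
  if (dt <= 0) stop("`dt` must be positive")
  if (p_return <= 0) stop("`p_return` must be positive")
  if (nest_radius <= 0) stop("`nest_radius` must be positive")
  if (max_loop_duration <= 0) stop("`max_loop_duration` must be positive")

  structure(list(gamma = gamma, sigma = sigma, omega_var = omega_var,
                 p_return = p_return, alpha = alpha, eta_star = eta_star,
                 speed = speed, dt = dt, nest_radius = nest_radius,
                 max_loop_duration = max_loop_duration),
            class = "bee_params")
}

#' @export
print.bee_params <- function(x, ...) {
  cat("Persistent-turning-walker parameters\n")
  cat(sprintf("  gamma     %.4g 1/s   (angular-speed autocorrelation)\n",
              x$gamma))
  cat(sprintf("  sigma     %.4g       (noise amplitude; Var(omega) = %.4g)\n",
              x$sigma, x$omega_var))
  cat(sprintf("  alpha     %.4g s     (mean exploration time; p_return = %.4g)\n",
              x$alpha, x$p_return))
  cat(sprintf("  eta*      %.4g 1/s   (homing strength)\n", x$eta_star))
  cat(sprintf("  speed     %.4g m/s, dt %.4g s, nest radius %.4g m, censor %g s\n",
              x$speed, x$dt, x$nest_radius, x$max_loop_duration))
  invisible(x)
}

#' Instantaneous kinematic state of one simulated bee
#'
#' @param position numeric 2-vector, m.
#' @param heading flight direction, rad, wrapped to (-pi, pi].
#' @param angular_speed signed turning rate, rad/s.
#' @param switch_time the exploration-to-return switching time tau drawn for
#'   the current loop, s.
#' @param clock elapsed time within the current loop, s.
#' @return An object of class `bee_state`.  The phase is derived from the
#'   clock: the bee is in the return phase exactly when `clock >= switch_time`.
#' @export
bee_state <- function(position = c(0, 0), heading = 0, angular_speed = 0,
                      switch_time = Inf, clock = 0) {
  stopifnot(length(position) == 2, is.finite(heading))
  heading <- wrap_angle(heading)
  structure(list(position = as.numeric(position), heading = heading,
                 angular_speed = angular_speed,
                 phase = if (clock >= switch_time) "return" else "exploration",
                 switch_time = switch_time, clock = clock),
            class = "bee_state")
}
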