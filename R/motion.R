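#' Wrap an angle to (-pi, pi]
#'
#' @param a angle(s) in radians.
#' @return Angle(s) mapped into the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi)
  ifelse(w <= 0, w + pi, w - pi)
}

#' Signed angle from the flight direction to the homing direction
#'
#' Returns the rotation phi in (-pi, pi] that maps the current velocity
#' direction onto the homing vector H = nest - position.  Positive angles are
#' counterclockwise, so a target angular speed `eta * phi` applied through the
#' heading update steers the bee toward the nest.
#'
#' @param position current position, 2-vector, m.
#' @param heading current flight direction, rad.
#' @param nest nest position, 2-vector, m.
#' @return Signed angle in (-pi, pi], rad.
#' @export
homing_angle <- function(position, heading, nest) {
  h <- c(nest[1] - position[1], nest[2] - position[2])
  if (h[1] == 0 && h[2] == 0)
    stop("homing direction undefined: position coincides with the nest")
  wrap_angle(atan2(h[2], h[1]) - heading)
}

#' Target angular speed of the steering term
#'
#' Zero during the exploration phase; during the return phase it is the homing
#' strength times the signed angle between the heading and the nest direction,
#' so the bee continuously turns toward home.
#'
#' @param state a [bee_state()].
#' @param params a [model_params()].
#' @param nest nest position, 2-vector, m.
#' @return Target angular speed, rad/s.
#' @export
target_angular_speed <- function(state, params, nest = c(0, 0)) {
  if (state$phase != "return") return(0)
  params$eta_star * homing_angle(state$position, state$heading, nest)
}

#' Exact one-step Ornstein-Uhlenbeck update of the angular speed
#'
#' Uses the Green function of the OU process over one time step:
#' `omega' = omega * a + omega_target * (1 - a) + s * noise`, with
#' `a = exp(-gamma * dt)` and transition standard deviation
#' `s = sigma * sqrt((1 - exp(-2 * gamma * dt)) / (2 * gamma))`, which tends
#' to 0 as `dt -> 0` and to the stationary variance `sigma^2/(2*gamma)` as
#' `dt -> Inf`.  Exact for any step size: halving `dt` leaves the law of the
#' process unchanged.
#'
#' @param omega current angular speed, rad/s.
#' @param omega_target target angular speed, rad/s.
#' @param params a [model_params()].
#' @param noise standard-normal draw(s).
#' @return Updated angular speed, rad/s.
#' @export
ou_update <- function(omega, omega_target, params, noise) {
  a <- exp(-params$gamma * params$dt)
  s <- ou_step_sd(params)
  omega * a + omega_target * (1 - a) + s * noise
}

ou_step_sd <- function(params) {
  params$sigma *
    sqrt((1 - exp(-2 * params$gamma * params$dt)) / (2 * params$gamma))
}

#' Advance the full bee state by one time step
#'
#' Update order within a step: the position moves with the current velocity,
#' the heading turns with the current angular speed, the velocity is recomputed
#' from the new heading at constant speed, the phase flips to `return` once the
#' loop clock reaches the switching time, and finally the angular speed is
#' updated by [ou_update()] with the steering target evaluated at the new
#' position and heading.  This is the reference single-step implementation;
#' the compiled simulation engine performs the identical sequence.
#'
#' @inheritParams target_angular_speed
#' @param noise a standard-normal draw for the angular-speed update.
#' @return The new [bee_state()].
#' @export
advance_state <- function(state, params, nest = c(0, 0), noise = rnorm(1)) {
  dt <- params$dt
  pos <- state$position +
    params$speed * c(cos(state$heading), sin(state$heading)) * dt
  heading <- wrap_angle(state$heading + state$angular_speed * dt)
  clock <- state$clock + dt
  phase <- if (clock >= state$switch_time) "return" else state$phase
  tmp <- bee_state(pos, heading, state$angular_speed,
                   switch_time = state$switch_time, clock = clock)
  tmp$phase <- phase
  omega_target <- if (phase == "return" && all(pos == nest)) 0 else
    target_angular_speed(tmp, params, nest)
  tmp$angular_speed <- ou_update(state$angular_speed, omega_target, params,
                                 noise)
  tmp
}

#' Draw exploration-phase durations
#'
#' Switching from exploration to return happens with constant probability per
#' unit time, so switching times are exponential with mean `alpha = 1/p_return`.
#'
#' @param params a [model_params()].
#' @param n number of draws.
#' @return Exponential variates, s.
#' @export
draw_switch_time <- function(params, n = 1) {
  rexp(n, rate = params$p_return)
}

#' Simulate one nest-to-nest loop
#'
#' The bee starts at the nest with a uniformly random heading and zero angular
#' speed, explores until its exponentially distributed switching time, then
#' homes under the steering term.  The loop ends at the first time the bee is
#' within `nest_radius` of the nest while in the return phase, or is censored
#' at `max_loop_duration`.
#'
#' @param params a [model_params()].
#' @param nest nest position, 2-vector, m.
#' @param record_interval recording resolution, s; must be a multiple of
#'   `params$dt`.  The first and final samples are always recorded.
#' @return A `bee_loop` (see [bee_track()]) with fields `censored` and
#'   `switch_time`.
#' @export
simulate_loop <- function(params, nest = c(0, 0),
                          record_interval = params$dt) {
  every <- record_steps(record_interval, params$dt)
  res <- cpp_ptw_simulate(params$gamma, params$sigma, params$eta_star,
                          params$p_return, params$speed, params$dt,
                          params$nest_radius, params$max_loop_duration,
                          as.numeric(nest), 0, TRUE, every,
                          matrix(numeric(0), 0, 2), 0, 0L, 1L, Inf,
                          logical(0))
  tr <- bee_track(res$track[, 1], res$track[, 2], res$track[, 3],
                  sampling_interval = record_interval, nest = nest,
                  phase = res$phase)
  as_bee_loop(tr, censored = res$censored, switch_time = res$switch_time)
}

#' Simulate a multi-loop foraging trip
#'
#' Chains loops for exactly `duration` seconds of simulated time: whenever the
#' bee re-enters the nest disc in the return phase it immediately starts a
#' fresh loop (new uniform heading, zero angular speed, fresh switching time),
#' making successive loops independent and identically distributed.
#'
#' @inheritParams simulate_loop
#' @param duration trip duration, s.
#' @return A `bee_track` with attribute `loop_entries` (times of return-phase
#'   nest entries, s).
#' @export
simulate_trip <- function(params, duration = 900, nest = c(0, 0),
                          record_interval = params$dt) {
  stopifnot(duration > 0)
  every <- record_steps(record_interval, params$dt)
  res <- cpp_ptw_simulate(params$gamma, params$sigma, params$eta_star,
                          params$p_return, params$speed, params$dt,
                          params$nest_radius, params$max_loop_duration,
                          as.numeric(nest), duration, FALSE, every,
                          matrix(numeric(0), 0, 2), 0, 0L, 1L, Inf,
                          logical(0))
  tr <- bee_track(res$track[, 1], res$track[, 2], res$track[, 3],
                  sampling_interval = record_interval, nest = nest,
                  phase = res$phase)
  tr$loop_entries <- res$loop_entries
  tr
}

record_steps <- function(record_interval, dt) {
  every <- as.integer(round(record_interval / dt))
  if (every < 1L || abs(every * dt - record_interval) > 1e-9)
    stop("`record_interval` must be a positive multiple of `dt`")
  every
}

#' Simulate the angular-speed process alone
#'
#' Iterates the exact OU transition with zero target angular speed (pure
#' exploration), which is an AR(1) recursion; used to check the stationary
#' variance `sigma^2 / (2 * gamma)` of the turning dynamics.
#'
#' @param n number of retained steps.
#' @param params a [model_params()].
#' @param omega0 initial angular speed, rad/s.
#' @param burn_in steps discarded before recording.
#' @return Numeric vector of `n` angular speeds, rad/s.
#' @export
simulate_angular_speed <- function(n, params, omega0 = 0, burn_in = 0) {
  a <- exp(-params$gamma * params$dt)
  eps <- rnorm(n + burn_in, 0, ou_step_sd(params))
  om <- stats::filter(eps, a, method = "recursive", init = omega0)
  as.numeric(om)[(burn_in + 1):(burn_in + n)]
}
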