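#' Cart-pole environment constants
#'
#' The classic pole-balancing benchmark: a pole hinged to a cart that slides
#' on a frictionless track, controlled by a fixed-magnitude push left or
#' right at every timestep. Defaults follow the widely used published
#' specification of the task: gravity 9.8 m/s^2, cart mass 1 kg, pole mass
#' 0.1 kg, pole half-length 0.5 m, force 10 N, Euler integration at 0.02 s,
#' failure when |position| > 2.4 m or |angle| > 12 degrees.
#'
#' @param gravity,cart_mass,pole_mass,pole_half_length,force_mag Physical
#'   constants (SI units).
#' @param dt Integration timestep in seconds.
#' @param x_threshold Failure bound on cart position (m).
#' @param theta_threshold Failure bound on pole angle (rad).
#' @return A list of environment constants.
#' @export
cartpole_params <- function(gravity = 9.8, cart_mass = 1.0, pole_mass = 0.1,
                            pole_half_length = 0.5, force_mag = 10.0,
                            dt = 0.02, x_threshold = 2.4,
                            theta_threshold = 12 * pi / 180) {
  list(gravity = gravity, cart_mass = cart_mass, pole_mass = pole_mass,
       pole_half_length = pole_half_length, force_mag = force_mag,
       dt = dt, x_threshold = x_threshold, theta_threshold = theta_threshold)
}

#' Draw a cart-pole start state
#'
#' All four state variables (position, velocity, angle, angular velocity)
#' are perturbed uniformly in `(-0.05, 0.05)`, using R's RNG stream.
#'
#' @return Numeric state vector `c(x, x_dot, theta, theta_dot)`.
#' @export
cartpole_reset <- function() {
  stats::runif(4, min = -0.05, max = 0.05)
}

#' Advance the cart-pole one timestep
#'
#' Explicit Euler step of the standard cart-pole equations of motion:
#' positions are advanced with the current velocities, then velocities with
#' the accelerations computed from the pre-step state.
#'
#' @param state Numeric state vector `c(x, x_dot, theta, theta_dot)`.
#' @param action `1` = push left, `2` = push right.
#' @param params Environment constants from [cartpole_params()].
#' @return List with `state` (next state) and `terminal` (logical: a failure
#'   bound was exceeded).
#' @export
cartpole_step <- function(state, action, params = cartpole_params()) {
  if (!(action %in% c(1L, 2L))) {
    stop("`action` must be 1 (push left) or 2 (push right)", call. = FALSE)
  }
  x <- state[1]; x_dot <- state[2]; theta <- state[3]; theta_dot <- state[4]
  force <- if (action == 2L) params$force_mag else -params$force_mag
  total_mass <- params$cart_mass + params$pole_mass
  polemass_length <- params$pole_mass * params$pole_half_length
  cos_t <- cos(theta)
  sin_t <- sin(theta)
  temp <- (force + polemass_length * theta_dot^2 * sin_t) / total_mass
  theta_acc <- (params$gravity * sin_t - cos_t * temp) /
    (params$pole_half_length *
       (4 / 3 - params$pole_mass * cos_t^2 / total_mass))
  x_acc <- temp - polemass_length * theta_acc * cos_t / total_mass
  nxt <- c(x + params$dt * x_dot,
           x_dot + params$dt * x_acc,
           theta + params$dt * theta_dot,
           theta_dot + params$dt * theta_acc)
  terminal <- abs(nxt[1]) > params$x_threshold ||
    abs(nxt[3]) > params$theta_threshold
  list(state = nxt, terminal = terminal)
}

#' Fixed observation bounds for normalizing cart-pole state
#'
#' Velocities are unbounded in the dynamics, so they are clamped to fixed
#' bounds before min-max scaling; this keeps normalization stateless.
#' Bounds: position +/-2.4 m, velocity +/-3 m/s, angle +/-12 degrees,
#' angular velocity +/-3 rad/s.
#'
#' @return A 2 x 4 matrix with rows `low`, `high`.
#' @export
cartpole_obs_bounds <- function() {
  rbind(low = c(-2.4, -3, -12 * pi / 180, -3),
        high = c(2.4, 3, 12 * pi / 180, 3))
}

#' Clamp-then-scale a state vector to `[0, 1]`
#'
#' @param state Cart-pole state vector.
#' @param bounds Bounds matrix from [cartpole_obs_bounds()].
#' @return Normalized observation in `[0, 1]^4`.
#' @export
normalize_observation <- function(state, bounds = cartpole_obs_bounds()) {
  clamped <- pmin(pmax(state, bounds["low", ]), bounds["high", ])
  (clamped - bounds["low", ]) / (bounds["high", ] - bounds["low", ])
}
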