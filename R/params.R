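#' Model parameters for the prey movement model
#'
#' Bundles the kinematic and sensory constants of the self-propelled prey
#' model. Distances are measured in body diameters (`D`) and time in
#' simulation steps (one step = one rendered frame = 20 ms).
#'
#' @param v_star Expected optimum travel speed, D per step. The travel-cost
#'   function is zero here, so an isolated individual relaxes to this speed.
#' @param phi Cost scale of the travel-cost function; larger values mean
#'   stronger speed regulation towards `v_star`.
#' @param eta Noise magnitude in `[0, 1]`. Speed is perturbed by a uniform
#'   factor in `[1 - eta, 1 + eta]` and heading rotated by a uniform angle in
#'   `[-eta * pi / 2, eta * pi / 2]` each step.
#' @param v_min,v_max Hard speed bounds, D per step, applied after every
#'   full step.
#' @param turn_limit Maximum heading change per step, radians. Applied to the
#'   combined social + noise heading change.
#' @param dt Step duration (one frame); positions advance by
#'   `speed * heading * dt`.
#'
#' @return A list of class `"model_params"`.
#' @examples
#' p <- model_params()
#' p$v_star
#' @export
model_params <- function(v_star = 0.44, phi = 0.1, eta = 0.1,
                         v_min = 0.1, v_max = 1.5,
                         turn_limit = pi / 2, dt = 1) {
  stopifnot(
    "eta must lie in [0, 1]" = eta >= 0 && eta <= 1,
    "need 0 < v_min < v_star < v_max" =
      v_min > 0 && v_min < v_star && v_star < v_max,
    "turn_limit must be positive" = turn_limit > 0,
    "dt must be positive" = dt > 0,
    "phi must be non-negative" = phi >= 0
  )
  structure(
    list(v_star = v_star, phi = phi, eta = eta, v_min = v_min,
         v_max = v_max, turn_limit = turn_limit, dt = dt),
    class = "model_params"
  )
}

#' A single prey agent's state
#'
#' @param position Numeric length-2, position in body diameters.
#' @param speed Scalar speed, D per step.
#' @param heading Numeric length-2 direction; normalized to unit length.
#' @param m Social (motion) threshold: the Weber-law ratio a neighbour's
#'   apparent motion must reach, relative to the mean optic flow, to capture
#'   this agent's attention.
#' @param is_target Logical; whether this agent is the designated target.
#'
#' @return A list of class `"prey_state"`.
#' @examples
#' prey_state(c(0, 0), speed = 0.4, heading = c(1, 0))
#' @export
prey_state <- function(position, speed, heading, m = 1.5, is_target = FALSE) {
  stopifnot(all(is.finite(position)), length(position) == 2,
            is.finite(speed), speed >= 0, length(heading) == 2)
  nrm <- sqrt(sum(heading^2))
  if (nrm == 0) stop("heading must be a non-zero vector")
  structure(
    list(position = as.numeric(position), speed = as.numeric(speed),
         heading = as.numeric(heading) / nrm, m = m,
         is_target = isTRUE(is_target)),
    class = "prey_state"
  )
}

#' Scenario configuration for one trial
#'
#' Collects every parameter that defines a trial: group size, the social
#' thresholds of the target (`m_t`) and of its group members (`m_g`), the
#' target's initial escape factor `v_e` (applied over the first five frames),
#' the initial organization mode, the veiled rendering flag, the arena, and
#' the trial seed. The seed fully determines the trajectory, which is what
#' makes veiled/visible replay pairs possible.
#'
#' @param n Group size (default 25).
#' @param m_t,m_g Social thresholds of the target and of the other group
#'   members. The published design uses levels `c(0.5, 1.5, 2.5, 10)`.
#' @param v_e Target initial escape factor; the target's speed is multiplied
#'   by `v_e` on each of the first five steps (then clamped). `v_e = 1` is
#'   the identity; the published design uses `c(1, 10)`.
#' @param init_mode `"disordered"` (i.i.d. uniform headings) or `"ordered"`
#'   (one global heading plus individual wobble).
#' @param wobble Half-width in radians of the uniform heading wobble applied
#'   around the global direction under ordered starts.
#' @param veiled Logical; veiled trials hide the target's neighbours from the
#'   predator. The flag never enters the prey dynamics.
#' @param seed Integer trial seed; identical (seed, config) pairs replay
#'   bit-identical trajectories.
#' @param n_steps Number of simulation steps (frames) to run.
#' @param radius Radius in D of the centred disc in which agents are placed
#'   without overlap.
#' @param arena Numeric length-2, arena width and height in D (pixels at the
#'   published render scale).
#' @param init_speed Initial speed of every agent, D per step.
#' @param params A [model_params()] object.
#'
#' @return A list of class `"scenario_config"`.
#' @examples
#' cfg <- scenario_config(seed = 7, m_t = 2.5, m_g = 2.5)
#' cfg$v_e
#' @export
scenario_config <- function(n = 25, m_t = 1.5, m_g = 1.5, v_e = 1,
                            init_mode = c("disordered", "ordered"),
                            wobble = 0.175, veiled = FALSE, seed = 1L,
                            n_steps = 300L, radius = 15,
                            arena = c(1440, 900), init_speed = 0.1,
                            params = model_params()) {
  init_mode <- match.arg(init_mode)
  stopifnot(
    "n must be >= 1" = n >= 1,
    "v_e must be >= 1" = v_e >= 1,
    "wobble must be >= 0" = wobble >= 0,
    "thresholds must be >= 0" = m_t >= 0 && m_g >= 0,
    "arena must be two positive extents" =
      length(arena) == 2 && all(arena > 0),
    inherits(params, "model_params")
  )
  structure(
    list(n = as.integer(n), m_t = m_t, m_g = m_g, v_e = v_e,
         init_mode = init_mode, wobble = wobble, veiled = isTRUE(veiled),
         seed = as.integer(seed), n_steps = as.integer(n_steps),
         radius = radius, arena = as.numeric(arena),
         init_speed = init_speed, params = params),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  n = %d, m_t = %g, m_g = %g, v_e = %g\n",
              x$n, x$m_t, x$m_g, x$v_e))
  cat(sprintf("  init = %s (wobble %.3f rad), veiled = %s\n",
              x$init_mode, x$wobble, x$veiled))
  cat(sprintf("  seed = %d, n_steps = %d, arena = %g x %g D\n",
              x$seed, x$n_steps, x$arena[1], x$arena[2]))
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  v* = %g, phi = %g, eta = %g\n", x$v_star, x$phi, x$eta))
  cat(sprintf("  speed bounds [%g, %g] D/step, turn limit %.4g rad/step\n",
              x$v_min, x$v_max, x$turn_limit))
  invisible(x)
}
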