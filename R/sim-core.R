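#' Apparent-motion weight of one neighbour
#'
#' The influence a neighbour exerts on an observer is weighted by its
#' apparent (angular) motion: the magnitude of the relative velocity scaled
#' by distance, `omega = |v_j - v_i| / max(d_ij, D)` with the body diameter
#' `D = 1` serving as the minimum optical distance. A neighbour moving
#' identically to the observer generates no optic flow and has zero weight;
#' at fixed relative speed the weight decays with distance.
#'
#' @param observer,neighbor [prey_state()] objects (distinct agents).
#' @return Non-negative scalar weight (per step).
#' @examples
#' a <- prey_state(c(0, 0), 0.4, c(1, 0))
#' b <- prey_state(c(5, 0), 0.4, c(0, 1))
#' perceived_weight(a, b)
#' @export
perceived_weight <- function(observer, neighbor) {
  stopifnot(inherits(observer, "prey_state"), inherits(neighbor, "prey_state"))
  dv <- neighbor$speed * neighbor$heading - observer$speed * observer$heading
  d <- sqrt(sum((neighbor$position - observer$position)^2))
  sqrt(sum(dv^2)) / max(d, 1)
}

# Pairwise weight matrix: entry [j, i] is the apparent motion of neighbour j
# seen by observer i. Diagonal is zero and excluded from means.
perceived_weight_matrix <- function(pos, vel) {
  n <- nrow(pos)
  dx <- outer(pos[, 1], pos[, 1], "-")   # [j, i] = x_j - x_i
  dy <- outer(pos[, 2], pos[, 2], "-")
  d <- sqrt(dx^2 + dy^2)
  rvx <- outer(vel[, 1], vel[, 1], "-")
  rvy <- outer(vel[, 2], vel[, 2], "-")
  w <- sqrt(rvx^2 + rvy^2) / pmax(d, 1)
  diag(w) <- 0
  w
}

#' Neighbours standing out from the optic flow
#'
#' Filters an observer's perceived neighbours down to the set whose motion
#' cue is strong enough relative to the mean optic flow: neighbour `j` is
#' attended iff `w_j / mean(w) >= m`. This is a Weber-law signal-to-noise
#' rule: what matters is the cue's proportion of the background, not its
#' absolute size. When the field is degenerate (mean flow zero) nothing
#' stands out and the set is empty.
#'
#' @param weights Non-negative per-neighbour apparent-motion weights.
#' @param m Social threshold (`m >= 0`).
#' @return Integer indices into `weights` of the attended neighbours.
#' @examples
#' attention_set(c(2, 1, 1), m = 1.5)  # only the first stands out
#' @export
attention_set <- function(weights, m) {
  stopifnot(all(weights >= 0), m >= 0)
  if (length(weights) == 0) return(integer(0))
  wbar <- mean(weights)
  if (wbar == 0) return(integer(0))
  which(weights / wbar >= m)
}

#' Socially adjusted velocity
#'
#' Pools the relative motion that grabbed the observer's attention into a
#' velocity adjustment: the observer's own velocity plus the mean, over
#' attended neighbours, of each neighbour's direction unit vector scaled by
#' its apparent-motion weight. In the full model the direction is the
#' neighbour's motion relative to the observer, `unit(v_j - v_i)`, so the
#' pooled term seeks velocity consensus and vanishes once the group moves
#' as one. An empty attention set leaves the velocity unchanged (asocial
#' motion).
#'
#' @param velocity Observer's current velocity vector (speed times heading).
#' @param weights Per-neighbour weights, aligned with `headings` rows.
#' @param headings Matrix of per-neighbour direction unit vectors (one row
#'   each; relative-motion directions in the full model).
#' @param attended Integer indices of attended neighbours (e.g. from
#'   [attention_set()]).
#' @return Length-2 socially adjusted velocity.
#' @examples
#' social_velocity(c(0, 0.4), weights = 1, headings = rbind(c(1, 0)), 1L)
#' @export
social_velocity <- function(velocity, weights, headings, attended) {
  if (length(attended) == 0) return(velocity)
  w <- weights[attended]
  h <- headings[attended, , drop = FALSE]
  velocity + colMeans(w * h)
}

#' Travel cost of moving away from the optimum speed
#'
#' Signed cost of the current speed relative to the expected optimum
#' `v_star`: zero at the optimum, negative below it (the agent accelerates),
#' positive above it (the agent decelerates). The cost varies linearly with
#' speed, `gamma = phi * (v - v_star) / v_star`, clamped to (-0.9, 0.9) so
#' the multiplicative update can never reverse or null a velocity.
#'
#' @param speed Non-negative speed(s), D per step.
#' @param params A [model_params()] object.
#' @return Signed cost, same length as `speed`.
#' @examples
#' travel_cost(c(0.22, 0.44, 0.88), model_params())
#' @export
travel_cost <- function(speed, params = model_params()) {
  stopifnot(all(speed >= 0))
  pmin(pmax(params$phi * (speed - params$v_star) / params$v_star, -0.9), 0.9)
}

#' Cost-regulated velocity update
#'
#' Converts a socially adjusted velocity into the next step's speed and
#' heading: the speed is dampened multiplicatively by the travel cost,
#' `v' = |v_s| * (1 - gamma(|v_s|))`, then clamped to the speed bounds; the
#' heading turns towards the direction of `v_s`, with the change per step
#' clipped to the turning limit. A zero social velocity keeps the previous
#' heading and relaxes the speed from the lower bound.
#'
#' @param v_s Length-2 socially adjusted velocity.
#' @param heading_prev Previous heading unit vector (turn clamp reference).
#' @param params A [model_params()] object.
#' @param clamp_turn Apply the turning limit here (`TRUE` by default). The
#'   full stepper defers the clamp until after noise so that the limit binds
#'   the combined social + noise heading change.
#' @return List with elements `speed` and `heading`.
#' @examples
#' velocity_update(c(0, 0.5), heading_prev = c(0, 1))
#' @export
velocity_update <- function(v_s, heading_prev, params = model_params(),
                            clamp_turn = TRUE) {
  stopifnot(all(is.finite(v_s)))
  s <- sqrt(sum(v_s^2))
  if (s > 0) {
    speed <- s * (1 - travel_cost(s, params))
    heading <- v_s / s
  } else {
    speed <- params$v_min * (1 - travel_cost(params$v_min, params))
    heading <- heading_prev
  }
  if (clamp_turn) {
    heading <- clamp_heading(heading, heading_prev, params$turn_limit)
  }
  list(speed = min(max(speed, params$v_min), params$v_max), heading = heading)
}

# Rotate `from` towards `to` by at most `limit` radians.
clamp_heading <- function(to, from, limit) {
  delta <- atan2(to[2], to[1]) - atan2(from[2], from[1])
  delta <- atan2(sin(delta), cos(delta))
  delta <- max(min(delta, limit), -limit)
  theta <- atan2(from[2], from[1]) + delta
  c(cos(theta), sin(theta))
}

#' Stochastic perturbation of speed and heading
#'
#' Adds the per-step noise of the position update: speed is scaled by an
#' independent uniform factor in `[1 - eta, 1 + eta]` and the heading rotated
#' by an independent uniform angle in `[-eta * pi / 2, eta * pi / 2]`.
#' Vectorized over agents; draws come from the session RNG so seeded runs
#' replay exactly.
#'
#' @param speed Numeric speeds.
#' @param heading Matrix of heading unit vectors (one row per agent) or a
#'   single length-2 vector.
#' @param eta Noise magnitude in `[0, 1]`; `eta = 0` is the identity.
#' @return List with perturbed `speed` and `heading` (un-clamped).
#' @examples
#' set.seed(1)
#' apply_noise(0.4, c(1, 0), eta = 0.1)
#' @export
apply_noise <- function(speed, heading, eta) {
  stopifnot(eta >= 0, eta <= 1)
  if (is.null(dim(heading))) heading <- matrix(heading, nrow = 1)
  n <- length(speed)
  u1 <- runif(n)
  u2 <- runif(n)
  speed_new <- speed * (1 + eta * (2 * u1 - 1))
  ang <- eta * (pi / 2) * (2 * u2 - 1)
  theta <- atan2(heading[, 2], heading[, 1]) + ang
  list(speed = speed_new, heading = cbind(cos(theta), sin(theta)))
}

# Symmetric separation of overlapping pairs: any pair closer than one body
# diameter is pushed apart along the line of centres until exactly D apart.
# Pairs are visited in fixed (i < j) order so seeded runs replay exactly.
resolve_overlaps <- function(pos) {
  n <- nrow(pos)
  if (n < 2) return(pos)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      dx <- pos[j, 1] - pos[i, 1]
      dy <- pos[j, 2] - pos[i, 2]
      d <- sqrt(dx^2 + dy^2)
      if (d < 1) {
        if (d > 0) {
          ux <- dx / d
          uy <- dy / d
        } else {
          ux <- 1
          uy <- 0
        }
        push <- (1 - d) / 2
        pos[i, 1] <- pos[i, 1] - ux * push
        pos[i, 2] <- pos[i, 2] - uy * push
        pos[j, 1] <- pos[j, 1] + ux * push
        pos[j, 2] <- pos[j, 2] + uy * push
      }
    }
  }
  pos
}

#' Advance a prey group by one step (reference engine)
#'
#' One synchronous update of every agent: perception and attention are
#' computed in parallel from the time-t state, then each agent's socially
#' adjusted velocity is dampened by the travel cost, perturbed by noise, the
#' combined heading change is clipped to the turning limit, speeds are
#' clamped, positions advance, and overlapping pairs are separated. This is
#' the plain-R reference implementation; [simulate_trial()] uses a compiled
#' equivalent by default.
#'
#' @param group A group state as returned by [init_group()] (list with
#'   matrices `pos`, `heading`, vectors `speed`, `m`, and `target` index).
#' @param params A [model_params()] object.
#' @param escape_factor Multiplier applied to the target's post-update speed
#'   this step (the escape burst); 1 outside the burst window.
#' @param weight_fn Optional replacement for the apparent-motion weight:
#'   a function of (`pos`, `vel`) matrices returning the n x n weight matrix
#'   (entry `[j, i]` = weight of neighbour j seen by observer i, zero
#'   diagonal). The default is the distance-scaled relative speed used
#'   throughout the package; the hook exists so alternative optic-flow
#'   formulations can be swapped in at the reference-engine level.
#' @return The updated group state.
#' @export
step_prey <- function(group, params = model_params(), escape_factor = 1,
                      weight_fn = NULL) {
  pos <- group$pos
  heading <- group$heading
  speed <- group$speed
  m <- group$m
  n <- nrow(pos)
  vel <- speed * heading

  # social velocity for every agent from the synchronous time-t state.
  # The attended contribution omega_ji * dir(v_j - v_i) simplifies to
  # (v_j - v_i) / max(d_ij, 1): relative motion scaled by optical distance.
  vs <- vel
  if (n > 1) {
    default_w <- is.null(weight_fn)
    w <- if (default_w) perceived_weight_matrix(pos, vel)
         else weight_fn(pos, vel)
    wbar <- colSums(w) / (n - 1)
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    dclamp <- pmax(sqrt(dx^2 + dy^2), 1)
    for (i in seq_len(n)) {
      wi <- w[-i, i]
      att <- if (wbar[i] > 0) which(wi / wbar[i] >= m[i]) else integer(0)
      if (length(att) > 0) {
        dv <- sweep(vel[-i, , drop = FALSE], 2, vel[i, ])
        if (default_w) {
          # omega * unit(dv) collapses to dv / max(d, D)
          contrib <- dv[att, , drop = FALSE] / dclamp[-i, i][att]
        } else {
          nrm <- sqrt(rowSums(dv^2))
          u <- dv / ifelse(nrm > 0, nrm, 1)
          contrib <- wi[att] * u[att, , drop = FALSE]
        }
        vs[i, ] <- vel[i, ] + colMeans(contrib)
      }
    }
  }

  s <- sqrt(rowSums(vs^2))
  gamma <- travel_cost(pmax(s, 0), params)
  new_speed <- s * (1 - gamma)
  still <- s == 0
  if (any(still)) {
    new_speed[still] <- params$v_min * (1 - travel_cost(params$v_min, params))
  }
  theta_old <- atan2(heading[, 2], heading[, 1])
  theta_des <- ifelse(still, theta_old, atan2(vs[, 2], vs[, 1]))

  # noise, then the turn limit on the combined heading change
  u1 <- runif(n)
  u2 <- runif(n)
  new_speed <- new_speed * (1 + params$eta * (2 * u1 - 1))
  theta_new <- theta_des + params$eta * (pi / 2) * (2 * u2 - 1)
  delta <- atan2(sin(theta_new - theta_old), cos(theta_new - theta_old))
  delta <- pmin(pmax(delta, -params$turn_limit), params$turn_limit)
  theta <- theta_old + delta

  if (escape_factor != 1) {
    new_speed[group$target] <- new_speed[group$target] * escape_factor
  }
  new_speed <- pmin(pmax(new_speed, params$v_min), params$v_max)
  heading <- cbind(cos(theta), sin(theta))
  pos <- pos + new_speed * heading * params$dt
  pos <- resolve_overlaps(pos)

  list(pos = pos, heading = heading, speed = new_speed, m = m,
       target = group$target)
}

#' Simulate one trial's prey trajectory
#'
#' Runs the full seeded simulation for a scenario: the trial RNG is seeded
#' from `config$seed`, the target is designated, the group initialized, and
#' the group stepped `config$n_steps` times with the escape burst applied to
#' the target over the first five steps. Identical (seed, config) pairs give
#' bit-identical trajectories; the veiled flag never enters this code path.
#'
#' @param config A [scenario_config()] object.
#' @param engine `"cpp"` (compiled fast path, default) or `"r"` (reference
#'   stepper). Both consume the RNG stream in the same draw order.
#' @return A tibble of class `"prey_trajectory"` with one row per agent per
#'   recorded step: `step`, `agent`, `x`, `y`, `speed`, `heading_x`,
#'   `heading_y`, `is_target`. The scenario is attached as attribute
#'   `"config"`.
#' @examples
#' traj <- simulate_trial(scenario_config(n = 5, n_steps = 20, seed = 1))
#' dplyr::count(traj, step)
#' @export
simulate_trial <- function(config, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "scenario_config"))
  engine <- match.arg(engine)
  set.seed(config$seed)
  group <- init_group(config)
  params <- config$params
  n <- config$n
  n_steps <- config$n_steps

  if (engine == "cpp") {
    res <- cpp_simulate(group$pos, group$speed, group$heading, group$m,
                        group$target, n_steps, config$v_e, 5L,
                        params$v_star, params$phi, params$eta,
                        params$v_min, params$v_max, params$turn_limit,
                        params$dt)
    X <- res$x; Y <- res$y; S <- res$speed; HX <- res$hx; HY <- res$hy
  } else {
    X <- Y <- S <- HX <- HY <- matrix(0, n_steps + 1, n)
    X[1, ] <- group$pos[, 1]; Y[1, ] <- group$pos[, 2]
    S[1, ] <- group$speed
    HX[1, ] <- group$heading[, 1]; HY[1, ] <- group$heading[, 2]
    for (t in seq_len(n_steps)) {
      esc <- if (t <= 5) config$v_e else 1
      group <- step_prey(group, params, escape_factor = esc)
      X[t + 1, ] <- group$pos[, 1]; Y[t + 1, ] <- group$pos[, 2]
      S[t + 1, ] <- group$speed
      HX[t + 1, ] <- group$heading[, 1]; HY[t + 1, ] <- group$heading[, 2]
    }
  }

  out <- tibble::tibble(
    step = rep(0:n_steps, times = n),
    agent = rep(seq_len(n), each = n_steps + 1),
    x = as.vector(X), y = as.vector(Y), speed = as.vector(S),
    heading_x = as.vector(HX), heading_y = as.vector(HY),
    is_target = rep(seq_len(n) == group$target, each = n_steps + 1)
  )
  attr(out, "config") <- config
  class(out) <- c("prey_trajectory", class(out))
  out
}

#' @export
print.prey_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    cat(sprintf(
      "# prey_trajectory: n = %d agents, %d steps, seed = %d, m_t = %g, m_g = %g\n",
      cfg$n, cfg$n_steps, cfg$seed, cfg$m_t, cfg$m_g))
  }
  NextMethod()
}
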