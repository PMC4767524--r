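#' Initialize a prey group for a trial
#'
#' Builds the time-zero group state from a scenario: one member is designated
#' as the target (drawn uniformly from the trial RNG stream), headings are
#' assigned by the initial-organization mode, and positions are placed
#' without overlap (pairwise distance >= one body diameter) inside a centred
#' disc. Disordered starts draw i.i.d. uniform headings on `[0, 2*pi)`;
#' ordered starts share one global heading wobbled independently per agent by
#' a uniform angle in `[-wobble, +wobble]`. All agents start at the low
#' initial speed so the group accelerates up to its cruise speed.
#'
#' Draws come from the current RNG state: callers that need replay seed the
#' RNG first ([simulate_trial()] does this from `config$seed`).
#'
#' @param config A [scenario_config()] object.
#' @return A group state: list with `pos` (n x 2 matrix, arena-centred),
#'   `heading` (n x 2 unit rows), `speed`, `m` (target gets `m_t`, others
#'   `m_g`), and `target` (index).
#' @examples
#' set.seed(1)
#' g <- init_group(scenario_config(n = 10))
#' nrow(g$pos)
#' @export
init_group <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n
  target <- sample.int(n, 1)

  if (config$init_mode == "disordered") {
    theta <- runif(n, 0, 2 * pi)
  } else {
    global <- runif(1, 0, 2 * pi)
    theta <- global + runif(n, -config$wobble, config$wobble)
  }
  heading <- cbind(cos(theta), sin(theta))

  # non-overlapping placement: each disk of diameter 1 must fit the density
  density <- n * pi * 0.5^2 / (pi * config$radius^2)
  pos <- matrix(0, n, 2)
  centre <- config$arena / 2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(10000L)) {
      r <- config$radius * sqrt(runif(1))
      a <- runif(1, 0, 2 * pi)
      cand <- centre + r * c(cos(a), sin(a))
      if (i == 1) { ok <- TRUE } else {
        d2 <- (pos[seq_len(i - 1), 1] - cand[1])^2 +
          (pos[seq_len(i - 1), 2] - cand[2])^2
        ok <- all(d2 >= 1)
      }
      if (ok) { pos[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) {
      stop(sprintf(
        "cannot place %d non-overlapping agents in a disc of radius %g (packing density %.3f)",
        n, config$radius, density))
    }
  }

  m <- rep(config$m_g, n)
  m[target] <- config$m_t
  list(pos = pos, heading = heading, speed = rep(config$init_speed, n),
       m = m, target = target)
}

#' Apply the target's escape burst to a group state
#'
#' On each of the first five steps of a trial the target's speed is scaled by
#' the escape factor, `v_T(t) = v_e * v_T(t - dt)`, then clamped to the
#' maximum speed. Outside the burst window (or at `v_e = 1`) the group is
#' returned unchanged. [simulate_trial()] applies the same rule inside the
#' stepping loop; this operation exposes it for standalone use.
#'
#' @param group A group state (see [init_group()]).
#' @param config A [scenario_config()] object supplying `v_e` and the speed
#'   bounds.
#' @param step_index 1-based step number.
#' @return The group state with the target's speed scaled and clamped.
#' @examples
#' set.seed(1)
#' g <- init_group(scenario_config(n = 5, v_e = 10))
#' apply_escape_burst(g, scenario_config(n = 5, v_e = 10), 1)$speed
#' @export
apply_escape_burst <- function(group, config, step_index) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(group$target) || length(group$target) != 1) {
    stop("group has no designated target")
  }
  if (step_index >= 1 && step_index <= 5 && config$v_e != 1) {
    s <- group$speed[group$target] * config$v_e
    group$speed[group$target] <- min(s, config$params$v_max)
  }
  group
}

#' Build a veiled/visible replay pair
#'
#' Returns two scenario configurations sharing the seed and every dynamics
#' parameter, differing only in the veiled rendering flag. Because the seed
#' fully determines the prey dynamics and the flag never enters the dynamics
#' code path, the two trials replay bit-identical trajectories; only what the
#' predator is shown differs.
#'
#' @param config A [scenario_config()] object (its `veiled` flag is ignored).
#' @return Named list with elements `visible` and `veiled`.
#' @examples
#' pair <- make_veiled_pair(scenario_config(seed = 42))
#' identical(pair$visible$seed, pair$veiled$seed)
#' @export
make_veiled_pair <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  visible <- config
  visible$veiled <- FALSE
  veiled <- config
  veiled$veiled <- TRUE
  list(visible = visible, veiled = veiled)
}

#' Enumerate the full factorial trial design
#'
#' Builds the three-session factorial design of the targeting experiment:
#'
#' * Session I — homogeneous groups (`m_t = m_g`): escape factor
#'   `v_e` in \{1, 10\} x threshold m in \{0.5, 1.5, 2.5, 10\} x initial
#'   organization (16 cells).
#' * Session II — sensory heterogeneity: `m_t` x `m_g` (4 x 4) x initial
#'   organization at `v_e = 10` (32 cells). The 8 homogeneous cells coincide
#'   with session I cells and are counted once.
#' * Session III — veiled replicates of every session II cell (32 cells),
#'   each sharing its seed with the matching visible trial.
#'
#' With two replicates per unique cell this yields exactly 144 trial specs.
#' Seeds for visible trials are drawn from the player seed; veiled trials
#' copy the seed of their matching visible trial (same cell and replicate),
#' which is what enables seed replay. Presentation order is a seeded
#' permutation of all trials.
#'
#' @param player_seed Integer seed for per-player seed assignment and
#'   presentation order.
#' @param n_replicates Replicates per unique cell (published design: 2).
#' @param m_levels,v_e_levels,init_levels Factor levels; defaults are the
#'   published ones.
#' @return A tibble with one row per trial: `trial_id`, `session`, `m_t`,
#'   `m_g`, `v_e`, `init_mode`, `veiled`, `replicate`, `seed`, `order`.
#' @examples
#' design <- build_design(player_seed = 1)
#' nrow(design)  # 144
#' @export
build_design <- function(player_seed = 1L, n_replicates = 2L,
                         m_levels = c(0.5, 1.5, 2.5, 10),
                         v_e_levels = c(1, 10),
                         init_levels = c("disordered", "ordered")) {
  s1 <- tidyr::expand_grid(v_e = v_e_levels, m = m_levels,
                           init_mode = init_levels) |>
    dplyr::mutate(session = "I", m_t = .data$m, m_g = .data$m,
                  veiled = FALSE) |>
    dplyr::select(-"m")
  s2 <- tidyr::expand_grid(m_t = m_levels, m_g = m_levels,
                           init_mode = init_levels) |>
    dplyr::mutate(session = "II", v_e = max(v_e_levels), veiled = FALSE)
  # session I already covers the homogeneous high-escape cells
  s2 <- dplyr::anti_join(
    s2,
    dplyr::filter(s1, .data$v_e == max(v_e_levels)),
    by = c("m_t", "m_g", "v_e", "init_mode")
  )
  s3 <- tidyr::expand_grid(m_t = m_levels, m_g = m_levels,
                           init_mode = init_levels) |>
    dplyr::mutate(session = "III", v_e = max(v_e_levels), veiled = TRUE)

  cells <- dplyr::bind_rows(s1, s2, s3) |>
    dplyr::select("session", "m_t", "m_g", "v_e", "init_mode", "veiled")
  trials <- tidyr::expand_grid(cells,
                               replicate = seq_len(n_replicates))

  set.seed(player_seed)
  visible <- dplyr::filter(trials, !.data$veiled) |>
    dplyr::mutate(seed = sample.int(.Machine$integer.max,
                                    dplyr::n()))
  veiled <- dplyr::filter(trials, .data$veiled) |>
    dplyr::left_join(
      dplyr::select(visible, "m_t", "m_g", "v_e", "init_mode",
                    "replicate", "seed"),
      by = c("m_t", "m_g", "v_e", "init_mode", "replicate")
    )
  out <- dplyr::bind_rows(visible, veiled) |>
    dplyr::mutate(order = sample.int(dplyr::n()),
                  trial_id = seq_len(dplyr::n())) |>
    dplyr::arrange(.data$order) |>
    dplyr::select("trial_id", "session", "m_t", "m_g", "v_e",
                  "init_mode", "veiled", "replicate", "seed", "order")
  out
}

#' Turn one design row into a scenario configuration
#'
#' @param row One row of the tibble returned by [build_design()].
#' @param ... Further arguments passed to [scenario_config()] (e.g. `n`,
#'   `n_steps`, `params`).
#' @return A [scenario_config()] object.
#' @export
design_row_config <- function(row, ...) {
  scenario_config(m_t = row$m_t, m_g = row$m_g, v_e = row$v_e,
                  init_mode = row$init_mode, veiled = row$veiled,
                  seed = row$seed, ...)
}
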