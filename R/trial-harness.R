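#' Surrogate predator policy
#'
#' A scripted stand-in for the human player, used to exercise the trial
#' pipeline end to end. It is explicitly a synthetic test fixture, not a
#' model of human behaviour: the cursor pursues the target's position as it
#' appeared `visual_delay` ms ago (human visual response is roughly
#' 100-150 ms), after an initial `motor_delay` ms of immobility (roughly the
#' time to initiate a hand movement), with proportional-gain pursuit, a
#' bounded cursor speed, and seeded positional jitter.
#'
#' @param visual_delay_ms Perceptual lag applied to the pursued target
#'   position (default 125 ms; rounded to whole 20 ms frames).
#' @param motor_delay_ms Immobile period at trial start (default 300 ms).
#' @param gain Proportional pursuit gain per frame.
#' @param max_speed Cursor speed bound, pixels per frame.
#' @param click_radius Distance (pixels) to the perceived target position at
#'   which the predator clicks.
#' @param jitter Standard deviation (pixels) of seeded Gaussian cursor
#'   jitter per frame.
#' @return A list of class `"predator_policy"`.
#' @export
predator_policy <- function(visual_delay_ms = 125, motor_delay_ms = 300,
                            gain = 0.25, max_speed = 15, click_radius = 5,
                            jitter = 0.5) {
  stopifnot(visual_delay_ms >= 0, motor_delay_ms >= 0, gain > 0,
            max_speed > 0, click_radius >= 0, jitter >= 0)
  structure(
    list(visual_delay_ms = visual_delay_ms, motor_delay_ms = motor_delay_ms,
         gain = gain, max_speed = max_speed, click_radius = click_radius,
         jitter = jitter),
    class = "predator_policy"
  )
}

frame_ms <- 20

#' Run the surrogate predator over a prey trajectory
#'
#' Plays out the cursor path against a simulated trajectory, frame by frame
#' (one frame = 20 ms, the recording interval of cursor and prey). The trial
#' ends at the first of: a click (cursor within `click_radius` of the
#' perceived, delay-lagged target position), the target leaving the arena
#' (a miss, eligible for edge correction), or the trajectory running out
#' (a plain miss). Deterministic given the RNG state; [run_trial()] seeds
#' the whole trial from the scenario seed.
#'
#' @param trajectory A [simulate_trial()] tibble with a designated target.
#' @param policy A [predator_policy()].
#' @param arena Arena extents; defaults to the trajectory's scenario arena.
#' @param cursor_start Cursor start position; default bottom-centre of the
#'   arena.
#' @return A list of class `"prey_trial"`: `trajectory`, `cursor` tibble
#'   (`step`, `x`, `y`), `click` (list with `time_ms`, `x`, `y`) or `NULL`,
#'   `d_T` (click-to-target distance, pixels), `latency_ms`, `miss`,
#'   `target_exit_step`, `edge_corrected`.
#' @export
surrogate_predator <- function(trajectory, policy = predator_policy(),
                               arena = NULL, cursor_start = NULL) {
  cfg <- attr(trajectory, "config")
  if (is.null(arena)) {
    if (is.null(cfg)) stop("supply `arena` for trajectories without a config")
    arena <- cfg$arena
  }
  tgt <- trajectory |>
    dplyr::filter(.data$is_target) |>
    dplyr::arrange(.data$step)
  if (nrow(tgt) == 0) stop("trajectory has no designated target")
  n_steps <- max(tgt$step)
  vd <- round(policy$visual_delay_ms / frame_ms)
  md <- round(policy$motor_delay_ms / frame_ms)
  if (is.null(cursor_start)) cursor_start <- c(arena[1] / 2, arena[2] * 0.1)

  cur <- matrix(NA_real_, n_steps + 1, 2)
  cur[1, ] <- cursor_start
  click <- NULL
  d_T <- NA_real_
  latency_ms <- NA_real_
  miss <- TRUE
  exit_step <- NA_integer_
  end_step <- n_steps

  tx <- tgt$x
  ty <- tgt$y
  for (t in seq_len(n_steps)) {
    # target escaping off-screen ends the trial as a miss
    if (tx[t + 1] < 0 || tx[t + 1] > arena[1] ||
        ty[t + 1] < 0 || ty[t + 1] > arena[2]) {
      exit_step <- t
      end_step <- t
      cur[t + 1, ] <- cur[t, ]
      break
    }
    pos <- cur[t, ]
    if (t > md) {
      k <- max(t - vd, 0) + 1
      perceived <- c(tx[k], ty[k])
      v <- policy$gain * (perceived - pos)
      spd <- sqrt(sum(v^2))
      if (spd > policy$max_speed) v <- v * policy$max_speed / spd
      pos <- pos + v + policy$jitter * rnorm(2)
      if (sqrt(sum((pos - perceived)^2)) <= policy$click_radius) {
        cur[t + 1, ] <- pos
        click <- list(time_ms = t * frame_ms, x = pos[1], y = pos[2])
        d_T <- sqrt((pos[1] - tx[t + 1])^2 + (pos[2] - ty[t + 1])^2)
        latency_ms <- t * frame_ms
        miss <- FALSE
        end_step <- t
        break
      }
    }
    cur[t + 1, ] <- pos
  }

  cursor <- tibble::tibble(step = 0:end_step,
                           x = cur[seq_len(end_step + 1), 1],
                           y = cur[seq_len(end_step + 1), 2])
  structure(
    list(trajectory = trajectory, cursor = cursor, click = click,
         d_T = d_T, latency_ms = latency_ms, miss = miss,
         target_exit_step = exit_step, edge_corrected = FALSE,
         arena = arena),
    class = "prey_trial"
  )
}

#' @export
print.prey_trial <- function(x, ...) {
  cat("<prey_trial>\n")
  if (!x$miss) {
    cat(sprintf("  capture at %g ms, d_T = %.2f px%s\n", x$latency_ms, x$d_T,
                if (x$edge_corrected) " (edge-corrected)" else ""))
  } else {
    cat(sprintf("  miss%s\n",
                if (!is.na(x$target_exit_step)) {
                  sprintf(" (target exited at step %d)", x$target_exit_step)
                } else ""))
  }
  invisible(x)
}

#' Run one complete trial
#'
#' Seeds the trial RNG from the scenario seed, simulates the prey, and plays
#' the surrogate predator over the result. Veiled/visible pairs sharing a
#' seed therefore produce identical prey trajectories; the veiled flag only
#' changes what a renderer would show.
#'
#' @param config A [scenario_config()].
#' @param policy A [predator_policy()].
#' @param engine Simulation engine passed to [simulate_trial()].
#' @return A `"prey_trial"` record (see [surrogate_predator()]).
#' @export
run_trial <- function(config, policy = predator_policy(),
                      engine = c("cpp", "r")) {
  trajectory <- simulate_trial(config, engine = match.arg(engine))
  surrogate_predator(trajectory, policy)
}

#' Log capture latency
#'
#' @param record A `"prey_trial"` record with a click (possibly
#'   edge-corrected).
#' @return `P_L`, the natural log of the capture latency in ms; `NA` with a
#'   warning for an uncorrected miss.
#' @examples
#' exp(6.908)  # ~1000 ms
#' @export
capture_latency <- function(record) {
  if (is.null(record$click)) {
    warning("capture latency undefined for an uncorrected miss")
    return(NA_real_)
  }
  log(record$latency_ms)
}

#' Capture accuracy transform
#'
#' Normalized, log-scaled inverse of the click-to-target distance:
#' `P_A = 1 - log(d_T + 1) / max(log(d_T + 1))`, the max taken over the
#' analysis dataset. A direct hit scores 1; the worst recorded click scores
#' exactly 0. The normalizing max is attached as attribute `"max_log_d"`
#' and must travel with any saved scores for reproducibility.
#'
#' @param d_T Non-negative click-to-target distances (pixels) for the whole
#'   dataset over which the normalization is defined.
#' @return `P_A` values in `[0, 1]`, same length as `d_T`.
#' @examples
#' capture_accuracy(c(0, 9, 99))  # 1, 0.5, 0
#' @export
capture_accuracy <- function(d_T) {
  stopifnot(all(d_T >= 0, na.rm = TRUE))
  ld <- log(d_T + 1)
  mx <- max(ld, na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) {
    warning("all click distances are zero; accuracy set to 1 by convention")
    out <- rep(1, length(d_T))
    out[is.na(d_T)] <- NA_real_
    return(structure(out, max_log_d = 0))
  }
  structure(1 - ld / mx, max_log_d = mx)
}

#' Edge-effect correction of a missed trial
#'
#' When the target reaches the safety of the boundary before a click, the
#' raw record is a miss with no latency or distance. The correction scores
#' the trial at the boundary-crossing frame: the capture point becomes the
#' cursor position when the target crossed, the latency the crossing time,
#' and `d_T` the cursor-to-target distance at that frame. Records with a
#' genuine click, or plain misses where the target never exited, are
#' returned unchanged.
#'
#' @param record A `"prey_trial"` record.
#' @param arena Arena extents (defaults to the record's own).
#' @return The (possibly corrected) record.
#' @export
correct_edge_effects <- function(record, arena = NULL) {
  if (is.null(arena)) arena <- record$arena
  if (!record$miss || is.na(record$target_exit_step)) return(record)
  k <- record$target_exit_step
  tgt <- record$trajectory |>
    dplyr::filter(.data$is_target, .data$step == k)
  cur <- record$cursor[record$cursor$step == k, ]
  record$click <- list(time_ms = k * frame_ms, x = cur$x, y = cur$y)
  record$latency_ms <- k * frame_ms
  record$d_T <- sqrt((cur$x - tgt$x)^2 + (cur$y - tgt$y)^2)
  record$edge_corrected <- TRUE
  record$miss <- FALSE
  record
}

#' Score a set of trial records
#'
#' Applies edge correction, the log-latency transform, and the dataset-wide
#' accuracy normalization to a list of trial records.
#'
#' @param records List of `"prey_trial"` records.
#' @param edge_correct Apply [correct_edge_effects()] first (default TRUE).
#' @return A tibble with one row per record: `latency_ms`, `d_T`, `P_L`,
#'   `P_A`, `miss`, `edge_corrected`; the accuracy normalization constant is
#'   attached as attribute `"max_log_d"`.
#' @export
score_trials <- function(records, edge_correct = TRUE) {
  if (inherits(records, "prey_trial")) records <- list(records)
  if (edge_correct) records <- lapply(records, correct_edge_effects)
  latency <- vapply(records, function(r) {
    if (is.null(r$click)) NA_real_ else r$latency_ms
  }, numeric(1))
  d_T <- vapply(records, function(r) r$d_T, numeric(1))
  p_a <- capture_accuracy(d_T)
  out <- tibble::tibble(
    latency_ms = latency,
    d_T = d_T,
    P_L = log(latency),
    P_A = as.numeric(p_a),
    miss = vapply(records, function(r) r$miss, logical(1)),
    edge_corrected = vapply(records, function(r) r$edge_corrected, logical(1))
  )
  attr(out, "max_log_d") <- attr(p_a, "max_log_d")
  out
}
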