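#' Rendering scale of the published experiment
#'
#' Animations were rendered at 50 frames per second on a 110 pixels-per-inch
#' display, with one body diameter `D` equal to one pixel. These constants
#' convert model speeds (D per step) to on-screen speeds (cm per second).
#'
#' @param fps Frames per second (one step = one frame).
#' @param ppi Pixels per inch of the display.
#' @param d_px Pixels per body diameter.
#' @return A list of class `"render_scale"`.
#' @export
render_scale <- function(fps = 50, ppi = 110, d_px = 1) {
  stopifnot(fps > 0, ppi > 0, d_px > 0)
  structure(list(fps = fps, ppi = ppi, d_px = d_px), class = "render_scale")
}

#' Convert model speed to on-screen speed
#'
#' `v` body diameters per step become `v * d_px * fps / ppi * 2.54` cm per
#' second. At the published scale the speed floor 0.1 D/step renders at
#' 0.12 cm/s and the mean cruise speed 0.400 D/step at 0.46 cm/s.
#'
#' @param v Speed(s) in D per step.
#' @param scale A [render_scale()].
#' @return Speed(s) in cm per second (unrounded).
#' @examples
#' speed_to_cm_per_s(c(0.1, 0.4))
#' @export
speed_to_cm_per_s <- function(v, scale = render_scale()) {
  stopifnot(all(v >= 0))
  v * scale$d_px * scale$fps / scale$ppi * 2.54
}

#' Write / read a trajectory as delimited text
#'
#' One row per agent per step, columns `step`, `agent`, `x`, `y`, `speed`,
#' `heading_x`, `heading_y`, `is_target`.
#'
#' @param trajectory A trajectory tibble.
#' @param path File path (CSV).
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns the trajectory tibble.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory)[, c("step", "agent", "x", "y", "speed",
                                          "heading_x", "heading_y",
                                          "is_target")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  df$is_target <- as.logical(df$is_target)
  class(df) <- c("prey_trajectory", class(df))
  df
}

#' Write / read a trial design as delimited text
#'
#' @param design A [build_design()] tibble.
#' @param path File path (CSV).
#' @return `write_design()` returns `path` invisibly; `read_design()` the
#'   design tibble.
#' @export
write_design <- function(design, path) {
  write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  df$veiled <- as.logical(df$veiled)
  df
}

#' Write / read a scenario configuration (YAML or JSON)
#'
#' Round-trips a [scenario_config()] through a plain-text file; the format
#' is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `write_scenario_config()` returns `path` invisibly;
#'   `read_scenario_config()` the reconstructed config.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$params <- unclass(x$params)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  p <- x$params
  scenario_config(
    n = x$n, m_t = x$m_t, m_g = x$m_g, v_e = x$v_e,
    init_mode = x$init_mode, wobble = x$wobble, veiled = x$veiled,
    seed = x$seed, n_steps = x$n_steps, radius = x$radius,
    arena = unlist(x$arena), init_speed = x$init_speed,
    params = model_params(v_star = p$v_star, phi = p$phi, eta = p$eta,
                          v_min = p$v_min, v_max = p$v_max,
                          turn_limit = p$turn_limit, dt = p$dt)
  )
}

#' Run a batch of trials and write all artifacts
#'
#' Executes every row of a design: simulates the prey, runs the surrogate
#' predator, scores captures (with edge correction and the batch-wide
#' accuracy normalization), and computes the kinetic summary per trial.
#' Writes `scores.csv`, `metrics.csv`, optionally one trajectory CSV per
#' trial, and a `manifest.json` listing each artifact with its seed and MD5
#' hash. Re-running the same design into a fresh directory reproduces
#' identical hashes.
#'
#' @param design A [build_design()] tibble (or any subset of its rows).
#' @param out_dir Output directory (created if needed).
#' @param policy A [predator_policy()].
#' @param write_trajectories Also write per-trial trajectory CSVs.
#' @param ... Passed to [scenario_config()] for every trial (e.g. `n`,
#'   `n_steps`).
#' @return The manifest as a tibble (`trial_id`, `seed`, `status`, `file`,
#'   `md5`), invisibly also written to `manifest.json`. Trials that error
#'   are marked `status = "failed"` and do not abort the batch.
#' @export
run_batch <- function(design, out_dir, policy = predator_policy(),
                      write_trajectories = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- split(design, seq_len(nrow(design)))
  results <- purrr::map(rows, function(row) {
    tryCatch({
      cfg <- design_row_config(row, ...)
      rec <- run_trial(cfg, policy)
      # metrics over the trial as experienced: start to capture/miss
      ks <- kinetic_summary(rec$trajectory,
                            window = c(0, max(rec$cursor$step)))
      list(row = row, record = rec, kinetics = ks, ok = TRUE)
    }, error = function(e) list(row = row, error = conditionMessage(e),
                                ok = FALSE))
  })
  ok <- vapply(results, function(r) r$ok, logical(1))

  manifest <- tibble::tibble(trial_id = design$trial_id,
                             seed = design$seed,
                             status = ifelse(ok, "ok", "failed"),
                             file = NA_character_, md5 = NA_character_)
  files <- character(0)

  if (any(ok)) {
    scored <- score_trials(lapply(results[ok], function(r) r$record))
    scores <- dplyr::bind_cols(
      dplyr::bind_rows(lapply(results[ok], function(r) r$row)),
      scored
    )
    metrics <- dplyr::bind_cols(
      dplyr::select(scores, "trial_id"),
      dplyr::bind_rows(lapply(results[ok], function(r) r$kinetics))
    )
    scores_path <- file.path(out_dir, "scores.csv")
    metrics_path <- file.path(out_dir, "metrics.csv")
    write.csv(as.data.frame(scores), scores_path, row.names = FALSE)
    write.csv(as.data.frame(metrics), metrics_path, row.names = FALSE)
    files <- c(files, scores_path, metrics_path)
    if (write_trajectories) {
      traj_dir <- file.path(out_dir, "trajectories")
      dir.create(traj_dir, showWarnings = FALSE)
      for (r in results[ok]) {
        p <- file.path(traj_dir, sprintf("trial_%04d.csv", r$row$trial_id))
        write_trajectory(r$record$trajectory, p)
        i <- which(manifest$trial_id == r$row$trial_id)
        manifest$file[i] <- p
        manifest$md5[i] <- unname(tools::md5sum(p))
        files <- c(files, p)
      }
    }
  }

  hashes <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(
    list(n_trials = nrow(design), n_ok = sum(ok),
         seeds = design$seed, artifacts = hashes,
         failed = design$trial_id[!ok]),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  attr(manifest, "artifacts") <- hashes
  manifest
}
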