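#' Path tortuosity
#'
#' Dimensionless turning metric of a path: one minus the ratio of net
#' displacement (straight-line distance from start to finish) to total path
#' length. A perfectly straight path scores 0; a closed path that returns to
#' its start scores 1.
#'
#' @param path Two-column matrix or data frame of ordered positions
#'   (columns x, y), at the step-resolved sampling of the trajectory.
#' @return Scalar in `[0, 1]`.
#' @examples
#' tortuosity(cbind(0:5, 0))            # straight: 0
#' tortuosity(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))  # closed: 1
#' @export
tortuosity <- function(path) {
  path <- as.matrix(path)[, 1:2, drop = FALSE]
  stopifnot(nrow(path) >= 2, all(is.finite(path)))
  steps <- diff(path)
  total <- sum(sqrt(rowSums(steps^2)))
  if (total == 0) stop("tortuosity is undefined for a zero-length path")
  net <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
  1 - net / total
}

#' Collective order (polarization)
#'
#' Mean resultant length of the group's heading unit vectors,
#' `rho = |sum(h_i)| / n`: 1 for a perfectly aligned group, 0 for a fully
#' disordered one (e.g. headings in opposite pairs).
#'
#' @param headings Matrix with one heading unit vector per row. Non-unit
#'   rows are normalized with a warning.
#' @return Scalar in `[0, 1]`.
#' @examples
#' polarization(rbind(c(1, 0), c(1, 0)))   # 1
#' polarization(rbind(c(1, 0), c(-1, 0)))  # 0
#' @export
polarization <- function(headings) {
  headings <- as.matrix(headings)[, 1:2, drop = FALSE]
  stopifnot(nrow(headings) >= 1, all(is.finite(headings)))
  nrm <- sqrt(rowSums(headings^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    if (any(nrm == 0)) stop("zero heading vector cannot be normalized")
    warning("non-unit headings normalized")
    headings <- headings / nrm
  }
  sqrt(sum(colMeans(headings)^2))
}

# Clip a convex polygon (vertex matrix, counter-clockwise) by the half-plane
# a*x + b*y <= c (Sutherland-Hodgman step). Returns the clipped vertex set.
clip_halfplane <- function(poly, a, b, cc) {
  nv <- nrow(poly)
  if (nv == 0) return(poly)
  out <- matrix(0, nv + 4, 2)
  k <- 0
  for (i in seq_len(nv)) {
    p <- poly[i, ]
    q <- poly[if (i == nv) 1 else i + 1, ]
    fp <- a * p[1] + b * p[2] - cc
    fq <- a * q[1] + b * q[2] - cc
    if (fp <= 0) { k <- k + 1; out[k, ] <- p }
    if ((fp < 0) != (fq < 0) && fp != fq) {
      tpar <- fp / (fp - fq)
      k <- k + 1
      out[k, ] <- p + tpar * (q - p)
    }
  }
  out[seq_len(k), , drop = FALSE]
}

polygon_area <- function(poly) {
  nv <- nrow(poly)
  if (nv < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nv, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Voronoi cell areas clipped to the arena
#'
#' Area of each site's Voronoi cell — the region of the arena closer to that
#' site than to any other — computed by clipping the arena rectangle by the
#' perpendicular-bisector half-plane of every other site. Cells tile the
#' arena exactly, so the areas sum to the arena area. Coincident sites are
#' perturbed by 1e-9 with a warning so every cell is well defined.
#'
#' @param positions Two-column matrix of site positions.
#' @param arena Numeric length-2 (width, height); the arena is the rectangle
#'   `[0, width] x [0, height]`.
#' @return Numeric vector of cell areas, one per site.
#' @examples
#' voronoi_cell_areas(rbind(c(25, 50), c(75, 50)), arena = c(100, 100))
#' @export
voronoi_cell_areas <- function(positions, arena) {
  positions <- as.matrix(positions)[, 1:2, drop = FALSE]
  stopifnot(nrow(positions) >= 1, all(is.finite(arena)), all(arena > 0))
  n <- nrow(positions)
  if (n > 1) {
    d <- as.matrix(stats::dist(positions))
    diag(d) <- Inf
    if (any(d < 1e-12)) {
      warning("coincident sites perturbed by 1e-9")
      dup <- which(apply(d < 1e-12, 1, any))
      positions[dup, ] <- positions[dup, ] +
        1e-9 * cbind(seq_along(dup), -seq_along(dup))
    }
  }
  rect <- rbind(c(0, 0), c(arena[1], 0), arena, c(0, arena[2]))
  vapply(seq_len(n), function(i) {
    poly <- rect
    for (j in seq_len(n)) {
      if (j == i) next
      # keep points at least as close to i as to j:
      # 2 (p_j - p_i) . x <= |p_j|^2 - |p_i|^2
      a <- 2 * (positions[j, 1] - positions[i, 1])
      b <- 2 * (positions[j, 2] - positions[i, 2])
      cc <- sum(positions[j, ]^2) - sum(positions[i, ]^2)
      poly <- clip_halfplane(poly, a, b, cc)
      if (nrow(poly) < 3) break
    }
    polygon_area(poly)
  }, numeric(1))
}

#' Voronoi polygon area of the target
#'
#' The target's personal space: every point of its Voronoi cell is closer to
#' the target than to any neighbour, so the clipped cell area measures its
#' spatial isolation — and its exposure to a predator.
#'
#' @inheritParams voronoi_cell_areas
#' @param target_index Which site is the target.
#' @return Scalar cell area.
#' @export
voronoi_area <- function(positions, target_index, arena) {
  voronoi_cell_areas(positions, arena)[target_index]
}

#' Mean nearest-neighbour distance
#'
#' @param positions Two-column matrix of positions (at least two).
#' @return Mean over agents of the distance to the nearest other agent.
#' @examples
#' mean_nnd(rbind(c(0, 0), c(5, 0)))  # 5
#' @export
mean_nnd <- function(positions) {
  positions <- as.matrix(positions)[, 1:2, drop = FALSE]
  if (nrow(positions) < 2) stop("mean_nnd needs at least two positions")
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Per-frame kinetic series of a trajectory
#'
#' Frame-resolved versions of the windowed metrics: group mean speed,
#' polarization, mean nearest-neighbour distance, the target's speed, and
#' the target's Voronoi polygon area, for every step in the window.
#'
#' @param trajectory A [simulate_trial()] tibble (or any tibble with the same
#'   columns).
#' @param window Integer length-2 step range (inclusive); default the whole
#'   trajectory.
#' @param arena Arena extents for Voronoi clipping; defaults to the
#'   trajectory's scenario arena.
#' @return A tibble with columns `step`, `v_T`, `vpa`, `v_G`, `rho`, `nnd`.
#' @export
kinetic_series <- function(trajectory, window = NULL, arena = NULL) {
  cfg <- attr(trajectory, "config")
  if (is.null(arena)) {
    if (is.null(cfg)) stop("supply `arena` for trajectories without a config")
    arena <- cfg$arena
  }
  steps <- sort(unique(trajectory$step))
  if (is.null(window)) window <- range(steps)
  keep <- steps[steps >= window[1] & steps <= window[2]]
  if (length(keep) == 0) stop("empty analysis window")

  df <- dplyr::filter(trajectory, .data$step %in% keep)
  per_frame <- df |>
    dplyr::group_by(.data$step) |>
    dplyr::group_map(function(g, key) {
      tgt <- which(g$is_target)
      tibble::tibble(
        step = key$step,
        v_T = if (length(tgt) == 1) g$speed[tgt] else NA_real_,
        vpa = if (length(tgt) == 1) {
          voronoi_area(cbind(g$x, g$y), tgt, arena)
        } else NA_real_,
        v_G = mean(g$speed),
        rho = polarization(cbind(g$heading_x, g$heading_y)),
        nnd = if (nrow(g) > 1) mean_nnd(cbind(g$x, g$y)) else NA_real_
      )
    }) |>
    dplyr::bind_rows()
  per_frame
}

#' Windowed kinetic summary of a trajectory
#'
#' The per-trial metric set: target mean speed `v_T`, target path tortuosity
#' `tor`, target Voronoi polygon area `vpa`, group mean speed `v_G`,
#' collective order `rho`, and mean nearest-neighbour distance `nnd`, each
#' averaged over the frames of the analysis window (tortuosity is computed
#' on the target's step-resolved path across the window). A stationary
#' target has undefined tortuosity; the summary then carries `tor = NA` and
#' `tor_defined = FALSE` instead of failing.
#'
#' @inheritParams kinetic_series
#' @return A one-row tibble with the six metrics, `tor_defined`, and the
#'   window bounds; the per-frame series is attached as attribute
#'   `"series"`.
#' @examples
#' traj <- simulate_trial(scenario_config(n = 5, n_steps = 30, seed = 2))
#' kinetic_summary(traj)
#' @export
kinetic_summary <- function(trajectory, window = NULL, arena = NULL) {
  series <- kinetic_series(trajectory, window = window, arena = arena)
  tgt_path <- trajectory |>
    dplyr::filter(.data$is_target,
                  .data$step >= min(series$step),
                  .data$step <= max(series$step)) |>
    dplyr::arrange(.data$step)
  tor <- NA_real_
  tor_defined <- FALSE
  if (nrow(tgt_path) >= 2) {
    tor <- tryCatch(tortuosity(cbind(tgt_path$x, tgt_path$y)),
                    error = function(e) NA_real_)
    tor_defined <- !is.na(tor)
  }
  out <- tibble::tibble(
    v_T = mean(series$v_T), tor = tor, vpa = mean(series$vpa),
    v_G = mean(series$v_G), rho = mean(series$rho), nnd = mean(series$nnd),
    tor_defined = tor_defined,
    window_start = min(series$step), window_end = max(series$step)
  )
  attr(out, "series") <- series
  out
}
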