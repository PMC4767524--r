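# Small shared fixtures, all built in code.

small_config <- function(seed = 1L, n = 10L, n_steps = 50L, ...) {
  scenario_config(n = n, n_steps = n_steps, seed = seed, ...)
}

# hand-built 3-agent, 10-step trajectory used for spreadsheet-style
# recomputation of the kinetic metrics
toy_trajectory <- function() {
  steps <- 0:9
  agents <- list(
    # target: unit steps along x
    data.frame(agent = 1, step = steps, x = steps, y = 0,
               speed = 1, heading_x = 1, heading_y = 0, is_target = TRUE),
    # diagonal mover
    data.frame(agent = 2, step = steps, x = 3 + 0.5 * steps,
               y = 4 + 0.5 * steps, speed = sqrt(0.5),
               heading_x = 1 / sqrt(2), heading_y = 1 / sqrt(2),
               is_target = FALSE),
    # slow mover along y
    data.frame(agent = 3, step = steps, x = 10, y = 2 + 0.2 * steps,
               speed = 0.2, heading_x = 0, heading_y = 1, is_target = FALSE)
  )
  out <- tibble::as_tibble(do.call(rbind, agents))
  class(out) <- c("prey_trajectory", class(out))
  out
}
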