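test_that("log-latency transform brackets the published trial durations", {
  rec <- list(click = list(time_ms = 1000), latency_ms = 1000, miss = FALSE)
  expect_equal(capture_latency(rec), log(1000))
  expect_equal(capture_latency(rec), 6.908, tolerance = 1e-4)
  # the printed latency range endpoints on the log scale
  expect_equal(log(493), 6.2, tolerance = 0.01)
  expect_equal(log(4447), 8.4, tolerance = 0.01)
  # equal latencies map to equal P_L
  rec2 <- list(click = list(time_ms = 1000), latency_ms = 1000, miss = FALSE)
  expect_identical(capture_latency(rec), capture_latency(rec2))
  # an uncorrected miss has no latency
  expect_warning(p <- capture_latency(list(click = NULL)), "miss")
  expect_true(is.na(p))
})

test_that("accuracy transform is normalized, bounded and anti-monotone", {
  # direct hit scores 1, worst click scores exactly 0, {0, 9, 99} -> 0.5
  p <- capture_accuracy(c(0, 9, 99))
  expect_equal(as.numeric(p), c(1, 0.5, 0))
  expect_equal(attr(p, "max_log_d"), log(100))
  # anti-monotone in d_T within a dataset
  set.seed(21)
  d <- sort(runif(50, 0, 500))
  pa <- as.numeric(capture_accuracy(d))
  expect_true(all(diff(pa) <= 0))
  expect_true(all(pa >= 0 & pa <= 1))
  # all-zero distances fall back to 1 with a warning
  expect_warning(p0 <- capture_accuracy(c(0, 0)))
  expect_equal(as.numeric(p0), c(1, 1))
})

test_that("surrogate predator captures a pursuable target deterministically", {
  cfg <- scenario_config(n = 6, seed = 101, n_steps = 250, arena = c(200, 200),
                         radius = 8)
  policy <- predator_policy(jitter = 0)
  set.seed(1)
  rec1 <- run_trial(cfg, policy)
  set.seed(1)
  rec2 <- run_trial(cfg, policy)
  expect_false(rec1$miss)
  expect_identical(rec1$latency_ms, rec2$latency_ms)
  expect_identical(rec1$d_T, rec2$d_T)
  # cursor is sampled on the native one-frame (20 ms) grid
  expect_equal(diff(rec1$cursor$step), rep(1, nrow(rec1$cursor) - 1))
  # motor delay keeps the cursor immobile at first
  md <- round(policy$motor_delay_ms / 20)
  first <- rec1$cursor[rec1$cursor$step <= md, ]
  expect_true(all(first$x == first$x[1] & first$y == first$y[1]))
})

test_that("degenerate pursuit of a stationary target is an immediate hit", {
  # target frozen at the cursor start position, zero delays and jitter
  steps <- 0:50
  tr <- tibble::tibble(step = steps, agent = 1L, x = 50, y = 10, speed = 0,
                       heading_x = 1, heading_y = 0, is_target = TRUE)
  class(tr) <- c("prey_trajectory", class(tr))
  policy <- predator_policy(visual_delay_ms = 0, motor_delay_ms = 0,
                            gain = 1, max_speed = 1e6, click_radius = 5,
                            jitter = 0)
  rec <- surrogate_predator(tr, policy, arena = c(100, 100),
                            cursor_start = c(50, 10))
  expect_false(rec$miss)
  expect_equal(rec$latency_ms, 20)
  expect_equal(rec$d_T, 0)
})

test_that("a target outrunning the cursor is flagged a miss at the boundary", {
  steps <- 0:100
  tr <- tibble::tibble(step = steps, agent = 1L, x = 50 + 1.5 * steps, y = 50,
                       speed = 1.5, heading_x = 1, heading_y = 0,
                       is_target = TRUE)
  class(tr) <- c("prey_trajectory", class(tr))
  policy <- predator_policy(gain = 0.01, max_speed = 0.2, jitter = 0)
  rec <- surrogate_predator(tr, policy, arena = c(100, 100),
                            cursor_start = c(5, 95))
  expect_true(rec$miss)
  expect_false(is.na(rec$target_exit_step))

  # edge correction scores the trial at the boundary-crossing frame
  fixed <- correct_edge_effects(rec)
  expect_true(fixed$edge_corrected)
  expect_false(fixed$miss)
  k <- rec$target_exit_step
  expect_equal(fixed$latency_ms, k * 20)
  cur <- rec$cursor[rec$cursor$step == k, ]
  tgt <- dplyr::filter(tr, step == k)
  expect_equal(fixed$d_T, sqrt((cur$x - tgt$x)^2 + (cur$y - tgt$y)^2))

  # a record with a genuine click is untouched
  cfg <- scenario_config(n = 6, seed = 101, n_steps = 250,
                         arena = c(200, 200), radius = 8)
  hit <- run_trial(cfg, predator_policy(jitter = 0))
  expect_identical(correct_edge_effects(hit), hit)

  # a plain miss with the target still on-screen stays a miss
  tr2 <- tibble::tibble(step = 0:20, agent = 1L, x = 50, y = 50, speed = 0,
                        heading_x = 1, heading_y = 0, is_target = TRUE)
  class(tr2) <- c("prey_trajectory", class(tr2))
  never <- surrogate_predator(tr2, predator_policy(motor_delay_ms = 1e5),
                              arena = c(100, 100))
  expect_true(correct_edge_effects(never)$miss)
})

test_that("longer visual delays do not speed up capture", {
  latency_at <- function(vd) {
    mean(vapply(1:8, function(s) {
      cfg <- scenario_config(n = 6, seed = 700 + s, n_steps = 300,
                             arena = c(200, 200), radius = 8)
      rec <- run_trial(cfg, predator_policy(visual_delay_ms = vd,
                                            jitter = 0))
      if (is.null(rec$click)) 300 * 20 else rec$latency_ms
    }, numeric(1)))
  }
  expect_lte(latency_at(40), latency_at(400))
})

test_that("scoring a batch of records applies both transforms coherently", {
  recs <- lapply(1:5, function(s) {
    cfg <- scenario_config(n = 6, seed = 800 + s, n_steps = 250,
                           arena = c(200, 200), radius = 8)
    run_trial(cfg, predator_policy(jitter = 0))
  })
  sc <- score_trials(recs)
  expect_equal(nrow(sc), 5)
  captured <- !sc$miss
  expect_true(all(sc$P_L[captured] == log(sc$latency_ms[captured])))
  expect_true(all(sc$P_A[captured] >= 0 & sc$P_A[captured] <= 1))
  # the worst recorded distance anchors the accuracy scale at 0
  expect_equal(min(sc$P_A, na.rm = TRUE), 0)
  expect_true(is.numeric(attr(sc, "max_log_d")))
})

test_that("veiled and visible paired trials yield identical prey paths", {
  pair <- make_veiled_pair(scenario_config(n = 10, seed = 55, n_steps = 120,
                                           arena = c(300, 300)))
  pol <- predator_policy(jitter = 0)
  rec_vis <- run_trial(pair$visible, pol)
  rec_vei <- run_trial(pair$veiled, pol)
  expect_identical(rec_vis$trajectory$x, rec_vei$trajectory$x)
  expect_identical(rec_vis$trajectory$speed, rec_vei$trajectory$speed)
})
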