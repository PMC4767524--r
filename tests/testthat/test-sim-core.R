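test_that("perceived weight is apparent motion over clamped distance", {
  mk <- function(pos, speed, heading) prey_state(pos, speed, heading)
  # zero relative motion gives zero weight at any distance
  a <- mk(c(0, 0), 0.4, c(1, 0))
  for (d in c(0.3, 1, 7)) {
    expect_identical(perceived_weight(a, mk(c(d, 0), 0.4, c(1, 0))), 0)
  }
  # relative speed 0.5 at distance 5 -> 0.1
  b <- mk(c(5, 0), 0.9, c(1, 0))
  expect_equal(perceived_weight(a, b), 0.1)
  # denominator clamps at one body diameter below distance 1
  b_close <- mk(c(0.5, 0), 0.9, c(1, 0))
  expect_equal(perceived_weight(a, b_close), 0.5)
  # weight decreases with distance at fixed relative speed
  w <- vapply(c(2, 4, 8, 16), function(d) {
    perceived_weight(a, mk(c(d, 0), 0.9, c(1, 0)))
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("attention set follows the Weber ratio rule", {
  # m = 0 admits every perceived neighbour when flow is non-degenerate
  expect_identical(attention_set(c(0.2, 0.5, 1), m = 0), 1:3)
  # weights {2, 1, 1}: only the strong cue reaches 1.5x the mean flow
  expect_identical(attention_set(c(2, 1, 1), m = 1.5), 1L)
  # degenerate flow -> empty set
  expect_identical(attention_set(c(0, 0, 0), m = 0), integer(0))
  expect_identical(attention_set(numeric(0), m = 1), integer(0))
})

test_that("attention set shrinks monotonically in m for a fixed field", {
  set.seed(42)
  for (rep in 1:20) {
    w <- runif(15, 0, 2)
    sizes <- vapply(c(0, 0.5, 1, 1.5, 2.5, 5, 10),
                    function(m) length(attention_set(w, m)), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("social velocity pools attended relative motion", {
  # empty set: no social term
  expect_equal(
    social_velocity(c(0, 0.4), numeric(0), matrix(0, 0, 2), integer(0)),
    c(0, 0.4))
  # one attended neighbour with omega = 1 and direction (1, 0)
  expect_equal(
    social_velocity(c(0, 0.4), 1, rbind(c(1, 0)), 1L), c(1, 0.4))
  # equal weights with opposite directions cancel
  expect_equal(
    social_velocity(c(0, 0.4), c(0.7, 0.7), rbind(c(1, 0), c(-1, 0)), 1:2),
    c(0, 0.4))
})

test_that("travel cost is zero at v*, linear and signed around it", {
  p <- model_params()
  expect_identical(travel_cost(0.44, p), 0)
  expect_equal(travel_cost(0.88, p), 0.1)
  expect_equal(travel_cost(0.22, p), -0.05)
  # below v* the agent accelerates, above it decelerates
  expect_true(travel_cost(0.2, p) < 0)
  expect_true(travel_cost(1.2, p) > 0)
  # clamp keeps the dampening factor meaningful at extreme speeds
  expect_lt(abs(travel_cost(100, p)), 1)
})

test_that("isolated agent relaxes to the optimum speed", {
  p <- model_params(eta = 0)
  # fixed point
  up <- velocity_update(0.44 * c(1, 0), c(1, 0), p)
  expect_equal(up$speed, 0.44)
  # strictly increasing relaxation from the speed floor
  v <- 0.1
  seen <- v
  for (i in 1:200) {
    v <- velocity_update(v * c(1, 0), c(1, 0), p)$speed
    seen <- c(seen, v)
  }
  expect_true(all(diff(seen) > 0 | abs(seen[-1] - 0.44) < 1e-12))
  expect_lt(abs(v - 0.44), 0.001)
})

test_that("heading change per step is clipped to the turn limit", {
  p <- model_params()
  # requested reversal (pi) is cut to pi/2
  up <- velocity_update(c(-0.4, 0), heading_prev = c(1, 0), p)
  ang <- acos(sum(up$heading * c(1, 0)))
  expect_equal(ang, pi / 2)
  # zero social velocity keeps the heading
  up0 <- velocity_update(c(0, 0), heading_prev = c(0, 1), p)
  expect_equal(up0$heading, c(0, 1))
})

test_that("noise respects its stated bounds and law", {
  # eta = 0 is the identity
  set.seed(1)
  res <- apply_noise(0.4, c(1, 0), eta = 0)
  expect_equal(res$speed, 0.4)
  expect_equal(as.numeric(res$heading), c(1, 0))
  # eta = 0.1 keeps perturbed speeds within +-10%
  set.seed(2)
  res <- apply_noise(rep(0.4, 5000), matrix(c(1, 0), 5000, 2, byrow = TRUE),
                     eta = 0.1)
  expect_true(all(res$speed >= 0.36 & res$speed <= 0.44))
  # eta = 1: rotation angles uniform on [-pi/2, pi/2]
  set.seed(3)
  res <- apply_noise(rep(1, 1e5), matrix(c(1, 0), 1e5, 2, byrow = TRUE),
                     eta = 1)
  ang <- atan2(res$heading[, 2], res$heading[, 1])
  expect_true(all(ang >= -pi / 2 - 1e-12 & ang <= pi / 2 + 1e-12))
  ks <- max(abs(sort((ang + pi / 2) / pi) - (seq_along(ang) / length(ang))))
  expect_lt(ks, 0.01)
})

test_that("single-agent kinematics advance position by speed * heading", {
  # at the optimum speed and zero noise the step is exactly (v*, 0)
  p <- model_params(eta = 0, v_star = 0.4)
  g <- list(pos = rbind(c(0, 0)), heading = rbind(c(1, 0)), speed = 0.4,
            m = 1.5, target = 1L)
  g2 <- step_prey(g, p)
  expect_equal(as.numeric(g2$pos), c(0.4, 0))
  g3 <- step_prey(g2, p)
  expect_equal(as.numeric(g3$pos), c(0.8, 0))
})

test_that("seeded trials replay bit-identically and engines agree", {
  cfg <- small_config(seed = 77, n = 12, n_steps = 60)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  expect_identical(t1$speed, t2$speed)
  tr <- simulate_trial(cfg, engine = "r")
  expect_equal(t1$x, tr$x, tolerance = 1e-9)
  expect_equal(t1$speed, tr$speed, tolerance = 1e-9)
  # different seeds differ
  t3 <- simulate_trial(small_config(seed = 78, n = 12, n_steps = 60))
  expect_false(identical(t1$x, t3$x))
})

test_that("full-step invariants hold along a simulated trial", {
  cfg <- small_config(seed = 5, n = 15, n_steps = 80)
  tr <- simulate_trial(cfg)
  p <- cfg$params
  expect_true(all(is.finite(tr$x) & is.finite(tr$y)))
  after <- dplyr::filter(tr, step > 0)
  expect_true(all(after$speed >= p$v_min - 1e-12 &
                    after$speed <= p$v_max + 1e-12))
  nrm <- sqrt(tr$heading_x^2 + tr$heading_y^2)
  expect_true(all(abs(nrm - 1) < 1e-9))
  # overlap resolution keeps pairwise distances at >= one body diameter
  last <- dplyr::filter(tr, step == max(step))
  d <- stats::dist(cbind(last$x, last$y))
  expect_true(all(d >= 1 - 1e-9))
})

test_that("speeds converge to v* without noise and stay near it with noise", {
  for (m in c(0, 1.5, 10)) {
    cfg <- scenario_config(n = 10, m_t = m, m_g = m, seed = 40 + m,
                           n_steps = 500,
                           params = model_params(eta = 0))
    tr <- simulate_trial(cfg)
    last <- dplyr::filter(tr, step == 500)
    expect_true(all(abs(last$speed - 0.44) < 1e-3),
                label = sprintf("eta=0 convergence at m=%g", m))
  }
  # with noise the long-run mean sits within 0.02 of v*
  sp <- vapply(1:20, function(s) {
    tr <- simulate_trial(scenario_config(n = 10, m_t = 1.5, m_g = 1.5,
                                         seed = 900 + s, n_steps = 400))
    mean(dplyr::filter(tr, step > 300)$speed)
  }, numeric(1))
  expect_lt(abs(mean(sp) - 0.44), 0.02)
})

test_that("steady-state polarization is higher for attentive prey", {
  rho_at <- function(m, seeds) {
    vapply(seeds, function(s) {
      tr <- simulate_trial(scenario_config(n = 25, m_t = m, m_g = m,
                                           seed = s, n_steps = 300))
      g <- dplyr::filter(tr, step == 300)
      polarization(cbind(g$heading_x, g$heading_y))
    }, numeric(1))
  }
  seeds <- 1:200
  r15 <- rho_at(1.5, seeds)
  r10 <- rho_at(10, 1000 + seeds)
  expect_gt(mean(r15) - mean(r10), 0.1)
})

test_that("social averaging delays departure, dampened under ordered starts", {
  lag_of <- function(m, init, seeds) {
    vapply(seeds, function(s) {
      tr <- simulate_trial(scenario_config(n = 25, m_t = m, m_g = m,
                                           init_mode = init, seed = s,
                                           n_steps = 250))
      gs <- tapply(tr$speed, tr$step, mean)
      hit <- which(gs >= 0.9 * 0.44)
      if (length(hit) == 0) 250 else as.numeric(names(gs)[hit[1]])
    }, numeric(1))
  }
  seeds <- 1:40
  dis <- mean(lag_of(1.5, "disordered", seeds)) -
    mean(lag_of(10, "disordered", 500 + seeds))
  ord <- mean(lag_of(1.5, "ordered", 2000 + seeds)) -
    mean(lag_of(10, "ordered", 2500 + seeds))
  expect_gt(dis, 0)
  # ordered starts shrink the social departure lag by at least half
  expect_lt(ord, dis / 2)
})

test_that("the perception-weight hook swaps the optic-flow formulation", {
  set.seed(60)
  g <- init_group(scenario_config(n = 8))
  g$speed <- runif(8, 0.2, 1)
  p <- model_params()
  # a hook reproducing the default formula reproduces the default step
  default_like <- function(pos, vel) {
    d <- as.matrix(stats::dist(pos))
    w <- sqrt(outer(vel[, 1], vel[, 1], "-")^2 +
                outer(vel[, 2], vel[, 2], "-")^2) / pmax(d, 1)
    diag(w) <- 0
    w
  }
  set.seed(61); a <- step_prey(g, p)
  set.seed(61); b <- step_prey(g, p, weight_fn = default_like)
  expect_equal(a$pos, b$pos, tolerance = 1e-12)
  # an all-zero weight field silences social interaction entirely
  set.seed(62); asocial <- step_prey(g, p, weight_fn = function(pos, vel) {
    matrix(0, nrow(pos), nrow(pos))
  })
  g_lone <- g
  g_lone$m <- rep(1e9, 8)
  set.seed(62); lone <- step_prey(g_lone, p)
  expect_equal(asocial$speed, lone$speed)
})
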