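test_that("parameter bounds are enforced and model-specific", {
  expect_error(model_params(theta = 31), "bounds")
  expect_error(model_params(tau = 1001), "bounds")
  expect_error(model_params(mu = -0.1), "bounds")
  expect_identical(param_bounds("M1")$free, "tau")
  expect_identical(param_bounds("M2")$free, "tau")
  expect_identical(param_bounds("M3")$free, c("theta", "tau", "mu"))
})

test_that("action sets have equally spaced directions plus a null action", {
  a <- action_set(128L)
  expect_identical(a$size, 129L)
  expect_equal(a$dirs[6L, ], c(cos(2 * pi * 5 / 128), sin(2 * pi * 5 / 128)))
  expect_equal(a$dirs[129L, ], c(0, 0))
  expect_identical(a$null_code, 128L)
  expect_identical(action_set(8L)$size, 9L)
})

test_that("position prediction extrapolates with model-specific lags", {
  # stationary agent: prediction equals the current position for any theta
  Y <- matrix(rep(c(0.1, -0.2), each = 6L), ncol = 2L)
  for (m in c("M1", "M2", "M3")) {
    expect_equal(predict_agent_position(Y, 7, m), c(0.1, -0.2))
  }
  # constant per-frame velocity (0.01, 0), zero acceleration, theta = 10
  Y <- cbind(seq(-0.05, 0, by = 0.01), 0)
  expect_equal(predict_agent_position(Y, 10, "M2"), c(0.1, 0))
  # M1 ignores theta entirely
  expect_equal(predict_agent_position(Y, 10, "M1"), c(0, 0))
  # velocity 0.01 and acceleration 0.002 per frame at theta = 10:
  # 0.01*10 + 0.002*100/2 = 0.2
  Y <- cbind(c(-0.018, -0.01, 0), 0)
  expect_equal(predict_agent_position(Y, 10, "M2"), c(0.2, 0),
               tolerance = 1e-12)
  # M3 with integer theta = 2 uses lag-2 differences
  Y3 <- cbind(c(0, 0, 0.01, 0.02, 0.04, 0.06), 0)
  # v = y(t)-y(t-2) = 0.04, a = v - (y(t-2)-y(t-4)) = 0.04 - 0.02 = 0.02
  expect_equal(predict_agent_position(Y3, 2, "M3"),
               c(0.06 + 0.04 * 2 + 0.02 * 2, 0))
  # short history degrades gracefully to zero derivatives
  expect_equal(predict_agent_position(Y3[6L, , drop = FALSE], 3, "M3"),
               Y3[6L, ])
})

test_that("softmax action probabilities normalize and hit known values", {
  aset <- action_set(128L)
  set.seed(4)
  for (i in 1:1000) {
    p <- action_probabilities(runif(2L, -0.3, 0.3), runif(2L, -0.3, 0.3),
                              sample(c("hunt", "escape"), 1L), aset,
                              0.006, runif(1L, -1000, 1000))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # tau = 0: uniform over all actions
  p0 <- action_probabilities(c(0, 0), c(0.1, 0), "hunt", aset, 0.006, 0)
  expect_equal(p0, rep(1 / 129, 129L), tolerance = 1e-15)
  # two-action softmax with Q = (0, -1), tau = 1: p = (0.731, 0.269)
  expect_equal(exp(1 * 0) / (exp(0) + exp(-1)), 0.7310586, tolerance = 1e-6)
  # large tau concentrates on the distance-minimizing action in hunt
  pL <- action_probabilities(c(0, 0), c(0.1, 0), "hunt", aset, 0.006, 1e8)
  expect_identical(which.max(pL), 1L)  # action 0 points at +x
  expect_gt(max(pL), 0.999)
})

test_that("probabilities are equivariant under common 90-degree rotations", {
  aset <- action_set(128L)
  rot90 <- matrix(c(0, 1, -1, 0), 2L)
  player <- c(0.12, -0.05)
  y_pred <- c(-0.2, 0.08)
  for (cond in c("hunt", "escape")) {
    p <- action_probabilities(player, y_pred, cond, aset, 0.006, 250)
    pr <- action_probabilities(as.numeric(rot90 %*% player),
                               as.numeric(rot90 %*% y_pred),
                               cond, aset, 0.006, 250)
    # rotating by 90 degrees shifts direction indices by 32; null unchanged
    expect_equal(pr[1:128], p[(((0:127) - 32L) %% 128L) + 1L],
                 tolerance = 1e-12)
    expect_equal(pr[129L], p[129L], tolerance = 1e-12)
  }
})

test_that("hunt- and escape-optimal actions are antipodal", {
  aset <- action_set(128L)
  set.seed(5)
  for (i in 1:50) {
    player <- runif(2L, -0.3, 0.3)
    y_pred <- runif(2L, -0.3, 0.3)
    ph <- action_probabilities(player, y_pred, "hunt", aset, 0.006, 5e4)
    pe <- action_probabilities(player, y_pred, "escape", aset, 0.006, 5e4)
    bh <- which.max(ph[1:128]) - 1L
    be <- which.max(pe[1:128]) - 1L
    expect_identical((bh + 64L) %% 128L, be)
  }
})

test_that("movement discretization maps displacements to nearest directions", {
  aset <- action_set(128L)
  speed <- 0.006
  expect_identical(discretize_movement(c(0, 0), aset, speed), aset$null_code)
  # below a quarter step length counts as no movement
  expect_identical(discretize_movement(c(0.2 * speed, 0), aset, speed),
                   aset$null_code)
  # exactly along direction 5
  ang5 <- 2 * pi * 5 / 128
  expect_identical(
    discretize_movement(speed * c(cos(ang5), sin(ang5)), aset, speed), 5L)
  # 1.0 degree with 2.8125-degree spacing rounds to direction 0
  a <- pi / 180
  expect_identical(discretize_movement(speed * c(cos(a), sin(a)), aset, speed),
                   0L)
  # exact half-spacing ties go to the lower index
  half <- pi / 128
  expect_identical(
    discretize_movement(speed * c(cos(half), sin(half)), aset, speed), 0L)
})

test_that("generative policies honor momentum and the reactive limit", {
  aset <- action_set(8L)
  speed <- 0.006
  Y <- cbind(seq(0.3, 0.2, length.out = 40L), 0)
  # mu = 1: every intermediate frame repeats the planned action
  pol <- make_policy("M3", model_params(theta = 5, tau = 50, mu = 1), aset,
                     speed)
  set.seed(6)
  pstate <- NULL
  steps <- matrix(NA_real_, 20L, 2L)
  for (t in 0:19) {
    res <- pol(c(0, 0), Y[seq_len(t + 1L), , drop = FALSE], t, "hunt",
               "main", pstate)
    pstate <- res$pstate
    steps[t + 1L, ] <- res$step
  }
  for (blk in list(1:5, 6:10, 11:15, 16:20)) {
    expect_true(all(apply(steps[blk, ], 2L, function(x) length(unique(x))) == 1L))
  }
  # mu = 0: intermediate actions are uniform over the action set
  pol0 <- make_policy("M3", model_params(theta = 10, tau = 0, mu = 0), aset,
                      speed)
  set.seed(7)
  acts <- integer(0L)
  pstate <- NULL
  for (t in 0:9999) {
    res <- pol0(c(0, 0), Y[1:2, ], t %% 100L, "hunt", "main",
                if (t %% 100L == 0L) NULL else pstate)
    pstate <- res$pstate
    if (t %% 10L != 0L) {
      acts <- c(acts, discretize_movement(res$step, aset, speed))
    }
  }
  freq <- tabulate(acts + 1L, 9L) / length(acts)
  expect_true(all(abs(freq - 1 / 9) < 4 * sqrt((1 / 9) * (8 / 9) / length(acts))))
  # M1 with a large tau is a pursuit curve toward the agent's position
  cfg <- arena_config(agent_speed = 0.002, boost_prob_per_s = 0)
  # a policy can be built from raw parameters beyond the fitted bounds to
  # realize the deterministic limit
  polr <- make_policy("M1", c(theta = 1, tau = 1e6, mu = 1), aset, speed)
  state <- new_session_state(cfg)
  state$player_xy <- c(-0.3, 0)
  state$agent_xy <- c(0.3, 0)
  set.seed(8)
  res <- run_trial(list(condition = "hunt", duration_s = 2), polr, state, cfg)
  fr <- res$trial$frames
  st <- diff(cbind(fr$player_x, fr$player_y))
  tow <- cbind(fr$agent_x, fr$agent_y)[seq_len(nrow(st)), ] -
    cbind(fr$player_x, fr$player_y)[seq_len(nrow(st)), ]
  cosang <- rowSums(st * tow) /
    (sqrt(rowSums(st^2)) * sqrt(rowSums(tow^2)))
  expect_true(all(cosang > cos(2 * pi / 8)))
})
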