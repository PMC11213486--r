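test_that("respawn distributions match the protocol", {
  cfg <- arena_config()
  set.seed(1)
  n <- 2e4L
  draws <- replicate(n, sample_respawn(cfg), simplify = FALSE)
  player <- t(vapply(draws, `[[`, numeric(2L), "player_xy"))
  agent <- t(vapply(draws, `[[`, numeric(2L), "agent_xy"))
  # all inside the arena
  expect_true(all(sqrt(rowSums(player^2)) <= cfg$radius + 1e-12))
  expect_true(all(sqrt(rowSums(agent^2)) <= cfg$radius + 1e-12))
  # agent centered on the origin (within 3 standard errors per axis)
  se <- apply(agent, 2L, sd) / sqrt(n)
  expect_true(all(abs(colMeans(agent)) < 3 * se))
  # player radial distance uniform on [0, radius]: mean radius/2
  r <- sqrt(rowSums(player^2))
  se_r <- cfg$radius / sqrt(12) / sqrt(n)
  expect_lt(abs(mean(r) - cfg$radius / 2), 3 * se_r)
})

test_that("agent costs implement chase/flee with a center penalty", {
  cfg <- arena_config(center_cost_weight = 0)
  near <- c(0.1, 0)
  far <- c(0.2, 0)
  player <- c(0, 0)
  cost_pred <- agent_cost(rbind(near, far), player, "predator", cfg)
  cost_prey <- agent_cost(rbind(near, far), player, "prey", cfg)
  expect_lt(cost_pred[1L], cost_pred[2L])  # predator prefers closer
  expect_gt(cost_prey[1L], cost_prey[2L])  # prey prefers farther
  # the literal cost-sign flag flips both
  cfg_lit <- arena_config(center_cost_weight = 0, cost_sign_literal = TRUE)
  expect_gt(agent_cost(near, player, "predator", cfg_lit),
            agent_cost(far, player, "predator", cfg_lit))
  # candidates outside the arena are infinitely expensive
  expect_identical(agent_cost(c(2, 2), player, "prey", cfg), Inf)
  # strong center weight pulls a boundary prey inward even with the player
  # at the center: brute-force enumeration of the 30 candidates
  cfg_w <- arena_config(center_cost_weight = 10)
  prey <- c(cfg_w$radius - cfg_w$agent_speed, 0)
  ang <- 2 * pi * (0:29) / 30
  cand <- cbind(prey[1L] + cfg_w$agent_speed * cos(ang),
                prey[2L] + cfg_w$agent_speed * sin(ang))
  costs <- agent_cost(cand, c(0, 0), "prey", cfg_w)
  best <- cand[which.min(costs), ]
  expect_lt(sqrt(sum(best^2)), sqrt(sum(prey^2)))
})

test_that("step_agent equals the brute-force argmin over candidates", {
  cfg <- arena_config()
  set.seed(2)
  for (i in 1:1000) {
    agent <- sample_respawn(cfg)$agent_xy
    player <- sample_respawn(cfg)$player_xy
    role <- sample(c("predator", "prey"), 1L)
    speed <- runif(1L, 0.001, 0.02)
    got <- step_agent(agent, player, role, speed, cfg)
    ang <- 2 * pi * (seq_len(cfg$n_candidates) - 1L) / cfg$n_candidates
    cand <- cbind(agent[1L] + speed * cos(ang), agent[2L] + speed * sin(ang))
    costs <- vapply(seq_len(nrow(cand)), function(j) {
      d_play <- sqrt(sum((cand[j, ] - player)^2))
      dc <- sqrt(sum(cand[j, ]^2))
      if (dc > cfg$radius + 1e-12) return(Inf)
      s <- if (role == "predator") 1 else -1
      s * d_play + cfg$center_cost_weight * dc^2 / cfg$radius
    }, 0)
    want <- if (all(is.infinite(costs))) agent else cand[which.min(costs), ]
    expect_identical(got, want)
  }
})

test_that("greedy steps chase the player and ties break to candidate 0", {
  cfg <- arena_config(center_cost_weight = 0)
  # predator 0.1 left of the player steps within one candidate spacing of
  # due right
  step <- step_agent(c(-0.1, 0), c(0, 0), "predator", 0.006, cfg) - c(-0.1, 0)
  expect_lt(abs(atan2(step[2L], step[1L])), 2 * pi / cfg$n_candidates)
  # co-located prey and player at the center: all candidates tie, the
  # lowest-index candidate (along +x) wins
  got <- step_agent(c(0, 0), c(0, 0), "prey", 0.006, cfg)
  expect_equal(got, c(0.006, 0), tolerance = 1e-15)
})

test_that("difficulty staircase follows the success rate with a dead band", {
  cfg <- arena_config()
  sp <- 0.006
  expect_equal(update_difficulty(rep(TRUE, 4L), sp, cfg),
               sp + cfg$calibration_step)
  expect_equal(update_difficulty(rep(FALSE, 4L), sp, cfg),
               sp - cfg$calibration_step)
  expect_equal(update_difficulty(c(TRUE, TRUE, FALSE, FALSE), sp, cfg), sp)
  expect_equal(update_difficulty(rep(TRUE, 4L), cfg$agent_speed_range[2L], cfg),
               cfg$agent_speed_range[2L])
})

test_that("higher prey speed never helps hunt success (paired seeds)", {
  cfg_slow <- arena_config(agent_speed = 0.002, boost_prob_per_s = 0)
  cfg_fast <- arena_config(agent_speed = 0.005, boost_prob_per_s = 0)
  aset <- action_set(8L)
  policy <- make_policy("M1", model_params(tau = 1000), aset, 0.006)
  catches <- function(cfg) {
    vapply(1:100, function(s) {
      set.seed(s)
      state <- new_session_state(cfg)
      res <- run_trial(list(condition = "hunt", duration_s = 6),
                       policy, state, cfg)
      res$trial$outcome == "success"
    }, TRUE)
  }
  expect_gte(sum(catches(cfg_slow)), sum(catches(cfg_fast)))
})

test_that("trial kinematics, capture and termination follow the protocol", {
  aset <- action_set(8L)
  still <- function(player_xy, agent_traj, frame, condition, phase, pstate) {
    list(step = c(0, 0), pstate = pstate)
  }
  # stationary player, approaching predator, equal speeds, no boost:
  # capture occurs and the escape fails
  cfg <- arena_config(boost_prob_per_s = 0)
  state <- new_session_state(cfg)
  state$player_xy <- c(0, 0)
  state$agent_xy <- c(0.2, 0)
  set.seed(3)
  res <- run_trial(list(condition = "escape", duration_s = 10), still, state, cfg)
  expect_true(res$trial$terminated_by_capture)
  expect_identical(res$trial$outcome, "failure")
  # a near-stationary predator never catches the player: success
  cfg0 <- arena_config(agent_speed = 1e-9, boost_prob_per_s = 0)
  state <- new_session_state(cfg0)
  state$player_xy <- c(0, 0)
  state$agent_xy <- c(0.3, 0)
  res <- run_trial(list(condition = "escape", duration_s = 2), still, state, cfg0)
  expect_identical(res$trial$outcome, "success")
  # 2 s at 16 ms per frame: 125 logged frames when no capture
  expect_identical(nrow(res$trial$frames), 125L)
  expect_identical(res$trial$frames$frame, 0:124)
  # over-long policy steps are renormalized with a warning
  greedy <- function(player_xy, agent_traj, frame, condition, phase, pstate) {
    list(step = c(1, 0), pstate = pstate)
  }
  warns <- capture_warnings(
    res <- run_trial(list(condition = "escape", duration_s = 0.2),
                     greedy, state, cfg0))
  expect_true(any(grepl("renormalized", warns)))
  d <- diff(cbind(res$trial$frames$player_x, res$trial$frames$player_y))
  expect_equal(max(sqrt(rowSums(d^2))), cfg0$player_speed, tolerance = 1e-9)
})

test_that("sessions respect the cue schedule, containment and reproducibility", {
  cfg <- arena_config()
  aset <- action_set(8L)
  policy <- make_policy("M3", condition_param_means("keyboard-9"), aset,
                        cfg$player_speed)
  set.seed(9)
  s1 <- run_session(policy, cfg, n_trials = 121L, duration_range = c(0.5, 1.5))
  set.seed(9)
  s2 <- run_session(policy, cfg, n_trials = 121L, duration_range = c(0.5, 1.5))
  expect_identical(s1, s2)  # bit-identical under the same seed
  expect_identical(nrow(s1$meta), 121L)
  expect_false(s1$meta$is_switch[1L])  # first trial has no switch/stay cue
  # every logged position lies inside the arena
  for (tr in s1$trials) {
    r <- sqrt(tr$frames$player_x^2 + tr$frames$player_y^2)
    expect_true(all(r <= cfg$radius + 1e-9))
    ra <- sqrt(tr$frames$agent_x^2 + tr$frames$agent_y^2)
    expect_true(all(ra <= cfg$radius + 1e-9))
  }
  # switch cues are Bernoulli(0.5) over the 120 cued trials, and the
  # pre-encounter stage follows captures with probability 0.4
  set.seed(10)
  s3 <- run_session(policy, cfg, n_trials = 400L, duration_range = c(0.5, 1))
  expect_lt(abs(mean(s3$meta$is_switch[-1L]) - 0.5), 3 * 0.5 / sqrt(399))
  prev_cap <- c(FALSE, s3$meta$terminated_by_capture[-400L])
  expect_gt(sum(prev_cap), 30L)
  p_pre <- mean(s3$meta$pre_s[prev_cap] > 0)
  expect_lt(abs(p_pre - 0.4), 3 * 0.5 / sqrt(sum(prev_cap)))
  expect_true(all(s3$meta$pre_s[!prev_cap] == 0))
})

test_that("session logs round-trip through delimited text with checksums", {
  cfg <- arena_config()
  aset <- action_set(8L)
  policy <- make_policy("M3", condition_param_means("keyboard-9"), aset,
                        cfg$player_speed)
  set.seed(11)
  se <- run_session(policy, cfg, n_trials = 6L, duration_range = c(1, 2),
                    subject_id = "sX", run_id = 2L)
  dir <- tempfile("sess")
  write_session_log(se, dir)
  back <- read_session_log(dir, cfg)
  expect_equal(back$meta$outcome, se$meta$outcome)
  for (i in seq_along(se$trials)) {
    expect_equal(back$trials[[i]]$frames$player_x,
                 se$trials[[i]]$frames$player_x, tolerance = 1e-12)
    expect_equal(back$trials[[i]]$condition, se$trials[[i]]$condition)
  }
  # tampering breaks the checksum
  con <- file.path(dir, "trials.csv")
  writeLines(c(readLines(con), "tamper"), con)
  expect_error(read_session_log(dir, cfg), "checksum")
})
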