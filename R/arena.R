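#' Arena task configuration
#'
#' Parameters of the 2D circular hunt/escape arena. One distance unit is the
#' screen height; positions are updated every 16-ms frame and the player moves
#' at a fixed 0.006 units/frame. The scripted computer agent (prey in the hunt
#' condition, predator in the escape condition) takes a greedy step over
#' `n_candidates` equally spaced candidate positions, its speed is calibrated
#' every `calibration_block` trials to hold the player's success rate near
#' `target_success`, and the predator intermittently "boosts".
#'
#' Values without a stated experimental source (arena radius, capture radius,
#' center-cost weight, boost parameters, calibration step and speed range) are
#' package defaults chosen to produce a playable task; all are configurable.
#'
#' @param radius arena radius in screen-height units.
#' @param frame_dt frame duration in seconds.
#' @param player_speed player step length, units/frame.
#' @param agent_speed initial agent step length, units/frame (calibrated online).
#' @param capture_radius player-agent distance below which capture is declared.
#' @param center_cost_weight weight of the quadratic center-distance cost term.
#' @param n_candidates number of candidate agent steps per frame.
#' @param boost_prob_per_s per-second probability that the predator starts a boost.
#' @param boost_multiplier speed multiplier while boosting (>= 1).
#' @param boost_duration_frames boost length in frames.
#' @param calibration_block number of completed trials per condition between
#'   difficulty updates.
#' @param calibration_step speed increment per difficulty update, units/frame.
#' @param agent_speed_range allowed range for the calibrated agent speed.
#' @param target_success success rate the calibration aims at.
#' @param cost_sign_literal if `TRUE`, use the literal (behaviorally
#'   inconsistent) cost-sign reading in which the prey's cost increases with
#'   distance from the player; default is the flee/chase-consistent convention.
#' @return an object of class `arena_config`.
#' @export
arena_config <- function(radius = 0.5, frame_dt = 0.016, player_speed = 0.006,
                         agent_speed = 0.006, capture_radius = 0.02,
                         center_cost_weight = 0.5, n_candidates = 30L,
                         boost_prob_per_s = 0.5, boost_multiplier = 1.8,
                         boost_duration_frames = 12L, calibration_block = 4L,
                         calibration_step = 5e-4,
                         agent_speed_range = c(0.0005, 0.015),
                         target_success = 0.5,
                         cost_sign_literal = FALSE) {
  stopifnot(radius > 0, player_speed > 0, player_speed < radius,
            capture_radius > 0, center_cost_weight >= 0,
            n_candidates >= 3, boost_multiplier >= 1,
            boost_duration_frames >= 0, calibration_block >= 1,
            calibration_step >= 0, length(agent_speed_range) == 2,
            agent_speed_range[1] <= agent_speed_range[2],
            target_success > 0, target_success < 1)
  structure(list(radius = radius, frame_dt = frame_dt,
                 player_speed = player_speed, agent_speed = agent_speed,
                 capture_radius = capture_radius,
                 center_cost_weight = center_cost_weight,
                 n_candidates = as.integer(n_candidates),
                 boost_prob_per_s = boost_prob_per_s,
                 boost_multiplier = boost_multiplier,
                 boost_duration_frames = as.integer(boost_duration_frames),
                 calibration_block = as.integer(calibration_block),
                 calibration_step = calibration_step,
                 agent_speed_range = agent_speed_range,
                 target_success = target_success,
                 cost_sign_literal = cost_sign_literal),
            class = "arena_config")
}

vnorm <- function(x) sqrt(sum(x * x))

clip_to_arena <- function(xy, radius) {
  r <- vnorm(xy)
  if (r > radius) xy * (radius / r) else xy
}

#' Respawn positions after a capture
#'
#' The agent respawns from an isotropic Gaussian centered on the arena center
#' (per-axis SD = radius/4), rejection-sampled to lie inside the arena; the
#' player respawns with radial distance uniform on \[0, radius\] and uniform
#' angle. Uses the current RNG state.
#'
#' @param config an [arena_config()].
#' @return list with `player_xy` and `agent_xy` (length-2 numeric vectors).
#' @export
sample_respawn <- function(config) {
  R <- config$radius
  repeat {
    agent <- stats::rnorm(2L, mean = 0, sd = R / 4)
    if (vnorm(agent) <= R) break
  }
  r <- stats::runif(1L, 0, R)
  a <- stats::runif(1L, 0, 2 * pi)
  list(player_xy = c(r * cos(a), r * sin(a)), agent_xy = agent)
}

#' Cost of candidate agent positions
#'
#' The predator's cost grows with distance to the player (chase) and the
#' prey's cost shrinks with it (flee); both pay a center-distance penalty
#' `w * d_center^2 / radius` (quadratic ramp, equal to `w * d_center` at the
#' wall) that keeps the agent off the boundary. Candidates outside the arena
#' cost `Inf`.
#'
#' @param candidate_xy matrix with one candidate position per row (or a
#'   length-2 vector).
#' @param player_xy player position.
#' @param role `"predator"` or `"prey"`.
#' @param config an [arena_config()].
#' @return numeric cost vector, one per candidate.
#' @export
agent_cost <- function(candidate_xy, player_xy, role, config) {
  role <- match.arg(role, c("predator", "prey"))
  if (is.null(dim(candidate_xy))) candidate_xy <- matrix(candidate_xy, ncol = 2L)
  dx <- candidate_xy[, 1L] - player_xy[1L]
  dy <- candidate_xy[, 2L] - player_xy[2L]
  d_play <- sqrt(dx * dx + dy * dy)
  d_cen2 <- candidate_xy[, 1L]^2 + candidate_xy[, 2L]^2
  s <- if (role == "predator") 1 else -1
  if (config$cost_sign_literal) s <- -s
  cost <- s * d_play + config$center_cost_weight * d_cen2 / config$radius
  cost[sqrt(d_cen2) > config$radius + 1e-12] <- Inf
  cost
}

agent_candidates <- function(agent_xy, speed, n) {
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(agent_xy[1L] + speed * cos(ang), agent_xy[2L] + speed * sin(ang))
}

#' Greedy agent step
#'
#' Evaluates `n_candidates` equally spaced positions at distance `speed` from
#' the current agent position (candidate 0 along +x) and moves to the
#' cheapest under [agent_cost()]; ties break to the lowest candidate index,
#' and the agent stays in place if every candidate is outside the arena.
#'
#' @inheritParams agent_cost
#' @param agent_xy current agent position.
#' @param speed effective step length this frame (boosted when applicable).
#' @return the new agent position.
#' @export
step_agent <- function(agent_xy, player_xy, role, speed, config) {
  stopifnot(speed > 0)
  cand <- agent_candidates(agent_xy, speed, config$n_candidates)
  cost <- agent_cost(cand, player_xy, role, config)
  if (all(is.infinite(cost))) return(agent_xy)
  # tolerant argmin so exact geometric ties (equal costs up to rounding)
  # deterministically resolve to the lowest candidate index
  cand[which(cost <= min(cost) + 1e-12)[1L], ]
}

#' Staircase difficulty update
#'
#' After each completed block of trials in a condition, the agent speed moves
#' by `calibration_step` in the direction that pushes the player's success
#' rate toward `target_success` (faster agent when the player is above
#' target, slower when below, unchanged at target), clipped to
#' `agent_speed_range`.
#'
#' @param block_outcomes logical vector of trial successes in the last block.
#' @param agent_speed current agent speed for this condition.
#' @param config an [arena_config()].
#' @return the updated agent speed.
#' @export
update_difficulty <- function(block_outcomes, agent_speed, config) {
  rate <- mean(block_outcomes)
  if (rate > config$target_success) {
    agent_speed <- agent_speed + config$calibration_step
  } else if (rate < config$target_success) {
    agent_speed <- agent_speed - config$calibration_step
  }
  min(max(agent_speed, config$agent_speed_range[1L]), config$agent_speed_range[2L])
}

cap_step <- function(step, max_len) {
  len <- vnorm(step)
  if (len > max_len + 1e-12) {
    warning("player policy returned a step longer than player_speed; renormalized",
            call. = FALSE)
    step <- step * (max_len / len)
  }
  step
}

new_session_state <- function(config) {
  sp <- sample_respawn(config)
  list(player_xy = sp$player_xy, agent_xy = sp$agent_xy,
       agent_speed = list(hunt = config$agent_speed,
                          escape = config$agent_speed))
}

#' Run one trial of the arena task
#'
#' Advances the task frame by frame: the player moves according to
#' `player_policy`, then the agent takes its greedy step (with random boosts
#' when it is the predator), and capture is declared when the player-agent
#' distance falls below `capture_radius`. An optional pre-encounter phase
#' records the player moving alone before the agent appears. Positions
#' persist into the next trial unless the trial ended in a capture, in which
#' case both are respawned.
#'
#' @param spec list with `condition` (`"hunt"` or `"escape"`), `duration_s`,
#'   and optionally `pre_s` (pre-encounter duration, 0 for none), `is_switch`,
#'   `trial_index`.
#' @param player_policy a policy function, e.g. from [make_policy()]; called
#'   as `policy(player_xy, agent_traj, frame, condition, phase, pstate)` and
#'   returning `list(step=, pstate=)`. Steps longer than `player_speed` are
#'   renormalized with a warning.
#' @param state session state from [new_session_state()] (player/agent
#'   positions and per-condition agent speeds).
#' @param config an [arena_config()].
#' @return list with `trial` (a `trial_log`) and the updated `state`.
#' @export
run_trial <- function(spec, player_policy, state, config) {
  cond <- match.arg(spec$condition, c("hunt", "escape"))
  role <- if (cond == "hunt") "prey" else "predator"
  fdt <- config$frame_dt
  pre_s <- if (is.null(spec$pre_s)) 0 else spec$pre_s
  n_pre <- if (pre_s > 0) max(1L, as.integer(round(pre_s / fdt))) else 0L
  n_main <- max(2L, as.integer(round(spec$duration_s / fdt)))
  aspd <- state$agent_speed[[cond]]
  pstate <- NULL

  pre <- NULL
  if (n_pre > 0L) {
    pre <- matrix(NA_real_, n_pre, 2L)
    for (t in seq_len(n_pre)) {
      pre[t, ] <- state$player_xy
      res <- player_policy(state$player_xy, NULL, t - 1L, cond, "pre", pstate)
      pstate <- res$pstate
      state$player_xy <- clip_to_arena(
        state$player_xy + cap_step(res$step, config$player_speed), config$radius)
    }
  }

  P <- matrix(NA_real_, n_main, 2L)
  A <- matrix(NA_real_, n_main, 2L)
  boost <- logical(n_main)
  boost_left <- 0L
  captured <- FALSE
  t_end <- n_main
  for (t in seq_len(n_main)) {
    P[t, ] <- state$player_xy
    A[t, ] <- state$agent_xy
    res <- player_policy(state$player_xy, A[seq_len(t), , drop = FALSE],
                         t - 1L, cond, "main", pstate)
    pstate <- res$pstate
    state$player_xy <- clip_to_arena(
      state$player_xy + cap_step(res$step, config$player_speed), config$radius)
    eff <- aspd
    if (role == "predator") {
      if (boost_left <= 0L &&
          stats::runif(1L) < config$boost_prob_per_s * fdt) {
        boost_left <- config$boost_duration_frames
      }
      if (boost_left > 0L) {
        eff <- aspd * config$boost_multiplier
        boost[t] <- TRUE
        boost_left <- boost_left - 1L
      }
    }
    state$agent_xy <- step_agent(state$agent_xy, state$player_xy, role, eff,
                                 config)
    if (vnorm(state$player_xy - state$agent_xy) < config$capture_radius) {
      captured <- TRUE
      t_end <- t
      break
    }
  }
  success <- if (cond == "hunt") captured else !captured
  if (captured) {
    sp <- sample_respawn(config)
    state$player_xy <- sp$player_xy
    state$agent_xy <- sp$agent_xy
  }
  idx <- seq_len(t_end)
  trial <- structure(list(
    condition = cond,
    is_switch = isTRUE(spec$is_switch),
    trial_index = if (is.null(spec$trial_index)) NA_integer_ else spec$trial_index,
    frames = data.frame(frame = idx - 1L,
                        player_x = P[idx, 1L], player_y = P[idx, 2L],
                        agent_x = A[idx, 1L], agent_y = A[idx, 2L],
                        boost = boost[idx]),
    pre_frames = pre,
    outcome = if (success) "success" else "failure",
    terminated_by_capture = captured,
    duration_s = spec$duration_s, pre_s = pre_s,
    agent_speed = aspd), class = "trial_log")
  list(trial = trial, state = state)
}

#' Run a session of trials
#'
#' Emits `n_trials` trials. The condition of the first trial is random; each
#' subsequent trial switches with probability `switch_prob` (the switch/stay
#' cue). A pre-encounter stage of duration uniform on `pre_range` seconds is
#' inserted with probability `pre_prob` after capture-terminated trials. Main
#' trial durations are uniform on `duration_range` seconds. When `calibrate`
#' is `TRUE` the per-condition agent speed is updated by [update_difficulty()]
#' every `calibration_block` completed trials of that condition.
#'
#' @inheritParams run_trial
#' @param n_trials number of trials.
#' @param duration_range range (s) of the main-stage duration.
#' @param switch_prob probability that the cue signals a condition switch.
#' @param pre_prob probability of a pre-encounter stage after a capture.
#' @param pre_range range (s) of the pre-encounter duration.
#' @param calibrate enable online difficulty calibration.
#' @param warmup_trials unrecorded trials run before the session with the
#'   same schedule and calibration, so the recorded session starts near the
#'   staircase equilibrium (emulating the practice/continuous calibration
#'   that precedes the recorded task). 0 disables the warm-up.
#' @param subject_id,run_id identifiers stored in the log.
#' @return a `session_log`: list with `trials` (list of `trial_log`), `meta`
#'   (one row per trial), `config`, `subject_id`, `run_id`.
#' @export
run_session <- function(player_policy, config, n_trials = 121L,
                        duration_range = c(2, 10), switch_prob = 0.5,
                        pre_prob = 0.4, pre_range = c(0, 10),
                        calibrate = TRUE, warmup_trials = 0L,
                        subject_id = "s1", run_id = 1L) {
  state <- new_session_state(config)
  trials <- vector("list", n_trials)
  meta <- vector("list", n_trials)
  cond <- sample(c("hunt", "escape"), 1L)
  prev_captured <- FALSE
  history <- list(hunt = logical(0L), escape = logical(0L))
  n_total <- warmup_trials + n_trials
  for (k in seq_len(n_total)) {
    i <- k - warmup_trials
    is_switch <- FALSE
    if (k > 1L) {
      is_switch <- stats::runif(1L) < switch_prob
      if (is_switch) cond <- if (cond == "hunt") "escape" else "hunt"
    }
    pre_s <- 0
    if (prev_captured && stats::runif(1L) < pre_prob) {
      pre_s <- stats::runif(1L, pre_range[1L], pre_range[2L])
    }
    dur <- stats::runif(1L, duration_range[1L], duration_range[2L])
    res <- run_trial(list(condition = cond, duration_s = dur, pre_s = pre_s,
                          is_switch = i > 1L && is_switch, trial_index = i),
                     player_policy, state, config)
    state <- res$state
    tr <- res$trial
    prev_captured <- tr$terminated_by_capture
    history[[cond]] <- c(history[[cond]], tr$outcome == "success")
    if (calibrate &&
        length(history[[cond]]) %% config$calibration_block == 0L) {
      block <- utils::tail(history[[cond]], config$calibration_block)
      state$agent_speed[[cond]] <-
        update_difficulty(block, state$agent_speed[[cond]], config)
    }
    if (i < 1L) next
    trials[[i]] <- tr
    meta[[i]] <- data.frame(
      subject_id = subject_id, run_id = run_id, trial_index = i,
      condition = cond, is_switch = i > 1L && is_switch, pre_s = pre_s,
      duration_s = dur, n_frames = nrow(tr$frames),
      outcome = tr$outcome,
      terminated_by_capture = tr$terminated_by_capture,
      agent_speed = tr$agent_speed)
  }
  structure(list(trials = trials, meta = do.call(rbind, meta),
                 config = config, subject_id = subject_id, run_id = run_id),
            class = "session_log")
}

#' Write a session log as delimited text
#'
#' Writes one long-format frames table (one row per frame, pre-encounter
#' frames included with `phase = "pre"`) and one per-trial metadata table,
#' plus MD5 checksums, and reads them back.
#'
#' @param session a `session_log`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_session_log <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(session$trials, function(tr) {
    main <- cbind(data.frame(subject_id = session$subject_id,
                             run_id = session$run_id,
                             trial_index = tr$trial_index,
                             condition = tr$condition,
                             is_switch = tr$is_switch,
                             phase = "main"), tr$frames)
    if (!is.null(tr$pre_frames)) {
      np <- nrow(tr$pre_frames)
      pre <- data.frame(subject_id = session$subject_id,
                        run_id = session$run_id,
                        trial_index = tr$trial_index,
                        condition = tr$condition, is_switch = tr$is_switch,
                        phase = "pre", frame = seq_len(np) - 1L,
                        player_x = tr$pre_frames[, 1L],
                        player_y = tr$pre_frames[, 2L],
                        agent_x = NA_real_, agent_y = NA_real_,
                        boost = FALSE)
      rbind(pre, main)
    } else main
  })
  frames_path <- file.path(dir, "frames.csv")
  meta_path <- file.path(dir, "trials.csv")
  utils::write.csv(do.call(rbind, rows), frames_path, row.names = FALSE)
  utils::write.csv(session$meta, meta_path, row.names = FALSE)
  sums <- tools::md5sum(c(frames_path, meta_path))
  writeLines(paste(sums, basename(names(sums))), file.path(dir, "MD5"))
  invisible(c(frames_path, meta_path))
}

#' Read a session log written by [write_session_log()]
#'
#' Verifies checksums and reconstructs the `session_log` structure.
#'
#' @param dir directory containing `frames.csv`, `trials.csv` and `MD5`.
#' @param config the [arena_config()] used to generate the log.
#' @return a `session_log`.
#' @export
read_session_log <- function(dir, config = arena_config()) {
  frames_path <- file.path(dir, "frames.csv")
  meta_path <- file.path(dir, "trials.csv")
  md5 <- utils::read.table(file.path(dir, "MD5"),
                           col.names = c("sum", "file"),
                           colClasses = "character")
  have <- tools::md5sum(file.path(dir, md5$file))
  if (!all(unname(have) == md5$sum)) stop("checksum mismatch in ", dir)
  frames <- utils::read.csv(frames_path)
  meta <- utils::read.csv(meta_path)
  trials <- lapply(seq_len(nrow(meta)), function(i) {
    fr <- frames[frames$trial_index == meta$trial_index[i], ]
    main <- fr[fr$phase == "main", c("frame", "player_x", "player_y",
                                     "agent_x", "agent_y", "boost")]
    rownames(main) <- NULL
    pre <- fr[fr$phase == "pre", c("player_x", "player_y")]
    structure(list(condition = meta$condition[i],
                   is_switch = meta$is_switch[i],
                   trial_index = meta$trial_index[i],
                   frames = main,
                   pre_frames = if (nrow(pre)) as.matrix(pre) else NULL,
                   outcome = meta$outcome[i],
                   terminated_by_capture = meta$terminated_by_capture[i],
                   duration_s = meta$duration_s[i], pre_s = meta$pre_s[i],
                   agent_speed = meta$agent_speed[i]), class = "trial_log")
  })
  structure(list(trials = trials, meta = meta, config = config,
                 subject_id = meta$subject_id[1L], run_id = meta$run_id[1L]),
            class = "session_log")
}
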