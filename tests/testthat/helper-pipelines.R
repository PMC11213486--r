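# Lazily computed pipelines shared across test files. The decoding cohort
# (5 subjects x 60 two-second trials, joystick modality) and the model-
# comparison cohort (20 keyboard subjects, ~100 windows each) are expensive,
# so they are built once on first use and cached for the whole test run.
.pipeline_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .pipeline_cache, inherits = FALSE)) {
    assign(key, expr, envir = .pipeline_cache)
  }
  get(key, envir = .pipeline_cache, inherits = FALSE)
}

# decoding cohort: generate with the default condition means, fit M3 per
# window, build trial features and the LOTO decoder
decoding_pipeline <- function() cached("decoding", {
  cfg <- cohort_config(n_subjects = 5L, trials_per_subject = 60L,
                       duration_range = c(2, 2))
  cohort <- generate_cohort(cfg, seed = 1L)
  fits <- fit_cohort(cohort, models = "M3")
  features <- trial_features(fits)
  decoder <- fit_decoder_loto(features)
  list(cohort = cohort, fits = fits, features = features, decoder = decoder)
})

# model-comparison cohort: M3-generated keyboard sessions, all three models
# fit to every window
selection_pipeline <- function() cached("selection", {
  cfg <- cohort_config(n_subjects = 20L, trials_per_subject = 16L,
                       duration_range = c(2, 4), modality = "keyboard-9")
  cohort <- generate_cohort(cfg, seed = 2L)
  fits <- fit_cohort(cohort, models = c("M1", "M2", "M3"))
  list(cohort = cohort, fits = fits)
})

# small cohort for trajectory-metric and switching properties; keyboard
# condition means, under which the variability contrast is driven by tau
# (the joystick means carry the modality's mu reversal, which washes out
# the per-frame heading-change contrast)
metrics_cohort <- function() cached("metrics", {
  generate_cohort(cohort_config(n_subjects = 3L, trials_per_subject = 25L,
                                modality = "keyboard-9"),
                  seed = 5L)
})

# full Cp time course over the decoding cohort (expensive; cached)
cp_pipeline <- function() cached("cp", {
  pipe <- decoding_pipeline()
  cp_timecourse(pipe$fits, pipe$features)
})

# simulate one trial and return its windows (keyboard modality by default
# keeps likelihood evaluations cheap)
simulate_windows <- function(params, condition = "hunt", n_dir = 8L,
                             duration_s = 4, agent_speed = 0.002,
                             config = arena_config(agent_speed = agent_speed,
                                                   boost_prob_per_s = 0),
                             model_id = "M3") {
  aset <- action_set(n_dir)
  policy <- make_policy(model_id, params, aset, config$player_speed)
  state <- new_session_state(config)
  res <- run_trial(list(condition = condition, duration_s = duration_s),
                   policy, state, config)
  segment_windows(res$trial, aset, config$player_speed)
}

# independent frame-by-frame likelihood oracle: loops over frames, recomputes
# the prediction, values and softmax naively, never touching the package's
# vectorized path
oracle_negloglik <- function(window, model_id, params, aset, offset = 0L) {
  theta <- if (is.na(params["theta"])) 1 else params[["theta"]]
  n_act <- window$n_act
  nf <- length(window$obs)
  ti <- if (model_id == "M3") max(1L, round(theta)) else 1L
  if (model_id == "M3") {
    o <- offset %% ti
    dec_frames <- if (o == 0L) seq(1L, nf, by = ti) else
      unique(c(1L, seq(1L + o, nf, by = ti)))
  } else dec_frames <- seq_len(nf)
  total <- 0
  planned <- NA_integer_
  for (t in seq_len(nf)) {
    g <- window$g0 + t - 1L
    if (t %in% dec_frames) {
      traj <- window$Y[seq_len(g), , drop = FALSE]
      y_pred <- predict_agent_position(traj, theta, model_id)
      q <- numeric(n_act)
      for (a in seq_len(n_act)) {
        d2 <- (window$land_x[t, a] - y_pred[1L])^2 +
          (window$land_y[t, a] - y_pred[2L])^2
        q[a] <- window$sign * d2
      }
      p <- exp(params[["tau"]] * q - max(params[["tau"]] * q))
      p <- p / sum(p)
      total <- total - log(max(p[window$obs[t] + 1L], 1e-12))
      planned <- window$obs[t]
    } else {
      mu <- params[["mu"]]
      p <- mu * (window$obs[t] == planned) + (1 - mu) / n_act
      total <- total - log(max(p, 1e-12))
    }
  }
  total
}

# synthetic window with arbitrary kinematics, for likelihood oracle tests
random_window <- function(aset, speed = 0.006, nf = 30L, hist = 8L) {
  n <- nf + hist + 1L
  P <- matrix(cumsum(stats::rnorm(2L * n, sd = speed)), ncol = 2L) / 4
  Y <- matrix(cumsum(stats::rnorm(2L * n, sd = speed)), ncol = 2L) / 4
  s <- hist + 1L
  idx <- s:(s + nf - 1L)
  obs <- sample(0:(nrow(aset$dirs) - 1L), nf, replace = TRUE)
  list(obs = obs, start = s, start_s = (s - 1L) * 0.016,
       land_x = outer(P[idx, 1L], speed * aset$dirs[, 1L], `+`),
       land_y = outer(P[idx, 2L], speed * aset$dirs[, 2L], `+`),
       Y = Y, g0 = s, sign = sample(c(-1, 1), 1L), n_act = nrow(aset$dirs),
       condition = "hunt")
}

rotate_trial <- function(trial, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  rot <- function(x, y) cbind(x, y) %*% t(R)
  p <- rot(trial$frames$player_x, trial$frames$player_y)
  a <- rot(trial$frames$agent_x, trial$frames$agent_y)
  trial$frames$player_x <- p[, 1L]
  trial$frames$player_y <- p[, 2L]
  trial$frames$agent_x <- a[, 1L]
  trial$frames$agent_y <- a[, 2L]
  if (!is.null(trial$pre_frames)) {
    trial$pre_frames <- trial$pre_frames %*% t(R)
  }
  trial
}
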