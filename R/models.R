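#' Discrete action set
#'
#' The player's continuous movement is discretized into `n_directions`
#' equally spaced unit directions plus an optional null (no-movement) action.
#' Direction `k` (0-based) points at angle `2*pi*k/n_directions` from +x; the
#' null action has code `n_directions`. The joystick task uses 128 directions
#' (129 actions), the keyboard task 8 (9 actions).
#'
#' @param n_directions number of movement directions.
#' @param include_null include the no-movement action.
#' @return an `action_set`: list with `dirs` (one row per action, the null
#'   action a zero row), `n_dir`, `size`, `null_code`.
#' @export
action_set <- function(n_directions = 128L, include_null = TRUE) {
  n <- as.integer(n_directions)
  stopifnot(n >= 2L)
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  dirs <- cbind(cos(ang), sin(ang))
  null_code <- NA_integer_
  if (include_null) {
    dirs <- rbind(dirs, c(0, 0))
    null_code <- n
  }
  structure(list(dirs = dirs, n_dir = n, size = nrow(dirs),
                 null_code = null_code, include_null = include_null),
            class = "action_set")
}

#' Parameter bounds of the generative movement models
#'
#' The decision time step `theta` lies in (0, 30\] frames, the softmax
#' precision `tau` in \[-1000, 1000\], and the continuation (momentum)
#' probability `mu` in \[0, 1\]. M1 (reactive) and M2 (one-step predictive,
#' `theta` fixed at 1) have the single free parameter `tau`; M3 has all three.
#'
#' @param model_id `"M1"`, `"M2"` or `"M3"`.
#' @return named list with `lower`, `upper`, `free` (free-parameter names).
#' @export
param_bounds <- function(model_id = c("M3", "M1", "M2")) {
  model_id <- match.arg(model_id)
  lower <- c(theta = 1e-6, tau = -1000, mu = 0)
  upper <- c(theta = 30, tau = 1000, mu = 1)
  free <- switch(model_id, M1 = "tau", M2 = "tau",
                 M3 = c("theta", "tau", "mu"))
  list(lower = lower, upper = upper, free = free)
}

#' Validated model parameters
#'
#' @param theta decision time step in frames.
#' @param tau softmax precision.
#' @param mu continuation probability on non-decision frames.
#' @return named numeric vector `c(theta, tau, mu)`.
#' @export
model_params <- function(theta = 1, tau = 0, mu = 1) {
  b <- param_bounds("M3")
  p <- c(theta = theta, tau = tau, mu = mu)
  if (any(p < b$lower - 1e-12) || any(p > b$upper + 1e-12)) {
    stop("model parameters outside bounds (0,30] x [-1000,1000] x [0,1]")
  }
  p
}

theta_frames <- function(theta) max(1L, as.integer(round(theta)))

#' Predicted future agent position
#'
#' The player extrapolates the agent's trajectory:
#' `y_pred = y(t) + y'(t) * theta + y''(t) * theta^2 / 2`.
#' M1 makes no prediction (`y_pred = y(t)`). M2 uses per-frame differences
#' for `y'` and `y''` with the horizon `theta`; M3 computes the differences
#' at lag `round(theta)` (the same timescale as its decision cadence) while
#' the horizon uses the continuous `theta`. When the history is too short
#' for a lag the corresponding derivative is taken as zero.
#'
#' @param agent_traj matrix of agent positions, one row per frame, up to and
#'   including the current frame.
#' @param theta prediction time step (frames); ignored by M1.
#' @param model_id `"M1"`, `"M2"` or `"M3"`.
#' @return the predicted position (length-2 numeric).
#' @export
predict_agent_position <- function(agent_traj, theta, model_id = "M3") {
  m <- nrow(agent_traj)
  y <- agent_traj[m, ]
  if (model_id == "M1") return(y)
  lag <- if (model_id == "M2") 1L else theta_frames(theta)
  v <- if (m - lag >= 1L) y - agent_traj[m - lag, ] else c(0, 0)
  a <- if (m - 2L * lag >= 1L) {
    v - (agent_traj[m - lag, ] - agent_traj[m - 2L * lag, ])
  } else c(0, 0)
  y + v * theta + a * theta^2 / 2
}

softmax_log <- function(z) {
  m <- max(z)
  z - m - log(sum(exp(z - m)))
}

#' Softmax action probabilities
#'
#' Each action lands at `player_xy + speed * direction` (the null action in
#' place). Its value is the negative squared Euclidean distance to the
#' predicted agent position in the hunt condition and the positive squared
#' distance in the escape condition; probabilities are
#' `exp(tau * Q) / sum(exp(tau * Q))`, computed with max-subtraction.
#'
#' @param player_xy player position.
#' @param y_pred predicted agent position.
#' @param condition `"hunt"` or `"escape"`.
#' @param aset an [action_set()].
#' @param speed player step length, units/frame.
#' @param tau softmax precision.
#' @return probability vector over the actions (sums to 1).
#' @export
action_probabilities <- function(player_xy, y_pred, condition, aset, speed,
                                 tau) {
  land_x <- player_xy[1L] + speed * aset$dirs[, 1L]
  land_y <- player_xy[2L] + speed * aset$dirs[, 2L]
  d2 <- (land_x - y_pred[1L])^2 + (land_y - y_pred[2L])^2
  if (!all(is.finite(d2))) stop("non-finite action values: corrupt positions")
  s <- if (condition == "hunt") -1 else 1
  exp(softmax_log(tau * s * d2))
}

#' Discretize an observed displacement into an action code
#'
#' Displacements shorter than a quarter of the step length map to the null
#' action; otherwise the nearest direction by angle is chosen, with ties
#' going to the lower index.
#'
#' @param frame_displacement length-2 displacement between consecutive frames.
#' @param aset an [action_set()].
#' @param speed player step length, units/frame.
#' @return integer action code (0-based; `aset$null_code` for no movement).
#' @export
discretize_movement <- function(frame_displacement, aset, speed) {
  discretize_path(matrix(frame_displacement, ncol = 2L), aset, speed)
}

# vectorized version over a matrix of displacements (one per row)
discretize_path <- function(disp, aset, speed) {
  n <- aset$n_dir
  len <- sqrt(disp[, 1L]^2 + disp[, 2L]^2)
  ang <- atan2(disp[, 2L], disp[, 1L]) %% (2 * pi)
  spacing <- 2 * pi / n
  x <- ang / spacing
  k <- floor(x + 0.5)
  # exact half-spacing ties go to the lower index
  tie <- abs(x + 0.5 - round(x + 0.5)) < 1e-9 & abs(x - round(x)) > 1e-9
  k[tie] <- k[tie] - 1L
  k <- as.integer(k %% n)
  k[len < 0.25 * speed] <- aset$null_code
  k
}

#' Generative player policy
#'
#' Wraps a movement model as a policy usable by [run_trial()]. At decision
#' frames (every frame for M1/M2; every `round(theta)` frames for M3) an
#' action is sampled from [action_probabilities()]; on M3's intermediate
#' frames the planned action is repeated with probability `mu`, otherwise an
#' action is drawn uniformly. During the pre-encounter phase the policy
#' follows `prep`: `"optimal"` moves toward the boundary before an escape and
#' toward the center before a hunt (the task's optimal preparatory strategy,
#' given that the agent tends to appear near the center); `"hold"` stays put.
#'
#' @param model_id `"M1"`, `"M2"` or `"M3"`.
#' @param params either a parameter vector from [model_params()] or a list
#'   with elements `hunt` and `escape` of such vectors.
#' @param aset an [action_set()].
#' @param speed player step length, units/frame.
#' @param prep preparatory strategy for the pre-encounter phase.
#' @param jitter_frac SD of within-trial parameter jitter, as a fraction of
#'   the magnitude of each parameter; drawn once per trial and truncated to
#'   the parameter bounds. 0 disables jitter.
#' @param arena_radius arena radius, used only by the preparatory strategy.
#' @return a policy function.
#' @export
make_policy <- function(model_id, params, aset, speed,
                        prep = c("optimal", "hold"), jitter_frac = 0,
                        arena_radius = 0.5) {
  model_id <- match.arg(model_id, c("M1", "M2", "M3"))
  prep <- match.arg(prep)
  if (!is.list(params)) params <- list(hunt = params, escape = params)
  b <- param_bounds("M3")
  jitter <- function(p) {
    if (jitter_frac <= 0) return(p)
    out <- p
    for (nm in names(p)) {
      sd <- jitter_frac * max(abs(p[[nm]]), 1e-6)
      out[[nm]] <- rtrunc_norm(1L, p[[nm]], sd, b$lower[[nm]], b$upper[[nm]])
    }
    out
  }
  function(player_xy, agent_traj, frame, condition, phase, pstate) {
    if (phase == "pre") {
      if (prep == "hold") return(list(step = c(0, 0), pstate = pstate))
      r <- vnorm(player_xy)
      step <- if (condition == "escape") {
        if (r > 0.95 * arena_radius) c(0, 0)
        else if (r < 1e-9) c(speed, 0) else player_xy / r * speed
      } else {
        if (r < 0.1 * arena_radius) c(0, 0) else -player_xy / r * speed
      }
      return(list(step = step, pstate = pstate))
    }
    if (is.null(pstate) || frame == 0L) {
      pstate <- list(trial_params = jitter(params[[condition]]),
                     planned = aset$null_code)
    }
    p <- pstate$trial_params
    ti <- if (model_id == "M3") theta_frames(p[["theta"]]) else 1L
    if (frame %% ti == 0L) {
      y_pred <- predict_agent_position(agent_traj, p[["theta"]], model_id)
      pr <- action_probabilities(player_xy, y_pred, condition, aset, speed,
                                 p[["tau"]])
      act <- sample.int(aset$size, 1L, prob = pr) - 1L
      pstate$planned <- act
    } else {
      act <- if (stats::runif(1L) < p[["mu"]]) pstate$planned
             else sample.int(aset$size, 1L) - 1L
    }
    list(step = speed * aset$dirs[act + 1L, ], pstate = pstate)
  }
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1L, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}
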