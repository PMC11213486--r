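#' Segment a trial into moving windows
#'
#' Behavior is segmented into 500-ms windows of 30 frames with a step of 15
#' frames (250 ms truncated to integer frames), starting at the first frame
#' on which the player moved; frames before the first movement are excluded,
#' and trials with fewer than 30 scorable frames after the first movement
#' yield no windows. Each window holds the 30 discretized player actions,
#' the per-frame player positions, and the full main-phase agent trajectory
#' so that lagged derivatives can reach back before the window start.
#'
#' @param trial a `trial_log`.
#' @param aset an [action_set()].
#' @param speed player step length, units/frame.
#' @param window_len,window_step window length and step in frames.
#' @return list of window structures (possibly empty); each has `obs`,
#'   `start` (1-based first action frame), `start_s` (window start time in
#'   seconds from trial start), `land_x`/`land_y` (landing points, frames x
#'   actions), `Y` (agent trajectory), `g0` (global index of the first
#'   window frame), `sign`, `n_act`, `condition`.
#' @export
segment_windows <- function(trial, aset, speed, window_len = 30L,
                            window_step = 15L, frame_dt = 0.016) {
  P <- cbind(trial$frames$player_x, trial$frames$player_y)
  Y <- cbind(trial$frames$agent_x, trial$frames$agent_y)
  n <- nrow(P)
  if (n < 2L) return(list())
  acts <- discretize_path(diff(P), aset, speed)
  moving <- which(acts != aset$null_code)
  if (!length(moving)) return(list())
  fm <- moving[1L]
  n_act <- n - 1L
  if (n_act - fm + 1L < window_len) return(list())
  starts <- seq(fm, n_act - window_len + 1L, by = window_step)
  cond <- trial$condition
  s_q <- if (cond == "hunt") -1 else 1
  lapply(starts, function(s) {
    idx <- s:(s + window_len - 1L)
    list(obs = acts[idx],
         start = s,
         start_s = (s - 1L) * frame_dt,
         land_x = outer(P[idx, 1L], speed * aset$dirs[, 1L], `+`),
         land_y = outer(P[idx, 2L], speed * aset$dirs[, 2L], `+`),
         Y = Y, g0 = s, sign = s_q, n_act = nrow(aset$dirs),
         condition = cond)
  })
}

# y_pred rows for a set of (1-based) global frame indices
ypred_at <- function(Y, gidx, theta, model_id) {
  y <- Y[gidx, , drop = FALSE]
  if (model_id == "M1") return(y)
  lag <- if (model_id == "M2") 1L else theta_frames(theta)
  horizon <- theta
  i1 <- gidx - lag
  i2 <- gidx - 2L * lag
  v <- matrix(0, length(gidx), 2L)
  a <- matrix(0, length(gidx), 2L)
  ok1 <- i1 >= 1L
  ok2 <- i2 >= 1L
  v[ok1, ] <- y[ok1, , drop = FALSE] - Y[i1[ok1], , drop = FALSE]
  a[ok2, ] <- v[ok2, , drop = FALSE] -
    (Y[i1[ok2], , drop = FALSE] - Y[i2[ok2], , drop = FALSE])
  y + v * horizon + a * horizon^2 / 2
}

# signed squared-distance values at decision frames: rows = decision frames,
# columns = actions
decision_values <- function(w, dec, theta, model_id) {
  yp <- ypred_at(w$Y, w$g0 + dec - 1L, theta, model_id)
  q <- w$sign * ((w$land_x[dec, , drop = FALSE] - yp[, 1L])^2 +
                   (w$land_y[dec, , drop = FALSE] - yp[, 2L])^2)
  if (!all(is.finite(q))) stop("non-finite action values: corrupt positions")
  q
}

# -sum log softmax probability of the observed actions given value matrix Q
nll_softmax <- function(Q, obs, tau) {
  z <- tau * Q
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  lse <- m + log(rowSums(exp(z - m)))
  lp <- z[cbind(seq_along(obs), obs + 1L)] - lse
  -sum(pmax(lp, log(1e-12)))
}

# negative log-likelihood of M3's intermediate (non-decision) frames:
# p = mu * 1[obs == planned] + (1 - mu) / |A|
nll_intermediate <- function(n_match, n_miss, mu, n_act) {
  out <- 0
  if (n_match > 0L) {
    out <- out - n_match * log(max(mu + (1 - mu) / n_act, 1e-12))
  }
  if (n_miss > 0L) {
    out <- out - n_miss * log(max((1 - mu) / n_act, 1e-12))
  }
  out
}

# Split window frames into decision frames and intermediate frames for M3.
# The decision grid has cadence round(theta); `offset` shifts the grid
# relative to the window start (the generating process's decisions are not
# aligned with window boundaries), with the leading partial segment anchored
# by a pseudo-decision at the first frame. Each intermediate frame's planned
# action is the observed action at the most recent decision frame.
m3_frame_split <- function(obs, theta, offset = 0L) {
  ti <- theta_frames(theta)
  nf <- length(obs)
  o <- as.integer(offset) %% ti
  dec <- if (o == 0L) seq.int(1L, nf, by = ti) else {
    unique(c(1L, seq.int(1L + o, nf, by = ti)))
  }
  if (length(dec) == nf) {
    return(list(dec = dec, n_match = 0L, n_miss = 0L))
  }
  planned <- obs[dec][findInterval(seq_len(nf), dec)]
  inter <- setdiff(seq_len(nf), dec)
  match <- obs[inter] == planned[inter]
  list(dec = dec, n_match = sum(match), n_miss = sum(!match))
}

#' Windowed negative log-likelihood
#'
#' Sums `-log p(observed action)` over the window's 30 frames. M1 and M2
#' score every frame with [action_probabilities()] (M1 from the current agent
#' position, M2 from a one-step prediction with per-frame derivatives). M3
#' scores decision frames (the window's first frame and every `round(theta)`
#' frames thereafter) with the softmax, identifying the latent planned action
#' with the observed action at that frame, and scores intermediate frames as
#' `mu * 1[obs = planned] + (1 - mu) / |A|`. Probabilities are floored at
#' 1e-12 before the log.
#'
#' @param window a window structure from [segment_windows()].
#' @param model_id `"M1"`, `"M2"` or `"M3"`.
#' @param params parameter vector from [model_params()] (M1/M2 use `tau` only).
#' @param offset shift (frames) of M3's decision grid relative to the window
#'   start; the generating process's decision cadence is not aligned with
#'   window boundaries, so [fit_window()] profiles this nuisance over
#'   `0..round(theta)-1`.
#' @return negative log-likelihood in nats.
#' @export
window_negloglik <- function(window, model_id, params, offset = 0L) {
  model_id <- match.arg(model_id, c("M1", "M2", "M3"))
  theta <- if (is.na(params["theta"])) 1 else params[["theta"]]
  tau <- params[["tau"]]
  nf <- length(window$obs)
  if (model_id != "M3") {
    Q <- decision_values(window, seq_len(nf), theta, model_id)
    return(nll_softmax(Q, window$obs, tau))
  }
  sp <- m3_frame_split(window$obs, theta, offset)
  Q <- decision_values(window, sp$dec, theta, "M3")
  nll_softmax(Q, window$obs[sp$dec], tau) +
    nll_intermediate(sp$n_match, sp$n_miss, params[["mu"]], window$n_act)
}

#' Bayesian information criterion
#'
#' `bic = 2 * nll + k * log(n_obs)` with `nll` in nats, `k` the number of
#' free parameters and `n_obs` the number of scored frames.
#'
#' @param nll negative log-likelihood in nats.
#' @param k number of free parameters.
#' @param n_obs number of scored observations.
#' @return the BIC value.
#' @export
model_bic <- function(nll, k, n_obs) {
  stopifnot(n_obs >= 1)
  2 * nll + k * log(n_obs)
}

n_free_params <- function(model_id) length(param_bounds(model_id)$free)

#' Fit one window by bounded maximum likelihood
#'
#' For M1/M2 the likelihood is concave in the single parameter `tau`, which
#' is found by Brent's method on its bounds. For M3, each integer `theta` on
#' `theta_grid` gives a profiled start: the momentum `mu` has a closed-form
#' optimum from the intermediate-frame match counts and `tau` is again
#' concave given the decision-frame cadence, so each start is
#' (theta, tau*, mu*); the two best starts are then polished jointly over
#' (theta, tau, mu) with bounded L-BFGS-B (numerical gradients, nll tolerance
#' ~1e-6), theta continuous in (0, 30] and rounded wherever it indexes
#' frames. Deterministic given the window.
#'
#' @param window a window structure from [segment_windows()].
#' @param model_id `"M1"`, `"M2"` or `"M3"`.
#' @param theta_grid integer starting values for `theta` (M3 only).
#' @return a one-row data.frame: `model`, `theta`, `tau`, `mu`, `nll`,
#'   `n_obs`, `bic`, `converged`.
#' @export
fit_window <- function(window, model_id,
                       theta_grid = c(1, 2, 3, 5, 8, 12, 18, 25, 30)) {
  model_id <- match.arg(model_id, c("M1", "M2", "M3"))
  b <- param_bounds(model_id)
  nf <- length(window$obs)
  k <- n_free_params(model_id)
  if (model_id != "M3") {
    Q <- decision_values(window, seq_len(nf), 1, model_id)
    f <- function(tau) nll_softmax(Q, window$obs, tau)
    op <- stats::optimize(f, c(b$lower["tau"], b$upper["tau"]))
    nll <- op$objective
    out <- data.frame(model = model_id, theta = if (model_id == "M2") 1 else NA,
                      tau = op$minimum, mu = NA_real_, offset = NA_integer_,
                      nll = nll, n_obs = nf, bic = model_bic(nll, k, nf),
                      converged = TRUE)
    return(out)
  }
  theta_grid <- theta_grid[theta_grid <= min(30, nf)]
  n_act <- window$n_act
  starts <- list()
  for (ti in theta_grid) {
    Qall <- decision_values(window, seq_len(nf), ti, "M3")
    for (o in 0:(ti - 1L)) {
      sp <- m3_frame_split(window$obs, ti, o)
      if (sp$n_match + sp$n_miss > 0L) {
        qstar <- sp$n_match / (sp$n_match + sp$n_miss)
        mu <- min(max((qstar * n_act - 1) / (n_act - 1), 0), 1)
      } else mu <- 1
      Q <- Qall[sp$dec, , drop = FALSE]
      obs_d <- window$obs[sp$dec]
      op <- stats::optimize(function(tau) nll_softmax(Q, obs_d, tau),
                            c(-1000, 1000), tol = 0.5)
      nll <- op$objective + nll_intermediate(sp$n_match, sp$n_miss, mu, n_act)
      starts[[length(starts) + 1L]] <-
        list(par = c(theta = ti, tau = op$minimum, mu = mu),
             offset = o, nll = nll)
    }
  }
  ord <- order(vapply(starts, `[[`, 0, "nll"))
  best <- starts[[ord[1L]]]
  converged <- TRUE
  # polish the best starts jointly over (theta, tau, mu), holding each
  # start's decision-grid offset fixed
  polished <- 0L
  for (i in ord) {
    st <- starts[[i]]
    if (polished >= 2L) break
    if (polished > 0L && st$par["theta"] == best$par["theta"]) next
    polished <- polished + 1L
    fn <- function(p) {
      window_negloglik(window, "M3",
                       c(theta = p[1L], tau = p[2L], mu = p[3L]),
                       offset = st$offset)
    }
    op <- tryCatch(
      stats::optim(st$par, fn, method = "L-BFGS-B",
                   lower = c(0.51, -1000, 0), upper = c(30, 1000, 1),
                   control = list(maxit = 30L, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(op)) {
      converged <- FALSE
    } else if (op$value < best$nll) {
      best <- list(par = op$par, offset = st$offset, nll = op$value)
      if (op$convergence != 0L) converged <- FALSE
    }
  }
  data.frame(model = "M3", theta = unname(best$par[1L]),
             tau = unname(best$par[2L]), mu = unname(best$par[3L]),
             offset = best$offset, nll = best$nll, n_obs = nf,
             bic = model_bic(best$nll, k, nf), converged = converged)
}

#' Fit models to every window of a trial
#'
#' @param trial a `trial_log`.
#' @param models character vector of model ids to fit.
#' @param aset an [action_set()].
#' @param speed player step length, units/frame.
#' @param ... passed to [segment_windows()].
#' @return data.frame with one row per window x model (zero rows if the
#'   trial has no scorable windows).
#' @export
fit_trial <- function(trial, models = "M3", aset, speed, ...) {
  wins <- segment_windows(trial, aset, speed, ...)
  if (!length(wins)) return(NULL)
  rows <- lapply(seq_along(wins), function(i) {
    w <- wins[[i]]
    do.call(rbind, lapply(models, function(m) {
      cbind(data.frame(trial_index = trial$trial_index,
                       condition = trial$condition,
                       is_switch = trial$is_switch,
                       window = i, start_s = w$start_s),
            fit_window(w, m))
    }))
  })
  do.call(rbind, rows)
}

#' Fit models to every trial of a session
#'
#' @param session a `session_log`.
#' @inheritParams fit_trial
#' @return data.frame keyed by subject/run/trial/window/model.
#' @export
fit_session <- function(session, models = "M3", aset, speed = NULL, ...) {
  if (is.null(speed)) speed <- session$config$player_speed
  rows <- lapply(session$trials, fit_trial, models = models, aset = aset,
                 speed = speed, ...)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  cbind(data.frame(subject_id = session$subject_id,
                   run_id = session$run_id), out)
}

#' Per-subject model evidence matrix
#'
#' Approximates each subject's log model evidence as `-BIC/2` summed over
#' that subject's windows, the input to [bms_pxp()].
#'
#' @param fits a window-fit data.frame covering >= 2 models.
#' @return matrix subjects x models of summed log evidence.
#' @export
evidence_matrix <- function(fits) {
  ag <- stats::aggregate(bic ~ subject_id + model, data = fits, FUN = sum)
  ev <- stats::xtabs(ev ~ subject_id + model,
                     data = transform(ag, ev = -bic / 2))
  matrix(ev, nrow = nrow(ev), dimnames = dimnames(ev))
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects: a
#' variational Dirichlet scheme estimates the population frequencies of the
#' candidate models from per-subject log evidences, exceedance probabilities
#' (probability that each model is the most frequent) are obtained by Monte
#' Carlo over the posterior Dirichlet, and the Bayes omnibus risk (BOR, the
#' posterior probability that all models are equally frequent) protects them:
#' `PXP = EP * (1 - BOR) + BOR / M`.
#'
#' @param evidence matrix subjects x models of log model evidence
#'   (e.g. from [evidence_matrix()]).
#' @param n_samples Monte-Carlo draws for the exceedance probabilities.
#' @return list with `alpha` (posterior Dirichlet), `expected_freq`, `ep`,
#'   `bor`, `pxp`, `assignment` (posterior model probabilities per subject).
#' @export
bms_pxp <- function(evidence, n_samples = 1e5) {
  evidence <- as.matrix(evidence)
  n <- nrow(evidence)
  K <- ncol(evidence)
  if (n < 2L) stop("random-effects model selection needs >= 2 subjects")
  if (K < 2L) stop("need >= 2 models")
  alpha0 <- rep(1, K)
  alpha <- alpha0
  g <- matrix(0, n, K)
  for (it in seq_len(500L)) {
    w <- sweep(evidence, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- w - apply(w, 1L, max)
    g <- exp(w) / rowSums(exp(w))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < 1e-8) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  a0 <- sum(alpha)
  dg <- digamma(alpha) - digamma(a0)
  # free energy of the random-effects model (H1)
  elj <- lgamma(sum(alpha0)) - sum(lgamma(alpha0)) +
    sum((alpha0 - 1) * dg) + sum(g * (evidence + rep(dg, each = n)))
  sqf <- sum(lgamma(alpha)) - lgamma(a0) - sum((alpha - 1) * dg)
  sqm <- -sum(g[g > 0] * log(g[g > 0]))
  f1 <- elj + sqf + sqm
  # evidence of the null (all models equally frequent)
  mx <- apply(evidence, 1L, max)
  f0 <- sum(log(rowMeans(exp(evidence - mx))) + mx)
  bor <- 1 / (1 + exp(f1 - f0))
  draws <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                  n_samples, K)
  ep <- tabulate(max.col(draws, ties.method = "first"), K) / n_samples
  pxp <- ep * (1 - bor) + bor / K
  mods <- colnames(evidence)
  names(ep) <- names(pxp) <- names(alpha) <- mods
  list(alpha = alpha, expected_freq = alpha / a0, ep = ep, bor = bor,
       pxp = pxp, assignment = g)
}
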