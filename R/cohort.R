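#' Condition-specific parameter means of the generative model
#'
#' Group means of the fitted M3 parameters by condition and movement
#' modality: joystick (129 actions) — theta 15.5 (hunt) vs 11.4 (escape),
#' tau 322.0 vs 49.6, mu 0.68 vs 0.74; keyboard (9 actions) — theta 15.6 vs
#' 10.9, tau 383.8 vs 29.3, mu 0.95 vs 0.95. Hunting is slower-cadence and
#' more deterministic; escaping is faster-cadence and more stochastic, which
#' makes the evasion trajectory less predictable.
#'
#' @param modality `"joystick-129"` or `"keyboard-9"`.
#' @return list with `hunt` and `escape` parameter vectors.
#' @export
condition_param_means <- function(modality = c("joystick-129", "keyboard-9")) {
  modality <- match.arg(modality)
  if (modality == "joystick-129") {
    list(hunt = model_params(theta = 15.5, tau = 322.0, mu = 0.68),
         escape = model_params(theta = 11.4, tau = 49.6, mu = 0.74))
  } else {
    list(hunt = model_params(theta = 15.6, tau = 383.8, mu = 0.95),
         escape = model_params(theta = 10.9, tau = 29.3, mu = 0.95))
  }
}

#' Synthetic-cohort configuration
#'
#' Defines a cohort of simulated subjects whose movement is generated by M3
#' with condition-specific parameters: subject-level parameters are
#' truncated-normal draws around the condition means (SD =
#' `between_sd_frac` of each mean), fixed across that subject's trials, with
#' optional within-trial jitter. Trials follow the arena protocol (switch
#' cues with probability 0.5, pre-encounter stages after captures, online
#' difficulty calibration); synthetic trial durations default to 2-4 s to
#' keep window fitting desk-scale (the full 2-10 s protocol remains
#' available via `duration_range`).
#'
#' @param n_subjects number of simulated subjects.
#' @param trials_per_subject trials per subject.
#' @param duration_range main-stage duration range in seconds.
#' @param modality `"joystick-129"` (128 directions + null) or
#'   `"keyboard-9"` (8 directions + null).
#' @param means condition parameter means; defaults to
#'   [condition_param_means()] for the modality.
#' @param between_sd_frac between-subject SD as a fraction of each mean.
#' @param jitter_frac within-trial parameter jitter SD as a fraction of each
#'   mean.
#' @param switch_prob probability of a switch cue.
#' @param pre_prob,pre_range pre-encounter probability (after captures) and
#'   duration range (s).
#' @param calibrate enable online difficulty calibration.
#' @param warmup_trials unrecorded calibration trials before each session
#'   (see [run_session()]), so recorded trials reflect the staircase
#'   equilibrium rather than the cold start.
#' @param arena an [arena_config()].
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 5L, trials_per_subject = 60L,
                          duration_range = c(2, 4),
                          modality = c("joystick-129", "keyboard-9"),
                          means = NULL, between_sd_frac = 0.15,
                          jitter_frac = 0.05, switch_prob = 0.5,
                          pre_prob = 0.4, pre_range = c(0, 10),
                          calibrate = TRUE, warmup_trials = 60L,
                          arena = arena_config()) {
  modality <- match.arg(modality)
  if (is.null(means)) means <- condition_param_means(modality)
  stopifnot(between_sd_frac >= 0, jitter_frac >= 0, n_subjects >= 1,
            trials_per_subject >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 duration_range = duration_range, modality = modality,
                 means = means, between_sd_frac = between_sd_frac,
                 jitter_frac = jitter_frac, switch_prob = switch_prob,
                 pre_prob = pre_prob, pre_range = pre_range,
                 calibrate = calibrate,
                 warmup_trials = as.integer(warmup_trials), arena = arena),
            class = "cohort_config")
}

cohort_action_set <- function(config) {
  action_set(if (config$modality == "joystick-129") 128L else 8L)
}

#' Draw one subject's condition-specific parameters
#'
#' Truncated-normal draws around the condition means, truncated to the
#' parameter bounds, fixed across the subject's trials.
#'
#' @param config a [cohort_config()].
#' @return list with `hunt` and `escape` parameter vectors.
#' @export
sample_subject_params <- function(config) {
  b <- param_bounds("M3")
  lapply(config$means, function(m) {
    p <- m
    for (nm in names(m)) {
      sd <- config$between_sd_frac * abs(m[[nm]])
      p[[nm]] <- if (sd > 0) {
        rtrunc_norm(1L, m[[nm]], sd, b$lower[[nm]], b$upper[[nm]])
      } else m[[nm]]
    }
    p
  })
}

#' Generate a synthetic cohort
#'
#' For each subject, draws condition-specific M3 parameters, builds the
#' corresponding generative policy, and runs a full session against the
#' scripted arena agent. Fully reproducible from (config, seed); the
#' ground-truth parameters are kept in a manifest separate from the session
#' logs so they only enter analyses through explicit recovery tests.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @return a `cohort`: list with `sessions` (per-subject `session_log`s),
#'   `truth` (data.frame of ground-truth subject x condition parameters),
#'   `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  set.seed(seed)
  aset <- cohort_action_set(config)
  sessions <- vector("list", config$n_subjects)
  truth <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("s%02d", s)
    pars <- sample_subject_params(config)
    policy <- make_policy("M3", pars, aset, config$arena$player_speed,
                          prep = "optimal", jitter_frac = config$jitter_frac,
                          arena_radius = config$arena$radius)
    sessions[[s]] <- run_session(policy, config$arena,
                                 n_trials = config$trials_per_subject,
                                 duration_range = config$duration_range,
                                 switch_prob = config$switch_prob,
                                 pre_prob = config$pre_prob,
                                 pre_range = config$pre_range,
                                 calibrate = config$calibrate,
                                 warmup_trials = config$warmup_trials,
                                 subject_id = sid)
    truth[[s]] <- do.call(rbind, lapply(names(pars), function(cd) {
      data.frame(subject_id = sid, condition = cd,
                 theta = pars[[cd]][["theta"]], tau = pars[[cd]][["tau"]],
                 mu = pars[[cd]][["mu"]])
    }))
  }
  structure(list(sessions = sessions, truth = do.call(rbind, truth),
                 config = config, seed = seed), class = "cohort")
}

#' Fit movement models to a whole cohort
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param models model ids to fit per window.
#' @return combined window-fit data.frame (see [fit_session()]).
#' @export
fit_cohort <- function(cohort, models = "M3") {
  aset <- cohort_action_set(cohort$config)
  out <- lapply(cohort$sessions, fit_session, models = models, aset = aset)
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Combined per-trial metadata of a cohort
#'
#' @param cohort a `cohort`.
#' @return data.frame of all sessions' per-trial metadata.
#' @export
cohort_meta <- function(cohort) {
  do.call(rbind, lapply(cohort$sessions, `[[`, "meta"))
}
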