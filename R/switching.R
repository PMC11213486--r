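#' Transition magnitude after a switch
#'
#' The amount of state transition from the previous task toward the current
#' one: `curr_initial_cp - (1 - prev_final_cp)`. Both arguments are
#' condition-specific states in \[0, 1\] (each relative to its own trial's
#' condition), so `1 - prev_final_cp` is where the state stood with respect
#' to the *new* task just before the switch. For example, a hunt trial
#' ending at 76% hunt (`prev_final_cp = 0.76`, i.e. 24% toward escape)
#' followed by an escape trial starting at 60% escape gives a transition of
#' 0.36.
#'
#' @param prev_final_cp final-window `C_p` of the previous trial.
#' @param curr_initial_cp first-window `C_p` of the current trial.
#' @return transition magnitude in \[-1, 1\] (vectorized).
#' @export
transition_magnitude <- function(prev_final_cp, curr_initial_cp) {
  stopifnot(all(prev_final_cp >= 0 & prev_final_cp <= 1),
            all(curr_initial_cp >= 0 & curr_initial_cp <= 1))
  curr_initial_cp - (1 - prev_final_cp)
}

#' Time to reach a condition-specific criterion
#'
#' Time (s, from trial start) of the first window whose `C_p` reaches the
#' criterion (0.6 by default, i.e. substantial task specificity); censored
#' when the criterion is never reached.
#'
#' @param cp per-window `C_p` values of one trial, in window order.
#' @param times window start times in seconds (defaults to 240-ms spacing,
#'   15 frames at 16 ms).
#' @param threshold criterion level.
#' @return list with `time` (s, `NA` when censored) and `censored`.
#' @export
time_to_criterion <- function(cp, times = (seq_along(cp) - 1L) * 0.24,
                              threshold = 0.6) {
  stopifnot(length(cp) >= 1L, length(times) == length(cp))
  hit <- which(cp >= threshold)
  if (!length(hit)) return(list(time = NA_real_, censored = TRUE))
  list(time = times[hit[1L]], censored = FALSE)
}

#' Build per-trial transition records
#'
#' Joins each trial's initial `C_p` with the previous trial's final `C_p`
#' (within subject, consecutive trial indices only), computes the transition
#' magnitude on switch trials, and the time to criterion from the window
#' series. Trials with no windows are absent from the input and therefore
#' excluded listwise.
#'
#' @param cp output of [cp_timecourse()].
#' @param threshold criterion for [time_to_criterion()].
#' @return data.frame with one row per trial that has a scored predecessor:
#'   `subject_id`, `trial_index`, `condition`, `is_switch`,
#'   `prev_final_cp`, `initial_cp`, `transition` (`NA` on stay trials),
#'   `time_to_criterion`, `censored`.
#' @export
transition_records <- function(cp, threshold = 0.6) {
  tr <- cp$trials
  rows <- lapply(split(tr, tr$subject_id), function(d) {
    d <- d[order(d$trial_index), ]
    prev <- match(d$trial_index - 1L, d$trial_index)
    d$prev_final_cp <- d$final_cp[prev]
    d[!is.na(prev), ]
  })
  out <- do.call(rbind, rows)
  out$transition <- ifelse(out$is_switch,
                           transition_magnitude(out$prev_final_cp,
                                                out$initial_cp),
                           NA_real_)
  ttc <- lapply(seq_len(nrow(out)), function(i) {
    w <- cp$windows[cp$windows$subject_id == out$subject_id[i] &
                      cp$windows$trial_index == out$trial_index[i], ]
    w <- w[order(w$window), ]
    time_to_criterion(w$cp, w$start_s, threshold)
  })
  out$time_to_criterion <- vapply(ttc, function(x) x$time, 0)
  out$censored <- vapply(ttc, function(x) x$censored, TRUE)
  rownames(out) <- NULL
  out[, c("subject_id", "trial_index", "condition", "is_switch",
          "prev_final_cp", "initial_cp", "transition", "time_to_criterion",
          "censored")]
}

tidy_fit <- function(fit, flagged = FALSE) {
  co <- stats::coef(summary(fit))
  pcol <- grep("^Pr\\(", colnames(co))
  tab <- data.frame(term = rownames(co), estimate = co[, 1L],
                    se = co[, 2L],
                    statistic = co[, grep("value$", colnames(co))[1L]],
                    p_value = if (length(pcol)) co[, pcol[1L]] else NA_real_,
                    row.names = NULL)
  list(coefficients = tab, model = fit, flagged = flagged)
}

mixed_or_fixed <- function(formula_mixed, formula_fixed, data, family = NULL) {
  fit <- tryCatch({
    if (is.null(family)) {
      f <- lmerTest::lmer(formula_mixed, data = data)
      if (lme4::isSingular(f)) stop("singular fit")
      f
    } else {
      f <- lme4::glmer(formula_mixed, data = data, family = family)
      if (lme4::isSingular(f)) stop("singular fit")
      f
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) return(tidy_fit(fit))
  fit <- if (is.null(family)) stats::lm(formula_fixed, data = data)
         else stats::glm(formula_fixed, data = data, family = family)
  tidy_fit(fit, flagged = TRUE)
}

#' Suppression-load regression
#'
#' On switch trials, regresses the initial `C_p` of the current trial (or
#' the time to reach the criterion) on the final `C_p` of the previous trial
#' — the suppression load — with random intercepts for subject (and run when
#' present) and age/sex covariates when present. A negative slope on
#' `prev_final_cp` means a strongly condition-specific previous state impedes
#' the post-switch transition. Falls back to a fixed-effects model (flagged)
#' when the grouping is singular.
#'
#' @param records data.frame from [transition_records()].
#' @param outcome `"initial_cp"` or `"time_to_criterion"` (censored trials
#'   are excluded from the latter).
#' @return list with `coefficients` (term/estimate/se/statistic/p_value),
#'   `model`, `flagged`.
#' @export
suppression_load_model <- function(records,
                                   outcome = c("initial_cp",
                                               "time_to_criterion")) {
  outcome <- match.arg(outcome)
  d <- records[records$is_switch, ]
  if (outcome == "time_to_criterion") d <- d[!d$censored, ]
  covs <- intersect(c("age", "sex"), names(d))
  re <- c("(1 | subject_id)",
          if ("run_id" %in% names(d) && length(unique(d$run_id)) > 1L) {
            "(1 | run_id)"
          })
  rhs <- paste(c("prev_final_cp", covs), collapse = " + ")
  fm <- stats::as.formula(paste(outcome, "~", rhs, "+",
                                paste(re, collapse = " + ")))
  ff <- stats::as.formula(paste(outcome, "~", rhs))
  mixed_or_fixed(fm, ff, d)
}

#' Success ~ condition-specific state regression
#'
#' Mixed-effects logistic regression of trial success on the trial-mean
#' `C_p`, with random intercepts for subject (and run when present) and
#' age/sex covariates when present. A positive slope means condition-
#' specific movement generation pays off. Falls back to a fixed-effects
#' logistic model (flagged) on singular fits or separation.
#'
#' @param trials data.frame with `success` (logical or 0/1), `mean_cp`,
#'   `subject_id`, and optionally `run_id`, `age`, `sex`.
#' @return list with `coefficients`, `model`, `flagged`.
#' @export
success_cp_model <- function(trials) {
  covs <- intersect(c("age", "sex"), names(trials))
  re <- c("(1 | subject_id)",
          if ("run_id" %in% names(trials) &&
              length(unique(trials$run_id)) > 1L) "(1 | run_id)")
  rhs <- paste(c("mean_cp", covs), collapse = " + ")
  fm <- stats::as.formula(paste("success ~", rhs, "+",
                                paste(re, collapse = " + ")))
  ff <- stats::as.formula(paste("success ~", rhs))
  mixed_or_fixed(fm, ff, trials, family = stats::binomial())
}
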