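#' Thigmotaxis
#'
#' Fraction of frames spent in the outer half of the arena by area, i.e. at
#' radial distance greater than `radius / sqrt(2)` (the circle enclosing 50%
#' of the area); frames exactly on that circle count as inside.
#'
#' @param positions matrix of positions (one row per frame).
#' @param radius arena radius.
#' @return fraction in \[0, 1\].
#' @export
thigmotaxis <- function(positions, radius) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2L)
  if (!nrow(positions)) stop("thigmotaxis needs at least one frame")
  r <- sqrt(positions[, 1L]^2 + positions[, 2L]^2)
  mean(r > radius / sqrt(2))
}

player_steps <- function(trial) {
  P <- cbind(trial$frames$player_x, trial$frames$player_y)
  if (nrow(P) < 2L) return(NULL)
  diff(P)
}

#' Movement linearity
#'
#' Mean cosine between each actual movement step and the ideal straight-line
#' direction: toward the prey's current position in hunt, away from the
#' predator in escape. Frames with no player movement are skipped; trials
#' with no movement are undefined (`NA`).
#'
#' @param trial a `trial_log`.
#' @param exclude_boost drop frames on which the predator was boosting.
#' @return mean dot product in \[-1, 1\], or `NA`.
#' @export
linearity <- function(trial, exclude_boost = FALSE) {
  st <- player_steps(trial)
  if (is.null(st)) return(NA_real_)
  P <- cbind(trial$frames$player_x, trial$frames$player_y)
  A <- cbind(trial$frames$agent_x, trial$frames$agent_y)
  n <- nrow(st)
  ideal <- if (trial$condition == "hunt") {
    A[seq_len(n), , drop = FALSE] - P[seq_len(n), , drop = FALSE]
  } else {
    P[seq_len(n), , drop = FALSE] - A[seq_len(n), , drop = FALSE]
  }
  keep <- sqrt(rowSums(st^2)) > 1e-12 & sqrt(rowSums(ideal^2)) > 1e-12
  if (exclude_boost) keep <- keep & !trial$frames$boost[seq_len(n)]
  if (!any(keep)) return(NA_real_)
  su <- st[keep, , drop = FALSE] / sqrt(rowSums(st[keep, , drop = FALSE]^2))
  iu <- ideal[keep, , drop = FALSE] /
    sqrt(rowSums(ideal[keep, , drop = FALSE]^2))
  mean(rowSums(su * iu))
}

#' Movement variability
#'
#' Two variants of trajectory unpredictability. The primary measure is the
#' mean absolute frame-to-frame heading change in degrees (wrapped to
#' \[0, 180\]). The secondary measure is the number of direction changes per
#' second, capped at 59 (the per-second framing of a 60-Hz display). Heading
#' is defined only on moving frames and pauses break the heading chain, so
#' no change is counted across a pause.
#'
#' @param trial a `trial_log`.
#' @param exclude_boost drop frames on which the predator was boosting.
#' @param change_tol_deg minimum heading change (degrees) counted as a
#'   direction change in the per-second variant.
#' @return named vector `c(deg_per_frame, changes_per_s)` (`NA` when fewer
#'   than two moving frames).
#' @export
movement_variability <- function(trial, exclude_boost = FALSE,
                                 change_tol_deg = 1e-6) {
  st <- player_steps(trial)
  if (is.null(st)) return(c(deg_per_frame = NA_real_, changes_per_s = NA_real_))
  keep <- sqrt(rowSums(st^2)) > 1e-12
  if (exclude_boost) keep <- keep & !trial$frames$boost[seq_len(nrow(st))]
  heading <- rep(NA_real_, nrow(st))
  heading[keep] <- atan2(st[keep, 2L], st[keep, 1L]) * 180 / pi
  # consecutive moving frames only: pauses break the chain
  ok <- keep[-1L] & keep[-length(keep)]
  if (!any(ok)) {
    return(c(deg_per_frame = NA_real_, changes_per_s = NA_real_))
  }
  d <- abs(heading[-1L][ok] - heading[-length(heading)][ok])
  d <- ifelse(d > 180, 360 - d, d)
  dur_s <- nrow(trial$frames) * 0.016
  chg <- sum(d > change_tol_deg) / dur_s
  c(deg_per_frame = mean(d), changes_per_s = min(chg, 59))
}

#' Success rates by stratum
#'
#' Per-subject success proportions, stratified by condition, by switch/stay,
#' or overall.
#'
#' @param meta per-trial metadata (rows of `session_log$meta`, possibly from
#'   several subjects), with `subject_id`, `condition`, `is_switch`,
#'   `outcome` columns.
#' @param by `"condition"`, `"switch"`, or `"overall"`.
#' @return data.frame of per-subject rates with an `n` column (empty strata
#'   are absent).
#' @export
success_rates <- function(meta, by = c("condition", "switch", "overall")) {
  by <- match.arg(by)
  meta$success <- meta$outcome == "success"
  f <- switch(by,
              condition = success ~ subject_id + condition,
              switch = success ~ subject_id + is_switch,
              overall = success ~ subject_id)
  rate <- stats::aggregate(f, data = meta, FUN = mean)
  n <- stats::aggregate(f, data = meta, FUN = length)
  names(rate)[ncol(rate)] <- "rate"
  names(n)[ncol(n)] <- "n"
  merge(rate, n)
}

#' Trajectory metrics for a set of sessions
#'
#' Per-trial thigmotaxis (pre-encounter and main phases), linearity and
#' movement variability, tabulated for group-level comparison.
#'
#' @param sessions list of `session_log`s (or one).
#' @param exclude_boost drop predator-boost frames from linearity and
#'   variability.
#' @return data.frame with one row per trial.
#' @export
trajectory_metrics <- function(sessions, exclude_boost = FALSE) {
  if (inherits(sessions, "session_log")) sessions <- list(sessions)
  rows <- lapply(sessions, function(se) {
    R <- se$config$radius
    do.call(rbind, lapply(se$trials, function(tr) {
      mv <- movement_variability(tr, exclude_boost)
      data.frame(subject_id = se$subject_id, run_id = se$run_id,
                 trial_index = tr$trial_index, condition = tr$condition,
                 is_switch = tr$is_switch, outcome = tr$outcome,
                 thigmotaxis_pre = if (!is.null(tr$pre_frames)) {
                   thigmotaxis(tr$pre_frames, R)
                 } else NA_real_,
                 thigmotaxis_main = thigmotaxis(
                   cbind(tr$frames$player_x, tr$frames$player_y), R),
                 linearity = linearity(tr, exclude_boost),
                 variability_deg = mv[["deg_per_frame"]],
                 variability_changes_s = mv[["changes_per_s"]])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
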