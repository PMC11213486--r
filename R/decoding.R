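#' Trial-level feature table
#'
#' Averages the fitted M3 parameters over every window of a trial, giving one
#' representative (theta, tau, mu) per trial — the decoder's feature vector.
#'
#' @param fits window-fit data.frame from [fit_session()] (M3 rows are used).
#' @return data.frame with one row per subject x trial: `subject_id`,
#'   `trial_index`, `condition`, `theta`, `tau`, `mu`, `n_windows`.
#' @export
trial_features <- function(fits) {
  fits <- fits[fits$model == "M3", ]
  if (!nrow(fits)) stop("no M3 window fits supplied")
  ag <- stats::aggregate(cbind(theta, tau, mu) ~ subject_id + trial_index +
                           condition, data = fits, FUN = mean)
  nw <- stats::aggregate(window ~ subject_id + trial_index, data = fits,
                         FUN = length)
  names(nw)[3L] <- "n_windows"
  out <- merge(ag, nw, by = c("subject_id", "trial_index"))
  out[order(out$subject_id, out$trial_index), ]
}

zscore_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

zscore_apply <- function(X, z) sweep(sweep(X, 2L, z$mu), 2L, z$sd, `/`)

svm_train <- function(X, y, probability) {
  # inverse-frequency class weights remove the finite-sample majority bias
  # that leave-one-trial-out induces (the training fold always has one
  # fewer trial of the left-out class), keeping the permutation null at
  # chance
  tab <- table(y)
  w <- as.numeric(sum(tab) / (length(tab) * tab))
  names(w) <- names(tab)
  e1071::svm(x = X, y = y, kernel = "linear", cost = 1, scale = FALSE,
             class.weights = w, probability = probability)
}

feature_cols <- c("theta", "tau", "mu")

loto_one_subject <- function(feats, probability = TRUE) {
  X <- as.matrix(feats[, feature_cols])
  y <- factor(feats$condition, levels = c("escape", "hunt"))
  if (nlevels(droplevels(y)) < 2L) {
    stop("decoder needs both conditions for subject ", feats$subject_id[1L])
  }
  n <- nrow(X)
  p_hunt <- numeric(n)
  pred <- character(n)
  for (i in seq_len(n)) {
    z <- zscore_fit(X[-i, , drop = FALSE])
    fit <- svm_train(zscore_apply(X[-i, , drop = FALSE], z), y[-i],
                     probability)
    xt <- zscore_apply(X[i, , drop = FALSE], z)
    pr <- stats::predict(fit, xt, probability = probability)
    pred[i] <- as.character(pr)
    p_hunt[i] <- if (probability) {
      attr(pr, "probabilities")[1L, "hunt"]
    } else as.numeric(pr == "hunt")
  }
  data.frame(subject_id = feats$subject_id,
             trial_index = feats$trial_index,
             condition = as.character(y), predicted = pred,
             posterior_hunt = p_hunt,
             correct = pred == as.character(y))
}

#' Leave-one-trial-out condition decoder
#'
#' For each subject, a linear-kernel maximum-margin classifier (C = 1) is
#' trained on the trial features of all trials but one, with features
#' z-scored on the training fold and the posterior obtained by Platt sigmoid
#' calibration fit on the training fold only; the left-out trial is then
#' scored. Accuracy is the fraction of left-out trials whose maximum-
#' posterior class matches the condition, computed within subject and
#' averaged across subjects.
#'
#' @param features trial-feature data.frame from [trial_features()].
#' @param probability fit the Platt posterior (set `FALSE` for class-only
#'   decoding, e.g. inside permutation nulls).
#' @return list with `trials` (per-trial posterior and correctness),
#'   `subject_accuracy`, and `accuracy` (mean over subjects).
#' @export
fit_decoder_loto <- function(features, probability = TRUE) {
  per <- lapply(split(features, features$subject_id), loto_one_subject,
                probability = probability)
  trials <- do.call(rbind, per)
  rownames(trials) <- NULL
  acc <- vapply(per, function(d) mean(d$correct), 0)
  list(trials = trials, subject_accuracy = acc, accuracy = mean(acc))
}

#' Condition-specific state from a decoder posterior
#'
#' `C_p` is the task-appropriate decoding probability: the posterior
#' probability of hunt on hunt trials and its complement on escape trials.
#' `C_p = 1` means the movement-generation state is fully specific to the
#' current condition, `C_p = 0.5` undifferentiated, `C_p = 0` specific to
#' the wrong condition.
#'
#' @param posterior_hunt decoder posterior probability of the hunt state.
#' @param condition `"hunt"` or `"escape"` (vectorized).
#' @return `C_p` in \[0, 1\].
#' @export
cp_from_posterior <- function(posterior_hunt, condition) {
  if (any(posterior_hunt < 0 | posterior_hunt > 1)) {
    stop("posterior must lie in [0, 1]")
  }
  is_hunt <- rep_len(condition == "hunt", length(posterior_hunt))
  ifelse(is_hunt, posterior_hunt, 1 - posterior_hunt)
}

#' Per-window condition-specific state time courses
#'
#' Scores every window's fitted parameters with the decoder trained on all
#' trials of the subject except the window's own trial (leave-one-trial-out
#' discipline), converts the posterior to `C_p`, and summarizes each trial by
#' its initial (first-window), final (last-window) and mean `C_p`.
#'
#' @param fits window-fit data.frame (M3 rows are used).
#' @param features trial-feature data.frame from [trial_features()].
#' @return list with `windows` (per-window `C_p` rows, keyed by
#'   subject/trial/window with `start_s`) and `trials` (per-trial
#'   `initial_cp`, `final_cp`, `mean_cp`, `n_windows`).
#' @export
cp_timecourse <- function(fits, features) {
  fits <- fits[fits$model == "M3", ]
  out <- list()
  for (sid in unique(features$subject_id)) {
    fe <- features[features$subject_id == sid, ]
    fw <- fits[fits$subject_id == sid, ]
    X <- as.matrix(fe[, feature_cols])
    y <- factor(fe$condition, levels = c("escape", "hunt"))
    for (i in seq_len(nrow(fe))) {
      wrows <- fw[fw$trial_index == fe$trial_index[i], ]
      if (!nrow(wrows)) next
      z <- zscore_fit(X[-i, , drop = FALSE])
      fit <- svm_train(zscore_apply(X[-i, , drop = FALSE], z), y[-i], TRUE)
      xt <- zscore_apply(as.matrix(wrows[, feature_cols]), z)
      pr <- stats::predict(fit, xt, probability = TRUE)
      ph <- attr(pr, "probabilities")[, "hunt"]
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, trial_index = fe$trial_index[i],
        condition = fe$condition[i], is_switch = wrows$is_switch,
        window = wrows$window, start_s = wrows$start_s,
        posterior_hunt = as.numeric(ph),
        cp = cp_from_posterior(as.numeric(ph), fe$condition[i]))
    }
  }
  windows <- do.call(rbind, out)
  rownames(windows) <- NULL
  trials <- do.call(rbind, lapply(
    split(windows, list(windows$subject_id, windows$trial_index),
          drop = TRUE),
    function(d) {
      d <- d[order(d$window), ]
      data.frame(subject_id = d$subject_id[1L],
                 trial_index = d$trial_index[1L],
                 condition = d$condition[1L], is_switch = d$is_switch[1L],
                 initial_cp = d$cp[1L], final_cp = d$cp[nrow(d)],
                 mean_cp = mean(d$cp), n_windows = nrow(d))
    }))
  trials <- trials[order(trials$subject_id, trials$trial_index), ]
  rownames(trials) <- NULL
  list(windows = windows, trials = trials)
}

#' Permutation null for the condition decoder
#'
#' Shuffles condition labels within subject and reruns the leave-one-trial-
#' out decoder for each permutation (class decisions only; no posterior
#' calibration is needed for accuracy), giving the chance-level distribution
#' of decoding accuracy and an empirical p-value for an observed accuracy.
#'
#' @param features trial-feature data.frame from [trial_features()].
#' @param n_perm number of permutations (>= 100 recommended).
#' @param observed optional observed accuracy to be tested.
#' @return list with `accuracies` (length `n_perm`), `mean`, and `p_value`
#'   (when `observed` is given; `(1 + #{null >= observed}) / (n_perm + 1)`).
#' @export
decoding_null <- function(features, n_perm = 100L, observed = NULL) {
  acc <- vapply(seq_len(n_perm), function(p) {
    perm <- permute_condition_labels(features)
    fit_decoder_loto(perm, probability = FALSE)$accuracy
  }, 0)
  p_value <- if (is.null(observed)) NA_real_ else {
    (1 + sum(acc >= observed)) / (n_perm + 1)
  }
  list(accuracies = acc, mean = mean(acc), p_value = p_value)
}

#' Shuffle condition labels within subject
#'
#' Permutes the `condition` column within each subject, preserving the label
#' multiset per subject and leaving everything else untouched. Used to build
#' chance-level decoding nulls.
#'
#' @param x a data.frame with `subject_id` and `condition` columns.
#' @return `x` with conditions permuted within subject.
#' @export
permute_condition_labels <- function(x) {
  for (sid in unique(x$subject_id)) {
    i <- which(x$subject_id == sid)
    x$condition[i] <- x$condition[sample(i)]
  }
  x
}
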