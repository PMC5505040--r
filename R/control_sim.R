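#' Finite-state controller configuration
#'
#' The controller gates classifier posteriors into hand commands: a
#' command is emitted only when the decoder is idle (the previous movement
#' has finished executing) and the winning class's posterior exceeds
#' `theta`. On real hardware movement termination is sensed from motor
#' currents; the simulator replaces that with a fixed execution-duration
#' surrogate.
#'
#' @param theta posterior rejection threshold (default 0.995).
#' @param exec_duration_s movement execution time surrogate in seconds
#'   (default 1.0).
#' @param tick_s decision interval in seconds (default 0.05, the window
#'   increment).
#' @return object of class `controller_config`.
#' @export
controller_config <- function(theta = 0.995, exec_duration_s = 1.0,
                              tick_s = 0.05) {
  if (theta <= 0 || exec_duration_s <= 0 || tick_s <= 0)
    stop("all controller parameters must be positive", call. = FALSE)
  structure(list(theta = theta, exec_duration_s = exec_duration_s,
                 tick_s = tick_s), class = "controller_config")
}

#' Pick-and-place trial configuration
#'
#' A trial requires the command sequence `required_commands` (by default
#' three grips each followed by hand open, then the index-pointer press:
#' seven commands in total) to be realised within `time_limit_s` (60 s for
#' able-bodied subjects, 75 s for the amputee participant). A wrong
#' command invalidates progress until an `open_class` command is issued
#' (the user-correction rule).
#'
#' @param time_limit_s trial time limit in seconds (default 60).
#' @param required_commands ordered class-id sequence; default
#'   `c(1, 5, 2, 5, 3, 5, 4)` = power, open, lateral, open, tripod, open,
#'   index pointer under the real-time class map.
#' @param open_class class id of the hand-open command (default 5).
#' @return object of class `trial_config`.
#' @export
trial_config <- function(time_limit_s = 60,
                         required_commands = c(1L, 5L, 2L, 5L, 3L, 5L, 4L),
                         open_class = 5L) {
  if (time_limit_s <= 0) stop("time_limit_s must be > 0", call. = FALSE)
  if (!length(required_commands))
    stop("required_commands must be non-empty", call. = FALSE)
  structure(list(time_limit_s = time_limit_s,
                 required_commands = as.integer(required_commands),
                 open_class = as.integer(open_class)),
            class = "trial_config")
}

#' Initial controller state
#' @return list state consumed by [fsm_step()].
#' @export
fsm_init <- function() list(mode = "IDLE", until = -Inf, pose = NA_integer_)

#' One tick of the finite-state controller
#'
#' While EXECUTING, no command can be emitted; the state returns to IDLE
#' once the execution window has elapsed. While IDLE, a command is emitted
#' iff the maximum posterior exceeds `theta`, the winning class is a
#' movement (not rest, class 0), and it differs from the current hand pose
#' (re-gripping an already-formed grip is suppressed as a physical no-op).
#'
#' @param state controller state from [fsm_init()] or a previous step.
#' @param posterior normalized probability vector named by class id.
#' @param t current time in seconds.
#' @param cfg a [controller_config()].
#' @return list `(state, command)`; `command` is `NA` when none is
#'   emitted.
#' @export
fsm_step <- function(state, posterior, t, cfg = controller_config()) {
  if (abs(sum(posterior) - 1) > 1e-6)
    stop("posterior is not normalized", call. = FALSE)
  if (state$mode == "EXECUTING") {
    if (t < state$until)
      return(list(state = state, command = NA_integer_))
    state$mode <- "IDLE"
  }
  best <- which.max(posterior)
  cls <- as.integer(names(posterior)[best])
  if (length(cls) == 0L || is.na(cls))
    cls <- as.integer(best)
  if (posterior[best] > cfg$theta && cls != 0L &&
      (is.na(state$pose) || cls != state$pose)) {
    state$mode <- "EXECUTING"
    state$until <- t + cfg$exec_duration_s
    state$pose <- cls
    return(list(state = state, command = cls))
  }
  list(state = state, command = NA_integer_)
}

# Score a command log against the required sequence with the
# open-to-correct rule. Returns list(success, completion_time).
score_commands <- function(log_t, log_cls, tc) {
  idx <- 1L; err <- FALSE
  done_t <- NA_real_
  for (i in seq_along(log_cls)) {
    cls <- log_cls[i]
    if (err) {
      if (cls == tc$open_class) err <- FALSE
      next
    }
    if (cls == tc$required_commands[idx]) {
      idx <- idx + 1L
      if (idx > length(tc$required_commands)) { done_t <- log_t[i]; break }
    } else if (cls != tc$open_class) {
      err <- TRUE
    }
  }
  success <- !is.na(done_t) && done_t <= tc$time_limit_s
  list(success = success,
       completion_time = if (success) done_t else NA_real_)
}

#' Simulate one closed-loop pick-and-place trial
#'
#' Runs the full decoding pipeline tick by tick on a control stream:
#' synchronise, window, extract features, standardize with the training
#' statistics, compute posteriors, and gate them through the finite-state
#' controller. The trial succeeds iff the emitted command log realises the
#' required command sequence in order within the time limit; a wrong
#' command invalidates progress until an open command is issued.
#'
#' @param model an [fit_lda()] model trained on standardized features.
#' @param standardizer the [fit_standardizer()] used at training time.
#' @param stream list `(recording, intents)` from
#'   [generate_control_stream()].
#' @param wc [window_config()] matching the training features.
#' @param cc a [controller_config()].
#' @param tc a [trial_config()].
#' @param modality,sensors feature-extraction settings matching training.
#' @return object of class `trial_result`: `success`,
#'   `completion_time_s`, `command_log` (data.frame time, class),
#'   `rejection_fraction`.
#' @export
simulate_trial <- function(model, standardizer, stream,
                           wc = window_config(),
                           cc = controller_config(), tc = trial_config(),
                           modality = "both", sensors = NULL) {
  F <- build_feature_matrix(synchronize(stream$recording), wc,
                            modality = modality, sensors = sensors)
  Fz <- apply_standardizer(standardizer, F)
  P <- predict_posterior(model, Fz$X)
  state <- fsm_init()
  times <- F$t
  cmd_t <- numeric(0); cmd_c <- integer(0)
  n_reject <- 0L
  for (i in seq_along(times)) {
    if (times[i] > tc$time_limit_s) break
    if (max(P[i, ]) <= cc$theta) n_reject <- n_reject + 1L
    step <- fsm_step(state, P[i, ], times[i], cc)
    state <- step$state
    if (!is.na(step$command)) {
      cmd_t <- c(cmd_t, times[i]); cmd_c <- c(cmd_c, step$command)
    }
  }
  n_ticks <- sum(times <= tc$time_limit_s)
  sc <- score_commands(cmd_t, cmd_c, tc)
  structure(list(success = sc$success,
                 completion_time_s = sc$completion_time,
                 command_log = data.frame(time = cmd_t, class = cmd_c),
                 rejection_fraction = if (n_ticks) n_reject / n_ticks else NA),
            class = "trial_result")
}

#' Completion-rate and completion-time summary
#'
#' Completion rate (CR) is the percentage of successful trials;
#' completion time (CT) statistics are computed over successful trials
#' only. The CT confidence interval uses the percentile bootstrap of the
#' mean (100 iterations); with fewer than two successes no interval is
#' reported.
#'
#' @param results list of `trial_result` objects.
#' @param n_boot bootstrap iterations for the CT interval.
#' @param seed RNG seed for the bootstrap.
#' @return list `cr` (%), `ct_mean` (s, `NA` if no success), `ct_ci`
#'   (`c(low, high)` or `NULL`), `n_trials`, `n_success`.
#' @export
completion_metrics <- function(results, n_boot = 100L, seed = 1L) {
  if (!length(results)) stop("empty trial collection", call. = FALSE)
  succ <- vapply(results, function(r) isTRUE(r$success), logical(1))
  cts <- vapply(results, function(r) r$completion_time_s, numeric(1))[succ]
  list(cr = 100 * mean(succ),
       ct_mean = if (length(cts)) mean(cts) else NA_real_,
       ct_ci = if (length(cts) >= 2L) bootstrap_ci(cts, n_boot, seed = seed)
               else NULL,
       n_trials = length(results), n_success = sum(succ))
}
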