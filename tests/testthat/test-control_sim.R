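post <- function(winner, p, classes = 0:5) {
  v <- rep((1 - p) / (length(classes) - 1L), length(classes))
  v[match(winner, classes)] <- p
  names(v) <- classes
  v
}

test_that("fsm_step gates commands by confidence, state and pose", {
  cc <- controller_config(theta = 0.995, exec_duration_s = 1)
  s0 <- fsm_init()
  step <- fsm_step(s0, post(1L, 0.999), t = 0, cfg = cc)
  expect_equal(step$command, 1L)
  expect_equal(step$state$mode, "EXECUTING")
  # executing: nothing can fire, even at full confidence
  step2 <- fsm_step(step$state, post(2L, 0.999), t = 0.5, cfg = cc)
  expect_true(is.na(step2$command))
  # back to idle after the execution window
  step3 <- fsm_step(step$state, post(2L, 0.999), t = 1.2, cfg = cc)
  expect_equal(step3$command, 2L)
  # sub-threshold confidence never fires
  step4 <- fsm_step(s0, post(1L, 0.99), t = 0, cfg = cc)
  expect_true(is.na(step4$command))
  expect_equal(step4$state$mode, "IDLE")
  # rest and pose repeats are suppressed
  expect_true(is.na(fsm_step(s0, post(0L, 0.999), 0, cc)$command))
  expect_true(is.na(fsm_step(step3$state, post(2L, 0.999), 3, cc)$command))
  expect_error(fsm_step(s0, c(`1` = 0.5, `2` = 0.2), 0, cc),
               "not normalized")
})

test_that("scripted posterior streams yield hand-verifiable command logs", {
  cc <- controller_config(theta = 0.9, exec_duration_s = 1, tick_s = 0.5)
  script <- list(post(1L, 0.99), post(1L, 0.99), post(0L, 0.99),
                 post(5L, 0.95), post(2L, 0.5), post(2L, 0.99))
  state <- fsm_init()
  log <- integer(0)
  for (i in seq_along(script)) {
    st <- fsm_step(state, script[[i]], t = (i - 1L) * 0.5, cfg = cc)
    state <- st$state
    if (!is.na(st$command)) log <- c(log, st$command)
  }
  # t=0 fires 1; t=0.5 executing; t=1.0 rest; t=1.5 fires 5; t=2.0 low
  # confidence; t=2.5 fires 2
  expect_identical(log, c(1L, 5L, 2L))
})

test_that("command scoring implements the open-to-correct rule", {
  tc <- trial_config(60, required_commands = c(1L, 5L, 2L), open_class = 5L)
  sc <- emgimu:::score_commands(c(1, 3, 5), c(1L, 5L, 2L), tc)
  expect_true(sc$success)
  expect_equal(sc$completion_time, 5)
  # a wrong command blocks progress until open is issued
  sc2 <- emgimu:::score_commands(c(1, 2, 3, 4, 5, 6),
                                 c(1L, 3L, 2L, 5L, 5L, 2L), tc)
  expect_true(sc2$success)
  expect_equal(sc2$completion_time, 6)
  sc3 <- emgimu:::score_commands(c(1, 2, 3), c(1L, 3L, 2L), tc)
  expect_false(sc3$success)
  # over the time limit is a failure
  tc2 <- trial_config(4, required_commands = c(1L, 5L, 2L))
  expect_false(emgimu:::score_commands(c(1, 3, 5), c(1L, 5L, 2L),
                                       tc2)$success)
})

test_that("a well-trained decoder completes the pick-and-place trial", {
  cfg <- default_configs("realtime", trial_duration_s = 2,
                         rest_duration_s = 1, n_sensors = 4L, seed = 3)
  F <- build_feature_matrix(synchronize(generate_recording(cfg)))
  S <- fit_standardizer(F)
  model <- fit_lda(apply_standardizer(S, F)$X, F$y)
  req <- c(1L, 5L, 2L, 5L, 3L, 5L, 4L)
  tr <- intent_trace(req, onset = seq(1, by = 3, length.out = 7),
                     offset = seq(3, by = 3, length.out = 7))
  stream <- generate_control_stream(
    default_configs("realtime", trial_duration_s = 2, rest_duration_s = 1,
                    n_sensors = 4L, seed = 101), tr)
  res <- simulate_trial(model, S, stream, tc = trial_config(60))
  expect_true(res$success)
  # completion time about the intent span: last intended command starts
  # at 19 s; allow the window length + one execution
  expect_lt(abs(res$completion_time_s - 19), 2.5)
  expect_identical(res$command_log$class, req)
  # theta = 1: no commands, failure at the time limit
  res1 <- simulate_trial(model, S, stream,
                         cc = controller_config(theta = 1),
                         tc = trial_config(60))
  expect_false(res1$success)
  expect_equal(nrow(res1$command_log), 0L)
  expect_equal(res1$rejection_fraction, 1)
})

test_that("raising theta weakly decreases commands on a fixed stream", {
  cfg <- default_configs("realtime", trial_duration_s = 2,
                         rest_duration_s = 1, n_sensors = 4L, seed = 3)
  F <- build_feature_matrix(synchronize(generate_recording(cfg)))
  S <- fit_standardizer(F)
  model <- fit_lda(apply_standardizer(S, F)$X, F$y)
  tr <- intent_trace(c(1L, 5L), onset = c(1, 4), offset = c(3, 6))
  stream <- generate_control_stream(
    default_configs("realtime", trial_duration_s = 2, rest_duration_s = 1,
                    n_sensors = 4L, seed = 55), tr)
  n_cmd <- rej <- numeric(0)
  for (th in c(0.5, 0.9, 0.995, 0.99999)) {
    r <- simulate_trial(model, S, stream,
                        cc = controller_config(theta = th),
                        tc = trial_config(60))
    n_cmd <- c(n_cmd, nrow(r$command_log))
    rej <- c(rej, r$rejection_fraction)
    # commands at least exec_duration apart
    if (nrow(r$command_log) > 1L)
      expect_true(all(diff(r$command_log$time) >= 1 - 1e-9))
  }
  expect_true(all(diff(n_cmd) <= 0))
  expect_true(all(diff(rej) >= 0))
})

test_that("completion metrics summarise trial collections", {
  mk <- function(success, ct = NA_real_)
    structure(list(success = success, completion_time_s = ct),
              class = "trial_result")
  res <- list(mk(TRUE, 20), mk(TRUE, 30), mk(TRUE, 25), mk(FALSE))
  m <- completion_metrics(res)
  expect_equal(m$cr, 75)
  expect_equal(m$ct_mean, 25)
  expect_length(m$ct_ci, 2L)
  m0 <- completion_metrics(list(mk(FALSE), mk(FALSE)))
  expect_equal(m0$cr, 0)
  expect_true(is.na(m0$ct_mean))
  expect_null(m0$ct_ci)
  mc <- completion_metrics(list(mk(TRUE, 10), mk(TRUE, 10)))
  expect_equal(unname(mc$ct_ci), c(10, 10))
  expect_error(completion_metrics(list()), "empty")
})
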