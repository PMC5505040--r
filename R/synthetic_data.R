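#' Synthetic acquisition-protocol configuration
#'
#' Describes a synthetic multi-sensor sEMG + inertial recording session.
#' The defaults emulate the offline acquisition protocol: each movement
#' class is repeated `n_repetitions` times with `trial_duration_s`-second
#' trials interleaved with 5-s resting periods, recorded by 12 EMG-IM
#' sensor pods (EMG at 2 kHz, inertial channels at 128 Hz).
#'
#' Surface EMG is modelled as amplitude-modulated Gaussian noise: during a
#' class-`c` segment, sensor `s` outputs zero-mean noise with standard
#' deviation `emg_gain[c + 1, s] * noise_sd_emg` (row 1 of the gain matrix
#' is the rest baseline). Inertial class structure is carried by channel
#' means (postural offsets): channel `j` has mean `im_offset[c + 1, j]`.
#' Sensors outside `informative_sensors` receive class-independent rows so
#' that they carry no decodable information. Optional extras: a 50 Hz
#' powerline sinusoid on the EMG channels, label-onset jitter to exercise
#' relabelling, and a linear coupling from the per-sensor EMG amplitude
#' envelope into inertial channels (for envelope-reconstruction tests).
#'
#' @param n_classes number of non-rest movement classes.
#' @param n_sensors number of EMG-IM sensors (default 12).
#' @param n_repetitions repetitions per class (default 6).
#' @param trial_duration_s,rest_duration_s movement / rest segment lengths
#'   in seconds (defaults 5 and 5).
#' @param f_emg,f_im sampling rates in Hz (defaults 2000 and 128).
#' @param emg_gain `(n_classes + 1) x n_sensors` matrix of per-class EMG
#'   amplitude scales; row 1 is rest. `NULL` uses a deterministic default
#'   pattern.
#' @param im_offset `(n_classes + 1) x 9 n_sensors` matrix of per-class
#'   inertial channel means; row 1 is rest. `NULL` uses a deterministic
#'   default pattern.
#' @param informative_sensors sensor indices carrying class information;
#'   the rest get class-independent gain/offset rows.
#' @param noise_sd_emg,noise_sd_im noise standard deviations.
#' @param coupling `NULL`, or a numeric vector of length 9 (recycled per
#'   sensor) or `9 * n_sensors`: channel `j` of sensor `s` receives
#'   `coupling[j] * envelope_s(t)` where the envelope is the instantaneous
#'   EMG noise standard deviation of that sensor.
#' @param powerline_amp amplitude of the injected 50 Hz interference.
#' @param onset_jitter_ms label-boundary jitter in ms (labels only; the
#'   signal keeps the true transition times).
#' @param seed random seed; all stochasticity flows through it.
#' @param class_map optional named character vector of class names.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 40L, n_sensors = 12L,
                         n_repetitions = 6L, trial_duration_s = 5,
                         rest_duration_s = 5, f_emg = 2000, f_im = 128,
                         emg_gain = NULL, im_offset = NULL,
                         informative_sensors = seq_len(n_sensors),
                         noise_sd_emg = 1, noise_sd_im = 0.2,
                         coupling = NULL, powerline_amp = 0,
                         onset_jitter_ms = 0, seed = 1L,
                         class_map = NULL) {
  n_classes <- as.integer(n_classes); n_sensors <- as.integer(n_sensors)
  n_repetitions <- as.integer(n_repetitions)
  if (any(c(n_classes, n_sensors, n_repetitions) < 1L))
    stop("n_classes, n_sensors and n_repetitions must all be >= 1",
         call. = FALSE)
  if (trial_duration_s <= 0 || rest_duration_s <= 0)
    stop("durations must be positive", call. = FALSE)
  if (noise_sd_emg < 0 || noise_sd_im < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (!all(informative_sensors %in% seq_len(n_sensors)))
    stop("informative_sensors must be a subset of 1..n_sensors",
         call. = FALSE)
  if (is.null(emg_gain))
    emg_gain <- default_emg_gain(n_classes, n_sensors, informative_sensors)
  if (is.null(im_offset))
    im_offset <- default_im_offset(n_classes, n_sensors, informative_sensors)
  emg_gain <- as.matrix(emg_gain); im_offset <- as.matrix(im_offset)
  if (nrow(emg_gain) != n_classes + 1L || ncol(emg_gain) != n_sensors)
    stop("emg_gain must be (n_classes + 1) x n_sensors", call. = FALSE)
  if (nrow(im_offset) != n_classes + 1L ||
      ncol(im_offset) != 9L * n_sensors)
    stop("im_offset must be (n_classes + 1) x 9*n_sensors", call. = FALSE)
  if (!is.null(coupling)) {
    if (length(coupling) == 9L) coupling <- rep(coupling, n_sensors)
    if (length(coupling) != 9L * n_sensors)
      stop("coupling must have length 9 or 9 * n_sensors", call. = FALSE)
  }
  if (is.null(class_map)) {
    class_map <- c("rest", sprintf("movement_%02d", seq_len(n_classes)))
    names(class_map) <- as.character(0:n_classes)
  }
  structure(list(n_classes = n_classes, n_sensors = n_sensors,
                 n_repetitions = n_repetitions,
                 trial_duration_s = trial_duration_s,
                 rest_duration_s = rest_duration_s,
                 f_emg = f_emg, f_im = f_im, emg_gain = emg_gain,
                 im_offset = im_offset,
                 informative_sensors = as.integer(informative_sensors),
                 noise_sd_emg = noise_sd_emg, noise_sd_im = noise_sd_im,
                 coupling = coupling, powerline_amp = powerline_amp,
                 onset_jitter_ms = onset_jitter_ms, seed = as.integer(seed),
                 class_map = class_map),
            class = "synth_config")
}

# Deterministic class-dependent amplitude pattern; rest row is a low
# baseline, non-informative sensors get a flat (class-independent) column.
default_emg_gain <- function(n_classes, n_sensors, informative) {
  g <- matrix(1, n_classes + 1L, n_sensors)
  for (s in informative) {
    g[1L, s] <- 0.3
    g[1L + seq_len(n_classes), s] <-
      0.6 + 1.6 * ((7 * seq_len(n_classes) + 3 * s) %% 11) / 10
  }
  g
}

default_im_offset <- function(n_classes, n_sensors, informative) {
  o <- matrix(0, n_classes + 1L, 9L * n_sensors)
  for (s in informative) for (a in 1:9) {
    j <- (s - 1L) * 9L + a
    o[1L + seq_len(n_classes), j] <-
      (((5 * seq_len(n_classes) + 2 * a + s) %% 9) - 4) / 4
  }
  o
}

#' Default generator configurations for the two experiment protocols
#'
#' `"offline"` reproduces the offline acquisition session: 40 movement
#' classes, 6 repetitions each, 12 sensors, 5-s trials interleaved with 5-s
#' rests. `"realtime"` reproduces the pick-and-place training session:
#' five grip classes (power, lateral, tripod, index pointer, open) plus
#' rest, 5 repetitions, 12 sensors.
#'
#' @param protocol `"offline"` or `"realtime"`.
#' @param ... overrides forwarded to [synth_config()].
#' @return a [synth_config()].
#' @export
default_configs <- function(protocol = c("offline", "realtime"), ...) {
  protocol <- tryCatch(match.arg(protocol),
                       error = function(e)
                         stop("unknown protocol; use \"offline\" or \"realtime\"",
                              call. = FALSE))
  base <- if (protocol == "offline") {
    list(n_classes = 40L, n_repetitions = 6L, n_sensors = 12L)
  } else {
    list(n_classes = 5L, n_repetitions = 5L, n_sensors = 12L,
         class_map = c("0" = "rest", "1" = "Power", "2" = "Lateral",
                       "3" = "Tripod", "4" = "Index pointer", "5" = "Open"))
  }
  do.call(synth_config, utils::modifyList(base, list(...)))
}

# Segment schedule shared by labels and signal synthesis: leading rest,
# then class-major repetitions, each trial followed by a rest period.
synth_schedule <- function(cfg) {
  classes <- rep(rep(seq_len(cfg$n_classes), each = cfg$n_repetitions),
                 times = 1L)
  seg_class <- integer(0); seg_dur <- numeric(0)
  seg_class <- c(0L, rbind(classes, 0L))
  seg_dur <- c(cfg$rest_duration_s,
               rbind(rep(cfg$trial_duration_s, length(classes)),
                     rep(cfg$rest_duration_s, length(classes))))
  data.frame(class = as.integer(seg_class),
             onset = cumsum(c(0, head(seg_dur, -1L))),
             offset = cumsum(seg_dur))
}

# Class id at each sample time for a segment table (rest elsewhere).
schedule_labels <- function(sched, n, fs) {
  t <- (seq_len(n) - 1L) / fs
  lab <- integer(n)
  act <- sched[sched$class != 0L, , drop = FALSE]
  for (i in seq_len(nrow(act)))
    lab[t >= act$onset[i] & t < act$offset[i]] <- act$class[i]
  lab
}

# Signal synthesis for an arbitrary segment table. Returns a recording.
synth_signals <- function(cfg, sched, duration_s) {
  n_emg <- round(duration_s * cfg$f_emg)
  n_im <- round(duration_s * cfg$f_im)
  lab_emg <- schedule_labels(sched, n_emg, cfg$f_emg)
  lab_im <- schedule_labels(sched, n_im, cfg$f_im)
  ns <- cfg$n_sensors
  emg <- matrix(0, n_emg, ns)
  t_emg <- (seq_len(n_emg) - 1L) / cfg$f_emg
  pl <- if (cfg$powerline_amp > 0)
    cfg$powerline_amp * sin(2 * pi * 50 * t_emg) else 0
  for (s in seq_len(ns)) {
    sd_s <- cfg$emg_gain[lab_emg + 1L, s] * cfg$noise_sd_emg
    emg[, s] <- stats::rnorm(n_emg) * sd_s + pl
  }
  im <- matrix(0, n_im, 9L * ns)
  for (s in seq_len(ns)) {
    env_s <- cfg$emg_gain[lab_im + 1L, s] * cfg$noise_sd_emg
    for (a in 1:9) {
      j <- (s - 1L) * 9L + a
      ch <- cfg$im_offset[lab_im + 1L, j] +
        stats::rnorm(n_im, sd = cfg$noise_sd_im)
      if (!is.null(cfg$coupling) && cfg$coupling[j] != 0)
        ch <- ch + cfg$coupling[j] * env_s
      im[, j] <- ch
    }
  }
  labels <- lab_emg
  if (cfg$onset_jitter_ms > 0) {
    jit <- cfg$onset_jitter_ms / 1000
    act <- sched[sched$class != 0L, , drop = FALSE]
    act$onset <- act$onset + stats::runif(nrow(act), -jit, jit)
    act$offset <- act$offset + stats::runif(nrow(act), -jit, jit)
    labels <- schedule_labels(act, n_emg, cfg$f_emg)
  }
  recording(emg = emg, im = im, f_emg = cfg$f_emg, f_im = cfg$f_im,
            labels = labels, class_map = cfg$class_map,
            layout = sensor_layout(ns),
            meta = list(generator = "emgimu::synth", seed = cfg$seed))
}

#' Generate a protocol-structured synthetic recording
#'
#' Produces a [recording()] following the trial structure of the offline
#' acquisition protocol: a leading rest period, then for each class in turn
#' `n_repetitions` movement trials each followed by a rest period, so the
#' total duration is `n_classes * n_repetitions * (trial + rest) + rest`
#' seconds. Identical configuration (including seed) yields bit-identical
#' output. The true (unjittered) segment schedule is attached as
#' `meta$schedule` for downstream ground-truth checks.
#'
#' @param cfg a [synth_config()].
#' @return a [recording()].
#' @export
generate_recording <- function(cfg) {
  if (!inherits(cfg, "synth_config"))
    stop("cfg must be a synth_config", call. = FALSE)
  set.seed(cfg$seed)
  sched <- synth_schedule(cfg)
  rec <- synth_signals(cfg, sched, max(sched$offset))
  rec$meta$schedule <- sched
  rec
}

#' Intent trace for control-stream simulation
#'
#' An ordered sequence of intended commands: for each entry the intended
#' class and the time interval over which the user "holds" that intent.
#' Intervals must be strictly increasing and non-overlapping.
#'
#' @param class integer class ids (non-rest).
#' @param onset,offset interval bounds in seconds.
#' @return object of class `intent_trace` (a data.frame).
#' @export
intent_trace <- function(class, onset, offset) {
  if (length(class) != length(onset) || length(onset) != length(offset))
    stop("class, onset and offset must have equal length", call. = FALSE)
  tr <- data.frame(class = as.integer(class), onset = onset, offset = offset)
  if (nrow(tr)) {
    if (any(tr$offset <= tr$onset))
      stop("each intent must have offset > onset", call. = FALSE)
    if (nrow(tr) > 1L && any(tr$onset[-1L] < tr$offset[-nrow(tr)]))
      stop("intent intervals must be non-overlapping and increasing",
           call. = FALSE)
  }
  class(tr) <- c("intent_trace", "data.frame")
  tr
}

#' Generate a real-time control signal stream
#'
#' Produces a recording whose class-conditional statistics follow `cfg`
#' during each intent interval and rest statistics elsewhere, emulating the
#' signal stream of the testing phase. The trace is returned unchanged for
#' scoring by the control simulator.
#'
#' @param cfg a [synth_config()].
#' @param intents an [intent_trace()].
#' @param tail_s rest padding after the final intent (default
#'   `cfg$rest_duration_s`).
#' @return list with elements `recording` and `intents`.
#' @export
generate_control_stream <- function(cfg, intents,
                                    tail_s = cfg$rest_duration_s) {
  if (!inherits(cfg, "synth_config"))
    stop("cfg must be a synth_config", call. = FALSE)
  if (!inherits(intents, "intent_trace"))
    intents <- intent_trace(intents$class, intents$onset, intents$offset)
  if (nrow(intents) && any(intents$class > cfg$n_classes))
    stop("intent class outside configured classes", call. = FALSE)
  duration <- if (nrow(intents)) max(intents$offset) + tail_s else tail_s
  if (nrow(intents) && any(intents$onset < 0))
    stop("intents must lie within [0, stream duration]", call. = FALSE)
  set.seed(cfg$seed)
  sched <- data.frame(class = intents$class, onset = intents$onset,
                      offset = intents$offset)
  rec <- synth_signals(cfg, sched, duration)
  list(recording = rec, intents = intents)
}
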