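# Small fixtures shared across the suite. Everything is generated in code;
# sizes are scaled down from the acquisition protocol (shorter trials,
# fewer repetitions) to keep the default run fast, without changing any
# model parameter.

# Compact protocol-style config: 5 movement classes + rest, 6 repetitions,
# 2 s trials / 1 s rests.
small_cfg <- function(seed = 1L, n_sensors = 4L, n_classes = 5L,
                      n_repetitions = 6L, ...) {
  synth_config(n_classes = n_classes, n_sensors = n_sensors,
               n_repetitions = n_repetitions, trial_duration_s = 2,
               rest_duration_s = 1, seed = seed, ...)
}

small_features <- function(seed = 1L, n_sensors = 4L, modality = "both",
                           ...) {
  rec <- generate_recording(small_cfg(seed = seed, n_sensors = n_sensors,
                                      ...))
  build_feature_matrix(synchronize(rec), modality = modality)
}

# Hand-built 2-sensor recording for dataio round trips.
tiny_recording <- function(duration_s = 1, f_emg = 2000, f_im = 128,
                           seed = 42L) {
  set.seed(seed)
  n_emg <- round(duration_s * f_emg)
  n_im <- round(duration_s * f_im)
  labels <- rep(0L, n_emg)
  labels[(n_emg %/% 2):n_emg] <- 1L
  recording(emg = matrix(rnorm(n_emg * 2), n_emg, 2),
            im = matrix(rnorm(n_im * 18), n_im, 18),
            f_emg = f_emg, f_im = f_im, labels = labels,
            class_map = c("0" = "rest", "1" = "movement_01"),
            layout = sensor_layout(2L))
}

# Config with two complementary informative sensors: sensor a resolves
# class parity, sensor b resolves the class pair, so only the union
# separates all classes. Used for SFSS planted-truth recovery.
complementary_cfg <- function(seed, n_sensors = 12L, a = 3L, b = 8L) {
  K <- 4L
  gain <- matrix(1, K + 1L, n_sensors)
  offs <- matrix(0, K + 1L, 9L * n_sensors)
  gain[1L, c(a, b)] <- 0.3
  for (k in seq_len(K)) {
    gain[k + 1L, a] <- if (k %% 2L == 0L) 0.8 else 2.0
    gain[k + 1L, b] <- if (k <= 2L) 0.8 else 2.0
    offs[k + 1L, (a - 1L) * 9L + 1:9] <- if (k %% 2L == 0L) -0.6 else 0.6
    offs[k + 1L, (b - 1L) * 9L + 1:9] <- if (k <= 2L) -0.6 else 0.6
  }
  synth_config(n_classes = K, n_sensors = n_sensors, n_repetitions = 3L,
               trial_duration_s = 1.5, rest_duration_s = 1,
               f_emg = 1000, f_im = 125,
               emg_gain = gain, im_offset = offs,
               informative_sensors = c(a, b), noise_sd_im = 0.4,
               seed = seed)
}

# Bare-bones feature_matrix for balancing/accuracy tests that only need
# labels and times.
fake_features <- function(y, t, repetition = rep(1L, length(y))) {
  structure(list(X = matrix(0, length(y), 1L), y = as.integer(y), t = t,
                 repetition = as.integer(repetition),
                 columns = data.frame(sensor = 1L, modality = "emg",
                                      feature = "MAV"),
                 class_map = stats::setNames(as.character(sort(unique(y))),
                                             sort(unique(y)))),
            class = "feature_matrix")
}
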