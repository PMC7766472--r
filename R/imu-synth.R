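# Seeded synthetic 9-axis IMU generator for five activity classes.
#
# The generator stands in for a wrist-worn IMU streaming gyroscope,
# accelerometer and magnetometer channels at 50 Hz. Each class is baseline
# Gaussian noise plus a deterministic class envelope: a half-sine transient
# for Fall / SitDown / StandUp (scaled per class), a sustained sinusoid for
# Walk, and nothing for Under (treated as a low-motion class). Channel signs
# during the transient are fixed so that the fused features M4 and M5 (which
# are signed products of channels) come out large and positive during a fall.

#' Activity classes understood by the generator
#' @export
ACTIVITY_CLASSES <- c("Fall", "SitDown", "StandUp", "Under", "Walk")

CHANNEL_NAMES <- c("Gx", "Gy", "Gz", "Ax", "Ay", "Az", "Mx", "My", "Mz")

## Per-channel sign pattern applied to the transient envelope. Chosen so that
## at peak amplitude a: M1 = M2 = M3 = (a+1)^3, M4 = a^3, M5 = 2 a^2, i.e.
## all five fused features are positive and rise together with the transient.
TRANSIENT_SIGNS <- c(Gx = -1, Gy = -1, Gz = 1,
                     Ax = 1, Ay = 1, Az = 1,
                     Mx = -1, My = 1, Mz = 1)

#' Configuration for the synthetic IMU generator
#'
#' Holds every free parameter of the signal model. Defaults are calibrated so
#' that, after feature fusion and binarization at the default thresholds
#' `c(16, 24, 32, 40, 48)`, a Fall drives all five features over their
#' thresholds for a contiguous run of samples (an all-high 5x5 window exists),
#' SitDown/StandUp cross only the lowest thresholds, Walk stays periodic and
#' sub-threshold, and Under stays at baseline.
#'
#' @param sample_rate sampling frequency in Hz.
#' @param duration recording length in seconds.
#' @param noise_sd standard deviation of the per-channel baseline Gaussian
#'   noise (arbitrary sensor units).
#' @param peaks named numeric vector of transient/oscillation peak amplitudes
#'   per class. The Fall peak must strictly exceed every other class's peak so
#'   the fused features can cross the upper thresholds only for falls.
#' @param transient_duration named numeric vector, half-sine transient length
#'   in seconds for the impulsive classes.
#' @param walk_freq gait frequency for the Walk class, Hz.
#' @param n_per_class recordings per class in [generate_dataset()].
#' @param seed master seed for [generate_dataset()].
#' @return an object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(n_per_class = 2)
#' rec <- generate_activity("Fall", cfg, seed = 1)
#' @export
synth_config <- function(sample_rate = 50,
                         duration = 6,
                         noise_sd = 0.1,
                         peaks = c(Fall = 6, SitDown = 2, StandUp = 1.8,
                                   Under = 0, Walk = 1.2),
                         transient_duration = c(Fall = 0.6, SitDown = 0.8,
                                                StandUp = 0.7),
                         walk_freq = 2,
                         n_per_class = 10,
                         seed = 1) {
  stopifnot(sample_rate > 0, duration > 0, noise_sd >= 0,
            walk_freq > 0, n_per_class >= 1)
  if (!all(ACTIVITY_CLASSES %in% names(peaks))) {
    stop("`peaks` must name all of: ", paste(ACTIVITY_CLASSES, collapse = ", "))
  }
  others <- setdiff(ACTIVITY_CLASSES, "Fall")
  if (!all(peaks["Fall"] > peaks[others])) {
    stop("the Fall peak amplitude must strictly exceed every other class's peak")
  }
  structure(list(sample_rate = sample_rate, duration = duration,
                 noise_sd = noise_sd, peaks = peaks,
                 transient_duration = transient_duration,
                 walk_freq = walk_freq, n_per_class = n_per_class,
                 seed = seed),
            class = "synth_config")
}

## Deterministic class envelope, one value per time point (unit peak).
class_envelope <- function(label, t, config) {
  dur <- config$duration
  env <- numeric(length(t))
  if (label %in% c("Fall", "SitDown", "StandUp")) {
    width <- config$transient_duration[[label]]
    t0 <- (dur - width) / 2  # transient centred in the recording
    inside <- t >= t0 & t <= t0 + width
    env[inside] <- sin(pi * (t[inside] - t0) / width)
  } else if (label == "Walk") {
    env <- sin(2 * pi * config$walk_freq * t)
  }                                        # Under: flat zero
  env
}

#' Generate one synthetic IMU recording
#'
#' @param label one of `"Fall"`, `"SitDown"`, `"StandUp"`, `"Under"`, `"Walk"`.
#' @param config a [synth_config()].
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return an `imu_recording`: list with `time` (seconds), `channels`
#'   (numeric matrix, one column per channel `Gx..Mz`), `sample_rate`,
#'   `label`, `seed`.
#' @examples
#' rec <- generate_activity("Walk", synth_config(), seed = 7)
#' nrow(rec$channels)  # sample_rate * duration
#' @export
generate_activity <- function(label, config = synth_config(), seed = 1) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  if (length(label) != 1L || !label %in% ACTIVITY_CLASSES) {
    stop("unknown activity label '", paste(label, collapse = ","),
         "'; must be one of: ", paste(ACTIVITY_CLASSES, collapse = ", "))
  }
  n <- round(config$sample_rate * config$duration)
  t <- (seq_len(n) - 1L) / config$sample_rate
  env <- class_envelope(label, t, config) * config$peaks[[label]]
  channels <- outer(env, TRANSIENT_SIGNS[CHANNEL_NAMES]) +
    with_seed(seed, matrix(stats::rnorm(n * 9L, sd = config$noise_sd), nrow = n))
  colnames(channels) <- CHANNEL_NAMES
  structure(list(time = t, channels = channels,
                 sample_rate = config$sample_rate,
                 label = label, seed = as.integer(seed)),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s: %d samples @ %g Hz (%.1f s), seed %d\n",
              x$label, nrow(x$channels), x$sample_rate,
              nrow(x$channels) / x$sample_rate, x$seed))
  invisible(x)
}

#' Plot the nine channels of a recording
#' @param x an `imu_recording`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.imu_recording <- function(x, ...) {
  graphics::matplot(x$time, x$channels, type = "l", lty = 1,
                    xlab = "time [s]", ylab = "sensor output",
                    main = paste("IMU recording:", x$label), ...)
  invisible(x)
}

#' Generate a balanced labeled dataset of synthetic recordings
#'
#' Draws `n_per_class` recordings for each of the five activity classes.
#' Per-recording seeds are derived from the master seed by a deterministic
#' counter offset, so the whole dataset is reproducible and recordings never
#' share a seed.
#'
#' @param config a [synth_config()]; `config$n_per_class` and `config$seed`
#'   control size and reproducibility.
#' @return list of `imu_recording` objects with a `labels` attribute.
#' @export
generate_dataset <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  stopifnot(config$n_per_class >= 1)
  counter <- 0L
  recs <- list()
  for (label in ACTIVITY_CLASSES) {
    for (k in seq_len(config$n_per_class)) {
      recs[[length(recs) + 1L]] <-
        generate_activity(label, config, seed = config$seed + counter)
      counter <- counter + 1L
    }
  }
  attr(recs, "labels") <- vapply(recs, `[[`, "", "label")
  attr(recs, "seed") <- config$seed
  recs
}
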