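#' Simulate physiological and telemetry sensor streams
#'
#' Generates seeded synthetic sensor channels on a shared clock: ECG (pulse
#' train at the configured heart rate plus baseline drift, 1000 Hz), PPG
#' (pulsatile waveform, 100 Hz), respiration (~0.25 Hz sinusoid, 100 Hz) and
#' scanner telemetry (near-constant gradient/RF readings with Gaussian
#' noise). Instability epochs from the schedule inject high-variance motion
#' bursts into the physiological channels.
#'
#' @param duration_s stream duration in seconds.
#' @param instability data.frame with columns `start_s`, `end_s`,
#'   `amplitude` (relative burst strength), or NULL for a quiet recording.
#' @param seed integer seed.
#' @param heart_rate_bpm heart rate.
#' @param channels subset of c("ecg","ppg","resp","gradient","rf").
#' @return named list of `sensor_stream` objects (fields `channel`,
#'   `rate_hz`, `t`, `values`, `noise_sd`).
#' @export
generate_streams <- function(duration_s, instability = NULL, seed = 1,
                             heart_rate_bpm = 70,
                             channels = c("ecg", "ppg", "resp", "gradient", "rf")) {
  stop_if_not(duration_s > 0, "duration must be > 0")
  specs <- list(
    ecg = list(rate = 1000, noise_sd = 0.010, amp = 1),      # mV scale
    ppg = list(rate = 100, noise_sd = 0.8, amp = 100),       # a.u.
    resp = list(rate = 100, noise_sd = 1.0, amp = 10),       # mm
    gradient = list(rate = 1000, noise_sd = 0.3, amp = 40),  # A
    rf = list(rate = 1000, noise_sd = 0.7, amp = 25))        # W
  hr_hz <- heart_rate_bpm / 60
  with_seed(seed, {
    out <- lapply(channels, function(ch) {
      sp <- specs[[ch]]
      t <- seq(0, duration_s - 1 / sp$rate, by = 1 / sp$rate)
      base <- switch(ch,
        ecg = {
          # Gaussian R peaks on a drifting baseline
          phase <- (t * hr_hz) %% 1
          sp$amp * exp(-((phase - 0.5) / 0.02)^2 / 2) +
            0.1 * sp$amp * sin(2 * pi * 0.3 * t)
        },
        ppg = sp$amp * (0.6 + 0.4 * sin(2 * pi * hr_hz * t)^2),
        resp = sp$amp * sin(2 * pi * 0.25 * t),
        gradient = rep(sp$amp, length(t)),
        rf = rep(sp$amp, length(t)))
      vals <- base + stats::rnorm(length(t), 0, sp$noise_sd)
      if (!is.null(instability) && nrow(instability) &&
          ch %in% c("ecg", "ppg", "resp")) {
        for (r in seq_len(nrow(instability))) {
          in_ep <- t >= instability$start_s[r] & t <= instability$end_s[r]
          vals[in_ep] <- vals[in_ep] +
            stats::rnorm(sum(in_ep), 0,
                         instability$amplitude[r] * 0.3 * sp$amp)
        }
      }
      structure(list(channel = ch, rate_hz = sp$rate, t = t, values = vals,
                     noise_sd = sp$noise_sd),
                class = "sensor_stream")
    })
    names(out) <- channels
    out
  })
}

#' Preprocess a sensor stream
#'
#' Channel-specific zero-phase filter chains: ECG gets 0.5 Hz high-pass plus
#' a mains notch; PPG a low-pass at 8 Hz; respiration a low-pass at 2 Hz;
#' telemetry channels (gradient/rf/table/temp) are z-score normalized.
#'
#' @param stream a `sensor_stream`.
#' @param mains_hz notch frequency (default 50).
#' @return the filtered `sensor_stream`.
#' @export
preprocess <- function(stream, mains_hz = 50) {
  ch <- stream$channel
  fs <- stream$rate_hz
  v <- stream$values
  zp <- function(filt, x) signal::filtfilt(filt, x)
  out <- switch(ch,
    ecg = {
      # median removal avoids filter edge transients from a large DC offset
      hp <- signal::butter(2, 0.5 / (fs / 2), type = "high")
      x <- zp(hp, v - stats::median(v))
      if (mains_hz < fs / 2) {
        bs <- signal::butter(2, c(mains_hz - 2, mains_hz + 2) / (fs / 2),
                             type = "stop")
        x <- zp(bs, x)
      }
      x
    },
    ppg = zp(signal::butter(2, min(8 / (fs / 2), 0.99), type = "low"), v),
    resp = zp(signal::butter(2, min(2 / (fs / 2), 0.99), type = "low"), v),
    gradient = ,
    rf = ,
    table = ,
    temp = (v - mean(v)) / max(stats::sd(v), .Machine$double.eps),
    stop(sprintf("unknown sensor channel '%s'", ch), call. = FALSE))
  stream$values <- out
  stream
}

#' Synchronize sensor streams onto readout timestamps
#'
#' Linearly interpolates each channel onto the acquisition readout
#' timestamps (shared clock).
#'
#' @param streams list of `sensor_stream` objects.
#' @param readout_times_s strictly increasing readout timestamps.
#' @return matrix (readouts x channels) with attribute `max_offset_s`
#'   (largest gap between a readout time and the nearest native sample, per
#'   channel).
#' @export
synchronize <- function(streams, readout_times_s) {
  stop_if_not(length(streams) >= 1, "need at least one stream")
  out <- matrix(NA_real_, length(readout_times_s), length(streams))
  colnames(out) <- vapply(streams, `[[`, "", "channel")
  offs <- numeric(length(streams))
  for (k in seq_along(streams)) {
    s <- streams[[k]]
    if (min(readout_times_s) > max(s$t) || max(readout_times_s) < min(s$t)) {
      stop(sprintf("stream '%s' does not overlap the readout window", s$channel),
           call. = FALSE)
    }
    out[, k] <- stats::approx(s$t, s$values, xout = readout_times_s,
                              rule = 2)$y
    offs[k] <- max(vapply(readout_times_s,
                          function(tt) min(abs(tt - s$t)), 0))
  }
  attr(out, "max_offset_s") <- stats::setNames(offs, colnames(out))
  out
}

#' Per-readout instability score
#'
#' For each channel, the short-window variance is converted to a robust
#' z-score (median/MAD), divided by a fixed saturation constant and clipped
#' to [0, 1]; channels are combined by the per-readout maximum.
#'
#' @param aligned matrix from [synchronize()] (readouts x channels).
#' @param window odd window length (readouts) for the rolling variance.
#' @param saturation robust z-score mapped to score 1.
#' @return numeric vector of scores in [0, 1], one per readout.
#' @export
instability_score <- function(aligned, window = 21, saturation = 5) {
  aligned <- as.matrix(aligned)
  n <- nrow(aligned)
  half <- floor(window / 2)
  per_channel <- apply(aligned, 2, function(v) {
    rv <- vapply(seq_len(n), function(i) {
      idx <- max(1, i - half):min(n, i + half)
      stats::var(v[idx])
    }, 0)
    med <- stats::median(rv)
    madv <- stats::mad(rv)
    z <- (rv - med) / max(madv, .Machine$double.eps)
    pmin(pmax(z / saturation, 0), 1)
  })
  per_channel <- matrix(per_channel, nrow = n)
  apply(per_channel, 1, max)
}

#' Map instability scores to confidence weights
#'
#' Affine map `w = 1 - 0.3 * score`, so weights span [0.7, 1.0]: quiet
#' readouts keep full confidence, maximally unstable readouts are moderately
#' down-weighted rather than rejected.
#'
#' @param score numeric vector of instability scores in [0, 1].
#' @return weights in [0.7, 1.0].
#' @export
confidence_weights <- function(score) {
  stop_if_not(all(score >= 0 & score <= 1), "scores must lie in [0, 1]")
  1.0 - 0.3 * score
}

#' Expand per-readout weights to a full k-space weight matrix
#'
#' All samples in a readout (phase-encode line, i.e. matrix row) share the
#' line's confidence weight.
#'
#' @param weights_per_line numeric vector (one weight per phase-encode line).
#' @param shape k-space grid shape.
#' @return matrix of per-sample weights.
#' @export
line_weights_matrix <- function(weights_per_line, shape) {
  stop_if_not(length(weights_per_line) == shape[1],
              "need one weight per phase-encode line")
  matrix(rep(weights_per_line, shape[2]), shape[1], shape[2])
}
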