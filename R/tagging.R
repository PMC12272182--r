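#' Specification of a RIFT tagging protocol
#'
#' RIFT (rapid invisible frequency tagging) modulates stimulus luminance or
#' contrast sinusoidally at a frequency above the flicker-perception
#' threshold. Four canonical protocols ("tagging types") are supported:
#'
#' * **Type 1** — full-amplitude luminance tagging: white bands oscillate
#'   0--100\% luminance, black bands stay at 0\%.
#' * **Type 2** — half-amplitude luminance tagging: white bands oscillate
#'   50--100\%, black bands stay at 0\%.
#' * **Type 3** — uniform additive luminance tagging: white bands 50--100\%
#'   and black bands 0--50\%, modulated in phase (constant contrast).
#' * **Type 4** — contrast tagging: white 50--100\% and black 0--50\% in
#'   anti-phase (constant mean luminance).
#'
#' @param tag_type integer 1--4, the tagging protocol.
#' @param frequency tagging frequency in Hz (default 60).
#' @param phase tagging phase in radians; wrapped into `[0, 2*pi)`.
#' @param frame_rate projector refresh rate in frames/s (default 1440).
#' @param duration stimulus duration in seconds.
#' @return an object of class `tagging_spec`.
#' @examples
#' spec <- tagging_spec(1, duration = 1)
#' wf <- generate_waveform(spec)
#' mean(wf$white)  # 0.5: full-amplitude tagging averages to mid-grey
#' @export
tagging_spec <- function(tag_type, frequency = 60, phase = 0,
                         frame_rate = 1440, duration = 1) {
  stop_if_not(length(tag_type) == 1 && tag_type %in% 1:4,
              "tag_type must be one of 1, 2, 3, 4")
  stop_if_not(is.numeric(frequency) && frequency > 0, "frequency must be > 0")
  stop_if_not(frame_rate >= 2 * frequency,
              "frame_rate below Nyquist limit for this tagging frequency")
  stop_if_not(duration > 0, "duration must be > 0")
  structure(
    list(tag_type = as.integer(tag_type), frequency = frequency,
         phase = wrap_2pi(phase), frame_rate = frame_rate,
         duration = duration),
    class = "tagging_spec"
  )
}

#' Generate the per-frame tagging waveform for a protocol
#'
#' Evaluates the luminance of the white and black stimulus bands at every
#' projector frame, together with the underlying modulation sinusoid
#' `s(t) = sin(2*pi*f*t + phase)`. Frame timestamps are frame starts
#' (`t = 0, 1/frame_rate, ...`); luminance is held constant within a frame
#' (zero-order hold, matching projector refresh semantics).
#'
#' @param spec a [tagging_spec()].
#' @return an object of class `tagging_waveform`: list with `white`, `black`
#'   (luminance fractions in `[0,1]` per frame), `modulation` (the unitless
#'   sinusoid) and `frame_times` (seconds).
#' @export
generate_waveform <- function(spec) {
  stop_if_not(inherits(spec, "tagging_spec"), "spec must be a tagging_spec")
  n_frames <- round(spec$duration * spec$frame_rate)
  t <- (seq_len(n_frames) - 1) / spec$frame_rate
  s <- sin(2 * pi * spec$frequency * t + spec$phase)
  bands <- switch(spec$tag_type,
    list(white = 0.5 + 0.5 * s,   black = rep(0, n_frames)),
    list(white = 0.75 + 0.25 * s, black = rep(0, n_frames)),
    list(white = 0.75 + 0.25 * s, black = 0.25 + 0.25 * s),
    list(white = 0.75 + 0.25 * s, black = 0.25 - 0.25 * s)
  )
  # clamp away floating noise outside [0,1] without altering interior values
  bands$white <- pmin(pmax(bands$white, 0), 1)
  bands$black <- pmin(pmax(bands$black, 0), 1)
  structure(
    list(white = bands$white, black = bands$black, modulation = s,
         frame_times = t, spec = spec),
    class = "tagging_waveform"
  )
}

#' Construct a tagging reference signal at the analysis sampling rate
#'
#' The analytic tagging sinusoid evaluated on the MEG analysis time grid:
#' `values[k] = sin(2*pi*f*(k - onset_index)/sample_rate + phase)` (indices
#' 1-based). The sinusoid is full-length — it is *not* zeroed before onset;
#' windowing is the spectral module's job.
#'
#' @param frequency tagging frequency, Hz.
#' @param phase tagging phase, radians.
#' @param sample_rate analysis sampling rate, Hz; must exceed `2*frequency`.
#' @param n_samples number of samples.
#' @param onset_index 1-based sample index of stimulus onset.
#' @return an object of class `tag_signal`.
#' @export
analytic_tag_signal <- function(frequency, phase, sample_rate, n_samples,
                                onset_index = 1L) {
  stop_if_not(sample_rate > 2 * frequency,
              "sample_rate below Nyquist limit for this frequency")
  stop_if_not(n_samples >= 1, "n_samples must be >= 1")
  k <- seq_len(n_samples)
  values <- sin(2 * pi * frequency * (k - onset_index) / sample_rate + phase)
  tag_signal(values, sample_rate, onset_index, frequency, phase)
}

#' @rdname analytic_tag_signal
#' @param values numeric samples of a tagging signal.
#' @export
tag_signal <- function(values, sample_rate, onset_index, frequency, phase) {
  structure(
    list(values = as.numeric(values), sample_rate = sample_rate,
         onset_index = as.integer(onset_index), frequency = frequency,
         phase = wrap_2pi(phase)),
    class = "tag_signal"
  )
}

#' Create and validate a projector flip log
#'
#' A flip log records the scheduled and actual time of every graphics-buffer
#' update ("flip") during stimulus presentation, in seconds relative to
#' stimulus onset. Flips that happened late stall the display; stalls longer
#' than 1 ms are compensated by [reconstruct_corrected_tag()].
#'
#' @param scheduled,actual numeric vectors of flip times (s); `actual` must
#'   be `>= scheduled` and both must be monotone nondecreasing.
#' @return a `data.frame` with columns `scheduled` and `actual`, class
#'   `flip_log`.
#' @export
flip_log <- function(scheduled, actual) {
  stop_if_not(length(scheduled) == length(actual),
              "scheduled and actual must have equal length")
  stop_if_not(all(actual >= scheduled - 1e-12),
              "flip log invalid: actual flip before its scheduled time")
  stop_if_not(!is.unsorted(scheduled) && !is.unsorted(actual),
              "flip log invalid: flip times must be monotone nondecreasing")
  structure(data.frame(scheduled = scheduled, actual = actual),
            class = c("flip_log", "data.frame"))
}

#' Reconstruct the corrected tagging signal from apparatus recordings
#'
#' The tagging sinusoid stored during an experimental session does not
#' perfectly describe what was displayed: the true stimulus onset must be
#' read off the light sensor, and any projector flip missed by more than
#' 1 ms stalled the display. This function (i) re-aligns the stored signal
#' so that its onset coincides with the first sample at which the
#' light-sensor trace exceeds `baseline_threshold * max(trace)`, and (ii)
#' inserts a matching delay at every flip whose lateness
#' (`actual - scheduled`) exceeds 1 ms, delaying all subsequent samples.
#' Delays are quantized to whole samples at the signal's sampling rate,
#' ties rounding down.
#'
#' @param stored a [tag_signal()] as generated during the session.
#' @param sensor_trace light-sensor samples at `stored$sample_rate`, same
#'   length as `stored$values`.
#' @param flips a [flip_log()] (times in s relative to stimulus onset).
#' @param baseline_threshold onset threshold as a fraction of the trace
#'   maximum, in (0, 1); default 0.5.
#' @return a corrected `tag_signal` with `onset_index` at the detected onset.
#' @export
reconstruct_corrected_tag <- function(stored, sensor_trace, flips,
                                      baseline_threshold = 0.5) {
  stop_if_not(inherits(stored, "tag_signal"), "stored must be a tag_signal")
  stop_if_not(baseline_threshold > 0 && baseline_threshold < 1,
              "baseline_threshold must be in (0, 1)")
  if (!inherits(flips, "flip_log")) flips <- flip_log(flips$scheduled, flips$actual)
  stop_if_not(length(sensor_trace) == length(stored$values),
              "sensor_trace length must match the stored signal")

  thr <- baseline_threshold * max(sensor_trace)
  onset <- which(sensor_trace > thr)[1]
  if (is.na(onset)) stop("no onset detected: light-sensor trace never exceeds threshold",
                         call. = FALSE)

  fs <- stored$sample_rate
  lateness <- flips$actual - flips$scheduled
  missed <- which(lateness > 1e-3)
  # per-flip delay quantized to whole samples, ties rounding down
  delay_samp <- ceiling(lateness[missed] * fs - 0.5)

  k <- seq_along(stored$values)
  t <- (k - onset) / fs
  delay <- numeric(length(t))
  for (j in seq_along(missed)) {
    delay <- delay + (t >= flips$actual[missed[j]]) * delay_samp[j] / fs
  }
  values <- sin(2 * pi * stored$frequency * (t - delay) + stored$phase)
  out <- tag_signal(values, fs, onset, stored$frequency, stored$phase)
  out$n_corrected_flips <- length(missed)
  out
}

#' Serialize a tagging waveform or signal to CSV
#'
#' @param x a `tagging_waveform` or `tag_signal`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(x, path) {
  if (inherits(x, "tagging_waveform")) {
    df <- data.frame(time_s = x$frame_times, white = x$white,
                     black = x$black, modulation = x$modulation)
  } else if (inherits(x, "tag_signal")) {
    t <- (seq_along(x$values) - x$onset_index) / x$sample_rate
    df <- data.frame(time_s = t, white = NA_real_, black = NA_real_,
                     modulation = x$values)
  } else stop("x must be a tagging_waveform or tag_signal", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
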