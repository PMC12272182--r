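#' Specify a simulated cortical source driven by the tagging
#'
#' A current dipole whose activity follows the displayed tagging modulation
#' with a participant-specific tagging-to-brain phase lag. The moment
#' direction is projected onto the tangential plane (radial sources are
#' magnetically silent in a spherical conductor) and normalized.
#'
#' @param position source position, mm 3-vector.
#' @param moment_direction desired moment direction (3-vector); its radial
#'   component is projected out.
#' @param amplitude source amplitude (arbitrary units proportional to nAm),
#'   must be >= 0.
#' @param extra_phase the tagging-to-brain phase lag delta, radians.
#' @return an object of class `source_spec`.
#' @export
source_spec <- function(position, moment_direction = c(1, 0, 0),
                        amplitude = 1, extra_phase = 0) {
  stop_if_not(amplitude >= 0, "amplitude must be >= 0")
  r <- position / vec_norm(position)
  m <- moment_direction - sum(moment_direction * r) * r
  stop_if_not(vec_norm(m) > 1e-9,
              "moment_direction is (near-)radial; no tangential component")
  structure(list(position = position, moment_direction = m / vec_norm(m),
                 amplitude = amplitude, extra_phase = wrap_2pi(extra_phase)),
            class = "source_spec")
}

#' Default occipital source layouts
#'
#' One midline occipital source for single-stimulus runs, or a
#' contralateral pair for two-stimulus runs: the first source (right
#' hemisphere, x > 0) responds to the left visual stimulus, the second
#' (left hemisphere) to the right stimulus.
#'
#' @param n_stimuli 1 or 2.
#' @param amplitude source amplitude.
#' @param extra_phase tagging-to-brain lag, radians (shared).
#' @return list of [source_spec()].
#' @export
default_sources <- function(n_stimuli = 1, amplitude = 1, extra_phase = 0) {
  if (n_stimuli == 1) {
    list(source_spec(c(0, -85, -5), c(1, 0, 0), amplitude, extra_phase))
  } else {
    list(source_spec(c( 20, -85, -5), c(1, 0, 0), amplitude, extra_phase),
         source_spec(c(-20, -85, -5), c(1, 0, 0), amplitude, extra_phase))
  }
}

#' Noise configuration for the MEG simulator
#'
#' Additive noise components, each with a configurable amplitude (standard
#' deviation in the same arbitrary sensor units as the forward-projected
#' signal): per-channel 1/f^alpha background (spectrally shaped white
#' noise), a spatially coherent ~10 Hz alpha component weighted towards
#' posterior channels with random phase and slow amplitude modulation per
#' trial, common-mode power-line noise at 50 Hz with random phase per trial,
#' and white sensor noise.
#'
#' @param background 1/f background amplitude (rms).
#' @param alpha alpha-band component amplitude.
#' @param line 50 Hz line-noise amplitude.
#' @param white white sensor-noise amplitude.
#' @param exponent spectral exponent of the background (power ~ 1/f^exponent).
#' @param alpha_freq alpha frequency, Hz.
#' @param line_freq mains frequency, Hz.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(background = 1, alpha = 2, line = 1, white = 0.3,
                         exponent = 1, alpha_freq = 10, line_freq = 50) {
  stop_if_not(all(c(background, alpha, line, white) >= 0),
              "noise amplitudes must be >= 0")
  structure(list(background = background, alpha = alpha, line = line,
                 white = white, exponent = exponent,
                 alpha_freq = alpha_freq, line_freq = line_freq),
            class = "noise_config")
}

# 1/f^(exponent) background noise, one epoch, channels x time (returned t x ch)
shaped_noise <- function(n_time, n_chan, fs, exponent) {
  x <- matrix(stats::rnorm(n_time * n_chan), n_time, n_chan)
  f <- c(0, seq_len(n_time - 1))
  f <- pmin(f, n_time - f) * fs / n_time        # two-sided frequency axis
  g <- c(0, 1 / f[-1]^(exponent / 2))           # amplitude shaping, DC removed
  g <- g / sqrt(mean(g^2))
  X <- stats::mvfft(x) * g
  Re(stats::mvfft(X, inverse = TRUE)) / n_time
}

#' Simulate epoched MEG-like sensor data with tagging responses
#'
#' Generates `n_trials` epochs of multichannel data in which each source
#' contributes `amplitude * sin(2*pi*f*t + phi_trial + delta)` during
#' stimulus presentation, mapped to the sensors through the
#' spherical-conductor forward model ([forward_radial()]). The neural drive
#' follows the *displayed* stimulus: the modulation is evaluated per
#' projector frame, held within frames, and delayed by any injected missed
#' flips. Alongside the sensor data the simulator emits, per trial, the
#' stored (analytic) tagging signal, an idealized light-sensor trace (zero
#' before onset, pedestal-mapped modulation `0.75 + 0.25*s` after onset so
#' that half-maximum onset detection is exact), and a flip log — everything
#' [reconstruct_corrected_tag()] consumes — plus full ground truth in
#' `trial_meta`.
#'
#' Phase modes: `"fixed"` uses `fixed_phase` on every trial; `"random"`
#' draws the tagging phase uniformly from `[0, 2*pi)` per trial;
#' `"two_stim_orthogonal"` (exactly 2 sources) drives the first source
#' (left stimulus) at a random phase and the second (right stimulus) at a
#' +90 degree offset.
#'
#' @param sources list of [source_spec()].
#' @param array a [make_sensor_array()].
#' @param n_trials number of trials.
#' @param noise a [noise_config()].
#' @param phase_mode one of `"fixed"`, `"random"`, `"two_stim_orthogonal"`.
#' @param fixed_phase tagging phase used in `"fixed"` mode (radians).
#' @param frequency tagging frequency, Hz (default 60).
#' @param tag_type tagging protocol 1--4 (metadata; the neural drive uses
#'   the modulation sinusoid itself).
#' @param sample_rate analysis sampling rate, Hz (default 600).
#' @param window epoch window relative to stimulus onset, s, half-open
#'   (default `c(-0.4, 1.2)`).
#' @param frame_rate projector frame rate, frames/s (default 1440).
#' @param flip_cfg missed-flip injection: list with `n_missed` (flips
#'   stalled per trial, default 0) and `stall_frames` (stall length in
#'   frames, default 2).
#' @param seed integer seed (required).
#' @return an object of class `rift_epochs`: list with `data` (trials x
#'   channels x time array), `time`, `sample_rate`, `onset_index`, `array`,
#'   `sources`, `trial_meta`, `tag` (stored per-trial signals + parameters),
#'   `light` (trials x time), `flips` (list of [flip_log()]).
#' @export
simulate_epochs <- function(sources, array, n_trials,
                            noise = noise_config(),
                            phase_mode = c("fixed", "random",
                                           "two_stim_orthogonal"),
                            fixed_phase = 0, frequency = 60, tag_type = 1,
                            sample_rate = 600, window = c(-0.4, 1.2),
                            frame_rate = 1440,
                            flip_cfg = list(n_missed = 0, stall_frames = 2),
                            seed) {
  phase_mode <- match.arg(phase_mode)
  stop_if_not(!missing(seed) && is.numeric(seed), "seed is required")
  stop_if_not(length(sources) >= 1, "need at least one source")
  if (phase_mode == "two_stim_orthogonal")
    stop_if_not(length(sources) == 2,
                "two_stim_orthogonal requires exactly 2 sources")
  set.seed(as.integer(seed))

  n_time <- round(diff(window) * sample_rate)
  t <- window[1] + (seq_len(n_time) - 1) / sample_rate
  onset_index <- which.min(abs(t))
  n_chan <- nrow(array$positions)
  model <- head_model(array)
  topo <- vapply(sources, function(s)
    forward_radial(s$position, s$amplitude * s$moment_direction, model),
    numeric(n_chan))                                   # n_chan x n_sources

  n_frames <- ceiling(window[2] * frame_rate)
  scheduled <- (seq_len(n_frames) - 1) / frame_rate
  n_missed <- flip_cfg$n_missed %||% 0
  stall <- (flip_cfg$stall_frames %||% 2) / frame_rate

  # per-trial stimulation phases
  phase1 <- switch(phase_mode,
    fixed = rep(wrap_2pi(fixed_phase), n_trials),
    random = stats::runif(n_trials, 0, 2 * pi),
    two_stim_orthogonal = stats::runif(n_trials, 0, 2 * pi))
  phase2 <- if (phase_mode == "two_stim_orthogonal")
    wrap_2pi(phase1 + pi / 2) else rep(NA_real_, n_trials)

  data <- array(0, dim = c(n_trials, n_chan, n_time))
  tag_stored <- matrix(0, n_trials, n_time)
  light <- matrix(0, n_trials, n_time)
  flips <- vector("list", n_trials)
  post_w <- exp(-((array$positions[, 2] - min(array$positions[, 2])) / 60)^2)

  for (tr in seq_len(n_trials)) {
    stall_vec <- numeric(n_frames)
    if (n_missed > 0) {
      miss_at <- sample(2:n_frames, n_missed)
      stall_vec[miss_at] <- stall
    }
    actual <- scheduled + cumsum(stall_vec)
    # the schedule re-anchors after a stall, so each missed flip appears in
    # the log exactly once (lateness = its own stall, not the accumulation)
    flips[[tr]] <- flip_log(actual - stall_vec, actual)

    frame_of <- findInterval(t, actual)     # 0 before onset
    on <- frame_of >= 1
    fidx <- frame_of[on]

    phases <- c(phase1[tr], phase2[tr])[seq_along(sources)]
    if (length(sources) == 1) phases <- phase1[tr]
    drive <- matrix(0, length(sources), n_time)
    for (s in seq_along(sources)) {
      fv <- sin(2 * pi * frequency * scheduled + phases[s] +
                  sources[[s]]$extra_phase)
      drive[s, on] <- fv[fidx]
    }
    signal <- topo %*% drive                # n_chan x n_time

    # noise
    eps <- noise$background * t(shaped_noise(n_time, n_chan, sample_rate,
                                             noise$exponent))
    if (noise$alpha > 0) {
      env <- 1 + 0.5 * sin(2 * pi * 0.4 * t + stats::runif(1, 0, 2 * pi))
      a <- noise$alpha * env * sin(2 * pi * noise$alpha_freq * t +
                                     stats::runif(1, 0, 2 * pi))
      eps <- eps + post_w %o% a
    }
    if (noise$line > 0) {
      l <- noise$line * sin(2 * pi * noise$line_freq * t +
                              stats::runif(1, 0, 2 * pi))
      eps <- eps + rep(1, n_chan) %o% l
    }
    if (noise$white > 0)
      eps <- eps + noise$white * matrix(stats::rnorm(n_chan * n_time),
                                        n_chan, n_time)
    data[tr, , ] <- signal + eps

    # stored tagging signal (left stimulus in two-stimulus mode)
    tag_stored[tr, ] <- sin(2 * pi * frequency * t + phase1[tr])
    # idealized light sensor: pedestal-mapped displayed modulation
    lum <- 0.75 + 0.25 * sin(2 * pi * frequency * scheduled + phase1[tr])
    light[tr, on] <- lum[fidx]
  }

  delta <- sources[[1]]$extra_phase
  trial_meta <- data.frame(
    trial = seq_len(n_trials), condition = phase_mode,
    n_stimuli = length(sources), tag_type = tag_type, frequency = frequency,
    phase_left = phase1, phase_right = phase2,
    fixed_phase = phase_mode == "fixed", delta = delta)

  structure(
    list(data = data, time = t, sample_rate = sample_rate,
         onset_index = onset_index, array = array, sources = sources,
         trial_meta = trial_meta,
         tag = list(signals = tag_stored, frequency = frequency,
                    phases = phase1, onset_index = onset_index),
         light = light, flips = flips),
    class = "rift_epochs"
  )
}

#' Reconstruct corrected tagging signals for every trial of an epochs object
#'
#' Applies [reconstruct_corrected_tag()] per trial using the stored tagging
#' signal, the simulated light-sensor trace, and the flip log.
#'
#' @param epochs a [simulate_epochs()] result.
#' @param baseline_threshold onset threshold, fraction of trace maximum.
#' @return matrix `n_trials x n_time` of corrected tagging signals.
#' @export
corrected_tag_signals <- function(epochs, baseline_threshold = 0.5) {
  stop_if_not(inherits(epochs, "rift_epochs"), "epochs must be rift_epochs")
  n_trials <- nrow(epochs$tag$signals)
  out <- matrix(0, n_trials, length(epochs$time))
  for (tr in seq_len(n_trials)) {
    stored <- tag_signal(epochs$tag$signals[tr, ], epochs$sample_rate,
                         epochs$onset_index, epochs$tag$frequency,
                         epochs$tag$phases[tr])
    corr <- reconstruct_corrected_tag(stored, epochs$light[tr, ],
                                      epochs$flips[[tr]], baseline_threshold)
    out[tr, ] <- corr$values
  }
  out
}

#' Simulate AXB discrimination behaviour
#'
#' Per-subject true accuracy is drawn from a normal distribution truncated
#' to (0, 1); every non-timeout trial is then correct with that subject's
#' accuracy. Timeouts occur independently with `timeout_rate` and carry no
#' response. The correct side is balanced-random across trials.
#'
#' @param n_subjects number of subjects (default 12).
#' @param n_trials_per_block trials per subject (default 50).
#' @param true_accuracy population mean accuracy, in (0, 1).
#' @param between_subject_sd s.d. of subject accuracies (default 0.05).
#' @param timeout_rate probability of a timeout per trial (default 0.023).
#' @param condition block label stored in the table.
#' @param seed integer seed (required).
#' @return a `data.frame` (class `response_table`) with columns
#'   `subject_id`, `block_condition`, `correct_side`, `response_side`,
#'   `timeout`.
#' @export
simulate_behavior <- function(n_subjects = 12, n_trials_per_block = 50,
                              true_accuracy = 0.5, between_subject_sd = 0.05,
                              timeout_rate = 0.023,
                              condition = "type1_vs_none", seed) {
  stop_if_not(!missing(seed) && is.numeric(seed), "seed is required")
  stop_if_not(true_accuracy > 0 && true_accuracy < 1,
              "true_accuracy must be in (0, 1)")
  stop_if_not(between_subject_sd >= 0, "between_subject_sd must be >= 0")
  set.seed(as.integer(seed))

  acc <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    repeat {
      a <- stats::rnorm(1, true_accuracy, between_subject_sd)
      if (between_subject_sd == 0) a <- true_accuracy
      if (a > 0 && a < 1) break
    }
    acc[s] <- a
  }

  n <- n_subjects * n_trials_per_block
  subject <- rep(seq_len(n_subjects), each = n_trials_per_block)
  # balanced-random correct side within each subject's block
  correct_side <- as.vector(vapply(seq_len(n_subjects), function(s) {
    sides <- rep(c("left", "right"), length.out = n_trials_per_block)
    sample(sides)
  }, character(n_trials_per_block)))
  timeout <- stats::runif(n) < timeout_rate
  correct <- stats::runif(n) < acc[subject]
  response_side <- ifelse(timeout, "none",
                          ifelse(correct, correct_side,
                                 ifelse(correct_side == "left",
                                        "right", "left")))
  out <- data.frame(subject_id = subject, block_condition = condition,
                    correct_side = correct_side,
                    response_side = response_side, timeout = timeout)
  attr(out, "true_subject_accuracy") <- acc
  class(out) <- c("response_table", "data.frame")
  out
}
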