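#' Boxcar-taper Fourier decomposition of epoched data
#'
#' Computes complex Fourier coefficients of every trial and channel over an
#' analysis window (default 0.2--1.2 s after onset: a 1 s segment, hence
#' 1 Hz frequency resolution), using a flat (boxcar) taper to minimize
#' power smearing across neighbouring frequencies. One-sided spectrum; bin
#' `k` sits at `k / window_length` Hz. The per-trial tagging reference
#' signals are transformed identically, giving the tagging coefficients
#' that the coherence and phase-correction machinery needs.
#'
#' @param epochs a [simulate_epochs()] result (or compatible list with
#'   `data`, `time`, `sample_rate`, `trial_meta`, `array`).
#' @param tag_signals `n_trials x n_time` matrix of tagging reference
#'   signals; defaults to the *corrected* signals via
#'   [corrected_tag_signals()]. Pass `epochs$tag$signals` to use the raw
#'   stored signals instead.
#' @param window analysis window, s, half-open (default `c(0.2, 1.2)`).
#' @return an object of class `rift_spectra`: list with `coeffs`
#'   (complex, trials x channels x frequencies), `freqs` (Hz),
#'   `tag_coeffs` (complex, trials x frequencies), `window`, `array`,
#'   `trial_meta`.
#' @export
fft_boxcar <- function(epochs, tag_signals = NULL, window = c(0.2, 1.2)) {
  t <- epochs$time
  fs <- epochs$sample_rate
  stop_if_not(window[1] >= min(t) && window[2] <= max(t) + 1 / fs,
              "analysis window lies outside the epoch")
  n_win <- round(diff(window) * fs)
  stop_if_not(abs(n_win - diff(window) * fs) < 1e-9,
              "window length times sample_rate must be an integer")
  idx <- which(t >= window[1] - 1e-9)[1] + seq_len(n_win) - 1
  stop_if_not(max(idx) <= length(t), "analysis window lies outside the epoch")

  if (is.null(tag_signals)) tag_signals <- corrected_tag_signals(epochs)

  n_trials <- dim(epochs$data)[1]
  n_chan <- dim(epochs$data)[2]
  n_freq <- n_win %/% 2 + 1
  freqs <- (seq_len(n_freq) - 1) / diff(window)

  coeffs <- array(0i, dim = c(n_trials, n_chan, n_freq))
  for (tr in seq_len(n_trials)) {
    m <- matrix(epochs$data[tr, , idx], nrow = n_chan)
    X <- stats::mvfft(t(m))
    coeffs[tr, , ] <- t(X[seq_len(n_freq), , drop = FALSE])
  }
  Gt <- stats::mvfft(t(tag_signals[, idx, drop = FALSE]))
  tag_coeffs <- t(Gt[seq_len(n_freq), , drop = FALSE])

  structure(
    list(coeffs = coeffs, freqs = freqs, tag_coeffs = tag_coeffs,
         window = window, array = epochs$array,
         trial_meta = epochs$trial_meta),
    class = "rift_spectra"
  )
}

#' Trial-averaged power spectrum
#'
#' Mean over trials of squared coefficient magnitudes.
#'
#' @param spec a [fft_boxcar()] result.
#' @return `channels x frequencies` matrix of nonnegative power values.
#' @export
power_spectrum <- function(spec) {
  stop_if_not(dim(spec$coeffs)[1] >= 1, "need at least one trial")
  apply(Mod(spec$coeffs)^2, c(2, 3), mean)
}

#' Inter-trial coherence (ITC)
#'
#' Magnitude of the across-trial mean of unit-normalized complex Fourier
#' coefficients: 1 means perfectly consistent phase across trials, 0 a
#' uniform phase distribution. Zero-magnitude coefficients are excluded
#' from the mean; an all-zero bin is defined as 0 with a warning. ITC of a
#' single trial is identically 1 and is flagged with a warning.
#'
#' @param spec a [fft_boxcar()] result.
#' @return `channels x frequencies` matrix of values in `[0, 1]`.
#' @export
itc <- function(spec) {
  n_trials <- dim(spec$coeffs)[1]
  if (n_trials < 2)
    warning("ITC of a single trial is identically 1", call. = FALSE)
  mag <- Mod(spec$coeffs)
  unit <- spec$coeffs / ifelse(mag > 0, mag, 1)
  unit[mag == 0] <- 0i
  n_ok <- apply(mag > 0, c(2, 3), sum)
  s <- apply(unit, c(2, 3), sum)
  if (any(n_ok == 0))
    warning("all-zero frequency bin(s): ITC defined as 0 there",
            call. = FALSE)
  out <- Mod(s) / pmax(n_ok, 1)
  out[n_ok == 0] <- 0
  out
}

#' Brain-to-tagging (phase-corrected) coherence
#'
#' Consistency of the phase *difference* between the corrected tagging
#' signal and the MEG data across trials — unlike ITC it survives random
#' stimulation phases. The default estimator is the magnitude-weighted
#' coherence `|sum_t F conj(G)| / sqrt(sum_t |F|^2 sum_t |G|^2)`; the
#' `"phase_only"` variant is the ITC of the phase-corrected coefficients
#' `F conj(G)/|F G|`, provided for comparison.
#'
#' @param spec a [fft_boxcar()] result with tagging coefficients.
#' @param method `"weighted"` (default) or `"phase_only"`.
#' @return `channels x frequencies` matrix of values in `[0, 1]`.
#' @export
tag_coherence <- function(spec, method = c("weighted", "phase_only")) {
  method <- match.arg(method)
  stop_if_not(!is.null(spec$tag_coeffs),
              "spectra lack tagging coefficients")
  n_trials <- dim(spec$coeffs)[1]
  stop_if_not(nrow(spec$tag_coeffs) == n_trials,
              "tagging coefficients missing for some trials")
  n_chan <- dim(spec$coeffs)[2]
  G <- spec$tag_coeffs                                   # trials x freqs
  if (method == "weighted") {
    # cross-spectrum: sum over trials of F * conj(G)
    n_freq <- dim(spec$coeffs)[3]
    num <- matrix(0i, n_chan, n_freq)
    for (tr in seq_len(n_trials))
      num <- num + matrix(spec$coeffs[tr, , ], n_chan, n_freq) *
        matrix(Conj(G[tr, ]), n_chan, n_freq, byrow = TRUE)
    pf <- apply(Mod(spec$coeffs)^2, c(2, 3), sum)
    pg <- colSums(Mod(G)^2)
    den <- sqrt(pf * matrix(pg, n_chan, length(pg), byrow = TRUE))
    out <- Mod(num) / ifelse(den > 0, den, 1)
    out[den == 0] <- 0
    out
  } else {
    corr <- spec
    n_freq <- dim(spec$coeffs)[3]
    for (tr in seq_len(n_trials)) {
      g <- G[tr, ]
      gu <- Conj(g) / ifelse(Mod(g) > 0, Mod(g), 1)
      corr$coeffs[tr, , ] <- matrix(spec$coeffs[tr, , ], n_chan, n_freq) *
        matrix(gu, n_chan, n_freq, byrow = TRUE)
    }
    itc(corr)
  }
}

#' Signal-to-noise ratio of a spectral peak, in decibels
#'
#' Compares the spectrum value at the frequency of interest with the mean
#' over neighbouring frequencies up to `halfwidth` Hz away, excluding the
#' immediately adjacent bins: neighbours are
#' `[foi - halfwidth, foi - gap]` and `[foi + gap, foi + halfwidth]`
#' (inclusive; 8 bins at 1 Hz spacing with the defaults).
#' `SNR = 10 * log10(x(foi) / mean(x(neighbours)))`.
#'
#' @param values spectrum values (vector along `freqs`, or a
#'   `channels x frequencies` matrix).
#' @param freqs frequency axis, Hz.
#' @param foi frequency of interest, Hz (default 60).
#' @param gap inner exclusion half-width, Hz (default 2).
#' @param halfwidth outer neighbour half-width, Hz (default 5).
#' @return SNR in dB (scalar, or vector per channel for matrix input).
#' @export
snr_db <- function(values, freqs, foi = 60, gap = 2, halfwidth = 5) {
  stop_if_not(min(freqs) <= foi - halfwidth + 1e-9 &&
                max(freqs) >= foi + halfwidth - 1e-9,
              "neighbour bins missing from the spectrum")
  lo <- which(freqs >= foi - halfwidth - 1e-9 & freqs <= foi - gap + 1e-9)
  hi <- which(freqs >= foi + gap - 1e-9 & freqs <= foi + halfwidth + 1e-9)
  i_foi <- which.min(abs(freqs - foi))
  stop_if_not(abs(freqs[i_foi] - foi) < 1e-6,
              "frequency of interest not on the frequency axis")
  stop_if_not(length(lo) > 0 && length(hi) > 0,
              "neighbour bins missing from the spectrum")
  nb <- c(lo, hi)
  if (is.matrix(values)) {
    stop_if_not(min(values) >= 0, "spectrum values must be >= 0")
    den <- rowMeans(values[, nb, drop = FALSE])
    stop_if_not(all(den > 0), "zero neighbour mean: SNR undefined")
    10 * log10(values[, i_foi] / den)
  } else {
    stop_if_not(min(values) >= 0, "spectrum values must be >= 0")
    den <- mean(values[nb])
    stop_if_not(den > 0, "zero neighbour mean: SNR undefined")
    10 * log10(values[i_foi] / den)
  }
}

#' Tidy CSV export of spectral measures
#'
#' @param spec a [fft_boxcar()] result.
#' @param path output CSV path.
#' @param measures which measures to include.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spec, path,
                              measures = c("power", "itc", "coherence")) {
  rows <- list()
  mats <- list(power = if ("power" %in% measures) power_spectrum(spec),
               itc = if ("itc" %in% measures) itc(spec),
               coherence = if ("coherence" %in% measures) tag_coherence(spec))
  for (m in names(mats)) {
    if (is.null(mats[[m]])) next
    rows[[m]] <- data.frame(
      channel = rep(spec$array$names, times = length(spec$freqs)),
      frequency = rep(spec$freqs, each = nrow(mats[[m]])),
      measure = m, value = as.vector(mats[[m]]))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
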