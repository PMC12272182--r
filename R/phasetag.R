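#' Phase-correct Fourier coefficients by the tagging phase
#'
#' Removes the (trial-varying) stimulation phase from the sensor Fourier
#' coefficients at the frequency of interest:
#' `F_corr = F * conj(G) / |G|` per trial and channel, where `G` is that
#' trial's tagging coefficient. This is unit-magnitude phase removal; it
#' equals division by the tagging coefficient up to a positive per-trial
#' scale, and leaves `|F_corr| = |F|`. Trials whose tagging coefficient
#' magnitude falls below `tol` are excluded with a warning.
#'
#' @param spec a [fft_boxcar()] result.
#' @param foi frequency of interest, Hz (default 60).
#' @param tol minimum tagging-coefficient magnitude.
#' @return complex `trials x channels` matrix of corrected coefficients at
#'   `foi`; excluded trial indices in attribute `"excluded"`.
#' @export
phase_correct <- function(spec, foi = 60, tol = 1e-12) {
  i_f <- which.min(abs(spec$freqs - foi))
  stop_if_not(abs(spec$freqs[i_f] - foi) < 1e-6,
              "frequency of interest not on the frequency axis")
  F <- spec$coeffs[, , i_f, drop = TRUE]
  if (is.null(dim(F))) F <- matrix(F, nrow = dim(spec$coeffs)[1])
  G <- spec$tag_coeffs[, i_f]
  bad <- which(Mod(G) < tol)
  if (length(bad) > 0)
    warning(sprintf("%d trial(s) excluded: tagging coefficient below tolerance",
                    length(bad)), call. = FALSE)
  keep <- setdiff(seq_along(G), bad)
  stop_if_not(length(keep) > 0, "no trials with a usable tagging coefficient")
  out <- F[keep, , drop = FALSE] * (Conj(G[keep]) / Mod(G[keep]))
  attr(out, "excluded") <- bad
  out
}

#' Project complex coefficients onto a phase
#'
#' The real amplitude of each channel's coefficient along the phase factor
#' `e^{i phi}`: `A_k = Re{conj(F_k) e^{i phi}} = Re{F_k} cos(phi) +
#' Im{F_k} sin(phi)`. Note `A(phi + pi) = -A(phi)`.
#'
#' @param coeffs complex per-channel vector (or any complex array).
#' @param phi projection phase, radians.
#' @return real amplitudes, same shape as `coeffs`.
#' @export
project_phase <- function(coeffs, phi) {
  Re(Conj(coeffs) * exp(1i * phi))
}

#' Tagging-to-brain phase-lag profile (projected global field power)
#'
#' Projects trial-averaged phase-corrected coefficients onto a grid of
#' candidate phases (0 to 2*pi in steps of pi/16, 32 points) and sums the
#' squared projected amplitudes over channels (global field power, GFP).
#' The GFP profile is pi-periodic (`A(phi + pi) = -A(phi)`), so the peak
#' phase is reported in `[0, pi)`; the induced joint sign flip of projected
#' topographies flips fitted dipole moments, not positions.
#'
#' @param coeffs complex per-channel vector: phase-corrected coefficients
#'   averaged over trials (averaging before projection; by linearity,
#'   projecting per trial and then averaging gives the same mean).
#' @return an object of class `phase_profile`: list with `phases` (32-point
#'   grid), `gfp`, `peak_phase` (radians in `[0, pi)`), `degenerate` flag.
#' @export
lag_profile <- function(coeffs) {
  stop_if_not(length(coeffs) >= 1, "need at least one channel")
  phases <- (0:31) * pi / 16
  gfp <- vapply(phases, function(p) sum(project_phase(coeffs, p)^2),
                numeric(1))
  degenerate <- all(gfp < 1e-30)
  if (degenerate)
    warning("all-zero coefficients: degenerate phase profile", call. = FALSE)
  peak <- wrap_pi(phases[which.max(gfp)])
  structure(list(phases = phases, gfp = gfp, peak_phase = peak,
                 degenerate = degenerate),
            class = "phase_profile")
}

#' Split two-stimulus data into orthogonal-phase topographies
#'
#' For two-stimulus trials in which the right stimulus is tagged at +90
#' degrees relative to the (random-phase) left stimulus: corrects the
#' coefficients by the left stimulus's tagging phase, averages over trials,
#' and projects at the participant's previously estimated peak phase lag
#' (attributing the result to the left stimulus) and at that phase +90
#' degrees (right stimulus). The peak phase should come from an
#' *independent* single-stimulus run of the same participant via
#' [lag_profile()].
#'
#' @param spec a [fft_boxcar()] result whose trials are two-stimulus
#'   orthogonal-phase trials (per `trial_meta`).
#' @param peak_phase the participant's tagging-to-brain peak phase lag.
#' @param foi frequency of interest, Hz.
#' @return an object of class `phase_topographies`: list with
#'   `topo_at_peak` and `topo_at_peak_plus_90` (per-channel amplitudes)
#'   plus `peak_phase`.
#' @export
disentangle_two_stim <- function(spec, peak_phase, foi = 60) {
  meta <- spec$trial_meta
  stop_if_not(!is.null(meta) && all(meta$condition == "two_stim_orthogonal"),
              "trials are not marked two_stim_orthogonal")
  stop_if_not(all(!is.na(meta$phase_left)) && all(!is.na(meta$phase_right)),
              "per-trial left/right phase metadata missing")
  corr <- phase_correct(spec, foi)
  avg <- colMeans(corr)
  structure(
    list(topo_at_peak = project_phase(avg, peak_phase),
         topo_at_peak_plus_90 = project_phase(avg, peak_phase + pi / 2),
         peak_phase = peak_phase),
    class = "phase_topographies"
  )
}
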