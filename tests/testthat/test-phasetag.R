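make_corrected_case <- function(n_trials, n_chan, delta, seed = 1) {
  # brain coefficients lagging the tagging by delta, random tag phases
  set.seed(seed)
  H <- rnorm(n_chan)                      # real topography (signed)
  phi <- runif(n_trials, 0, 2 * pi)
  G <- matrix(exp(1i * phi), n_trials, 1)
  FF <- array(0i, dim = c(n_trials, n_chan, 1))
  for (tr in seq_len(n_trials))
    FF[tr, , 1] <- H * exp(1i * (phi[tr] + delta))
  manual_spectra(FF, tag_coeffs = G, freqs = 60)
}

test_that("phase correction removes the trial-varying tagging phase", {
  sp <- make_corrected_case(20, 6, delta = 0.8)
  corr <- phase_correct(sp, 60)
  # every trial/channel now shares phase delta (mod pi for signed channels)
  ph <- Arg(corr) %% pi
  expect_lt(max(abs(ph - 0.8)), 1e-9)
  # magnitudes untouched by the unit-magnitude divisor
  expect_equal(Mod(corr), Mod(matrix(sp$coeffs[, , 1], nrow = 20)),
               ignore_attr = TRUE)
  # F = G gives phase 0
  spg <- manual_spectra(array(sp$tag_coeffs, dim = c(20, 1, 1)),
                        tag_coeffs = sp$tag_coeffs, freqs = 60)
  expect_lt(max(abs(Arg(phase_correct(spg, 60)))), 1e-12)
})

test_that("trials with a vanishing tagging coefficient are excluded", {
  sp <- make_corrected_case(5, 3, 0.2)
  sp$tag_coeffs[2, 1] <- 0i
  expect_warning(corr <- phase_correct(sp, 60), "excluded")
  expect_equal(nrow(corr), 4)
  expect_equal(attr(corr, "excluded"), 2L)
})

test_that("phase projection is the real part along the phase factor", {
  phi0 <- 1.1
  expect_equal(project_phase(exp(1i * phi0), phi0), 1)
  expect_equal(project_phase(exp(1i * phi0), phi0 + pi / 2), 0,
               tolerance = 1e-15)
  set.seed(2)
  z <- complex(real = rnorm(10), imaginary = rnorm(10))
  for (phi in runif(4, 0, 2 * pi)) {
    expect_equal(project_phase(z, phi + pi), -project_phase(z, phi))
    expect_equal(project_phase(z, phi),
                 Re(z) * cos(phi) + Im(z) * sin(phi))
  }
})

test_that("the lag profile peaks at the shared coefficient phase and its
           grid sum is rotation invariant", {
  set.seed(3)
  H <- rnorm(8)
  phi0 <- 5 * pi / 16                        # on-grid phase
  prof <- lag_profile(H * exp(1i * phi0))
  expect_equal(prof$peak_phase, phi0 %% pi)
  expect_true(all(is.finite(prof$gfp)) && all(prof$gfp >= 0))
  # pi-periodicity of the profile
  g <- matrix(prof$gfp, nrow = 16)
  expect_equal(g[, 1], g[, 2], tolerance = 1e-9)
  # total projected variance over the grid is invariant to global rotation
  z <- complex(real = rnorm(8), imaginary = rnorm(8))
  s1 <- sum(lag_profile(z)$gfp)
  s2 <- sum(lag_profile(z * exp(1i * 0.777))$gfp)
  expect_equal(s1, s2, tolerance = 1e-9)
  expect_warning(lag_profile(rep(0i, 4)), "degenerate")
})

test_that("an injected tagging-to-brain lag is recovered noise-free", {
  arr <- tiny_array()
  ep <- simulate_epochs(default_sources(1, 200, extra_phase = 0.7), arr, 8,
                        noise_config(0, 0, 0, 0), "random", seed = 6)
  sp <- fft_boxcar(ep)
  prof <- lag_profile(colMeans(phase_correct(sp, 60)))
  err <- min((prof$peak_phase - 0.7) %% pi, pi - (prof$peak_phase - 0.7) %% pi)
  expect_lte(err, pi / 16)
})

test_that("orthogonal-phase disentangling recovers each source's field", {
  arr <- tiny_array()
  model <- head_model(arr)
  src <- default_sources(2, 200, extra_phase = 1.3)
  ep <- simulate_epochs(src, arr, 10, noise_config(0, 0, 0, 0),
                        "two_stim_orthogonal", seed = 7)
  sp <- fft_boxcar(ep)
  # the lag must come from independent single-stimulus data: in the
  # two-stimulus mixture the two orthogonal responses flatten the profile
  solo_run <- simulate_epochs(default_sources(1, 200, extra_phase = 1.3),
                              arr, 8, noise_config(0, 0, 0, 0), "random",
                              seed = 70)
  prof <- lag_profile(colMeans(phase_correct(fft_boxcar(solo_run), 60)))
  topos <- disentangle_two_stim(sp, prof$peak_phase)
  f_left <- forward_radial(src[[1]]$position, src[[1]]$moment_direction, model)
  f_right <- forward_radial(src[[2]]$position, src[[2]]$moment_direction, model)
  expect_gt(cosine_sim(topos$topo_at_peak, f_left), 0.99)
  expect_gt(cosine_sim(topos$topo_at_peak_plus_90, f_right), 0.99)

  # at the exact response phase the cross-talk is numerically zero
  solo <- simulate_epochs(list(src[[1]], source_spec(src[[2]]$position,
                                                     amplitude = 0,
                                                     extra_phase = 1.3)),
                          arr, 10, noise_config(0, 0, 0, 0),
                          "two_stim_orthogonal", seed = 8)
  sps <- fft_boxcar(solo)
  avg <- colMeans(phase_correct(sps, 60))
  theta <- Arg(avg[which.max(Mod(avg))])
  at_peak <- project_phase(avg, theta)
  at_orth <- project_phase(avg, theta + pi / 2)
  expect_lt(max(abs(at_orth)), 1e-6 * max(abs(at_peak)))

  # relabelling which stimulus is "left" swaps the topographies (up to the
  # joint sign from the pi ambiguity)
  swapped <- ep
  swapped$tag$phases <- (ep$tag$phases + pi / 2) %% (2 * pi)
  swapped$tag$signals <- sin(2 * pi * 60 *
                               matrix(ep$time, 10, length(ep$time),
                                      byrow = TRUE) + swapped$tag$phases)
  swapped$trial_meta$phase_left <- swapped$tag$phases
  swapped$trial_meta$phase_right <- (swapped$tag$phases + pi / 2) %% (2 * pi)
  sp_sw <- fft_boxcar(swapped)
  topos_sw <- disentangle_two_stim(sp_sw, prof$peak_phase)
  expect_gt(cosine_sim(topos_sw$topo_at_peak, topos$topo_at_peak_plus_90),
            0.99)

  # metadata guard
  bad <- sp; bad$trial_meta$condition <- "fixed"
  expect_error(disentangle_two_stim(bad, 0), "two_stim_orthogonal")
})
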