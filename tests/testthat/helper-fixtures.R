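# shared fixtures: small deterministic objects built in code

tiny_array <- function(n = 16) make_sensor_array(n)

cosine_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# minimal spectra object built directly from coefficient arrays
manual_spectra <- function(coeffs, tag_coeffs = NULL,
                           freqs = seq_len(dim(coeffs)[3]) - 1) {
  structure(list(coeffs = coeffs, freqs = freqs, tag_coeffs = tag_coeffs,
                 window = c(0, 1), array = NULL, trial_meta = NULL),
            class = "rift_spectra")
}

# fast MCMC settings for unit tests (acceptance uses the defaults)
fast_mcmc <- list(chains = 2, adapt = 200, burn = 100, draws = 400)

quiet_fit_logistic <- function(tab, seed, mcmc = fast_mcmc) {
  suppressWarnings(fit_hier_logistic(tab, chains = mcmc$chains,
                                     adapt = mcmc$adapt, burn = mcmc$burn,
                                     draws = mcmc$draws, seed = seed))
}
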