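#' Per subject-by-condition accuracy summary of an AXB response table
#'
#' Timeout trials are excluded from all analyses. For the accuracy summary
#' only, subject-condition cells with at most one responded trial are
#' dropped (such data still enter the hierarchical model via
#' [fit_hier_logistic()], which uses single trials).
#'
#' @param responses a [simulate_behavior()] table (or compatible
#'   data.frame).
#' @return data.frame with `subject_id`, `block_condition`, `n_responded`,
#'   `n_correct`, `accuracy`.
#' @export
accuracy_table <- function(responses) {
  stop_if_not(nrow(responses) > 0, "empty response table")
  r <- responses[!responses$timeout, , drop = FALSE]
  r$correct <- r$response_side == r$correct_side
  agg <- stats::aggregate(correct ~ subject_id + block_condition, data = r,
                          FUN = function(x) c(n = length(x), k = sum(x)))
  out <- data.frame(subject_id = agg$subject_id,
                    block_condition = agg$block_condition,
                    n_responded = agg$correct[, "n"],
                    n_correct = agg$correct[, "k"])
  out <- out[out$n_responded > 1, , drop = FALSE]
  out$accuracy <- out$n_correct / out$n_responded
  rownames(out) <- NULL
  out
}

jags_logistic_model <- "
model {
  for (i in 1:M) {
    y[i] ~ dbin(p[i], n[i])
    logit(p[i]) <- (alpha + a_s[subj[i]]) + (beta + b_s[subj[i]]) * x[i]
  }
  for (s in 1:S) {
    a_s[s] ~ dnorm(0, tau_a)
    b_s[s] ~ dnorm(0, tau_b)
  }
  alpha ~ dnorm(0, prior_prec)
  beta ~ dnorm(0, prior_prec)
  sd_a ~ dnorm(0, 1) T(1e-3,)
  sd_b ~ dnorm(0, 1) T(1e-3,)
  tau_a <- pow(sd_a, -2)
  tau_b <- pow(sd_b, -2)
}"

jags_linear_model <- "
model {
  for (i in 1:M) {
    y[i] ~ dnorm(mu[i], tau)
    mu[i] <- (alpha + a_s[subj[i]]) + beta * x[i]
  }
  for (s in 1:S) {
    a_s[s] ~ dnorm(0, tau_a)
  }
  alpha ~ dnorm(0, prior_prec)
  beta ~ dnorm(0, prior_prec)
  # tiny lower truncation keeps precisions finite for degenerate data
  sd_a ~ dnorm(0, pow(sd_scale, -2)) T(1e-3 * sd_scale,)
  sigma ~ dnorm(0, pow(sd_scale, -2)) T(1e-3 * sd_scale,)
  tau_a <- pow(sd_a, -2)
  tau <- pow(sigma, -2)
}"

run_jags <- function(model_string, data, params, chains, adapt, burn,
                     draws, seed, extra_inits = list()) {
  inits <- lapply(seq_len(chains), function(c)
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = as.integer((seed + 1000003 * c) %% 2147483647)),
      extra_inits))
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = TRUE)
  if (burn > 0) stats::update(jm, n.iter = burn, progress.bar = "none")
  rjags::coda.samples(jm, params, n.iter = draws, progress.bar = "none")
}

posterior_summary <- function(samples, prior_scale, rhat_limit = 1.01) {
  draws <- do.call(rbind, lapply(samples, as.matrix))
  rhat <- tryCatch(
    coda::gelman.diag(samples, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, ncol(draws)))
  summ <- data.frame(parameter = colnames(draws),
                     mean = colMeans(draws),
                     sd = apply(draws, 2, stats::sd),
                     rhat = rhat[colnames(draws)])
  rownames(summ) <- NULL
  flagged <- any(!is.na(summ$rhat) & summ$rhat > rhat_limit)
  if (flagged)
    warning(sprintf("possible non-convergence: max r-hat = %.3f",
                    max(summ$rhat, na.rm = TRUE)), call. = FALSE)
  structure(list(draws = draws, samples = samples, summary = summ,
                 prior_scale = prior_scale, converged = !flagged),
            class = "rift_posterior")
}

#' Hierarchical Bayesian logistic regression for the AXB discrimination task
#'
#' Models the single-trial response side (0 = left, 1 = right) as a
#' function of the actually correct side (coded -0.5/+0.5), with both
#' intercept and sensitivity as subject-random effects (Bernoulli family,
#' logit link; trials are aggregated exactly into per-subject binomial
#' cells). With this coding, a population at accuracy `p` has sensitivity
#' `beta = 2 * logit(p)` when the intercept is 0. Priors are
#' weakly-informative zero-centered normals with scale `prior_scale` on the
#' coefficients and half-normal(0, 1) on the random-effect s.d.s. Timeout
#' trials are excluded. Convergence is checked with the Gelman--Rubin
#' statistic (r-hat > 1.01 is flagged with a warning).
#'
#' @param responses a [simulate_behavior()] table.
#' @param prior_scale prior s.d. of the regression coefficients
#'   (default 2.5).
#' @param chains,adapt,burn,draws MCMC settings (per chain).
#' @param seed integer seed (required).
#' @return a `rift_posterior`: posterior draws, per-parameter summary with
#'   r-hat, and the prior scale (used by [bayes_factor_01()]).
#' @export
fit_hier_logistic <- function(responses, prior_scale = 2.5, chains = 2,
                              adapt = 300, burn = 200, draws = 800, seed) {
  stop_if_not(!missing(seed) && is.numeric(seed), "seed is required")
  r <- responses[!responses$timeout, , drop = FALSE]
  stop_if_not(length(unique(r$subject_id)) >= 2, "need at least 2 subjects")
  r$y <- as.integer(r$response_side == "right")
  r$x <- ifelse(r$correct_side == "right", 0.5, -0.5)
  subj <- as.integer(factor(r$subject_id))
  cells <- stats::aggregate(y ~ subj + x,
                            data = data.frame(y = r$y, subj = subj, x = r$x),
                            FUN = function(v) c(k = sum(v), n = length(v)))
  dat <- list(y = cells$y[, "k"], n = cells$y[, "n"], x = cells$x,
              subj = cells$subj, M = nrow(cells), S = max(subj),
              prior_prec = 1 / prior_scale^2)
  samples <- run_jags(jags_logistic_model, dat,
                      c("alpha", "beta", "sd_a", "sd_b"),
                      chains, adapt, burn, draws, seed,
                      extra_inits = list(alpha = 0, beta = 0,
                                         sd_a = 0.5, sd_b = 0.5))
  posterior_summary(samples, prior_scale)
}

#' Savage--Dickey Bayes factor for the null on a coefficient
#'
#' `BF01 = posterior density at 0 / prior density at 0`, with the posterior
#' density estimated by a Gaussian kernel density over the MCMC draws and
#' the prior the zero-centered normal used in the fit. Values above 1
#' favour the null (no effect). If the kernel density at 0 is numerically
#' zero (posterior mass far from 0), BF01 is reported at a numerical floor
#' with `below_floor = TRUE`.
#'
#' @param posterior a `rift_posterior` from [fit_hier_logistic()] or
#'   [fit_hier_linear()].
#' @param parameter which coefficient (default `"beta"`).
#' @param floor numerical floor for BF01.
#' @return list with `bf01`, `bf10`, `posterior_density_0`,
#'   `prior_density_0`, `below_floor`.
#' @export
bayes_factor_01 <- function(posterior, parameter = "beta", floor = 1e-6) {
  b <- posterior$draws[, parameter]
  d <- stats::density(b)
  post0 <- if (0 >= min(d$x) && 0 <= max(d$x))
    stats::approx(d$x, d$y, xout = 0)$y else 0
  prior0 <- stats::dnorm(0, 0, posterior$prior_scale)
  bf01 <- post0 / prior0
  below <- !is.finite(bf01) || bf01 < floor
  if (below) bf01 <- floor
  list(bf01 = bf01, bf10 = 1 / bf01, posterior_density_0 = post0,
       prior_density_0 = prior0, below_floor = below)
}

#' Simulation-based sensitivity analysis of the invisibility test
#'
#' For each true underlying accuracy on a grid (default 0.40 to 0.60 in
#' steps of 0.01, 21 levels), simulates `n_sims` response tables of the
#' study's size and between-subject spread, runs the full hierarchical
#' logistic + Bayes-factor pipeline on each, and records BF01. Reports the
#' per-level median and inter-quartile range, a quadratic fit to the
#' median `log2(BF01)` against accuracy, and an inverse lookup from an
#' observed BF01 to the accuracy range whose median BF01 is at least as
#' large. Fitting failures are counted and reported, not silently dropped.
#'
#' @param grid accuracy levels (default `seq(0.40, 0.60, by = 0.01)`).
#' @param n_sims simulations per level (default 300; reduce for speed).
#' @param n_subjects,n_trials,between_subject_sd,timeout_rate passed to
#'   [simulate_behavior()].
#' @param mcmc list of settings for [fit_hier_logistic()].
#' @param seed integer seed (required); per-simulation seeds are derived
#'   deterministically from it.
#' @return an object of class `sensitivity_result`: list with `levels`
#'   (data.frame: accuracy, median_bf01, q25, q75, n_failed), `bf01`
#'   (matrix levels x sims), `quadratic` (lm fit of `log2(median BF01)`),
#'   `lookup` (function BF01 -> accuracy range), `n_failed`.
#' @export
sensitivity_analysis <- function(grid = seq(0.40, 0.60, by = 0.01),
                                 n_sims = 300, n_subjects = 12,
                                 n_trials = 50, between_subject_sd = 0.05,
                                 timeout_rate = 0.023,
                                 mcmc = list(chains = 2, adapt = 300,
                                             burn = 200, draws = 800),
                                 seed) {
  stop_if_not(!missing(seed) && is.numeric(seed), "seed is required")
  stop_if_not(all(grid > 0 & grid < 1), "grid must lie within (0, 1)")
  stop_if_not(n_sims >= 2, "n_sims must be >= 2")
  bf <- matrix(NA_real_, length(grid), n_sims)
  for (i in seq_along(grid)) {
    for (j in seq_len(n_sims)) {
      s <- (seed + 7919 * i + 104729 * j) %% 2147483647
      bf[i, j] <- tryCatch({
        tab <- simulate_behavior(n_subjects, n_trials, grid[i],
                                 between_subject_sd, timeout_rate,
                                 seed = s)
        post <- fit_hier_logistic(tab, chains = mcmc$chains,
                                  adapt = mcmc$adapt, burn = mcmc$burn,
                                  draws = mcmc$draws, seed = s)
        bayes_factor_01(post)$bf01
      }, error = function(e) NA_real_)
    }
  }
  lev <- data.frame(
    accuracy = grid,
    median_bf01 = apply(bf, 1, stats::median, na.rm = TRUE),
    q25 = apply(bf, 1, stats::quantile, probs = 0.25, na.rm = TRUE),
    q75 = apply(bf, 1, stats::quantile, probs = 0.75, na.rm = TRUE),
    n_failed = rowSums(is.na(bf)))
  quad <- stats::lm(log2(median_bf01) ~ accuracy + I(accuracy^2), data = lev)
  lookup <- function(bf01) {
    hit <- lev$accuracy[lev$median_bf01 >= bf01]
    if (length(hit) == 0) return(c(NA_real_, NA_real_))
    range(hit)
  }
  structure(list(levels = lev, bf01 = bf, quadratic = quad,
                 lookup = lookup, n_failed = sum(is.na(bf))),
            class = "sensitivity_result")
}

#' Hierarchical Bayesian linear model for paired condition contrasts
#'
#' Gaussian-likelihood hierarchical model with subject-random intercepts
#' and a fixed condition effect, used for paired comparisons of
#' per-participant summary measures (SNR in dB across analysis methods or
#' tagging types, dipole x-coordinates, explained variances). With two
#' conditions coded -0.5/+0.5, `beta` is the condition difference; the
#' Savage--Dickey BF01 on `beta` is available via [bayes_factor_01()]. The
#' coefficient prior scale defaults to `2.5 * sd(y)` (data-scaled
#' weakly-informative); residual and random-effect s.d.s get
#' half-normal(0, sd(y)) priors.
#'
#' @param values data.frame with one row per subject-condition observation.
#' @param value_col,condition_col,subject_col column names.
#' @param prior_scale coefficient prior s.d.; `NULL` for `2.5 * sd(y)`.
#' @param chains,adapt,burn,draws MCMC settings.
#' @param seed integer seed (required).
#' @return a `rift_posterior` (see [fit_hier_logistic()]).
#' @export
fit_hier_linear <- function(values, value_col = "value",
                            condition_col = "condition",
                            subject_col = "subject", prior_scale = NULL,
                            chains = 2, adapt = 300, burn = 200,
                            draws = 800, seed) {
  stop_if_not(!missing(seed) && is.numeric(seed), "seed is required")
  y <- values[[value_col]]
  cond <- values[[condition_col]]
  subj <- as.integer(factor(values[[subject_col]]))
  stop_if_not(max(subj) >= 2, "need at least 2 subjects")
  if (is.numeric(cond)) {
    x <- cond
  } else {
    lv <- sort(unique(as.character(cond)))
    stop_if_not(length(lv) == 2,
                "condition must be numeric or have exactly 2 levels")
    x <- ifelse(as.character(cond) == lv[2], 0.5, -0.5)
  }
  sdy <- stats::sd(y)
  if (sdy == 0) sdy <- 1
  if (is.null(prior_scale)) prior_scale <- 2.5 * sdy
  dat <- list(y = y, x = x, subj = subj, M = length(y), S = max(subj),
              prior_prec = 1 / prior_scale^2, sd_scale = sdy)
  samples <- run_jags(jags_linear_model, dat,
                      c("alpha", "beta", "sd_a", "sigma"),
                      chains, adapt, burn, draws, seed,
                      extra_inits = list(alpha = 0, beta = 0,
                                         sd_a = sdy / 2, sigma = sdy))
  posterior_summary(samples, prior_scale)
}
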