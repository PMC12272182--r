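mk_table <- function(correct_flags, timeouts = rep(FALSE, length(correct_flags)),
                     subject = 1) {
  n <- length(correct_flags)
  cs <- rep(c("left", "right"), length.out = n)
  data.frame(subject_id = subject, block_condition = "type1_vs_none",
             correct_side = cs,
             response_side = ifelse(timeouts, "none",
                                    ifelse(correct_flags, cs,
                                           ifelse(cs == "left", "right",
                                                  "left"))),
             timeout = timeouts)
}

test_that("accuracy table applies the timeout and single-trial exclusions", {
  t1 <- mk_table(c(rep(TRUE, 7), rep(FALSE, 3)))
  expect_equal(accuracy_table(t1)$accuracy, 0.7)

  t2 <- mk_table(c(rep(TRUE, 4), rep(FALSE, 4), TRUE, TRUE),
                 timeouts = c(rep(FALSE, 8), TRUE, TRUE))
  expect_equal(accuracy_table(t2)$accuracy, 0.5)
  expect_equal(accuracy_table(t2)$n_responded, 8)

  # a cell with exactly one responded trial is dropped from the summary
  # but its subject still enters the hierarchical model
  t3 <- rbind(mk_table(rep(TRUE, 10), subject = 1),
              mk_table(c(TRUE, rep(FALSE, 9)),
                       timeouts = c(FALSE, rep(TRUE, 9)), subject = 2))
  at <- accuracy_table(t3)
  expect_false(2 %in% at$subject_id)
  post <- quiet_fit_logistic(t3, seed = 5)
  expect_true("beta" %in% post$summary$parameter)
  expect_error(accuracy_table(t3[0, ]), "empty")
})

test_that("sensitivity posterior matches the logit coding identities", {
  # null: 12 x 150 trials at chance, beta near 0
  tab0 <- simulate_behavior(12, 150, 0.5, 0.05, 0.023, seed = 41)
  p0 <- quiet_fit_logistic(tab0, seed = 41,
                           mcmc = list(chains = 2, adapt = 300, burn = 200,
                                       draws = 800))
  b0 <- p0$summary[p0$summary$parameter == "beta", ]
  expect_lt(abs(b0$mean), 0.15)
  # r-hat is reported for every parameter; the fixed effects must converge
  expect_true(all(is.finite(p0$summary$rhat)))
  fx <- p0$summary$parameter %in% c("alpha", "beta")
  expect_true(all(p0$summary$rhat[fx] < 1.05))

  # strong effect: beta -> 2*logit(0.75) = 2.197 at large n
  tab1 <- simulate_behavior(12, 400, 0.75, 0.01, 0, seed = 42)
  p1 <- quiet_fit_logistic(tab1, seed = 42)
  b1 <- p1$summary[p1$summary$parameter == "beta", "mean"]
  expect_lt(abs(b1 - 2 * qlogis(0.75)), 0.3)

  # swapping left/right labels everywhere negates the intercept only
  tab_sw <- tab0
  swp <- function(x) c(left = "right", right = "left", none = "none")[x]
  tab_sw$correct_side <- unname(swp(tab0$correct_side))
  tab_sw$response_side <- unname(swp(tab0$response_side))
  p_sw <- quiet_fit_logistic(tab_sw, seed = 41)
  expect_lt(abs(b0$mean -
                  p_sw$summary[p_sw$summary$parameter == "beta", "mean"]),
            0.1)
  expect_lt(abs(p0$summary[p0$summary$parameter == "alpha", "mean"] +
                  p_sw$summary[p_sw$summary$parameter == "alpha", "mean"]),
            0.1)
})

test_that("Savage-Dickey Bayes factors behave at the null and under effects", {
  # posterior identical to the prior: BF01 = 1 up to KDE error
  set.seed(50)
  fake <- structure(list(draws = cbind(beta = rnorm(40000, 0, 2.5)),
                         prior_scale = 2.5), class = "rift_posterior")
  expect_equal(bayes_factor_01(fake)$bf01, 1, tolerance = 0.12)

  tab0 <- simulate_behavior(12, 150, 0.5, 0.05, 0.023, seed = 43)
  bf0 <- bayes_factor_01(quiet_fit_logistic(tab0, seed = 43))
  expect_gt(bf0$bf01, 3)

  tab1 <- simulate_behavior(12, 150, 0.75, 0.05, 0.023, seed = 44)
  bf1 <- bayes_factor_01(quiet_fit_logistic(tab1, seed = 44))
  expect_lt(bf1$bf01, 1 / 3)
  expect_equal(bf1$bf10, 1 / bf1$bf01)
})

test_that("null evidence accumulates with trial count", {
  med_bf <- function(n_trials) {
    median(vapply(1:6, function(i) {
      tab <- simulate_behavior(10, n_trials, 0.5, 0.03, 0,
                               seed = 600 + 10 * n_trials + i)
      bayes_factor_01(quiet_fit_logistic(tab, seed = i))$bf01
    }, numeric(1)))
  }
  expect_gt(med_bf(120), med_bf(12))
})

test_that("posterior intervals for the sensitivity are calibrated at chance", {
  covered <- vapply(1:100, function(i) {
    tab <- simulate_behavior(8, 40, 0.5, 0.04, 0, seed = 9000 + i)
    p <- quiet_fit_logistic(tab, seed = i,
                            mcmc = list(chains = 2, adapt = 150, burn = 50,
                                        draws = 300))
    q <- quantile(p$draws[, "beta"], c(0.025, 0.975))
    q[1] <= 0 && 0 <= q[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("hierarchical linear model recovers paired condition contrasts", {
  set.seed(60)
  subj_eff <- rnorm(12, 0, 1)
  df <- data.frame(
    subject = rep(1:12, 2),
    condition = rep(c("a_ctrl", "b_treat"), each = 12),
    value = c(5 + subj_eff + rnorm(12, 0, 0.5),
              8 + subj_eff + rnorm(12, 0, 0.5)))   # injected 3.0 difference
  p <- suppressWarnings(fit_hier_linear(df, chains = 2, adapt = 300,
                                        burn = 200, draws = 800, seed = 61))
  beta <- p$summary[p$summary$parameter == "beta", "mean"]
  expect_lt(abs(beta - 3), 0.5)

  # identical condition columns: contrast at 0, BF favours the null
  df0 <- df; df0$value <- rep(df$value[1:12], 2)
  p0 <- suppressWarnings(fit_hier_linear(df0, chains = 2, adapt = 300,
                                         burn = 200, draws = 800, seed = 62))
  expect_lt(abs(p0$summary[p0$summary$parameter == "beta", "mean"]), 0.3)
  expect_gt(bayes_factor_01(p0)$bf01, 1)

  # consistent subject relabelling leaves the contrast unchanged
  perm <- sample(12)
  dfp <- df; dfp$subject <- perm[df$subject]
  pp <- suppressWarnings(fit_hier_linear(dfp, chains = 2, adapt = 300,
                                         burn = 200, draws = 800, seed = 61))
  expect_lt(abs(beta - pp$summary[pp$summary$parameter == "beta", "mean"]),
            0.15)
})

test_that("the sensitivity analysis produces a chance-peaked BF curve", {
  # short chains on purpose; the per-fit convergence flags are expected
  sens <- suppressWarnings(
    sensitivity_analysis(grid = c(0.42, 0.50, 0.58), n_sims = 4,
                         n_subjects = 8, n_trials = 40,
                         mcmc = list(chains = 2, adapt = 150,
                                     burn = 50, draws = 300),
                         seed = 70))
  expect_equal(sens$n_failed, 0)
  expect_equal(which.max(sens$levels$median_bf01), 2)
  expect_true(all(sens$levels$q25 <= sens$levels$median_bf01))
  lk <- sens$lookup(sens$levels$median_bf01[2])
  expect_equal(lk, c(0.50, 0.50))
})
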