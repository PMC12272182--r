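random_tangential_dipole <- function(model, r_max = 0.8) {
  repeat {
    p <- runif(3, -1, 1)
    if (vec_norm_t(p) < 1 && vec_norm_t(p) > 0.2) break
  }
  pos <- p / vec_norm_t(p) * runif(1, 0.3, r_max) * model$sphere_radius
  m <- rnorm(3)
  r <- pos / vec_norm_t(pos)
  m <- m - sum(m * r) * r
  list(position = pos, moment = m / vec_norm_t(m))
}
vec_norm_t <- function(v) sqrt(sum(v^2))

test_that("silent configurations and linearity of the forward field", {
  model <- head_model(tiny_array())
  expect_equal(forward_radial(c(0, 0, 0), c(1, 2, 3), model),
               rep(0, 16))
  pos <- c(10, -40, 20)
  expect_equal(forward_radial(pos, 5 * pos, model), rep(0, 16))
  Q <- c(0.2, -1, 0.5)
  expect_identical(forward_radial(pos, 2 * Q, model),
                   2 * forward_radial(pos, Q, model))
  expect_error(forward_radial(c(0, -95, 0), Q, model), "inside")
})

test_that("a noise-free dipole field is inverted to within a millimetre", {
  model <- head_model(make_sensor_array(32))
  pos <- c(25, -80, 0)
  b <- tangential_basis(pos)
  topo <- forward_radial(pos, 0.6 * b$e1 + 0.8 * b$e2, model)
  fit <- fit_ecd(topo, model)
  expect_lt(vec_norm_t(fit$position - pos), 1)
  expect_gt(fit$r_squared, 0.999)
  expect_true(fit$converged)

  # positive scaling: same position, scaled moment
  fit2 <- fit_ecd(7 * topo, model)
  expect_lt(vec_norm_t(fit2$position - fit$position), 0.5)
  expect_equal(fit2$moment, 7 * fit$moment, tolerance = 1e-2)

  # sign flip: same position, negated moment, same r^2
  fit3 <- fit_ecd(-topo, model)
  expect_lt(vec_norm_t(fit3$position - fit$position), 0.5)
  expect_equal(fit3$moment, -fit$moment, tolerance = 1e-2)
  expect_equal(fit3$r_squared, fit$r_squared, tolerance = 1e-6)
})

test_that("forward/inverse round trip over random tangential dipoles", {
  set.seed(31)
  model <- head_model(make_sensor_array(32))
  errs <- r2s <- numeric(25)
  for (i in 1:25) {
    d <- random_tangential_dipole(model)
    topo <- forward_radial(d$position, d$moment, model)
    fit <- fit_ecd(topo, model)
    errs[i] <- vec_norm_t(fit$position - d$position)
    r2s[i] <- fit$r_squared
  }
  expect_lt(median(errs), 1)
  expect_gt(min(r2s), 0.99)
})

test_that("mirroring a topography through x = 0 mirrors the fitted x", {
  arr <- make_sensor_array(32)
  model <- head_model(arr)
  pos <- c(20, -75, 5)
  b <- tangential_basis(pos)
  topo <- forward_radial(pos, b$e1, model)
  # mirrored array: flip x of sensor positions; mirrored source field
  arr_m <- arr
  arr_m$positions[, 1] <- -arr_m$positions[, 1]
  arr_m$orientations[, 1] <- -arr_m$orientations[, 1]
  model_m <- head_model(arr_m)
  pos_m <- pos * c(-1, 1, 1)
  # reflected polar moment; the radial field then flips sign channel-wise
  # (the cross product is a pseudovector)
  topo_m <- forward_radial(pos_m, b$e1 * c(-1, 1, 1), model_m)
  expect_equal(topo_m, -topo, tolerance = 1e-9)
  fit <- fit_ecd(topo, model)
  fit_m <- fit_ecd(topo_m, model_m)
  expect_equal(fit_m$position[1], -fit$position[1], tolerance = 0.5)
})

test_that("explained variance does not degrade when noise shrinks", {
  set.seed(32)
  model <- head_model(make_sensor_array(32))
  pos <- c(-20, -80, -5)
  b <- tangential_basis(pos)
  topo <- forward_radial(pos, b$e2, model)
  r2_at <- function(noise_sd) mean(sapply(1:8, function(i) {
    fit_ecd(topo + rnorm(32, 0, noise_sd * max(abs(topo))), model)$r_squared
  }))
  expect_gt(r2_at(0.05), r2_at(0.3))
})

test_that("dx contrast is plain paired arithmetic with validation", {
  model <- head_model(make_sensor_array(32))
  mk <- function(x) {
    b <- tangential_basis(c(x, -80, 0))
    fit_ecd(forward_radial(c(x, -80, 0), b$e1, model), model)
  }
  f16 <- mk(16); f0 <- mk(0.5)
  same <- dx_contrast(list(f16, f0), list(f16, f0))
  expect_equal(same$table$dx, c(0, 0))
  d <- dx_contrast(list(f16, f16), list(f0, f0))
  expect_equal(unname(d$summary["mean"]), f16$position[1] - f0$position[1],
               tolerance = 1e-6)
  expect_error(dx_contrast(list(f16), list(f16, f0)), "equal length")
})

test_that("kernel densities normalize, localize, and cancel when identical", {
  g <- make_kde_grid(c(-60, 60), spacing = 10)
  a <- rbind(c(20, -30, 0), c(25, -35, 5))
  b <- rbind(c(-20, -30, 0))
  kd <- kde_diff(a, b, g)
  vv <- attr(g, "voxel_volume")
  expect_equal(sum(kd$density_a) * vv, 1, tolerance = 1e-6)
  expect_equal(sum(kd$density_b) * vv, 1, tolerance = 1e-6)
  # single-point set peaks at its own grid cell
  i_max <- which.max(kd$density_b)
  expect_equal(unlist(kd[i_max, c("x", "y", "z")], use.names = FALSE),
               c(-20, -30, 0))
  # identical sets cancel exactly
  same <- kde_diff(a, a, g)
  expect_equal(same$diff, rep(0, nrow(g)))
  expect_error(kde_diff(a[0, , drop = FALSE], b, g), "at least one")
})
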