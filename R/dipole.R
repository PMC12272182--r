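#' Spherical-conductor head model
#'
#' In a homogeneous conducting sphere the radial component of the magnetic
#' field of a current dipole has a closed form that is independent of the
#' volume currents, so radial magnetometers see only the primary source
#' term. This model replaces subject-specific single-shell conduction with
#' a sphere; positions are in the synthetic head frame (mm, origin at
#' sphere center, +x right, -y posterior), not true MNI space, but the
#' left/right logic (x > 0 = right hemisphere) is preserved.
#'
#' @param array a [make_sensor_array()].
#' @param sphere_radius conductor sphere radius, mm.
#' @param center sphere center (default origin).
#' @return an object of class `head_model`.
#' @export
head_model <- function(array, sphere_radius = array$sphere_radius,
                       center = c(0, 0, 0)) {
  stop_if_not(inherits(array, "sensor_array"), "array must be a sensor_array")
  r <- sqrt(rowSums(sweep(array$positions, 2, center)^2))
  stop_if_not(all(r > sphere_radius),
              "all sensors must lie outside the conductor sphere")
  structure(list(array = array, sphere_radius = sphere_radius,
                 center = center),
            class = "head_model")
}

#' Radial magnetic field of a current dipole in a conducting sphere
#'
#' Computes the radial field component `B_r` at every sensor for a current
#' dipole with moment `Q` at position `r_q` inside the sphere:
#' `B_r = -(Q x r_q) . r_hat / |r - r_q|^3` (in arbitrary units; the
#' constant `mu_0/4pi` is dropped). Radial sources and sources at the
#' sphere center are magnetically silent. The field is exactly linear in
#' the moment.
#'
#' @param position dipole position, mm 3-vector, strictly inside the sphere.
#' @param moment dipole moment 3-vector (arbitrary units).
#' @param model a [head_model()].
#' @return numeric vector of per-channel field values.
#' @export
forward_radial <- function(position, moment, model) {
  stop_if_not(inherits(model, "head_model"), "model must be a head_model")
  rq <- position - model$center
  stop_if_not(vec_norm(rq) < model$sphere_radius,
              "dipole position must be strictly inside the conductor sphere")
  sens <- sweep(model$array$positions, 2, model$center)
  rhat <- sens / sqrt(rowSums(sens^2))
  d <- sweep(sens, 2, rq)
  qxr <- cross3(moment, rq)
  -(rhat %*% qxr)[, 1] / rowSums(d^2)^1.5
}

# two unit vectors spanning the tangential plane at a source position
tangential_basis <- function(position, center = c(0, 0, 0)) {
  rq <- position - center
  n <- vec_norm(rq)
  if (n < 1e-9) return(list(e1 = c(1, 0, 0), e2 = c(0, 1, 0)))
  r <- rq / n
  a <- if (abs(r[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(a, r); e1 <- e1 / vec_norm(e1)
  e2 <- cross3(r, e1)
  list(e1 = e1, e2 = e2)
}

# residual sum of squares of the best tangential dipole at a position
ecd_rss <- function(position, topography, model) {
  rq <- position - model$center
  if (vec_norm(rq) >= 0.995 * model$sphere_radius) {
    # outside the admissible region: penalized, keeps the search inside
    return(sum(topography^2) * (1 + (vec_norm(rq) / model$sphere_radius)^2))
  }
  b <- tangential_basis(position, model$center)
  G <- cbind(forward_radial(position, b$e1, model),
             forward_radial(position, b$e2, model))
  fit <- tryCatch(qr.solve(qr(G), topography), error = function(e) c(0, 0))
  sum((topography - G %*% fit)^2)
}

#' Fit a single equivalent current dipole to a sensor topography
#'
#' Nonlinear least-squares search over dipole position with the (tangential)
#' moment solved linearly at every candidate position. The search starts at
#' the central calcarine sulcus, `(0, -88, -9)` mm, plus a fixed set of
#' deterministic offset restarts to guard against local minima; the best
#' solution is returned. Explained variance is
#' `r^2 = 1 - ||residual||^2 / ||topography||^2`.
#'
#' @param topography per-channel field values (nonzero; >= 6 channels).
#' @param model a [head_model()].
#' @param start starting position, mm (default `c(0, -88, -9)`).
#' @param restart_offsets matrix of deterministic start offsets (mm), one
#'   per row, prepended with the unmodified start.
#' @param reltol convergence tolerance of the position search.
#' @return an object of class `dipole_fit`: list with `position` (mm),
#'   `moment` (tangential 3-vector), `r_squared`, `converged`, `rss`.
#' @export
fit_ecd <- function(topography, model, start = c(0, -88, -9),
                    restart_offsets = rbind(c( 20, 0, 0), c(-20, 0, 0),
                                            c( 0, 20, 0), c( 0, 0, 20),
                                            c( 15, 15, 15)),
                    reltol = 1e-12) {
  stop_if_not(length(topography) == nrow(model$array$positions),
              "topography length must match the sensor array")
  stop_if_not(length(topography) >= 6, "need at least 6 channels")
  ss_tot <- sum(topography^2)
  stop_if_not(ss_tot > 0, "topography must be nonzero")

  # scale-normalize for numerical conditioning; moment rescaled afterwards
  scale <- sqrt(ss_tot)
  topo <- topography / scale

  starts <- rbind(start, sweep(restart_offsets, 2, start, "+"))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    s <- starts[i, ]
    if (vec_norm(s - model$center) >= 0.99 * model$sphere_radius) next
    opt <- stats::optim(s, ecd_rss, topography = topo, model = model,
                        method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 4000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  pos <- best$par
  b <- tangential_basis(pos, model$center)
  G <- cbind(forward_radial(pos, b$e1, model),
             forward_radial(pos, b$e2, model))
  m2 <- qr.solve(qr(G), topo)
  moment <- (m2[1] * b$e1 + m2[2] * b$e2) * scale
  rss <- sum((topo - G %*% m2)^2)
  structure(
    list(position = pos, moment = moment,
         r_squared = max(0, min(1, 1 - rss)),
         converged = best$convergence == 0, rss = rss * scale^2),
    class = "dipole_fit"
  )
}

#' Left/right displacement contrast between paired dipole fits
#'
#' For paired lists of dipole fits (same participants, same order) computes
#' the per-participant difference in x-coordinate,
#' `dx = x(left-stimulus fit) - x(right-stimulus fit)`. With contralateral
#' projection of visual hemifields, successful phase tagging implies
#' left-stimulus fits in the right hemisphere (x > 0) and vice versa, hence
#' `dx > 0`. The hierarchical Bayesian comparison of the paired
#' x-coordinates is available via [fit_hier_linear()].
#'
#' @param fits_left_stim,fits_right_stim lists of [fit_ecd()] results.
#' @return list with `table` (participant, x_left_stim, x_right_stim, dx)
#'   and `summary` (mean, sd, n).
#' @export
dx_contrast <- function(fits_left_stim, fits_right_stim) {
  stop_if_not(length(fits_left_stim) == length(fits_right_stim),
              "paired fit lists must have equal length")
  xl <- vapply(fits_left_stim, function(f) f$position[1], numeric(1))
  xr <- vapply(fits_right_stim, function(f) f$position[1], numeric(1))
  dx <- xl - xr
  list(
    table = data.frame(participant = seq_along(dx),
                       x_left_stim = xl, x_right_stim = xr, dx = dx),
    summary = c(mean = mean(dx), sd = stats::sd(dx), n = length(dx))
  )
}

#' Regular grid for volumetric kernel densities
#'
#' @param limits length-2 numeric, grid limits in mm applied to all axes.
#' @param spacing grid spacing in mm (default 5).
#' @return matrix with columns x, y, z, plus attribute `voxel_volume`.
#' @export
make_kde_grid <- function(limits = c(-90, 90), spacing = 5) {
  ax <- seq(limits[1], limits[2], by = spacing)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  attr(g, "voxel_volume") <- spacing^3
  g
}

# isotropic-Gaussian KDE over a grid, discretely normalized to integrate to 1
kde3 <- function(positions, grid, bandwidth) {
  dens <- numeric(nrow(grid))
  for (i in seq_len(nrow(positions))) {
    d2 <- rowSums(sweep(grid, 2, positions[i, ])^2)
    dens <- dens + exp(-d2 / (2 * bandwidth^2))
  }
  vv <- attr(grid, "voxel_volume")
  dens / (sum(dens) * vv)
}

#' Signed kernel-density difference of two sets of dipole positions
#'
#' Each set's 3D density is an isotropic-Gaussian KDE (default s.d. 15 mm)
#' over the grid, discretely normalized (sum times voxel volume = 1); the
#' result is `density_a - density_b`, e.g. the left- minus right-stimulus
#' dipole density across participants.
#'
#' @param positions_a,positions_b matrices of positions (rows = mm
#'   3-vectors), at least one row each.
#' @param grid a [make_kde_grid()] (default grid if `NULL`).
#' @param bandwidth Gaussian kernel s.d. in mm (default 15).
#' @return data.frame with columns x, y, z, density_a, density_b, diff.
#' @export
kde_diff <- function(positions_a, positions_b, grid = NULL, bandwidth = 15) {
  positions_a <- rbind(positions_a); positions_b <- rbind(positions_b)
  stop_if_not(nrow(positions_a) >= 1 && nrow(positions_b) >= 1,
              "each position set must contain at least one point")
  if (is.null(grid)) grid <- make_kde_grid()
  da <- kde3(positions_a, grid, bandwidth)
  db <- kde3(positions_b, grid, bandwidth)
  data.frame(x = grid[, 1], y = grid[, 2], z = grid[, 3],
             density_a = da, density_b = db, diff = da - db)
}
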