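#' Construct a synthetic MEG sensor array on a spherical cap
#'
#' Places `n_channels` radial magnetometers quasi-uniformly (deterministic
#' Fibonacci spiral) on a spherical cap of the helmet sphere, tilted so the
#' cap covers the superior and posterior head — the region where occipital
#' steady-state responses project. Coordinate frame: right-handed, mm,
#' origin at the conductor-sphere center, +x = right hemisphere,
#' -y = posterior, +z = superior.
#'
#' @param n_channels number of channels (>= 8).
#' @param helmet_radius helmet sphere radius in mm (default 110); must
#'   exceed `sphere_radius`.
#' @param sphere_radius conductor sphere radius in mm (default 90).
#' @param cap_halfwidth cap half-angle in radians (default 70 degrees).
#' @param seed accepted for interface symmetry with the other generators;
#'   the spiral layout is fully deterministic, so the seed does not alter
#'   the result.
#' @return an object of class `sensor_array`: list with `positions`
#'   (`n x 3` matrix, mm), `orientations` (unit radial vectors), `names`,
#'   `helmet_radius`, `sphere_radius`.
#' @export
make_sensor_array <- function(n_channels = 32, helmet_radius = 110,
                              sphere_radius = 90,
                              cap_halfwidth = 70 * pi / 180, seed = NULL) {
  stop_if_not(n_channels >= 8, "n_channels must be >= 8")
  stop_if_not(helmet_radius > sphere_radius,
              "helmet_radius must exceed sphere_radius")

  # cap axis tilted 40 degrees from vertical towards the back of the head
  tilt <- 40 * pi / 180
  axis <- c(0, -sin(tilt), cos(tilt))
  # local orthonormal frame around the cap axis
  e1 <- c(1, 0, 0)
  e2 <- cross3(axis, e1)

  i <- seq_len(n_channels)
  # uniform-area spacing in cos(polar angle) over the cap
  u <- 1 - (i - 0.5) / n_channels * (1 - cos(cap_halfwidth))
  theta <- acos(u)
  golden <- pi * (3 - sqrt(5))
  psi <- i * golden

  dir <- cbind(sin(theta) * cos(psi), sin(theta) * sin(psi), cos(theta))
  rot <- cbind(e1, e2, axis)  # columns: local x, y, z in head frame
  dir <- dir %*% t(rot)

  positions <- helmet_radius * dir
  structure(
    list(positions = positions, orientations = dir,
         names = sprintf("CH%03d", i),
         helmet_radius = helmet_radius, sphere_radius = sphere_radius),
    class = "sensor_array"
  )
}

#' Indices of posterior channels
#'
#' Channel selection used for sensor-averaged spectra: the posterior
#' fraction of the array by y-coordinate (most negative y = most posterior),
#' standing in for a parieto-occipital sensor group.
#'
#' @param array a [make_sensor_array()] result.
#' @param frac fraction of channels to keep (default 1/3).
#' @return integer channel indices.
#' @export
posterior_channels <- function(array, frac = 1 / 3) {
  n_keep <- max(1L, round(frac * nrow(array$positions)))
  order(array$positions[, 2])[seq_len(n_keep)]
}
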