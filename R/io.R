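# Plain-text on-disk container for epoched data: a directory of CSV
# matrices plus a JSON metadata sidecar. Bit-exact round trip at full
# double precision.

#' Save / load an epochs object as a plain-text container
#'
#' Writes a directory holding `meta.json` (sampling rate, window, array
#' geometry, per-trial metadata), `epochs_data.csv` (one row per
#' trial-channel pair, samples as columns), `tag_values.csv`,
#' `light_trace.csv` and `flips.csv`. [load_epochs()] reconstructs the
#' object; numeric values round-trip at full double precision.
#'
#' @param epochs a [simulate_epochs()] result.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = dm[1] * dm[2],
                 byrow = TRUE)
  idx <- expand.grid(channel = seq_len(dm[2]), trial = seq_len(dm[1]))
  num <- function(x) format(x, digits = 17, trim = TRUE, scientific = TRUE)
  df <- data.frame(trial = idx$trial, channel = idx$channel)
  utils::write.csv(cbind(df, as.data.frame(apply(flat, 2, num))),
                   file.path(dir, "epochs_data.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(as.data.frame(apply(epochs$tag$signals, 2, num)),
                   file.path(dir, "tag_values.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(as.data.frame(apply(epochs$light, 2, num)),
                   file.path(dir, "light_trace.csv"), row.names = FALSE,
                   quote = FALSE)
  fl <- do.call(rbind, lapply(seq_along(epochs$flips), function(tr)
    data.frame(trial = tr, scheduled = num(epochs$flips[[tr]]$scheduled),
               actual = num(epochs$flips[[tr]]$actual))))
  utils::write.csv(fl, file.path(dir, "flips.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(epochs$trial_meta, file.path(dir, "trial_meta.csv"),
                   row.names = FALSE)
  meta <- list(
    dims = dm, sample_rate = epochs$sample_rate,
    onset_index = epochs$onset_index, time = epochs$time,
    tag = list(frequency = epochs$tag$frequency, phases = epochs$tag$phases,
               onset_index = epochs$tag$onset_index),
    array = list(positions = epochs$array$positions,
                 orientations = epochs$array$orientations,
                 names = epochs$array$names,
                 helmet_radius = epochs$array$helmet_radius,
                 sphere_radius = epochs$array$sphere_radius))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  dm <- meta$dims
  d <- utils::read.csv(file.path(dir, "epochs_data.csv"))
  flat <- unname(as.matrix(d[, -(1:2), drop = FALSE]))
  data <- aperm(array(t(flat), dim = c(dm[3], dm[2], dm[1])), c(3, 2, 1))
  fl <- utils::read.csv(file.path(dir, "flips.csv"))
  flips <- lapply(split(fl, fl$trial), function(x)
    flip_log(x$scheduled, x$actual))
  array_ <- structure(
    list(positions = matrix(unlist(meta$array$positions), ncol = 3),
         orientations = matrix(unlist(meta$array$orientations), ncol = 3),
         names = meta$array$names,
         helmet_radius = meta$array$helmet_radius,
         sphere_radius = meta$array$sphere_radius),
    class = "sensor_array")
  structure(
    list(data = data, time = meta$time, sample_rate = meta$sample_rate,
         onset_index = meta$onset_index, array = array_, sources = NULL,
         trial_meta = utils::read.csv(file.path(dir, "trial_meta.csv")),
         tag = list(
           signals = unname(as.matrix(utils::read.csv(
             file.path(dir, "tag_values.csv")))),
           frequency = meta$tag$frequency, phases = meta$tag$phases,
           onset_index = meta$tag$onset_index),
         light = unname(as.matrix(utils::read.csv(
           file.path(dir, "light_trace.csv")))),
         flips = flips[order(as.integer(names(flips)))]),
    class = "rift_epochs")
}
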