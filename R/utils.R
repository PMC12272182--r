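# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Wrap an angle into [0, 2*pi)
#' @param x angle(s) in radians
#' @return wrapped angle(s)
#' @keywords internal
wrap_2pi <- function(x) x %% (2 * pi)

#' Wrap an angle into [0, pi)
#' @param x angle(s) in radians
#' @return wrapped angle(s)
#' @keywords internal
wrap_pi <- function(x) x %% pi

# circular distance between two angles under a given period
circ_dist <- function(a, b, period = 2 * pi) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

vec_norm <- function(v) sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
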