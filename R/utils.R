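# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap an angle (radians) into (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed
#'
#' Mixes a master seed with one or more integer labels into a new seed in
#' `[0, 2^31 - 2]`, so that independent random streams (trajectory, per-node
#' training noise, ICA initialisation, ...) can all be pinned to one master
#' seed without sharing a stream.
#'
#' @param seed Master seed (integer).
#' @param ... Integer labels identifying the consumer (e.g. layer, node).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.double(as.integer(seed) %% m)
  for (k in c(...)) {
    h <- (h * 48271 + as.double(k) + 1) %% m
  }
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_num <- function(x, name) {
  if (!is_scalar_num(x)) stopf("`%s` must be a single finite number", name)
  invisible(x)
}
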