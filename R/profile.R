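#' Depression multiplier of the 1D exponential leakage kernel
#'
#' On the ring, an active synapse is depressed by the factor `d` and the
#' depression amount halves with every neighbor step: the weight multiplier
#' at ring distance `delta` is `1 - (1 - d) * 2^(-delta)` for
#' `1 <= delta <= radius`, `d` at `delta = 0`, and 1 beyond the radius.
#' With the default `d = 0.5` the nearest neighbors are depressed to 0.75,
#' the next-nearest to 0.875 and the third to 0.9375.
#'
#' @param delta ring distance(s), nonnegative integers.
#' @param d center depression factor in (0, 1).
#' @param radius leakage radius, an integer in 0..3; radius 0 is specific
#'   (synapse-local) LTD.
#' @return numeric multiplier(s) in (0, 1].
#' @examples
#' depression_multiplier_1d(0:4, d = 0.5, radius = 3)
#' @export
depression_multiplier_1d <- function(delta, d = 0.5, radius = 1) {
  if (d <= 0 || d >= 1) stop("'d' must be in (0, 1)")
  if (radius < 0 || radius > 3) stop("'radius' must be in 0..3")
  if (any(delta < 0)) stop("'delta' must be nonnegative")
  m <- 1 - (1 - d) * 2^(-delta)
  m[delta > radius] <- 1
  m
}

#' Depression multiplier of the 3D Gaussian leakage kernel
#'
#' In 3D the depression spreads with a unit-peak Gaussian distance kernel:
#' the weight multiplier at Euclidean distance `delta` is
#' `1 - (1 - d) * exp(-delta^2 / (2 sigma^2))`, so the active synapse itself
#' (`delta = 0`) receives `d`.  There is no `1/sqrt(2 pi sigma^2)`
#' normalization: the kernel peak is pinned at 1 so that the center
#' multiplier equals `d` for every `sigma`.
#'
#' @param delta Euclidean distance(s) in micrometers.
#' @param d center depression factor in (0, 1).
#' @param sigma kernel standard deviation in micrometers, `> 0`.
#' @return numeric multiplier(s) in (0, 1].
#' @examples
#' depression_multiplier_3d(c(0, 0.75), d = 0.5, sigma = 0.75)
#' @export
depression_multiplier_3d <- function(delta, d = 0.5, sigma = 0.75) {
  if (d <= 0 || d >= 1) stop("'d' must be in (0, 1)")
  if (sigma <= 0) stop("'sigma' must be > 0")
  if (any(delta < 0)) stop("'delta' must be nonnegative")
  1 - (1 - d) * exp(-delta^2 / (2 * sigma^2))
}

#' Leakage profile of a plasticity rule
#'
#' Bundles the depression kernel of a learning rule: specific LTD (no
#' leakage), nonspecific LTD with exponential decay over ring neighbors, or
#' nonspecific LTD with a Gaussian kernel over Euclidean distance.
#'
#' @param mode `"specific"`, `"exponential"` (1D ring) or `"gaussian"` (3D).
#' @param d center depression factor, default 0.5.
#' @param radius ring leakage radius (1..3), for `mode = "exponential"`.
#' @param sigma Gaussian kernel SD in micrometers, for `mode = "gaussian"`.
#' @return an object of class `leak_profile`.
#' @examples
#' leak_profile("exponential", radius = 1)
#' leak_profile("gaussian", sigma = 0.75)
#' @export
leak_profile <- function(mode = c("specific", "exponential", "gaussian"),
                         d = 0.5, radius = NULL, sigma = NULL) {
  mode <- match.arg(mode)
  if (d <= 0 || d >= 1) stop("'d' must be in (0, 1)")
  if (mode == "exponential") {
    if (is.null(radius)) radius <- 1L
    if (radius < 0 || radius > 3) stop("'radius' must be in 0..3")
    if (radius == 0) mode <- "specific"   # radius 0 reduces to specific LTD
  }
  if (mode == "gaussian") {
    if (is.null(sigma)) sigma <- 0.75
    if (sigma <= 0) stop("'sigma' must be > 0")
  }
  structure(list(mode = mode, d = d,
                 radius = if (mode == "exponential") as.integer(radius),
                 sigma = if (mode == "gaussian") sigma),
            class = "leak_profile")
}

#' @export
print.leak_profile <- function(x, ...) {
  cat(switch(x$mode,
    specific    = sprintf("specific LTD (d = %g)\n", x$d),
    exponential = sprintf("nsLTD, exponential ring kernel (d = %g, radius = %d)\n",
                          x$d, x$radius),
    gaussian    = sprintf("nsLTD, Gaussian kernel (d = %g, sigma = %g um)\n",
                          x$d, x$sigma)))
  invisible(x)
}

#' Evaluate a leakage profile at given distances
#'
#' @param profile a `leak_profile`.
#' @param delta distances (ring steps or micrometers, depending on mode).
#' @return weight multipliers in (0, 1].
#' @export
leak_multiplier <- function(profile, delta) {
  stopifnot(inherits(profile, "leak_profile"))
  switch(profile$mode,
    specific    = ifelse(delta == 0, profile$d, 1),
    exponential = depression_multiplier_1d(delta, profile$d, profile$radius),
    gaussian    = depression_multiplier_3d(delta, profile$d, profile$sigma))
}

# Gaussian kernels are truncated at 5 sigma when applied on a layout: beyond
# that the multiplier deviates from 1 by less than 2e-6.
profile_cutoff <- function(profile) {
  stopifnot(profile$mode == "gaussian")
  5 * profile$sigma
}

# Per-site depression amounts a = 1 - multiplier over the whole neighborhood
# (center first, then one entry per site at each |delta| >= 1, both sides for
# the ring).  Used by the analytic module and the LTP factor.
profile_site_amounts <- function(profile) {
  switch(profile$mode,
    specific    = 1 - profile$d,
    exponential = {
      a <- (1 - profile$d) * 2^(-seq_len(profile$radius))
      c(1 - profile$d, rep(a, each = 2))
    },
    gaussian    = stop("site amounts are defined for ring profiles only"))
}
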