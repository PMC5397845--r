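#' Weight-conserving potentiation factor per stored pattern
#'
#' When each stored pattern slightly potentiates every synapse it does not
#' depress, the factor `L` that keeps the expected population-mean weight
#' at 1 balances the expected depression against the expected potentiation.
#' With sparsity `f`, per-site depression amounts `a = 1 - multiplier`
#' over the `m` sites of the kernel neighborhood (center plus both-side
#' neighbors), and neighborhoods that rarely overlap (`f * m` small), the
#' balance gives
#' \deqn{L = 1 + f \sum a / (1 - f m).}
#' At `f = 0.007`, `d = 0.5` this yields 1.0035 for specific LTD and
#' 1.0072, 1.0091, 1.0101 for exponential leakage to one, two and three
#' nearest neighbors.
#'
#' @param f pattern sparsity (fraction of ON bits), in (0, 1).
#' @param d center depression factor.
#' @param profile a ring [leak_profile] (`"specific"` or `"exponential"`);
#'   its own `d` is overridden by the `d` argument.
#' @return the potentiation factor, `> 1` (or exactly 1 when `d = 1` in the
#'   no-depression limit).
#' @examples
#' analytic_ltp_factor(0.007, 0.5, leak_profile("exponential", radius = 1))
#' @export
analytic_ltp_factor <- function(f, d = 0.5,
                                profile = leak_profile("specific")) {
  if (f <= 0 || f >= 1) stop("'f' must be in (0, 1)")
  stopifnot(inherits(profile, "leak_profile"))
  if (profile$mode == "gaussian")
    stop("closed-form LTP factors cover ring profiles only")
  profile$d <- d
  a <- profile_site_amounts(profile)
  m <- length(a)
  if (f * m >= 1)
    stop("kernel neighborhoods saturate the array (f * m >= 1)")
  1 + f * sum(a) / (1 - f * m)
}

# Per-side target probabilities q_delta of a ring noise kernel
# (delta = 1..radius); both sides together sum to 1.
noise_side_probs <- function(kernel) {
  stopifnot(kernel$mode == "exponential")
  a <- 2^(-seq_len(kernel$radius))
  a / (2 * sum(a))
}

#' Closed-form response moments of the trained linear unit
#'
#' Mean and variance of the response to stored, noisy-stored, or novel
#' patterns, derived under the assumption that the number of times a
#' synapse is hit by the ON bits (and kernel neighborhoods) of the stored
#' patterns follows a Poisson law.  For a synapse exposed to `P` patterns,
#' the expected weight is `exp(-P f A)` with `A` the summed depression
#' amounts over the kernel sites; synapses conditioned on belonging (or
#' not) to the read-out pattern count only the other `P - 1` exposures,
#' plus a first-order factor for leakage from the read-out pattern's own
#' ON bits.  Displaced and added bits are read out at the leak-depressed
#' weight of the neighbor they land on.  Valid in the sparse regime where
#' kernel neighborhoods rarely overlap (`f * m` small); 1D ring kernels
#' only — the 3D Gaussian case is studied by simulation.
#'
#' @param N pattern length.
#' @param n_on ON bits per pattern.
#' @param P number of stored patterns (loading).
#' @param profile ring [leak_profile] of the learning rule.
#' @param condition `"stored"`, `"noisy"`, or `"novel"`.
#' @param alpha fraction of ON bits displaced (noisy condition).
#' @param additive_fraction fraction of ON bits added (noisy condition).
#' @param noise_kernel ring [leak_profile] shaping the noise; defaults to
#'   the learning kernel itself (required explicitly for specific LTD).
#' @return named numeric vector `c(mean = , variance = )`.
#' @export
analytic_response_moments <- function(N, n_on, P, profile,
                                      condition = c("stored", "noisy", "novel"),
                                      alpha = 0, additive_fraction = 0,
                                      noise_kernel = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(profile, "leak_profile"))
  if (profile$mode == "gaussian")
    stop("closed-form moments cover ring kernels only; use simulation for Gaussian leakage")
  f <- n_on / N
  d <- profile$d
  a <- profile_site_amounts(profile)         # center + per-site amounts
  if (f * length(a) > 0.2)
    stop("outside the sparse regime the Poisson approximation breaks down (f * m > 0.2)")
  mult <- 1 - a                              # per-site multipliers
  A <- sum(a)
  B <- sum(1 - mult^2)
  E_U  <- exp(-(P - 1) * f * A)              # other-pattern weight factor
  E_U2 <- exp(-(P - 1) * f * B)
  if (condition == "novel") {
    E_W  <- exp(-P * f * A)
    E_W2 <- exp(-P * f * B)
    return(c(mean = n_on * E_W, variance = n_on * (E_W2 - E_W^2)))
  }
  if (condition == "stored") { alpha <- 0; additive_fraction <- 0 }
  # bits kept at their stored position read the directly depressed weight
  a0 <- 1 - d; b0 <- 1 - d^2
  mu_keep <- d * exp(-f * (A - a0)) * E_U
  m2_keep <- d^2 * exp(-f * (B - b0)) * E_U2
  n_d <- round(alpha * n_on)
  n_a <- round(additive_fraction * n_on)
  mu_t <- m2_t <- 0
  if (n_d + n_a > 0) {
    if (is.null(noise_kernel)) {
      if (profile$mode == "specific")
        stop("specific LTD needs an explicit 'noise_kernel'")
      noise_kernel <- profile
    }
    q <- noise_side_probs(noise_kernel)
    delta <- seq_along(q)
    mL <- leak_multiplier(profile, delta)    # read-out weight at the target
    aL <- 1 - mL
    bL <- 1 - mL^2
    # same-pattern leakage on the target runs over neighbor sites only
    # (a direct hit would make the target ON, which is conditioned out);
    # the site the displaced bit came from contributes the explicit mL.
    mu_t <- sum(2 * q * mL * exp(-f * (A - a0 - aL))) * E_U
    m2_t <- sum(2 * q * mL^2 * exp(-f * (B - b0 - bL))) * E_U2
  }
  n_keep <- n_on - n_d
  c(mean = n_keep * mu_keep + (n_d + n_a) * mu_t,
    variance = n_keep * (m2_keep - mu_keep^2) +
      (n_d + n_a) * (m2_t - mu_t^2))
}

#' Closed-form signal-to-noise ratio
#'
#' Evaluates the recognition statistic on the analytic response moments:
#' noisy-stored (or stored, at `alpha = 0`) versus novel.  Under
#' nonspecific LTD the displaced bits are read out at leak-depressed
#' neighbor weights, so the s/n falls more slowly with the noise fraction
#' `alpha` than under specific LTD, and the two curves cross at a
#' particular noise level.
#'
#' @inheritParams analytic_response_moments
#' @return a single nonnegative number.
#' @examples
#' analytic_snr(147400, 1000, 100, leak_profile("exponential", radius = 1),
#'              alpha = 0.3)
#' @export
analytic_snr <- function(N, n_on, P, profile, alpha = 0,
                         additive_fraction = 0, noise_kernel = NULL) {
  noisy <- analytic_response_moments(N, n_on, P, profile, "noisy",
                                     alpha, additive_fraction, noise_kernel)
  novel <- analytic_response_moments(N, n_on, P, profile, "novel")
  unname((noisy["mean"] - novel["mean"])^2 /
           ((noisy["variance"] + novel["variance"]) / 2))
}

#' Analytic s/n curves over a noise grid
#'
#' @param alphas vector of displacement fractions.
#' @param N,n_on,P as in [analytic_snr()].
#' @param rules named list of ring [leak_profile]s (e.g. specific LTD and
#'   one or more exponential radii).
#' @param noise_kernel kernel shaping the noise for every rule; defaults to
#'   each nonspecific rule's own kernel, and is required for specific LTD.
#' @param additive_matched logical: also add `alpha * n_on` ON bits at
#'   every level (the combined displacement + additive noise protocol).
#' @return a data.frame with columns `alpha`, `rule`, `snr`.
#' @export
analytic_snr_curve <- function(alphas, N, n_on, P, rules,
                               noise_kernel = NULL,
                               additive_matched = FALSE) {
  stopifnot(is.list(rules), length(names(rules)) == length(rules))
  out <- lapply(names(rules), function(nm) {
    pr <- rules[[nm]]
    nk <- if (!is.null(noise_kernel)) noise_kernel
          else if (pr$mode != "specific") pr
          else stop("specific LTD needs an explicit 'noise_kernel'")
    data.frame(alpha = alphas, rule = nm,
               snr = vapply(alphas, function(al)
                 analytic_snr(N, n_on, P, pr, alpha = al,
                              additive_fraction = if (additive_matched) al else 0,
                              noise_kernel = nk), numeric(1)))
  })
  do.call(rbind, out)
}
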