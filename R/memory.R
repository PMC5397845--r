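#' Store sparse binary patterns in a linear synaptic memory
#'
#' Trains the weight vector of a linear associative unit by one-shot
#' multiplicative depression.  All `N` weights start at 1; storing a pattern
#' multiplies the weight of every ON synapse by the depression factor `d`
#' and, for nonspecific rules, the weight of every neighbor at distance
#' `delta` by the kernel multiplier `leak_multiplier(profile, delta)`.
#' Contributions of all ON bits and all patterns combine multiplicatively,
#' so with specific LTD the final weight is `d` raised to the synapse's
#' total hit count, and the order in which patterns are stored is
#' irrelevant.
#'
#' With `ltp = TRUE`, every pattern additionally multiplies all synapses it
#' leaves untouched by the closed-form homeostatic potentiation factor of
#' [analytic_ltp_factor()], which keeps the expected population-mean weight
#' at 1 (ring profiles only).
#'
#' @param patterns a [pattern_set] of the patterns to store.
#' @param topology a [ring_topology] or [build_synthetic_morphology]
#'   spatial layout; its synapse count must equal the pattern length.
#' @param profile a [leak_profile]; ring topologies take `"specific"` or
#'   `"exponential"`, spatial layouts `"specific"` or `"gaussian"`.
#' @param ltp logical: apply weight-conserving potentiation to untouched
#'   synapses after each stored pattern.
#' @return an object of class `pattern_memory` with elements `weights`
#'   (length-`N` positive vector), `profile`, `topology`, `patterns`,
#'   `ltp` and `ltp_factor`.
#' @examples
#' ps <- generate_pattern_set(N = 200, n_on = 4, P = 10, seed = 1)
#' mem <- pattern_memory(ps, ring_topology(200), leak_profile("exponential", radius = 1))
#' summary(mem)
#' @export
pattern_memory <- function(patterns, topology, profile, ltp = FALSE) {
  stopifnot(inherits(patterns, "pattern_set"),
            inherits(topology, "synapse_topology"),
            inherits(profile, "leak_profile"))
  N <- n_synapses(topology)
  if (patterns$N != N)
    stop(sprintf("pattern length (%d) does not match topology size (%d)",
                 patterns$N, N))
  if (inherits(topology, "ring_topology") && profile$mode == "gaussian")
    stop("gaussian profiles require a spatial layout")
  if (inherits(topology, "spatial_layout") && profile$mode == "exponential")
    stop("exponential ring profiles require a ring topology")
  w <- if (profile$mode == "gaussian")
    train_gaussian(patterns, topology, profile)
  else
    train_ring(patterns, N, profile)
  lfac <- NULL
  if (ltp) {
    if (profile$mode == "gaussian")
      stop("closed-form LTP factors cover ring profiles only")
    lfac <- analytic_ltp_factor(patterns$n_on / N, profile$d, profile)
    u <- touched_counts_ring(patterns, N, profile)
    w <- w * lfac^(length(patterns$on) - u)
  }
  structure(list(weights = w, profile = profile, topology = topology,
                 patterns = patterns, ltp = ltp, ltp_factor = lfac),
            class = "pattern_memory")
}

# Ring training: accumulate hit counts per |delta| class with tabulate()
# and apply log-multipliers once per class.
train_ring <- function(patterns, N, profile) {
  k <- if (profile$mode == "specific") 0L else profile$radius
  all_on <- unlist(patterns$on, use.names = FALSE)
  logw <- numeric(N)
  for (delta in 0:k) {
    m <- leak_multiplier(profile, delta)
    if (delta == 0L) {
      cnt <- tabulate(all_on, N)
    } else {
      cnt <- tabulate((all_on - 1L + delta) %% N + 1L, N) +
             tabulate((all_on - 1L - delta) %% N + 1L, N)
    }
    logw <- logw + log(m) * cnt
  }
  exp(logw)
}

# Gaussian training: per distinct ON synapse, depress it and its cached
# neighbor list (kernel truncated at 5 sigma), weighted by how many stored
# patterns activate it.
train_gaussian <- function(patterns, layout, profile) {
  N <- nrow(layout$coords)
  nb <- spatial_neighbors(layout, profile_cutoff(profile))
  cnt <- tabulate(unlist(patterns$on, use.names = FALSE), N)
  logw <- numeric(N)
  logd <- log(profile$d)
  for (i in which(cnt > 0L)) {
    logw[i] <- logw[i] + cnt[i] * logd
    ni <- nb$idx[[i]]
    if (length(ni))
      logw[ni] <- logw[ni] +
        cnt[i] * log(leak_multiplier(profile, nb$dist[[i]]))
  }
  exp(logw)
}

# Number of stored patterns that touch (depress) each synapse.
touched_counts_ring <- function(patterns, N, profile) {
  k <- if (profile$mode == "specific") 0L else profile$radius
  aff <- lapply(patterns$on, function(on) {
    idx <- outer(on - 1L, (-k):k, "+") %% N + 1L
    unique(as.vector(idx))
  })
  tabulate(unlist(aff, use.names = FALSE), N)
}

#' @export
print.pattern_memory <- function(x, ...) {
  cat(sprintf("pattern_memory: %d synapses, %d stored patterns%s\n",
              length(x$weights), length(x$patterns$on),
              if (x$ltp) ", weight-conserving LTP" else ""))
  print(x$profile)
  cat(sprintf("mean weight %.4f\n", mean(x$weights)))
  invisible(x)
}

#' @export
summary.pattern_memory <- function(object, ...) {
  w <- object$weights
  structure(list(n = length(w), P = length(object$patterns$on),
                 profile = object$profile, ltp = object$ltp,
                 mean = mean(w), sd = stats::sd(w),
                 range = range(w)),
            class = "summary.pattern_memory")
}

#' @export
print.summary.pattern_memory <- function(x, ...) {
  cat(sprintf("Linear associative memory: %d synapses, %d stored patterns\n",
              x$n, x$P))
  print(x$profile)
  cat(sprintf("weights: mean %.4f, sd %.4f, range [%.4f, %.4f]%s\n",
              x$mean, x$sd, x$range[1], x$range[2],
              if (x$ltp) " (LTP homeostasis on)" else ""))
  invisible(x)
}

#' @export
coef.pattern_memory <- function(object, ...) object$weights

#' Responses of a trained memory to patterns
#'
#' The response to a pattern is the inner product of the weight vector with
#' the binary pattern vector, i.e. the sum of the weights at the pattern's
#' ON synapses — always nonnegative since weights are positive.
#'
#' @param object a [pattern_memory].
#' @param patterns a [pattern_set] (defaults to the stored patterns).
#' @param ... unused.
#' @return numeric vector of responses, one per pattern.
#' @export
predict.pattern_memory <- function(object, patterns = object$patterns, ...) {
  linear_response(object$weights, patterns)
}

#' @export
plot.pattern_memory <- function(x, ...) {
  graphics::hist(x$weights, breaks = 50, col = "grey80",
                 main = "Synaptic weight distribution",
                 xlab = "weight", ...)
  graphics::abline(v = mean(x$weights), col = "red3", lwd = 2)
  invisible(x)
}

#' Simulate noisy recall versions of the stored patterns
#'
#' Draws `nsim` independently degraded copies of the stored pattern set
#' under a [noise_spec] — the recall-side counterpart of the storage rule.
#'
#' @param object a [pattern_memory].
#' @param nsim number of noisy pattern sets to draw.
#' @param seed optional integer seed.
#' @param noise a [noise_spec]; by default kernel-matched to the memory's
#'   own leakage profile with 10% displacement.
#' @param ... unused.
#' @return a list of `nsim` [pattern_set] objects.
#' @export
simulate.pattern_memory <- function(object, nsim = 1, seed = NULL,
                                    noise = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise)) noise <- noise_spec(alpha = 0.1,
                                          kernel = matched_noise_kernel(object$profile))
  replicate(nsim, apply_noise(object$patterns, object$topology, noise),
            simplify = FALSE)
}

#' Rescale the weights of a trained memory
#'
#' Multiplies all weights by one scalar so that their mean equals
#' `target_mean`.  The signal-to-noise recognition statistic is invariant
#' under this rescaling, because the squared mean difference and the
#' variances scale by the same factor.
#'
#' @param memory a [pattern_memory] (or a bare numeric weight vector).
#' @param target_mean desired mean weight, `> 0`.
#' @return the rescaled memory (or weight vector).
#' @export
rescale_weights <- function(memory, target_mean = 1) {
  if (target_mean <= 0) stop("'target_mean' must be > 0")
  if (is.numeric(memory)) return(memory * (target_mean / mean(memory)))
  stopifnot(inherits(memory, "pattern_memory"))
  memory$weights <- memory$weights * (target_mean / mean(memory$weights))
  memory
}
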