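#' Displacement-target probabilities on the ring
#'
#' When an ON bit is displaced, its target neighbor is chosen with
#' probability proportional to the depression amount the leakage kernel
#' applies at that distance, `(1 - d) * 2^(-delta)`, normalized over the
#' `2 * radius` eligible targets (the center is excluded).  The factor
#' `(1 - d)` cancels in the normalization, so the probabilities depend on
#' the radius only: radius 1 gives 0.5 per neighbor, radius 2 gives 1/3 per
#' nearest and 1/6 per next-nearest neighbor.
#'
#' @param radius neighborhood radius, 1..3.
#' @param d depression factor (kept for interface symmetry; cancels).
#' @return named numeric vector of probabilities over signed offsets
#'   `-radius..-1, +1..+radius`; sums to 1.
#' @examples
#' neighbor_probabilities_1d(2)
#' @export
neighbor_probabilities_1d <- function(radius, d = 0.5) {
  if (radius < 1 || radius > 3)
    stop("'radius' must be in 1..3 (radius 0 has no eligible target)")
  delta <- seq_len(radius)
  a <- (1 - d) * 2^(-delta)
  p <- c(rev(a), a) / (2 * sum(a))
  names(p) <- c(-rev(delta), delta)
  p
}

#' Local pattern-noise specification
#'
#' Degrades stored patterns at recall with the same neighborhood kernels as
#' the plasticity leakage: a fraction `alpha` of the ON bits is displaced to
#' a kernel-weighted neighbor (arity preserved), and optionally a fraction
#' `additive_fraction` of new ON bits is added in the neighborhood of the
#' original ON bits.
#'
#' @param alpha fraction of ON bits displaced, in \[0, 1\].
#' @param additive_fraction fraction of ON bits newly added, in \[0, 1\].
#' @param kernel a [leak_profile] of mode `"exponential"` or `"gaussian"`
#'   defining the neighbor-sampling distribution.  When the learning rule is
#' specific LTD (which has no kernel of its own), pass the kernel of the
#' nonspecific rule it is being compared against, so both see identical
#' noise statistics.
#' @param seed optional integer seed applied when the noise is drawn.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(alpha, additive_fraction = 0, kernel, seed = NULL) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]")
  if (additive_fraction < 0 || additive_fraction > 1)
    stop("'additive_fraction' must be in [0, 1]")
  stopifnot(inherits(kernel, "leak_profile"))
  if (kernel$mode == "specific")
    stop("a noise kernel needs a neighborhood; use the kernel of the paired nonspecific rule")
  structure(list(alpha = alpha, additive_fraction = additive_fraction,
                 kernel = kernel, seed = seed),
            class = "noise_spec")
}

#' Noise kernel matched to a plasticity profile
#'
#' @param profile a nonspecific [leak_profile].
#' @return the same kernel, for use as a [noise_spec] kernel.
#' @export
matched_noise_kernel <- function(profile) {
  stopifnot(inherits(profile, "leak_profile"))
  if (profile$mode == "specific")
    stop("specific LTD has no kernel; choose the kernel of the compared nonspecific rule")
  profile
}

#' Apply local noise to a pattern set
#'
#' Displaces `round(alpha * n_on)` ON bits per pattern (chosen uniformly
#' without replacement) to kernel-weighted neighbors, then adds
#' `round(additive_fraction * n_on)` new ON bits, each anchored at a
#' uniformly chosen original ON bit and placed on a kernel-weighted
#' neighbor.  A target must be OFF when it is selected; vacated positions
#' are eligible for later displacements.  Collisions are resolved by
#' bounded resampling.  A congested bit with no eligible OFF neighbor
#' (possible at high noise when, e.g., both ring neighbors of a bit are
#' ON) keeps its position and a replacement ON bit is displaced instead,
#' so the displaced count stays exact; an error naming the congested site
#' is raised only when no bit can be displaced at all.
#'
#' @param patterns a [pattern_set].
#' @param topology the [ring_topology] or spatial layout the kernel lives on.
#' @param spec a [noise_spec].
#' @return a new [pattern_set]; arity per pattern is
#'   `n_on + round(additive_fraction * n_on)`.
#' @examples
#' ps <- generate_pattern_set(N = 500, n_on = 10, P = 3, seed = 1)
#' sp <- noise_spec(0.5, kernel = leak_profile("exponential", radius = 1), seed = 2)
#' noisy <- apply_noise(ps, ring_topology(500), sp)
#' lengths(noisy$on)
#' @export
apply_noise <- function(patterns, topology, spec) {
  stopifnot(inherits(patterns, "pattern_set"),
            inherits(topology, "synapse_topology"),
            inherits(spec, "noise_spec"))
  N <- n_synapses(topology)
  if (patterns$N != N) stop("pattern length does not match topology size")
  check_kernel_topology(spec$kernel, topology)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  samp <- make_neighbor_sampler(spec$kernel, topology)
  mask <- logical(N)
  out <- vector("list", length(patterns$on))
  for (j in seq_along(patterns$on)) {
    on <- patterns$on[[j]]
    mask[on] <- TRUE
    st <- displace_one(on, mask, samp, spec$alpha)
    if (spec$additive_fraction > 0)
      st <- add_one(st$on, on, st$mask, samp, spec$additive_fraction)
    out[[j]] <- sort.int(st$on)
    mask <- st$mask
    mask[st$on] <- FALSE   # restore the all-OFF mask for the next pattern
  }
  pattern_set(out, N)
}

#' Displace ON bits of a pattern set to kernel-weighted neighbors
#'
#' Displacement-only noise (no additive component); see [apply_noise()].
#'
#' @inheritParams apply_noise
#' @return a [pattern_set] with arity preserved exactly.
#' @export
displace_bits <- function(patterns, topology, spec) {
  spec$additive_fraction <- 0
  apply_noise(patterns, topology, spec)
}

#' Add ON bits in the neighborhood of a pattern's ON bits
#'
#' Additive-only noise (no displacement); see [apply_noise()].
#'
#' @inheritParams apply_noise
#' @return a [pattern_set] with arity `n_on + round(additive_fraction * n_on)`.
#' @export
add_bits <- function(patterns, topology, spec) {
  if (spec$additive_fraction <= 0) return(patterns)
  spec$alpha <- 0
  apply_noise(patterns, topology, spec)
}

check_kernel_topology <- function(kernel, topology) {
  if (kernel$mode == "exponential" && !inherits(topology, "ring_topology"))
    stop("ring noise kernels require a ring topology")
  if (kernel$mode == "gaussian" && !inherits(topology, "spatial_layout"))
    stop("gaussian noise kernels require a spatial layout")
  invisible(TRUE)
}

# Neighbor sampler of a noise kernel on a topology: $draw(origins) samples
# one kernel-weighted neighbor per origin (center excluded); $cand(i)
# lists an origin's eligible neighbors with their kernel weights.
make_neighbor_sampler <- function(kernel, topology) {
  if (kernel$mode == "exponential") {
    N <- topology$N
    q <- neighbor_probabilities_1d(kernel$radius, kernel$d)
    offs <- as.integer(names(q))
    list(
      draw = function(origins) {
        o <- sample(offs, length(origins), replace = TRUE, prob = q)
        (origins - 1L + o) %% N + 1L
      },
      cand = function(i) list(idx = (i - 1L + offs) %% N + 1L,
                              w = unname(q)))
  } else {
    nb <- spatial_neighbors(topology, profile_cutoff(kernel))
    s2 <- 2 * kernel$sigma^2
    list(
      # inverse-CDF draw over the truncated Gaussian kernel values
      draw = function(origins) {
        vapply(origins, function(i) {
          cand <- nb$idx[[i]]
          if (!length(cand))
            stop(sprintf("synapse %d has no neighbor within the noise kernel", i))
          kw <- exp(-nb$dist[[i]]^2 / s2)
          cdf <- cumsum(kw)
          cand[findInterval(stats::runif(1) * cdf[length(cdf)], cdf) + 1L]
        }, integer(1))
      },
      cand = function(i) {
        kw <- exp(-nb$dist[[i]]^2 / s2)
        list(idx = nb$idx[[i]], w = kw / sum(kw))
      })
  }
}

# Displace round(alpha * n_on) bits of one pattern.  'mask' marks the
# current ON set; origins are vacated before targets are drawn, so vacated
# positions are eligible targets.  A target must be OFF when accepted;
# rejected draws (target already ON, or clashing with an earlier draw of
# the same round) are resampled.  A congested bit — e.g. one whose ring
# neighbors are all ON — keeps its position and a replacement ON bit is
# displaced instead, so the displaced count stays exact; an error is
# raised only when no bit can be displaced at all.
displace_one <- function(on, mask, samp, alpha) {
  n <- length(on)
  n_d <- round(alpha * n)
  if (n_d == 0L) return(list(on = on, mask = mask))
  sel <- sample.int(n, n_d)
  origins <- on[sel]
  keep <- on[-sel]
  avail <- keep                 # replacement candidates, still in place
  mask[origins] <- FALSE
  placed <- integer(0)
  pending <- origins
  for (outer in 1:100) {
    for (attempt in 1:50) {
      tg <- samp$draw(pending)
      ok <- !mask[tg] & !duplicated(tg)
      acc <- tg[ok]
      mask[acc] <- TRUE
      placed <- c(placed, acc)
      pending <- pending[!ok]
      if (!length(pending)) break
    }
    if (!length(pending)) break
    # congested origins: restore them (unless their vacated site was taken
    # by an earlier displacement) and displace replacement bits instead
    newpend <- integer(0)
    for (o in pending) {
      if (mask[o]) {            # site reused; this bit must still move
        newpend <- c(newpend, o)
        next
      }
      mask[o] <- TRUE
      keep <- c(keep, o)
      if (!length(avail)) next  # nothing left to displace instead (alpha ~ 1)
      rpl <- sample.int(length(avail), 1L)
      r <- avail[rpl]
      avail <- avail[-rpl]
      keep <- keep[keep != r]
      mask[r] <- FALSE
      newpend <- c(newpend, r)
    }
    pending <- newpend
  }
  if (length(pending))
    stop("no eligible OFF target after bounded resampling near synapse(s) ",
         paste(utils::head(pending, 5), collapse = ", "))
  list(on = c(keep, placed), mask = mask)
}

# Add round(af * n_on) new ON bits anchored at uniformly drawn original ON
# bits; anchor and target are redrawn together on collision.  When batch
# resampling stalls (neighborhoods nearly saturated at high noise), the
# remaining bits are drawn without replacement from the explicit set of
# free kernel slots, weighted by their summed kernel mass over anchors;
# an error is raised only at genuine saturation.
add_one <- function(cur, original_on, mask, samp, af) {
  n_a <- round(af * length(original_on))
  if (n_a == 0L) return(list(on = cur, mask = mask))
  placed <- integer(0)
  need <- n_a
  for (attempt in 1:50) {
    anchors <- original_on[sample.int(length(original_on), need, replace = TRUE)]
    tg <- samp$draw(anchors)
    ok <- !mask[tg] & !duplicated(tg)
    acc <- tg[ok]
    mask[acc] <- TRUE
    placed <- c(placed, acc)
    need <- need - length(acc)
    if (need == 0L) break
  }
  if (need > 0L) {
    w <- numeric(0)
    slot <- integer(0)
    for (a in original_on) {
      cc <- samp$cand(a)
      slot <- c(slot, cc$idx)
      w <- c(w, cc$w)
    }
    keep <- !mask[slot]
    if (any(keep)) {
      agg <- rowsum(w[keep], slot[keep])
      free <- as.integer(rownames(agg))
      if (length(free) >= need) {
        acc <- if (length(free) == need) free
               else free[sample.int(length(free), need, prob = agg[, 1])]
        mask[acc] <- TRUE
        placed <- c(placed, acc)
        need <- 0L
      }
    }
  }
  if (need > 0L)
    stop("additive noise saturated: fewer free kernel slots than bits to add")
  list(on = c(cur, placed), mask = mask)
}
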