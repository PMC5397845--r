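#' Linear readout of a weight vector
#'
#' The response of the linear unit to a binary pattern is the inner product
#' of the synaptic weight vector with the pattern vector — the sum of the
#' weights at the pattern's ON synapses.
#'
#' @param w numeric weight vector (or a [pattern_memory]).
#' @param patterns a [pattern_set], or a single integer vector of ON indices.
#' @return numeric vector of nonnegative responses, one per pattern.
#' @export
linear_response <- function(w, patterns) {
  if (inherits(w, "pattern_memory")) w <- w$weights
  if (is.numeric(patterns) && !is.list(patterns))
    patterns <- pattern_set(list(as.integer(patterns)), N = length(w))
  stopifnot(inherits(patterns, "pattern_set"))
  if (patterns$N != length(w))
    stop(sprintf("pattern length (%d) does not match weight vector (%d)",
                 patterns$N, length(w)))
  vapply(patterns$on, function(on) sum(w[on]), numeric(1))
}

#' Signal-to-noise ratio between two response distributions
#'
#' The recognition statistic: the squared difference between the mean
#' responses to stored (or noisy-stored) and novel patterns, divided by the
#' mean of the two sample variances,
#' `(mu_s - mu_n)^2 / ((var_s + var_n) / 2)`.
#' Sample (n-1) variances are used.  The ratio is invariant under a common
#' rescaling of all responses (and hence of all synaptic weights).
#'
#' @param stored responses to stored or noisy-stored patterns (length >= 2).
#' @param novel responses to novel patterns (length >= 2).
#' @return a single nonnegative number; 0 iff the means coincide.
#' @examples
#' snr(c(10, 12, 11), c(5, 6, 7))
#' @export
snr <- function(stored, novel) {
  if (length(stored) < 2 || length(novel) < 2)
    stop("each response set needs at least 2 entries")
  pooled <- (stats::var(stored) + stats::var(novel)) / 2
  dmu <- mean(stored) - mean(novel)
  if (pooled == 0) {
    if (dmu == 0) return(0)
    stop("degenerate response distributions: distinct means with zero variance")
  }
  dmu^2 / pooled
}

#' Normalized performance gain of nonspecific over specific LTD
#'
#' `(snr_ns - snr_ltd) / (snr_ns + snr_ltd)`, in \[-1, 1\]: positive when
#' the nonspecific rule recognizes better, negative when the specific rule
#' does, antisymmetric under swapping the arguments.
#'
#' @param snr_ns s/n under the nonspecific rule (>= 0).
#' @param snr_ltd s/n under specific LTD (>= 0).
#' @return number in \[-1, 1\].
#' @export
normalized_gain <- function(snr_ns, snr_ltd) {
  if (any(snr_ns < 0) || any(snr_ltd < 0)) stop("s/n values must be >= 0")
  if (any(snr_ns + snr_ltd == 0))
    stop("normalized gain is undefined when both s/n values are 0")
  (snr_ns - snr_ltd) / (snr_ns + snr_ltd)
}

#' Crossover noise level of two s/n curves
#'
#' The noise level above which the nonspecific rule outperforms specific
#' LTD.  With `persistent = TRUE` (the default) this is the smallest grid
#' level at which `snr_ns` strictly exceeds `snr_ltd` and keeps exceeding
#' it at every higher level — robust against single-level sampling flukes,
#' with ties never counting as a crossover.  With `persistent = FALSE` it
#' is the onset: the smallest level at which `snr_ns` strictly exceeds
#' `snr_ltd`.  The two definitions coincide for displacement-only noise,
#' where the curves cross once; under combined displacement + additive
#' noise the specific-LTD curve rises again at high noise levels (the added
#' bits push the noisy-stored response mean above the novel mean) and only
#' the onset is well defined.
#'
#' @param noise_grid increasing vector of noise fractions (or percentages).
#' @param snr_ltd,snr_ns mean s/n per grid level for the two rules.
#' @param persistent logical; see Details.
#' @return the crossover level on the grid, or `NA` if there is none.
#' @examples
#' crossover_noise_level(c(0, .2, .4, .6), c(9, 5, 2, 1), c(6, 4, 3, 2))
#' @export
crossover_noise_level <- function(noise_grid, snr_ltd, snr_ns,
                                  persistent = TRUE) {
  stopifnot(length(noise_grid) == length(snr_ltd),
            length(noise_grid) == length(snr_ns))
  if (is.unsorted(noise_grid, strictly = TRUE))
    stop("'noise_grid' must be sorted strictly ascending")
  wins <- snr_ns > snr_ltd
  if (!any(wins)) return(NA_real_)
  if (!persistent) return(noise_grid[which(wins)[1]])
  # last position from which 'wins' holds through the end of the grid
  run <- rev(cumprod(rev(wins)))
  if (!run[length(run)]) return(NA_real_)
  noise_grid[which(as.logical(run))[1]]
}
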