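#' Configuration of a pattern-recognition experiment
#'
#' Bundles everything that determines a seeded experiment: the model
#' (ring or spatial layout), pattern dimensions, the learning rules to
#' compare, the noise protocol and the repeat structure.  Every run is
#' fully determined by the configuration plus `master_seed`: per-repeat
#' pattern seeds and per-condition noise seeds are derived from it by a
#' fixed counter scheme and recorded in every result row.
#'
#' Defaults follow the studied conditions: `"ANN-1D"` uses `N = 147400`
#' bits with 1000 ON (0.7% sparsity) on a ring, comparing specific LTD
#' against exponential leakage of radius 1-3; `"ANN-3D"` uses the surrogate
#' 1474 x 10 spine layout (`N = 14740`, 100 ON bits) comparing specific
#' LTD against a Gaussian kernel of sigma 0.75 um.  The noise grid is
#' 0-100% in 10% steps and each condition is repeated 10 times.  Noise
#' kernels are matched to each nonspecific rule; specific LTD, which has
#' no kernel of its own, is paired with the kernel of the first
#' nonspecific rule so that both arms of a comparison see identical noise
#' statistics.  Within a repeat all rules share one stored and one novel
#' pattern set (a paired comparison); novel patterns are drawn fresh each
#' repeat.
#'
#' @param model `"ANN-1D"` or `"ANN-3D"`.
#' @param N pattern length; default by model.
#' @param n_on ON bits per pattern; default by model.
#' @param P number of stored patterns (loading).
#' @param rules named list of [leak_profile]s; defaults by model.
#' @param alphas displacement-noise grid (fractions).
#' @param additive_matched logical: add `alpha * n_on` bits at every level
#'   (combined displacement + additive protocol).
#' @param repeats independent learning/recognition repetitions.
#' @param master_seed integer master seed.
#' @param ltp logical: weight-conserving potentiation during storage.
#' @param layout optional [build_synthetic_morphology] result or path to an
#'   SWC/CSV layout (ANN-3D); by default a surrogate morphology is
#'   generated from the master seed.
#' @param sigma_noise Gaussian noise-kernel SD in um (ANN-3D); defaults to
#'   the sigma of the first Gaussian rule.
#' @return an object of class `experiment_config`.
#' @examples
#' cfg <- experiment_config("ANN-1D", N = 2000, n_on = 14, P = 20,
#'                          repeats = 2, master_seed = 1)
#' @export
experiment_config <- function(model = c("ANN-1D", "ANN-3D"),
                              N = NULL, n_on = NULL, P = 100,
                              rules = NULL,
                              alphas = seq(0, 1, by = 0.1),
                              additive_matched = FALSE,
                              repeats = 10, master_seed = 1,
                              ltp = FALSE, layout = NULL,
                              sigma_noise = NULL) {
  model <- match.arg(model)
  if (is.null(N)) N <- if (model == "ANN-1D") 147400L else 14740L
  if (is.null(n_on)) n_on <- if (model == "ANN-1D") 1000L else 100L
  if (n_on <= 0 || n_on > N) stop("'n_on' must satisfy 0 < n_on <= N")
  if (P < 1) stop("'P' must be >= 1")
  if (repeats < 1) stop("'repeats' must be >= 1")
  if (any(alphas < 0 | alphas > 1)) stop("'alphas' must lie in [0, 1]")
  if (is.null(rules)) {
    rules <- if (model == "ANN-1D")
      list(LTD = leak_profile("specific"),
           nsLTD_r1 = leak_profile("exponential", radius = 1),
           nsLTD_r2 = leak_profile("exponential", radius = 2),
           nsLTD_r3 = leak_profile("exponential", radius = 3))
    else
      list(LTD = leak_profile("specific"),
           nsLTD_g075 = leak_profile("gaussian", sigma = 0.75))
  }
  stopifnot(is.list(rules), !is.null(names(rules)))
  if (model == "ANN-3D") {
    if (is.null(layout))
      layout <- build_synthetic_morphology(
        n_compartments = ceiling(N / 10), spines_per_compartment = 10,
        seed = derive_seed(master_seed, 999999L, 0L))
    else if (is.character(layout)) layout <- read_layout(layout)
    if (n_synapses(layout) != N)
      stop(sprintf("layout has %d spines but N = %d", n_synapses(layout), N))
    topology <- layout
  } else {
    topology <- ring_topology(N)
  }
  # pair each rule with a noise kernel
  ns <- Filter(function(p) p$mode != "specific", rules)
  if (!length(ns)) stop("at least one nonspecific rule is needed to define the noise kernel")
  kernels <- lapply(rules, function(p) {
    k <- if (p$mode == "specific") ns[[1]] else p
    if (!is.null(sigma_noise) && k$mode == "gaussian")
      k <- leak_profile("gaussian", d = k$d, sigma = sigma_noise)
    k
  })
  structure(list(model = model, N = as.integer(N), n_on = as.integer(n_on),
                 P = as.integer(P), rules = rules, kernels = kernels,
                 alphas = alphas, additive_matched = additive_matched,
                 repeats = as.integer(repeats),
                 master_seed = as.integer(master_seed),
                 ltp = ltp, topology = topology),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("experiment_config: %s, N = %d, n_on = %d, P = %d, %d repeats\n",
              x$model, x$N, x$n_on, x$P, x$repeats))
  cat(sprintf("rules: %s; noise grid %s%%%s%s\n",
              paste(names(x$rules), collapse = ", "),
              paste(round(100 * x$alphas), collapse = "/"),
              if (x$additive_matched) " + matched additive noise" else "",
              if (x$ltp) "; LTP on" else ""))
  invisible(x)
}

# Deterministic per-(condition, repeat) seed derivation; documented counter
# scheme, kept below 2^31.
derive_seed <- function(master, cond, rep) {
  as.integer(((master %% 100000) * 20011 + cond * 1009 + rep) %% 2147483587L) + 1L
}

#' Run a noise sweep
#'
#' For every rule, noise level and repeat: generate `P` stored and `P`
#' novel patterns (shared across rules within a repeat), train the memory,
#' degrade the stored patterns, and compute the s/n of noisy-stored versus
#' novel responses as well as the zero-noise stored-versus-novel s/n.
#'
#' @param config an [experiment_config].
#' @param progress logical: per-condition progress on stderr.
#' @return a data.frame of class `ltd_sweep`, one row per
#'   (rule, alpha, repeat), with columns `model`, `rule`, `kernel_param`,
#'   `alpha`, `rep`, `seed`, `snr_noisy`, `snr_stored`, `mean_weight`.
#' @export
run_noise_sweep <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- vector("list", 0L)
  for (r in seq_len(config$repeats)) {
    stored <- generate_pattern_set(config$N, config$n_on, config$P,
                                   derive_seed(config$master_seed, 0L, r))
    novel <- generate_pattern_set(config$N, config$n_on, config$P,
                                  derive_seed(config$master_seed, 1L, r))
    for (ci in seq_along(config$rules)) {
      rule_name <- names(config$rules)[ci]
      profile <- config$rules[[ci]]
      mem <- pattern_memory(stored, config$topology, profile,
                            ltp = config$ltp)
      resp_novel <- predict(mem, novel)
      resp_stored <- predict(mem, stored)
      snr_stored <- snr(resp_stored, resp_novel)
      if (progress)
        message(sprintf("repeat %d/%d, rule %s", r, config$repeats, rule_name))
      for (ai in seq_along(config$alphas)) {
        alpha <- config$alphas[ai]
        af <- if (config$additive_matched) alpha else 0
        nseed <- derive_seed(config$master_seed, 10L + ci * 100L + ai, r)
        if (alpha == 0 && af == 0) {
          snr_noisy <- snr_stored
        } else {
          spec <- noise_spec(alpha, af, kernel = config$kernels[[ci]],
                             seed = nseed)
          # a saturated noise level (e.g. 100% combined displacement +
          # additive noise exhausts the radius-1 slots) yields NA, not
          # an aborted sweep
          snr_noisy <- tryCatch(
            snr(predict(mem, apply_noise(stored, config$topology, spec)),
                resp_novel),
            error = function(e) {
              warning(sprintf("rule %s, alpha %.2f, repeat %d: %s",
                              rule_name, alpha, r, conditionMessage(e)),
                      call. = FALSE)
              NA_real_
            })
        }
        rows[[length(rows) + 1L]] <- data.frame(
          model = config$model, rule = rule_name,
          kernel_param = kernel_param(profile), alpha = alpha, rep = r,
          seed = nseed, snr_noisy = snr_noisy, snr_stored = snr_stored,
          mean_weight = mean(mem$weights))
      }
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("ltd_sweep", "data.frame")
  attr(res, "config") <- config
  res
}

kernel_param <- function(profile) {
  switch(profile$mode,
         specific = 0,
         exponential = profile$radius,
         gaussian = profile$sigma)
}

#' Run a loading sweep
#'
#' Repeats the noise sweep while varying the number of stored patterns;
#' training and test sets scale together (`P` stored, `P` novel).
#'
#' @param config an [experiment_config]; its `alphas` are the noise levels
#'   compared at each loading.
#' @param loadings vector of pattern counts.
#' @inheritParams run_noise_sweep
#' @return an `ltd_sweep` data.frame with an extra `loading` column.
#' @export
run_loading_sweep <- function(config, loadings = c(25, 50, 100, 200, 400),
                              progress = FALSE) {
  out <- lapply(loadings, function(P) {
    cfg <- config
    cfg$P <- as.integer(P)
    res <- run_noise_sweep(cfg, progress = progress)
    res$loading <- P
    res
  })
  res <- do.call(rbind, out)
  class(res) <- c("ltd_sweep", "data.frame")
  attr(res, "config") <- config
  res
}

#' Run a sparsity sweep
#'
#' Repeats the noise sweep while varying the density of ON bits per
#' pattern.
#'
#' @param config an [experiment_config].
#' @param densities vector of ON-bit fractions (e.g. 0.0035 to 0.056).
#' @inheritParams run_noise_sweep
#' @return an `ltd_sweep` data.frame with an extra `density` column.
#' @export
run_sparsity_sweep <- function(config,
                               densities = c(0.0035, 0.007, 0.014, 0.028, 0.056),
                               progress = FALSE) {
  out <- lapply(densities, function(f) {
    cfg <- config
    cfg$n_on <- as.integer(round(f * cfg$N))
    res <- run_noise_sweep(cfg, progress = progress)
    res$density <- f
    res
  })
  res <- do.call(rbind, out)
  class(res) <- c("ltd_sweep", "data.frame")
  attr(res, "config") <- config
  res
}

#' Run a kernel-mismatch sweep (ANN-3D)
#'
#' Varies the spatial spread of the depression leakage (`sigma_LTD`) while
#' the noise kernel stays fixed at `sigma_noise`, at a fixed displacement
#' fraction.  A `sigma_ltd` of 0 denotes specific LTD.
#'
#' @param config an `"ANN-3D"` [experiment_config].
#' @param sigma_ltd_grid leakage SDs in micrometers (0 for specific LTD).
#' @param sigma_noise noise-kernel SD in micrometers.
#' @param alpha displacement fraction applied at every grid point.
#' @inheritParams run_noise_sweep
#' @return an `ltd_sweep` data.frame; `kernel_param` holds `sigma_ltd`.
#' @export
run_mismatch_sweep <- function(config,
                               sigma_ltd_grid = c(0, 0.25, 0.5, 0.75, 1, 1.5),
                               sigma_noise = 0.75, alpha = 0.5,
                               progress = FALSE) {
  if (config$model != "ANN-3D")
    stop("the mismatch sweep is defined for the ANN-3D model")
  rules <- lapply(sigma_ltd_grid, function(s)
    if (s == 0) leak_profile("specific") else leak_profile("gaussian", sigma = s))
  names(rules) <- sprintf("sigma_%g", sigma_ltd_grid)
  cfg <- experiment_config("ANN-3D", N = config$N, n_on = config$n_on,
                           P = config$P, rules = rules, alphas = alpha,
                           repeats = config$repeats,
                           master_seed = config$master_seed,
                           ltp = config$ltp, layout = config$topology,
                           sigma_noise = sigma_noise)
  res <- run_noise_sweep(cfg, progress = progress)
  res$sigma_ltd <- sigma_ltd_grid[match(res$rule, names(rules))]
  res
}

#' Average a sweep over repeats
#'
#' @param res an `ltd_sweep` result.
#' @param extra additional grouping columns (e.g. `"loading"`).
#' @return a data.frame of per-(rule, alpha) means and SDs of the s/n.
#' @export
summarize_sweep <- function(res, extra = character(0)) {
  keys <- c("model", "rule", "kernel_param", "alpha", extra)
  keys <- keys[keys %in% names(res)]
  agg <- stats::aggregate(res[c("snr_noisy", "snr_stored")], res[keys],
                          function(v) c(mean = mean(v, na.rm = TRUE),
                                        sd = stats::sd(v, na.rm = TRUE)))
  out <- agg[keys]
  out$snr_noisy <- agg$snr_noisy[, "mean"]
  out$snr_noisy_sd <- agg$snr_noisy[, "sd"]
  out$snr_stored <- agg$snr_stored[, "mean"]
  out$snr_stored_sd <- agg$snr_stored[, "sd"]
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Crossover level of a sweep result
#'
#' Averages the s/n curves over repeats and applies
#' [crossover_noise_level()] to one specific-LTD / nonspecific pair.
#'
#' @param res an `ltd_sweep` result.
#' @param ltd_rule,ns_rule rule names as in the config.
#' @param persistent passed to [crossover_noise_level()].
#' @return the crossover noise fraction, or `NA`.
#' @export
sweep_crossover <- function(res, ltd_rule = "LTD", ns_rule,
                            persistent = TRUE) {
  s <- summarize_sweep(res)
  a <- s[s$rule == ltd_rule, ]
  b <- s[s$rule == ns_rule, ]
  a <- a[order(a$alpha), ]; b <- b[order(b$alpha), ]
  if (!nrow(a) || !nrow(b) || !identical(a$alpha, b$alpha))
    stop("rules not found or misaligned noise grids")
  ok <- is.finite(a$snr_noisy) & is.finite(b$snr_noisy)
  crossover_noise_level(a$alpha[ok], a$snr_noisy[ok], b$snr_noisy[ok],
                        persistent = persistent)
}

#' @export
plot.ltd_sweep <- function(x, ...) {
  s <- summarize_sweep(x)
  rules <- unique(s$rule)
  cols <- grDevices::hcl.colors(max(3, length(rules)), "Dark 3")[seq_along(rules)]
  graphics::plot(NULL, xlim = range(s$alpha), ylim = range(0, s$snr_noisy),
                 xlab = "noise fraction", ylab = "s/n",
                 main = "Recognition vs. local pattern noise", ...)
  for (i in seq_along(rules)) {
    si <- s[s$rule == rules[i], ]
    si <- si[order(si$alpha), ]
    graphics::lines(si$alpha, si$snr_noisy, col = cols[i], lwd = 2)
    graphics::points(si$alpha, si$snr_noisy, col = cols[i], pch = 16)
    graphics::arrows(si$alpha, si$snr_noisy - si$snr_noisy_sd,
                     si$alpha, si$snr_noisy + si$snr_noisy_sd,
                     angle = 90, code = 3, length = 0.02, col = cols[i])
  }
  graphics::legend("topright", legend = rules, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
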