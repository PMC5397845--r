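test_that("neighbor probabilities match the kernel-proportional rule", {
  p1 <- neighbor_probabilities_1d(1)
  expect_equal(unname(p1), c(0.5, 0.5))
  p2 <- neighbor_probabilities_1d(2)
  expect_equal(round(unname(p2[c("1", "2")]), 2), c(0.33, 0.17))
  for (r in 1:3) expect_equal(sum(neighbor_probabilities_1d(r)), 1)
  expect_error(neighbor_probabilities_1d(0), "radius")
})

test_that("displacement preserves arity exactly at every noise level", {
  topo <- ring_topology(5000)
  ps <- generate_pattern_set(5000, 40, 5, seed = 1)
  kern <- leak_profile("exponential", radius = 2)
  for (alpha in c(0, 0.13, 0.5, 1)) {
    noisy <- apply_noise(ps, topo, noise_spec(alpha, kernel = kern, seed = 2))
    expect_true(all(lengths(noisy$on) == 40))
    expect_true(all(vapply(noisy$on, anyDuplicated, integer(1)) == 0L))
    if (alpha == 0) expect_identical(noisy$on, ps$on)
  }
})

test_that("noisy and stored patterns share n_on - round(alpha n_on) bits", {
  # well-separated ON bits so displacement neighborhoods cannot collide
  topo <- ring_topology(10000)
  on <- seq(50L, 9950L, by = 100L)     # 100 bits, 100 apart
  ps <- pattern_set(list(on), 10000)
  kern <- leak_profile("exponential", radius = 3)
  for (alpha in c(0.1, 0.35, 0.8)) {
    noisy <- apply_noise(ps, topo, noise_spec(alpha, kernel = kern, seed = 5))
    shared <- length(intersect(noisy$on[[1]], on))
    expect_equal(shared, 100 - round(alpha * 100))
  }
})

test_that("1D displacement targets follow the stated distribution", {
  # many single-bit patterns give an empirical histogram of signed offsets
  N <- 101L
  n_rep <- 20000L
  origin <- 51L
  ps <- pattern_set(rep(list(origin), n_rep), N)
  topo <- ring_topology(N)
  noisy <- apply_noise(ps, topo,
                       noise_spec(1, kernel = leak_profile("exponential",
                                                           radius = 2),
                                  seed = 31))
  offs <- vapply(noisy$on, function(on) on[1] - origin, integer(1))
  q <- neighbor_probabilities_1d(2)
  counts <- table(factor(offs, levels = as.integer(names(q))))
  # 3-sigma multinomial band per offset
  for (k in seq_along(q)) {
    expected <- n_rep * q[k]
    expect_lt(abs(counts[k] - expected),
              3 * sqrt(n_rep * q[k] * (1 - q[k])) + 1e-9)
  }
})

test_that("kernel-matched displacement lands on leak-depressed synapses", {
  for (r in 1:3) {
    topo <- ring_topology(3000)
    ps <- generate_pattern_set(3000, 15, 1, seed = r)
    pr <- leak_profile("exponential", radius = r)
    mem <- pattern_memory(ps, topo, pr)
    noisy <- apply_noise(ps, topo, noise_spec(0.6, kernel = pr, seed = r + 10))
    moved <- setdiff(noisy$on[[1]], ps$on[[1]])
    expect_true(all(coef(mem)[moved] < 1))
  }
})

test_that("3D displacement samples kernel-weighted neighbors only", {
  lay <- build_synthetic_morphology(30, 10, 3.0, seed = 3)
  kern <- leak_profile("gaussian", sigma = 0.75)
  ps <- generate_pattern_set(300, 12, 4, seed = 4)
  noisy <- apply_noise(ps, lay, noise_spec(0.5, kernel = kern, seed = 5))
  for (j in seq_along(ps$on)) {
    moved <- setdiff(noisy$on[[j]], ps$on[[j]])
    expect_true(all(lengths(noisy$on) == 12))
    for (b in moved) {
      dmin <- min(topo_distance(lay, rep(b, 12), ps$on[[j]]))
      expect_lte(dmin, 5 * 0.75)     # within the truncated kernel support
    }
  }
})

test_that("additive noise adds the exact count inside the neighborhoods", {
  topo <- ring_topology(5000)
  ps <- generate_pattern_set(5000, 50, 3, seed = 6)
  kern <- leak_profile("exponential", radius = 1)
  sp <- noise_spec(alpha = 0.2, additive_fraction = 0.2, kernel = kern,
                   seed = 7)
  noisy <- apply_noise(ps, topo, sp)
  expect_true(all(lengths(noisy$on) == 60))
  # additive-only: every added bit is a ring neighbor of an original ON bit
  addonly <- add_bits(ps, topo, noise_spec(0, 0.4, kern, seed = 8))
  for (j in 1:3) {
    added <- setdiff(addonly$on[[j]], ps$on[[j]])
    expect_length(added, 20)
    for (b in added)
      expect_lte(min(topo_distance(topo, rep(b, 50), ps$on[[j]])), 1)
  }
  expect_identical(add_bits(ps, topo, noise_spec(0, 0, kern))$on, ps$on)
})

test_that("additive noise errors once the neighborhoods saturate", {
  topo <- ring_topology(6)
  ps <- pattern_set(list(c(1L, 2L, 3L, 4L, 5L)), 6)
  sp <- noise_spec(0, 1, leak_profile("exponential", radius = 1), seed = 9)
  expect_error(apply_noise(ps, topo, sp), "saturated")
})

test_that("noise draws are reproducible and kernels validated", {
  topo <- ring_topology(1000)
  ps <- generate_pattern_set(1000, 10, 2, seed = 10)
  kern <- leak_profile("exponential", radius = 1)
  a <- apply_noise(ps, topo, noise_spec(0.5, kernel = kern, seed = 77))
  b <- apply_noise(ps, topo, noise_spec(0.5, kernel = kern, seed = 77))
  expect_identical(a$on, b$on)
  expect_error(noise_spec(0.5, kernel = leak_profile("specific")), "kernel")
  expect_error(noise_spec(1.5, kernel = kern), "alpha")
  expect_error(apply_noise(ps, topo,
                           noise_spec(0.5, kernel = leak_profile("gaussian"))),
               "spatial layout")
})
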