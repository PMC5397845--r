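test_that("ring distance is the minimal wraparound path length", {
  topo <- ring_topology(10)
  expect_equal(topo_distance(topo, 1, 10), 1)   # wraparound
  expect_equal(topo_distance(topo, 1, 1), 0)
  big <- ring_topology(147400)
  expect_equal(topo_distance(big, 6, 9), 3)
  # symmetry and the triangle inequality on random triples
  set.seed(4)
  for (rep in 1:50) {
    ijk <- sample.int(147400, 3)
    dij <- topo_distance(big, ijk[1], ijk[2])
    dji <- topo_distance(big, ijk[2], ijk[1])
    djk <- topo_distance(big, ijk[2], ijk[3])
    dik <- topo_distance(big, ijk[1], ijk[3])
    expect_identical(dij, dji)
    expect_lte(dik, dij + djk)
  }
  expect_true(all(topo_distance(big, 1, 1:100) <= 147400 %/% 2))
  expect_error(ring_topology(2), ">= 3")
})

test_that("generated morphology has the requested spine counts and spacing", {
  lay <- build_synthetic_morphology(20, 10, 3.0, seed = 1)
  expect_equal(n_synapses(lay), 200)
  expect_equal(length(unique(lay$compartment)), 20)
  # axial attachment spacing is length/spines when necks are disabled
  lay0 <- build_synthetic_morphology(5, 10, 3.0, spine_neck_length = 0,
                                     seed = 2)
  d <- topo_distance(lay0, 1:9, 2:10)      # within the first compartment
  expect_equal(d, rep(0.3, 9), tolerance = 1e-12)
  two <- build_synthetic_morphology(1, 2, 1.0, spine_neck_length = 0,
                                    seed = 3)
  expect_equal(topo_distance(two, 1, 2), 0.5, tolerance = 1e-12)
  # spine necks displace heads by their length, perpendicular to the axis
  layn <- build_synthetic_morphology(1, 2, 1.0, spine_neck_length = 1,
                                     seed = 3)
  expect_gte(topo_distance(layn, 1, 2), 0.5)
  expect_error(build_synthetic_morphology(0, 10, 3), "invalid")
  expect_error(build_synthetic_morphology(10, 10, -1), "invalid")
})

test_that("morphology generation is reproducible under a seed", {
  a <- build_synthetic_morphology(30, 10, 3.0, seed = 5)
  b <- build_synthetic_morphology(30, 10, 3.0, seed = 5)
  expect_identical(a$coords, b$coords)
})

test_that("SWC import reads a collinear chain correctly", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment",
               "1 6 0 0 0 0.1 -1",
               "2 6 1 0 0 0.1 1",
               "3 6 2 0 0 0.1 2"), path)
  lay <- read_layout(path)
  expect_equal(n_synapses(lay), 3)
  expect_equal(lay$provenance, "imported")
  d <- sort(c(topo_distance(lay, 1, 2), topo_distance(lay, 2, 3),
              topo_distance(lay, 1, 3)))
  expect_equal(d, c(1, 1, 2))
})

test_that("malformed SWC records raise an error naming the line", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 6 0 0 0 0.1 -1", "2 6 oops 0 0 0.1 1"), path)
  expect_error(read_layout(path), "line 2")
})

test_that("layout export/import round-trips coordinates to 6 decimals", {
  lay <- build_synthetic_morphology(10, 10, 3.0, seed = 8)
  for (ext in c(".swc", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_layout(lay, path)
    back <- read_layout(path)
    expect_equal(back$coords, lay$coords, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # CSV keeps compartment ids
  path <- withr::local_tempfile(fileext = ".csv")
  write_layout(lay, path)
  expect_identical(read_layout(path)$compartment, lay$compartment)
  # degenerate single-row CSV gives a singleton layout
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "1.5,0,0"), p1)
  expect_equal(n_synapses(read_layout(p1)), 1)
})

test_that("cell-list neighbor search agrees with the dense distance matrix", {
  lay <- build_synthetic_morphology(15, 10, 3.0, seed = 13)
  cutoff <- 2.0
  nb <- nsplast:::spatial_neighbors(lay, cutoff)
  dm <- as.matrix(dist(lay$coords))
  for (i in c(1, 42, 77, 150)) {
    expected <- which(dm[i, ] <= cutoff & seq_len(150) != i)
    expect_setequal(nb$idx[[i]], expected)
    expect_equal(sort(nb$dist[[i]]), sort(dm[i, expected]),
                 ignore_attr = TRUE)
  }
})

test_that("self-avoidance keeps unrelated branches apart", {
  # without the separation constraint a random tree tangles; with it,
  # spines of far-apart compartments should rarely come within a kernel
  # width of each other
  lay <- build_synthetic_morphology(200, 10, 3.0, seed = 21)
  nb <- nsplast:::spatial_neighbors(lay, 1.0)
  comp <- lay$compartment
  close_foreign <- sum(vapply(seq_along(nb$idx), function(i)
    sum(abs(comp[nb$idx[[i]]] - comp[i]) > 5), numeric(1)))
  expect_lt(close_foreign / n_synapses(lay), 0.2)
})
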