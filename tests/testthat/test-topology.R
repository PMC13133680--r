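toy_diagram <- function(pairs, dim = 1L, max_edge = 1) {
  out <- data.frame(dimension = rep(dim, nrow(pairs)), birth = pairs[, 1],
                    death = pairs[, 2], capped = logical(nrow(pairs)))
  attr(out, "max_edge") <- max_edge
  class(out) <- c("persistence_diagram", "data.frame")
  out
}

test_that("vr persistence reproduces structured cases", {
  # two points merging at their distance; one essential component
  d2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  dg <- vr_persistence(d2, 1, 1)
  h0 <- dg[dg$dimension == 0, ]
  expect_equal(nrow(h0), 2)
  expect_equal(sort(h0$death), c(0.5, 1))
  expect_equal(h0$capped[order(h0$death)], c(FALSE, TRUE))
  # single point
  d1 <- matrix(0, 1, 1)
  dg1 <- vr_persistence(d1, 1, 1)
  expect_equal(nrow(dg1), 1)
  expect_equal(dg1$dimension, 0L)
  # unit square scaled to side 0.5: one H1 born at the side length,
  # dying at the diagonal
  pts <- rbind(c(0, 0), c(0.5, 0), c(0.5, 0.5), c(0, 0.5))
  dsq <- as.matrix(dist(pts))
  h1 <- vr_persistence(dsq, 2, 1)
  h1 <- h1[h1$dimension == 1, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, 0.5)
  expect_equal(h1$death, 0.5 * sqrt(2), tolerance = 1e-12)
  expect_error(vr_persistence(matrix(c(0, 1, 2, 0), 2), 1, 1), "symmetric")
})

test_that("vr persistence agrees with the reduction oracle on small cases", {
  withr::with_seed(21, {
    for (i in 1:12) {
      n <- sample(3:6, 1)
      d <- random_distance_matrix(n)
      expect_equal(diagram_to_matrix(vr_persistence(d, 2, 1)),
                   oracle_vr_persistence(d, 2, 1), tolerance = 1e-12)
    }
  })
})

test_that("landscape layers are the sorted tents of the diagram", {
  single <- toy_diagram(cbind(0, 2))
  pl <- persistence_landscape(single, 1, n = 5, k_max = 2)
  # grid 0, .5, 1, 1.5, 2 -> tent 0, .5, 1, .5, 0
  expect_equal(pl$layers[1, ], c(0, 0.5, 1, 0.5, 0))
  expect_equal(pl$layers[2, ], rep(0, 5))
  two <- toy_diagram(rbind(c(0, 2), c(1, 3)))
  pl2 <- persistence_landscape(two, 1, n = 7, k_max = 2)
  # at t = 1.5 both tents give 0.5
  expect_equal(pl2$layers[1, 4], 0.5)
  expect_equal(pl2$layers[2, 4], 0.5)
  empty <- toy_diagram(matrix(0, 0, 2))
  expect_true(all(persistence_landscape(empty, 1)$layers == 0))
})

test_that("landscape layers are pointwise ordered on random diagrams", {
  withr::with_seed(31, {
    for (i in 1:20) {
      k <- sample(1:8, 1)
      b <- runif(k, 0, 0.5)
      pairs <- cbind(b, b + runif(k, 0.01, 0.5))
      pl <- persistence_landscape(toy_diagram(pairs), 1, n = 60, k_max = 4)
      for (layer in 1:3)
        expect_true(all(pl$layers[layer, ] >= pl$layers[layer + 1, ] - 1e-12))
      expect_true(all(pl$layers >= 0))
    }
  })
})

test_that("betti curve counts alive features with closed intervals", {
  dg <- toy_diagram(rbind(c(0, 2), c(1, 3)))
  bc <- betti_curve(dg, 1, n = 7)       # grid 0, .5, ..., 3
  expect_equal(bc$values, c(1, 1, 2, 2, 2, 1, 1))
  # t = 2 is the first feature's death and still counts
  expect_equal(bc$values[bc$grid == 2], 2)
  expect_true(all(betti_curve(toy_diagram(matrix(0, 0, 2)), 1)$values == 0))
})

test_that("betti curve integral matches total persistence", {
  withr::with_seed(14, {
    for (i in 1:10) {
      k <- sample(1:6, 1)
      b <- runif(k); pairs <- cbind(b, b + runif(k, 0.05, 1))
      dg <- toy_diagram(pairs)
      n <- 2000
      bc <- betti_curve(dg, 1, n = n)
      integral <- sum(bc$values) * (bc$grid[2] - bc$grid[1])
      expect_equal(integral, sum(pairs[, 2] - pairs[, 1]),
                   tolerance = sum(pairs[, 2] - pairs[, 1]) * 0.01)
    }
  })
})

test_that("persistent entropy matches closed forms and is maximal when equal", {
  expect_equal(persistent_entropy(toy_diagram(cbind(0, 1)), 1), 0)
  expect_equal(persistent_entropy(toy_diagram(rbind(c(0, 2), c(1, 3))), 1),
               log(2))
  expect_equal(persistent_entropy(toy_diagram(rbind(c(0, 1), c(0, 3))), 1),
               -(0.25 * log(0.25) + 0.75 * log(0.75)), tolerance = 1e-12)
  expect_equal(persistent_entropy(toy_diagram(matrix(0, 0, 2)), 1), 0)
  withr::with_seed(7, {
    for (m in 2:5) {
      b <- runif(m)
      equal <- toy_diagram(cbind(b, b + 0.3))
      expect_equal(persistent_entropy(equal, 1), log(m))
      uneq <- equal; uneq$death <- uneq$birth + runif(m, 0.1, 0.9)
      expect_lte(persistent_entropy(uneq, 1), log(m) + 1e-12)
    }
  })
  # base is configurable
  expect_equal(persistent_entropy(toy_diagram(rbind(c(0, 2), c(1, 3))), 1,
                                  base = 2), 1)
})

test_that("amplitudes follow the grid p-norm definitions", {
  single <- toy_diagram(cbind(0, 2))
  amp <- landscape_amplitude(single, 1, n_layers = 1, p = 1, n = 100)
  expect_equal(amp, 50, tolerance = 0.6)
  expect_equal(landscape_amplitude(toy_diagram(matrix(0, 0, 2)), 1), 0)
  # adding a layer can only increase the p = 1 amplitude
  two <- toy_diagram(rbind(c(0, 2), c(1, 3)))
  expect_gte(landscape_amplitude(two, 1, n_layers = 2),
             landscape_amplitude(two, 1, n_layers = 1))
  bc <- list(grid = seq(0, 1, length.out = 100), values = rep(1, 100))
  expect_equal(betti_amplitude(bc, p = 1), 100)
  bc2 <- bc; bc2$values <- bc$values * 2
  expect_equal(betti_amplitude(bc2, 1), 2 * betti_amplitude(bc, 1))
  expect_equal(betti_amplitude(list(grid = bc$grid,
                                    values = rep(0, 100))), 0)
})

test_that("denoising drops short lifetimes and H2", {
  dg <- data.frame(dimension = c(0L, 0L, 1L, 2L),
                   birth = c(0, 0, 0.2, 0.3),
                   death = c(0.005, 0.5, 0.6, 0.7), capped = FALSE)
  attr(dg, "max_edge") <- 1
  class(dg) <- c("persistence_diagram", "data.frame")
  kept <- denoise_diagram(dg, min_lifetime = 0.01)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$dimension <= 1))
  expect_true(all(kept$death - kept$birth >= 0.01))
  ident <- denoise_diagram(dg, min_lifetime = 0)
  expect_equal(nrow(ident), 3)          # H2 still dropped
  expect_equal(nrow(denoise_diagram(dg, 0, drop_h2 = FALSE)), 4)
})
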