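test_that("overall density is the exact count-to-area ratio", {
  f <- assign_labels_random(generate_random_field(240, seed = 20),
                            c(0.2, 0.45, 0.35), seed = 21)
  expect_identical(overall_density(f), 0.024)
  per_type <- vapply(0:2, function(t) overall_density(f, t), numeric(1))
  expect_equal(sum(per_type), overall_density(f))
  g <- make_field(c(1, 2), c(1, 2), types = c(1, 1), bounds = c(0, 10, 0, 10))
  expect_identical(overall_density(g, 2), 0)
})

test_that("local density counts neighbours within R, excluding self", {
  iso <- make_field(c(50, 80), c(50, 80), bounds = c(0, 100, 0, 100))
  expect_equal(local_density(iso), c(0, 0))  # no neighbour within 8 um
  pair <- make_field(c(50, 55), c(50, 50), bounds = c(0, 100, 0, 100))
  expect_equal(local_density(pair), rep(1 / (64 * pi), 2))
  # periodic counting sees neighbours across the field edge
  wrap <- make_field(c(1, 99), c(50, 50), bounds = c(0, 100, 0, 100))
  expect_equal(local_density(wrap), rep(1 / (64 * pi), 2))
  # on CSR fields the mean local density estimates the overall density
  set.seed(22)
  ratio <- mean(replicate(20, {
    f <- generate_random_field(400)
    mean(local_density(f)) / overall_density(f)
  }))
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("pairwise distances follow the metric and the combinatorics", {
  f <- make_field(c(0, 3), c(0, 4), bounds = c(0, 10, 0, 10))
  expect_equal(pairwise_distances(f), 5)  # 3-4-5 triangle
  g <- assign_labels_random(generate_random_field(30, seed = 23),
                            c(0.3, 0.3, 0.4), seed = 24)
  expect_length(pairwise_distances(g), 30 * 29 / 2)
  n2 <- sum(g$nuclei$type == 2); n0 <- sum(g$nuclei$type == 0)
  expect_length(pairwise_distances(g, 2, 0), n2 * n0)
  # a nucleus's NND is its smallest pairwise distance
  d1 <- sqrt((g$nuclei$x - g$nuclei$x[1])^2 + (g$nuclei$y - g$nuclei$y[1])^2)
  expect_equal(nnd(g, periodic = FALSE)[1], min(d1[-1]))
})

test_that("nearest-neighbour distances match direct minima", {
  f <- make_field(c(0, 1, 3), c(5, 5, 5), bounds = c(0, 10, 0, 10))
  expect_equal(sort(nnd(f)), c(1, 1, 2))
  expect_equal(sort(nnd(f, periodic = FALSE)), c(1, 1, 2))
  # on the torus a point near the edge finds its wrapped neighbour
  wrap <- make_field(c(0.5, 9.5), c(5, 5), bounds = c(0, 10, 0, 10))
  expect_equal(nnd(wrap), c(1, 1))
  expect_equal(nnd(wrap, periodic = FALSE), c(9, 9))
  lattice <- generate_mold(mold_config(jitter = 0, process = "lattice"))
  expect_lt(diff(range(nnd(lattice))), 1e-9)
  expect_error(nnd(make_field(1, 1, bounds = c(0, 2, 0, 2))), "two nuclei")
})

test_that("regularity index is mean NND over sample SD", {
  expect_equal(regularity_index(c(1, 1, 2)), (4 / 3) / sqrt(1 / 3))
  expect_equal(regularity_index(c(1, 1, 2)), 2.309, tolerance = 1e-3)
  # scale invariance
  set.seed(25)
  v <- runif(50, 1, 3)
  expect_equal(regularity_index(v), regularity_index(10 * v))
  expect_error(regularity_index(c(1, 1, 1)), "degenerate")
  expect_error(regularity_index(c(1, 2)), "at least 3")
})

test_that("tiling produces 9 translated copies equal to the torus metric", {
  f <- make_field(5, 5, bounds = c(0, 10, 0, 10))
  tf <- tile_field(f)
  expect_identical(nrow(tf$nuclei), 9L)
  expect_setequal(tf$nuclei$x, c(5, -5, 15))
  # minimum tiled distance between parents equals the minimum image
  set.seed(26)
  g <- generate_random_field(10, c(0, 20, 0, 20))
  tg <- tile_field(g)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      imgs <- tg$nuclei[tg$nuclei$parent == j, ]
      tiled_min <- min(sqrt((imgs$x - g$nuclei$x[i])^2 +
                            (imgs$y - g$nuclei$y[i])^2))
      dx <- abs(g$nuclei$x[i] - g$nuclei$x[j]); dx <- min(dx, 20 - dx)
      dy <- abs(g$nuclei$y[i] - g$nuclei$y[j]); dy <- min(dy, 20 - dy)
      expect_equal(tiled_min, sqrt(dx^2 + dy^2))
    }
  }
})

test_that("K and H reproduce the two-point worked example", {
  f <- make_field(c(2, 5), c(5, 5), bounds = c(0, 10, 0, 10))
  k <- ripley_k(f, grid = radial_grid(10, 2))
  expect_equal(k$values[1], 0)        # r = 2 below the pair distance 3
  expect_equal(k$values[2], 50)       # K(4) = 2 / (0.02 * 2)
  h <- h_transform(k)
  expect_equal(h$values[2], sqrt(50 / pi) - 4)
  expect_lt(abs(h$values[2] - (-0.011)), 1e-3)
})

test_that("tiled K estimator equals brute-force torus counting exactly", {
  grid <- radial_grid(10, 2)  # r <= half the 20 um field side
  for (s in 1:5) {
    f <- generate_random_field(20, c(0, 20, 0, 20), seed = 30 + s)
    expect_equal(ripley_k(f, grid = grid)$values, brute_torus_k(f, NULL, grid))
  }
  # and for a typed pattern
  g <- assign_labels_random(generate_random_field(20, c(0, 20, 0, 20),
                                                  seed = 36),
                            c(0, 0.5, 0.5), seed = 37)
  expect_equal(ripley_k(g, 2, grid)$values, brute_torus_k(g, 2, grid))
})

test_that("K is monotone and translation-invariant on the torus", {
  f <- generate_random_field(60, seed = 38)
  k <- ripley_k(f)
  expect_true(all(diff(k$values) >= 0))
  shifted <- nuclear_field((f$nuclei$x + 31.7) %% 100,
                           (f$nuclei$y + 8.3) %% 100,
                           bounds = c(0, 100, 0, 100))
  expect_equal(ripley_k(shifted)$values, k$values)
})

test_that("CSR fields give K near pi r^2 and H near zero", {
  set.seed(39)
  grid <- radial_grid(50, 2)
  K <- replicate(60, ripley_k(generate_random_field(240), grid = grid)$values)
  expect_lt(max(abs(rowMeans(K) / (pi * grid$edges^2) - 1)), 0.03)
  H <- replicate(60, h_function(generate_random_field(240),
                                grid = grid)$values)
  expect_lt(max(abs(rowMeans(H))), 0.25)
})

test_that("mold fields show hard-core repulsion below the nuclear diameter", {
  for (s in 1:3) {
    m <- generate_mold(seed = 40 + s)
    h <- h_function(m)
    expect_true(all(h$values[h$r <= 6] < 0))
  }
})

test_that("bivariate K matches its worked example and exchange identity", {
  f <- make_field(c(0.5, 3.5), c(5, 5), types = c(0, 2),
                  bounds = c(0, 10, 0, 10))
  k02 <- ripley_k_bivariate(f, 0, 2, radial_grid(10, 2))
  expect_equal(k02$values[2], 100)  # 1 / (0.01 * 1)
  g <- assign_labels_random(generate_random_field(40, c(0, 30, 0, 30),
                                                  seed = 42),
                            c(0.4, 0.2, 0.4), seed = 43)
  grid <- radial_grid(15, 3)
  k_ij <- ripley_k_bivariate(g, 0, 2, grid)$values
  k_ji <- ripley_k_bivariate(g, 2, 0, grid)$values
  n0 <- sum(g$nuclei$type == 0); n2 <- sum(g$nuclei$type == 2)
  A <- field_area(g)
  expect_equal((n0 / A) * n0 * k_ij, (n2 / A) * n2 * k_ji)
  expect_error(ripley_k_bivariate(g, 1, 1), "distinct")
})

test_that("independently placed types give bivariate K near pi r^2", {
  # independence holds against the positions' own K: on CSR positions the
  # cross-K is pi r^2; on a hard-core mold, random labels make the cross-K
  # track the mold's combined K instead (zero below the nuclear spacing)
  set.seed(45)
  grid <- radial_grid(50, 2)
  K <- replicate(60, {
    g <- assign_labels_random(generate_random_field(240),
                              c(0.25, 0.5, 0.25))
    ripley_k_bivariate(g, 0, 2, grid)$values
  })
  expect_lt(max(abs(rowMeans(K) / (pi * grid$edges^2) - 1)), 0.06)
  m <- generate_mold(seed = 44)
  set.seed(46)
  Km <- rowMeans(replicate(40, {
    g <- assign_labels_random(m, c(0.25, 0.5, 0.25))
    ripley_k_bivariate(g, 0, 2, grid)$values
  }))
  k_all <- ripley_k(m, grid = grid)$values
  expect_equal(Km[1:3], k_all[1:3], tolerance = 0.1)  # hard core, not pi r^2
  expect_lt(max(abs(Km[10:25] / (pi * grid$edges[10:25]^2) - 1)), 0.06)
})

test_that("the H-transform maps benchmarks and bounds correctly", {
  grid <- radial_grid(20, 2)
  csr <- new_profile <- structure(
    list(grid = grid, r = grid$edges, values = pi * grid$edges^2,
         statistic = "K", types = integer()), class = "radial_profile")
  expect_equal(h_transform(csr)$values, rep(0, 10))
  zero <- structure(list(grid = grid, r = grid$edges,
                         values = rep(0, 10), statistic = "K",
                         types = integer()), class = "radial_profile")
  expect_equal(h_transform(zero)$values, -grid$edges)  # the H >= -r bound
  neg <- zero; neg$values[1] <- -1
  expect_error(h_transform(neg), "negative")
})
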