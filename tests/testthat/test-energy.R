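test_that("distance_to_line matches brute-force distances to the raster", {
  shape <- c(9L, 9L)
  line <- rbind(c(1, 3), c(9, 3)) # vertical line at col 3
  d <- distance_to_line(line, shape)

  raster <- which(rasterize_line(line, shape), arr.ind = TRUE)
  expect_equal(d, brute_distance_field(raster, shape))
  expect_equal(d[1, 5], 2)
  expect_true(all(d[raster] == 0))

  # polyline with a diagonal segment
  line2 <- rbind(c(2, 2), c(6, 5), c(6, 9))
  d2 <- distance_to_line(line2, shape)
  raster2 <- which(rasterize_line(line2, shape), arr.ind = TRUE)
  expect_equal(d2, brute_distance_field(raster2, shape))

  # 1-Lipschitz between 4-neighbors
  expect_true(all(abs(diff(d2)) <= 1 + 1e-12))
  expect_true(all(abs(t(diff(t(d2)))) <= 1 + 1e-12))

  expect_error(distance_to_line(rbind(c(1, 1)), shape), ">=2")
  expect_error(distance_to_line(rbind(c(0, 1), c(5, 5)), shape), "outside")
})

test_that("distance_to_mask is an exact Euclidean distance transform", {
  set.seed(21)
  for (k in 1:5) {
    m <- matrix(runif(64) < 0.15, 8, 8)
    if (!any(m)) m[3, 4] <- TRUE
    d <- distance_to_mask(m)
    expect_equal(d, brute_distance_field(which(m, arr.ind = TRUE), c(8L, 8L)))
  }
  expect_error(distance_to_mask(matrix(FALSE, 4, 4)), "empty")
})

test_that("energy_decrement floors exactly the pixels inside the line band", {
  shape <- c(5L, 5L)
  speed <- matrix(0.8, 5, 5)
  speed[5, 5] <- 0 # zero-speed pixel defines I_min = 0
  line <- rbind(c(1, 3), c(5, 3))
  d <- distance_to_line(line, shape)

  out <- energy_decrement(speed, d, t_d = 1.5)
  brute <- brute_distance_field(which(rasterize_line(line, shape),
                                      arr.ind = TRUE), shape)
  expected <- speed
  expected[brute < 1.5] <- 0
  expect_equal(out, expected)
  # band floored to the map minimum, everything else untouched
  expect_true(all(out[d < 1.5] == 0))
  expect_true(all(out[d >= 1.5] == speed[d >= 1.5]))

  # t_d = 0: no pixel satisfies D < 0, identity
  expect_identical(energy_decrement(speed, d, t_d = 0), speed)
  expect_error(energy_decrement(speed, d[1:4, ], 1), "shape")
})

test_that("source_energy equals the brute-force double sum", {
  # spec-style 3x3 case: two source pixels, unit edge map
  r0 <- matrix(FALSE, 3, 3); r0[1, 1] <- r0[1, 2] <- TRUE
  g <- matrix(1, 3, 3)
  e <- source_energy(r0, g, sigma = 1)
  expect_equal(e[3, 3], exp(-sqrt(8)) + exp(-sqrt(5)), tolerance = 1e-12)
  expect_equal(e, brute_source_energy(r0, g, 1), tolerance = 1e-9)

  # randomized grids up to 16x16
  set.seed(5)
  for (k in 1:4) {
    nr <- sample(6:16, 1); nc <- sample(6:16, 1)
    r0 <- matrix(runif(nr * nc) < 0.2, nr, nc)
    if (!any(r0)) r0[2, 2] <- TRUE
    g <- matrix(runif(nr * nc), nr, nc)
    sig <- runif(1, 2, 12)
    expect_equal(source_energy(r0, g, sig), brute_source_energy(r0, g, sig),
                 tolerance = 1e-9)
  }
})

test_that("source_energy single-pixel source decays monotonically", {
  r0 <- matrix(FALSE, 9, 9); r0[5, 5] <- TRUE
  g <- matrix(0.7, 9, 9)
  e <- source_energy(r0, g, sigma = 3)
  expect_equal(e[5, 5], 0.7) # distance 0, e^0 * g
  expect_true(all(e > 0))
  along <- e[5, 5:9]
  expect_true(all(diff(along) < 0))
  expect_error(source_energy(matrix(FALSE, 3, 3), g[1:3, 1:3], 1), "empty")
})

test_that("energy_tune_line applies branches, clamps and the D_l = 0 rule", {
  shape <- c(5L, 5L)
  r0 <- matrix(FALSE, 5, 5); r0[1:5, 1:2] <- TRUE
  line <- rbind(c(1, 4), c(5, 4))
  d_line <- distance_to_line(line, shape)
  d_src <- distance_to_mask(r0)
  g <- matrix(0.5, 5, 5)
  e <- source_energy(r0, g, sigma = 5)

  out <- energy_tune_line(g, e, r0, d_line, d_src,
                          tune_alpha = 1, tune_beta = 1)
  n <- sum(r0)
  # per-pixel branch enumeration
  for (i in 1:5) for (j in 1:5) {
    expected <-
      if (r0[i, j]) min(1, (1 / n) * e[i, j] + g[i, j])
      else if (d_line[i, j] <= d_src[i, j]) {
        if (d_line[i, j] == 0) (if (e[i, j] > 0) 0 else g[i, j])
        else max(0, g[i, j] - e[i, j] / d_line[i, j])
      } else g[i, j]
    expect_equal(out[i, j], expected)
  }
  expect_true(all(out >= 0 & out <= 1))
  # on-line pixels with positive source energy take the continuity value 0
  expect_true(all(out[d_line == 0 & !r0] == 0))
  # decay branch never raises the edge value; source branch never lowers it
  dec <- !r0 & d_line <= d_src
  expect_true(all(out[dec] <= g[dec]))
  expect_true(all(out[r0] >= g[r0]))

  # upper clamp engages for a strong source
  out_hot <- energy_tune_line(g, e * 1e6, r0, d_line, d_src, 1, 1)
  expect_true(all(out_hot[r0] == 1))
  # lower clamp engages in the decay branch
  expect_true(any(out_hot[dec & d_line > 0] == 0))
  expect_error(energy_tune_line(g, e, matrix(FALSE, 5, 5), d_line, d_src),
               "empty")
})

test_that("energy_tune_auto applies branches including the band edge", {
  r0 <- matrix(FALSE, 7, 7); r0[3:5, 1:2] <- TRUE
  g <- matrix(0.8, 7, 7)
  d_src <- distance_to_mask(r0)
  e <- source_energy(r0, g, sigma = 5)
  d_t <- 2
  out <- energy_tune_auto(g, e, r0, d_src, d_t = d_t,
                          tune_alpha = 1, tune_beta = 1)

  n <- sum(r0)
  for (i in 1:7) for (j in 1:7) {
    expected <-
      if (r0[i, j]) min(1, g[i, j] + (1 / n) * e[i, j])
      else if (d_src[i, j] > d_t)
        max(0, g[i, j] - e[i, j] / (d_src[i, j] - d_t))
      else if (d_src[i, j] > 0) g[i, j] / (1 + d_src[i, j] / d_t)
      else g[i, j]
    expect_equal(out[i, j], expected)
  }
  # band edge D_r = d_t belongs to the attenuation branch: g / 2
  at_edge <- which(abs(d_src - d_t) < 1e-12 & !r0)
  expect_gt(length(at_edge), 0)
  expect_equal(out[at_edge], rep(0.4, length(at_edge)))
  # far decay clamps to zero under a strong source
  far <- !r0 & d_src > d_t
  out_hot <- energy_tune_auto(g, e * 1e6, r0, d_src, d_t, 1, 1)
  expect_true(all(out_hot[far] == 0))
  # zero source energy leaves source pixels at g
  out_cold <- energy_tune_auto(g, e * 0, r0, d_src, d_t, 1, 1)
  expect_equal(out_cold[r0], g[r0])
  expect_true(all(out >= 0 & out <= 1))
})
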