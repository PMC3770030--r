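test_that("double_well and d_p match their closed forms", {
  expect_equal(double_well(0), 0)
  expect_equal(double_well(1), 0)
  expect_equal(double_well(0.5), 1 / (2 * pi^2))
  expect_equal(double_well(2), 0.5)
  # continuity at the branch point
  expect_equal(double_well(1 - 1e-9), double_well(1 + 1e-9), tolerance = 1e-7)

  expect_equal(d_p(1), 0)
  expect_equal(d_p(1e-12), 1, tolerance = 1e-6)
  expect_equal(d_p(0), 1)
  expect_equal(d_p(2), 0.5)
  expect_equal(d_p(1e6), 1, tolerance = 1e-5)
  # numerical derivative of p divided by s
  s <- c(0.2, 0.7, 1.3, 3)
  h <- 1e-6
  dp_num <- (double_well(s + h) - double_well(s - h)) / (2 * h) / s
  expect_equal(d_p(s), dp_num, tolerance = 1e-6)
  expect_error(double_well(-0.1), "non-negative")
})

test_that("smooth delta/Heaviside satisfy endpoint, derivative and unit-mass identities", {
  eps <- 1.5
  expect_equal(smooth_delta(0, eps), 2 / 3)
  expect_equal(smooth_delta(c(-eps, eps), eps), c(0, 0))
  expect_equal(smooth_heaviside(0, eps), 0.5)
  expect_equal(smooth_heaviside(c(-eps, eps, -5, 5), eps), c(0, 1, 0, 1))

  # H' = delta (numerically)
  x <- seq(-1.4, 1.4, by = 0.1)
  h <- 1e-6
  dH <- (smooth_heaviside(x + h, eps) - smooth_heaviside(x - h, eps)) / (2 * h)
  expect_equal(dH, smooth_delta(x, eps), tolerance = 1e-8)

  # unit mass over the support
  q <- stats::integrate(smooth_delta, -eps, eps, epsilon = eps,
                        rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-6)
  expect_error(smooth_delta(0, 0), "positive")
})

test_that("init_lsf is a binary step recoverable by thresholding", {
  r0 <- matrix(FALSE, 10, 10); r0[3:6, 4:8] <- TRUE
  phi <- init_lsf(r0, c = 2)
  expect_true(all(phi[r0] == -2))
  expect_true(all(phi[!r0] == 2))
  expect_identical(phi < 0, r0)
  expect_error(init_lsf(matrix(FALSE, 4, 4)), "empty")
  expect_error(mdrls_params(mu = 0.3, time_step = 1), "mu")
})

test_that("a signed-distance plane away from the zero set is stationary", {
  phi <- outer(rep(0, 40), 1:40, "+") + 10 # phi = col + 10, |grad| = 1
  et <- matrix(0.6, 40, 40)
  out <- evolve_step(phi, et, mdrls_params(), include_area_term = FALSE)
  expect_lt(max(abs(out - phi)), 1e-8)
})

test_that("dropping the area term equals area_alpha = 0 bitwise", {
  set.seed(31)
  phi <- matrix(rnorm(400, 0, 2), 20, 20)
  et <- matrix(runif(400), 20, 20)
  a <- evolve_step(phi, et, mdrls_params(area_alpha = 0), TRUE)
  b <- evolve_step(phi, et, mdrls_params(area_alpha = -1), FALSE)
  expect_identical(a, b)
})

test_that("evolve_step is translation-equivariant in the interior", {
  set.seed(13)
  base_phi <- matrix(rnorm(30 * 30, 0, 2), 30, 30)
  base_et <- matrix(runif(30 * 30), 30, 30)
  # embed with one-pixel shift
  phi1 <- base_phi[1:28, 1:28]; et1 <- base_et[1:28, 1:28]
  phi2 <- base_phi[2:29, 2:29]; et2 <- base_et[2:29, 2:29]
  o1 <- evolve_step(phi1, et1, mdrls_params(), TRUE)
  o2 <- evolve_step(phi2, et2, mdrls_params(), TRUE)
  # away from both boundaries the updates coincide
  expect_equal(o1[4:25, 4:25], o2[3:24, 3:24], tolerance = 1e-12)
})

test_that("a disk shrinks under the edge term alone (curvature flow)", {
  n <- 101
  phi <- outer(1:n, 1:n, function(i, j) sqrt((i - 51)^2 + (j - 51)^2) - 30)
  et <- matrix(1, n, n)
  p <- mdrls_params()
  radii <- numeric(0)
  for (it in 1:50) {
    phi <- evolve_step(phi, et, p, include_area_term = FALSE)
    if (it %% 10 == 0) {
      radii <- c(radii, stats::approx(phi[51, 51:101], 0:50, xout = 0)$y)
    }
  }
  expect_true(all(diff(radii) < 0))
  expect_lt(radii[length(radii)], 30)
  expect_true(all(is.finite(phi)))
})

test_that("expansion phase grows the inside-negative region", {
  r0 <- matrix(FALSE, 60, 60); r0[25:35, 25:35] <- TRUE
  phi <- init_lsf(r0, 2)
  et <- matrix(1, 60, 60)
  p <- mdrls_params(area_alpha = -1, inner_iters = 30L, outer_iters = 0L)
  out <- segment_two_phase(phi, et, p)
  expect_gt(sum(out < 0), sum(r0))
  # zero iterations return the input unchanged
  p0 <- mdrls_params(inner_iters = 0L, outer_iters = 0L)
  expect_identical(segment_two_phase(phi, et, p0), phi)
})
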