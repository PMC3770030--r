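test_that("phantom generation is deterministic and leaves caller RNG alone", {
  p1 <- generate_phantom(small_phantom_spec(rng_seed = 7))
  set.seed(123); before <- runif(3)
  p2 <- generate_phantom(small_phantom_spec(rng_seed = 7))
  expect_identical(p1$image, p2$image)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$seeds, p2$seeds)
  expect_identical(p1$line, p2$line)

  set.seed(123)
  expect_identical(runif(3), before) # generator did not disturb the stream

  p3 <- generate_phantom(small_phantom_spec(rng_seed = 8))
  expect_false(identical(p1$image, p3$image))
})

test_that("ground truth is the rasterized ellipse with the analytic area", {
  ph <- generate_phantom(small_phantom_spec())
  a <- ph$spec$organ_a
  expect_lt(abs(sum(ph$truth) - pi * prod(a$semi_axes)) /
              (pi * prod(a$semi_axes)), 0.02)

  # seeds strictly inside the truth mask
  expect_gte(nrow(ph$seeds), 3)
  expect_true(all(ph$truth[ph$seeds]))

  # standard line traces the interface: every vertex is within 2 px of the
  # truth boundary and inside the image
  d_truth <- distance_to_mask(ph$truth)
  vi <- cbind(pmax(1, pmin(128, round(ph$line[, 1]))),
              pmax(1, pmin(128, round(ph$line[, 2]))))
  expect_true(all(d_truth[vi] <= 2))
})

test_that("noise-free phantom is piecewise constant away from the interface band", {
  ph <- generate_phantom(small_phantom_spec(noise_sigma = 0))
  s <- ph$spec
  # sample deep inside each region
  expect_equal(ph$image[64, 40], s$intensity_a)
  expect_equal(ph$image[64, 100], s$intensity_b)
  expect_equal(ph$image[5, 5], s$background)
  d_line <- distance_to_line(ph$line, s$shape)
  far <- d_line > 40
  vals <- ph$image[far]
  expect_true(all(vals %in% c(s$intensity_a, s$intensity_b, s$background)))
})

test_that("the measured fraction of gradient-suppressed interface matches the spec", {
  for (f in c(0.3, 0.5)) {
    ph <- generate_phantom(phantom_spec(noise_sigma = 0,
                                        boundary_gap_fraction = f))
    arc <- pancseg:::interface_arc(ph$spec$shape, ph$spec$organ_a,
                                   ph$spec$organ_b)
    gm <- gradient_magnitude(ph$image, 1)
    pts <- cbind(pmax(1, pmin(256, round(arc$points[, 1]))),
                 pmax(1, pmin(256, round(arc$points[, 2]))))
    gmi <- gm[pts]
    ref <- stats::quantile(gmi, 0.75) # robust intact-crest level
    suppressed <- mean(gmi < 0.25 * ref)
    expect_lt(abs(suppressed - f), 0.05)
  }
})

test_that("degenerate organ configurations are rejected", {
  bad <- small_phantom_spec()
  bad$organ_b$center <- bad$organ_a$center
  expect_error(generate_phantom(bad), "overlap")
})

test_that("phantom artifacts round-trip through the file formats", {
  ph <- generate_phantom(small_phantom_spec())
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)

  img <- read_image(file.path(dir, "image.png"))
  expect_identical(dim(img), dim(ph$image))
  # 8-bit quantization: intensities survive to within half a level
  expect_lt(max(abs(img - pmin(pmax(ph$image, 0), 255))), 0.51)

  truth <- read_mask_png(file.path(dir, "truth.png"))
  expect_identical(truth, ph$truth)

  ann <- read_annotation(file.path(dir, "annotation.json"))
  expect_identical(ann$seeds, ph$seeds)
  expect_equal(ann$line, unname(as.matrix(ph$line)))
})
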