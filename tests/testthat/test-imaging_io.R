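test_that("pixel_to_patient maps the affine plane geometry", {
  meta <- plane_meta(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), 1.4, 1.4)
  expect_equal(pixel_to_patient(meta, c(10, 20)), c(28.0, 14.0, 0.0))
  expect_equal(pixel_to_patient(meta, c(0, 0)), meta$origin_mm)
  expect_error(pixel_to_patient(meta, c(NA, 1)), "finite")
})

test_that("pixel/patient round trip and affinity hold on random planes", {
  set.seed(101)
  for (i in 1:100) {
    rd <- rnorm(3); rd <- rd / sqrt(sum(rd^2))
    tmp <- rnorm(3); cd <- tmp - sum(tmp * rd) * rd; cd <- cd / sqrt(sum(cd^2))
    meta <- plane_meta(rnorm(3, 0, 50), rd, cd, runif(1, 0.5, 3), runif(1, 0.5, 3))
    p <- matrix(runif(20, -50, 200), 10, 2)
    expect_equal(patient_to_pixel(meta, pixel_to_patient(meta, p)), p,
                 tolerance = 1e-9)
    # affinity: f(a p + b q) - f(0) = a (f(p) - f(0)) + b (f(q) - f(0))
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    pq <- p[1:2, ]
    f0 <- pixel_to_patient(meta, c(0, 0))
    lhs <- pixel_to_patient(meta, a * pq[1, ] + b * pq[2, ]) - f0
    rhs <- a * (pixel_to_patient(meta, pq[1, ]) - f0) +
      b * (pixel_to_patient(meta, pq[2, ]) - f0)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("plane_meta validates orthonormal direction cosines", {
  expect_error(plane_meta(c(0, 0, 0), c(0, 2, 0), c(1, 0, 0), 1, 1), "unit")
  expect_error(plane_meta(c(0, 0, 0), c(0, 1, 0), c(0, 1, 0), 1, 1), "orthogonal")
})

test_that("bicubic resize preserves constants and scales centroids", {
  expect_equal(resize_bicubic(matrix(3.7, 10, 10), c(23, 17)),
               matrix(3.7, 23, 17), tolerance = 1e-9)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(resize_bicubic(img, c(64, 64)), img, tolerance = 1e-6)
  # centered bright square: centroid scales with the resize ratio
  sq <- matrix(0, 40, 40)
  sq[17:24, 21:28] <- 1
  centroid <- function(m) {
    w <- m / sum(m)
    c(sum(row(m) * w), sum(col(m) * w)) - 1  # 0-based
  }
  big <- resize_bicubic(sq, c(120, 120))
  big[big < 0.01] <- 0
  expect_equal(centroid(big), (centroid(sq) + 0.5) * 3 - 0.5, tolerance = 0.5)
})

test_that("minmax_normalize maps to [0,1] and flags constants", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- matrix(runif(100), 10)
  x01 <- minmax_normalize(x)
  expect_equal(range(x01), c(0, 1))
  expect_equal(minmax_normalize(x01), x01)
  expect_warning(z <- minmax_normalize(matrix(5, 3, 3)), "constant")
  expect_equal(z, matrix(0, 3, 3))
})

test_that("pad_cine zero-pads to 30 phases with a validity mask", {
  meta <- plane_meta(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), 1, 1)
  cine <- cine_series(array(runif(25 * 8 * 8), c(25, 8, 8)), meta, "s1")
  p <- pad_cine(cine)
  expect_equal(dim(p$frames), c(30, 8, 8))
  expect_equal(p$frames[26:30, , ], array(0, c(5, 8, 8)))
  expect_equal(sum(p$valid), 25)
  full <- cine_series(array(1, c(30, 8, 8)), meta, "s2")
  expect_equal(pad_cine(full)$frames, full$frames)
  expect_error(pad_cine(full, 29), "refusing")
})

test_that("stack_temporal_channels uses cyclic frame indexing", {
  meta <- plane_meta(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), 1, 1)
  frames <- array(0, c(30, 4, 4))
  for (t in 1:30) frames[t, , ] <- t - 1
  cine <- cine_series(frames, meta, "s1")
  s0 <- stack_temporal_channels(cine, 0)
  expect_equal(s0[1, 1, ], c(28, 29, 0, 1, 2))
  s15 <- stack_temporal_channels(cine, 15)
  expect_equal(s15[1, 1, ], c(13, 14, 15, 16, 17))
  one <- cine_series(array(7, c(1, 4, 4)), meta, "s2")
  expect_equal(stack_temporal_channels(one, 0), array(7, c(4, 4, 5)))
})

test_that("study write/read round trip preserves pixels and geometry", {
  dir <- withr::local_tempdir()
  meta <- plane_meta(c(1.25, -3.5, 10), c(0, 1, 0), c(1, 0, 0), 1.3, 1.3, 6)
  s1 <- cine_series(array(rnorm(5 * 16 * 16), c(5, 16, 16)), meta, "SER1")
  s2 <- cine_series(array(rnorm(2 * 16 * 16), c(2, 16, 16)), meta, "SER2")
  study <- cine_study(list(s1, s2), "t1")
  write_study(study, dir, view_labels = c(SER1 = "SAx"))
  back <- read_study(dir)
  expect_identical(back$study$series$SER1$frames, s1$frames)
  expect_identical(back$study$series$SER2$frames, s2$frames)
  expect_equal(back$study$series$SER1$meta$origin_mm, meta$origin_mm,
               tolerance = 1e-9)
  expect_equal(back$view_labels, c(SER1 = "SAx"))
})
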