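test_that("phase curve encoding is a peak-normalized Gaussian", {
  pc <- encode_phase_curve(12, 30)
  expect_equal(pc[13], 1.0)
  expect_equal(pc[17], exp(-0.5))  # 4 frames away, sigma 4
  for (k in 1:10) expect_equal(pc[13 - k], pc[13 + k])
  expect_true(all(pc >= 0 & pc <= 1))
  expect_error(encode_phase_curve(12, 30, sigma = 0), "positive")
  expect_error(encode_phase_curve(30, 30))
})

test_that("decode_es_phase averages curves and breaks ties early", {
  expect_equal(decode_es_phase(encode_phase_curve(7, 30)), 7L)
  # two equal-shape curves peaking at 10 and 12: the mean peaks at 11
  two <- list(encode_phase_curve(10, 30), encode_phase_curve(12, 30))
  avg <- (as.numeric(two[[1]]) + as.numeric(two[[2]])) / 2
  expect_equal(which.max(avg) - 1L, 11L)  # numeric oracle
  expect_equal(decode_es_phase(two), 11L)
  expect_warning(flat <- decode_es_phase(rep(0.3, 30)), "low-confidence")
  expect_equal(flat, 0L)
  # validity masking: padded frames carrying zeros must not win
  padded <- c(as.numeric(encode_phase_curve(20, 25)), rep(0, 5))
  expect_equal(decode_es_phase(padded, validity = c(rep(TRUE, 25), rep(FALSE, 5))),
               20L)
  expect_error(decode_es_phase(list(rep(0, 4)), validity = rep(FALSE, 4)),
               "invalid")
})

test_that("landmark heatmaps peak at the landmark with sigma 12", {
  hm <- encode_landmark_heatmap(rbind(P = c(100, 60)), c(128, 128))
  expect_equal(max(hm), 1.0)
  expect_equal(which(hm[, , 1] == 1, arr.ind = TRUE)[1, ], c(row = 101, col = 61))
  expect_equal(unname(hm[101, 73, 1]), exp(-0.5))  # 12 px away
  two <- encode_landmark_heatmap(rbind(A = c(30, 30), B = c(90, 100)),
                                 c(128, 128))
  expect_equal(dim(two)[3], 2)
  expect_equal(unname(which(two[, , 2] == max(two[, , 2]), arr.ind = TRUE)[1, ]),
               c(91, 101))
  expect_error(encode_landmark_heatmap(rbind(c(-1, 5)), c(64, 64)), "bounds")
})

test_that("heatmap decoding recovers sub-pixel landmark locations", {
  hm <- encode_landmark_heatmap(rbind(c(100, 60)), c(128, 128))
  dec <- decode_heatmap(hm[, , 1])
  expect_equal(dec$point, c(100, 60), tolerance = 0.1)
  expect_equal(dec$confidence, 1.0)
  # single nonzero pixel decodes exactly
  m <- matrix(0, 32, 32); m[8, 21] <- 0.4
  dec <- decode_heatmap(m)
  expect_equal(dec$point, c(7, 20))
  expect_equal(dec$confidence, 0.4)
  # non-integer location rendered on the grid
  hm <- encode_landmark_heatmap(rbind(c(50.5, 50.5)), c(128, 128))
  expect_equal(decode_heatmap(hm[, , 1])$point, c(50.5, 50.5), tolerance = 0.25)
  absent <- decode_heatmap(matrix(0, 16, 16))
  expect_true(all(is.na(absent$point)))
  expect_equal(absent$confidence, 0)
})

test_that("segmentation class maps follow the per-view labeling", {
  expect_equal(length(encode_segmentation_classes("2Ch LT")), 3)
  expect_equal(length(encode_segmentation_classes("4Ch")), 5)
  expect_equal(length(encode_segmentation_classes("2Ch RT")), 3)
  expect_setequal(names(encode_segmentation_classes("SAx")),
                  c("background", "LV cavity", "LV myocardium", "RV cavity",
                    "RV myocardium"))
  expect_error(encode_segmentation_classes("LVOT"), "not segmented")
  expect_error(encode_segmentation_classes("OTHER"), "not segmented")
})

test_that("landmark sets per view match the localization protocol", {
  expect_equal(landmark_set_for_view("3Ch"), c("MV1", "MV2", "AV1", "AV2"))
  expect_length(landmark_set_for_view("4Ch"), 5)
  expect_equal(landmark_set_for_view("RVOT"), c("PV1", "PV2"))
  expect_equal(landmark_set_for_view("SAx"), c("RV1", "RV2"))
  expect_error(landmark_set_for_view("2Ch LT"), "no landmarks")
})

test_that("codec round trips are exact for phase and sub-pixel for landmarks", {
  for (t in c(1, 5, 14, 29)) {
    expect_equal(decode_es_phase(encode_phase_curve(t, 30)), t)
  }
  set.seed(7)
  for (i in 1:20) {
    p <- runif(2, 10, 100)
    hm <- encode_landmark_heatmap(rbind(p), c(112, 112))
    expect_lt(sqrt(sum((decode_heatmap(hm[, , 1])$point - p)^2)), 0.25)
  }
})
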