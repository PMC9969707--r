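test_that("concentric disks trace endo and epi circles without a septum", {
  n <- 80
  rr <- matrix(0:(n - 1), n, n); cc <- t(rr)
  r <- sqrt((rr - 40)^2 + (cc - 40)^2)
  mask <- matrix(0L, n, n)
  mask[r <= 30] <- 2L  # LV myocardium
  mask[r <= 20] <- 1L  # LV cavity
  ctr <- extract_contours(mask, "2Ch LT")
  expect_null(ctr$septum)
  radii_endo <- sqrt(rowSums(sweep(ctr$lv_endo, 2, c(40, 40))^2))
  radii_epi <- sqrt(rowSums(sweep(ctr$epicardium, 2, c(40, 40))^2))
  expect_equal(mean(radii_endo), 20, tolerance = 1)
  expect_equal(mean(radii_epi), 30, tolerance = 1)
  expect_lt(diff(range(radii_endo)), 2)
})

test_that("papillary-like islands are merged into the cavity before tracing", {
  n <- 60
  rr <- matrix(0:(n - 1), n, n); cc <- t(rr)
  r <- sqrt((rr - 30)^2 + (cc - 30)^2)
  mask <- matrix(0L, n, n)
  mask[r <= 25] <- 2L
  mask[r <= 18] <- 1L
  mask[28:32, 28:32] <- 0L  # papillary island inside the cavity
  ctr <- extract_contours(mask, "2Ch LT")
  radii <- sqrt(rowSums(sweep(ctr$lv_endo, 2, c(30, 30))^2))
  expect_gt(min(radii), 15)  # no contour around the island
})

test_that("empty masks yield warnings, not errors", {
  expect_warning(expect_warning(
    ctr <- extract_contours(matrix(0L, 32, 32), "2Ch LT"), "no LV"),
    "empty mask")
  expect_null(ctr$lv_endo)
})

test_that("septum lies between the cavities and off the epicardium", {
  # synthetic 4Ch-like mask: two cavities sharing a wall
  n <- 100
  rr <- matrix(0:(n - 1), n, n); cc <- t(rr)
  lv <- sqrt((rr - 50)^2 + (cc - 35)^2)
  rv <- sqrt((rr - 50)^2 + (cc - 72)^2)
  mask <- matrix(0L, n, n)
  mask[lv <= 28] <- 2L
  mask[rv <= 18 & mask == 0L] <- 4L
  mask[rv <= 14 & mask != 2L] <- 3L
  mask[lv <= 20] <- 1L
  ctr <- extract_contours(mask, "4Ch")
  expect_gt(nrow(ctr$septum), 3)
  # septum points sit between the cavity centers (columns 35..72)
  expect_true(all(ctr$septum[, 2] > 35 & ctr$septum[, 2] < 72))
  # and are disjoint from the epicardial contour
  dmin <- vapply(seq_len(nrow(ctr$septum)), function(i)
    min(sqrt(rowSums(sweep(ctr$epicardium, 2, ctr$septum[i, ])^2))), 0)
  expect_gt(min(dmin), 0.7)  # disjoint point sets
})

test_that("lifting preserves labels and in-plane isometry", {
  meta <- plane_meta(c(5, -2, 30), c(0, 1, 0), c(1, 0, 0), 1.5, 1.5)
  ctr <- structure(list(lv_endo = rbind(c(10, 10), c(20, 10), c(20, 20)),
                        view = "2Ch LT"), class = "contour_set")
  lm <- rbind(MV1 = c(5, 5))
  lifted <- lift_to_3d(ctr, lm, meta)
  expect_equal(rownames(lifted$landmark_points), "MV1")
  expect_equal(unique(lifted$contour_points$lv_endo[, 3]), 30)  # constant z
  d2 <- sqrt(sum((ctr$lv_endo[2, ] - ctr$lv_endo[1, ])^2)) * 1.5
  d3 <- sqrt(sum((lifted$contour_points$lv_endo[2, ] -
                  lifted$contour_points$lv_endo[1, ])^2))
  expect_equal(d3, d2, tolerance = 1e-9)
})

test_that("phantom oracle guide points lie on the true surfaces", {
  ph <- fixture_phantom()
  g <- assemble_guide_points(oracle_predictions(ph), es_frame = ph$es_frame)
  vox <- ph$params$in_plane_spacing_mm
  ts <- ph$true_surfaces[["0"]]
  for (cl in c("lv_endo", "rv_endo", "epicardium")) {
    d <- point_to_surface(g$ed$contour_points[[cl]], ts[[cl]])$dist
    expect_lt(median(d), vox)
  }
  d <- point_to_surface(g$ed$contour_points$septum, ts$rv_endo)$dist
  expect_lt(median(d), vox)
  # bookkeeping: provenance covers every contour class
  expect_setequal(unique(g$ed$provenance$item[g$ed$provenance$item %in%
    c("lv_endo", "rv_endo", "septum", "epicardium")]),
    c("lv_endo", "rv_endo", "septum", "epicardium"))
  # all four valve pairs present (3Ch, 4Ch, RVOT and SAx views exist)
  expect_true(all(c("MV1", "MV2", "TV1", "TV2", "AV1", "AV2", "PV1", "PV2") %in%
                  rownames(g$ed$landmark_points)))
  # ES guides use the phantom ES frame geometry: LV endo guides match the ES
  # surface better than the ED surface
  d_es <- point_to_surface(g$es$contour_points$lv_endo,
                           ph$true_surfaces[[as.character(ph$es_frame)]]$lv_endo)$dist
  d_ed <- point_to_surface(g$es$contour_points$lv_endo, ts$lv_endo)$dist
  expect_lt(median(d_es), median(d_ed))
})

test_that("assembly requires at least one optimal SAx slice", {
  ph <- fixture_phantom()
  preds <- oracle_predictions(ph)
  for (sid in names(preds))
    if (identical(preds[[sid]]$view, "SAx")) preds[[sid]]$optimal <- FALSE
  expect_error(assemble_guide_points(preds, es_frame = ph$es_frame),
               "optimal SAx")
})
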