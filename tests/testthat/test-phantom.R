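test_that("phantom parameters are validated", {
  expect_error(phantom_params(lv_wall_mm = 30), "infeasible")
  expect_error(phantom_params(lv_wall_mm = 0), "positive")
  expect_error(phantom_params(ef_target_fraction = 1.2), "ef_target")
  expect_error(phantom_params(es_frame = 0), "es_frame")
  expect_error(phantom_params(sax_spacing_mm = -1), "spacings")
})

test_that("LV cavity volume curve bottoms at the requested ES frame", {
  ph <- fixture_phantom()
  v <- ph$analytic_volumes[, "lv_cavity"]
  expect_equal(unname(which.min(v)) - 1L, ph$es_frame)
  expect_equal(unname(which.max(v) - 1L), 0L)  # ED at frame 0
  ef <- (v[1] - min(v)) / v[1]
  expect_equal(unname(ef), 0.55, tolerance = 0.02)
})

test_that("phantom rendering is deterministic under the seed", {
  p <- phantom_params(seed = 33, img_px = 64L, n_frames = 6L, es_frame = 3L)
  a <- make_phantom(p, series = "4Ch")
  b <- make_phantom(p, series = "4Ch")
  expect_identical(a$study$series$LAX_4CH$frames, b$study$series$LAX_4CH$frames)
  p0 <- phantom_params(seed = 33, img_px = 64L, n_frames = 6L, es_frame = 3L,
                       noise_sd = 0)
  a0 <- make_phantom(p0, series = "4Ch")
  b0 <- make_phantom(p0, series = "4Ch")
  expect_identical(a0$study$series$LAX_4CH$frames, b0$study$series$LAX_4CH$frames)
})

test_that("every series is view-labeled; all eight categories appear", {
  ph <- make_phantom(phantom_params(seed = 2, img_px = 64L, n_frames = 4L,
                                    es_frame = 2L), render_frames = 0L)
  expect_setequal(names(ph$view_labels), names(ph$study$series))
  expect_setequal(unique(unname(ph$view_labels)), VIEW_LABELS)
  # masks share the image shape
  for (sid in names(ph$masks))
    expect_equal(dim(ph$masks[[sid]]), dim(ph$study$series[[sid]]$frames))
})

test_that("SAx optimality flags mark exactly the apex-to-base cavity range", {
  ph <- fixture_phantom()
  g <- ph$geom
  for (sid in names(ph$optimal_flags)) {
    z <- ph$planes[[sid]]$origin_mm[3]
    expect_equal(unname(ph$optimal_flags[sid]), z > -g$c && z < g$z_base)
  }
  expect_gt(sum(ph$optimal_flags), 0)
  expect_gt(sum(!ph$optimal_flags), 0)  # stack extends beyond apex and base
})

test_that("landmark pixels lift to the 3D valve-ring truth within a voxel", {
  ph <- fixture_phantom()
  vox <- ph$params$in_plane_spacing_mm
  for (sid in names(ph$landmarks_px)) {
    for (fr in names(ph$landmarks_px[[sid]])) {
      lifted <- pixel_to_patient(ph$planes[[sid]], ph$landmarks_px[[sid]][[fr]])
      d <- sqrt(rowSums((rbind(lifted) - ph$landmarks_3d[[sid]][[fr]])^2))
      expect_lt(max(d), vox)
    }
  }
})

test_that("analytic LV cavity volume matches the voxelized mask volume", {
  p <- phantom_params(seed = 4, sax_spacing_mm = 1.5, in_plane_spacing_mm = 1.0,
                      img_px = 96L, noise_sd = 0, n_frames = 4L, es_frame = 2L)
  ph <- make_phantom(p, render_frames = 0L, series = "SAx")
  vox <- 0
  for (sid in names(ph$masks)) {
    m <- ph$masks[[sid]][1, , ]
    vox <- vox + sum(m == 1) * 1.0 * 1.0 * 1.5
  }
  expect_equal(vox / 1000, unname(ph$analytic_volumes[1, "lv_cavity"]),
               tolerance = 0.03)
})

test_that("true surfaces are closed, outward-oriented and match analytic volumes", {
  ph <- fixture_phantom()
  ts <- ph$true_surfaces[["0"]]
  vols <- ph$analytic_volumes[1, ]
  expect_length(bivshape:::mesh_boundary_check(ts$lv_endo), 0)
  expect_length(bivshape:::mesh_boundary_check(ts$rv_endo), 0)
  expect_length(bivshape:::mesh_boundary_check(ts$epicardium), 0)
  expect_equal(mesh_signed_volume(ts$lv_endo) / 1000,
               unname(vols["lv_cavity"]), tolerance = 0.01)
  expect_equal(mesh_signed_volume(ts$rv_endo) / 1000,
               unname(vols["rv_cavity"]), tolerance = 0.01)
})

test_that("sample_population draws reproducible parameter tables", {
  rg <- list(lv_wall_mm = c(7, 10), ef_target_fraction = c(0.4, 0.6))
  a <- sample_population(5, rg, seed = 77, render = FALSE)
  b <- sample_population(5, rg, seed = 77, render = FALSE)
  expect_identical(a$params, b$params)
  expect_true(all(a$params$lv_wall_mm >= 7 & a$params$lv_wall_mm <= 10))
  # degenerate ranges pin parameters
  dg <- sample_population(5, list(lv_wall_mm = c(9, 9)), seed = 1,
                          render = FALSE)
  expect_equal(dg$params$lv_wall_mm, rep(9, 5))
  expect_error(sample_population(2, list(lv_wall_mm = c(10, 7))), "invalid")
  expect_error(sample_population(2, list(bogus = c(1, 2)), render = FALSE),
               "unknown parameter")
})
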