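test_that("template regions are closed, oriented and consistently labeled", {
  tpl <- fixture_template()
  for (r in c("lv_endo", "rv_endo", "epicardium")) {
    m <- tri_mesh(tpl$vertices, tpl$faces[tpl$face_region == r, ])
    expect_length(bivshape:::mesh_boundary_check(m), 0)
    expect_gt(mesh_signed_volume(m), 0)  # outward orientation
  }
  expect_equal(sort(unique(tpl$face_region)),
               c("epicardium", "lv_endo", "rv_endo"))
  expect_setequal(names(tpl$valve_rings), c("MV", "TV", "AV", "PV"))
  # septal anchors point into the septal sheet
  anch <- tpl$septal_anchor[tpl$septal_anchor > 0]
  expect_true(all(tpl$vertex_septal[anch]))
})

test_that("landmark registration recovers similarity transforms exactly", {
  tpl <- fixture_template()
  ref <- bivshape:::template_landmark_positions(tpl)
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tgt <- sweep(ref %*% t(R), 2, c(5, -3, 2), `+`)
  res <- landmark_register(tpl, tgt)
  expect_lt(res$rms, 1e-8)
  expect_equal(res$transform$R, R, tolerance = 1e-9)
  expect_equal(res$transform$t, c(5, -3, 2), tolerance = 1e-8)
  scl <- landmark_register(tpl, ref * 1.2)
  expect_equal(scl$transform$s, 1.2, tolerance = 1e-9)
  expect_error(landmark_register(tpl, ref[1:2, ]), "at least 3")
  line <- rbind(LV_APEX = c(0, 0, 0), MV_CENTER = c(0, 0, 10),
                TV_CENTER = c(0, 0, 20))
  expect_error(landmark_register(tpl, line), "collinear")
})

test_that("noisy landmark registration stays within 2 mm RMS", {
  tpl <- fixture_template()
  ref <- bivshape:::template_landmark_positions(tpl)
  set.seed(123)
  rms <- vapply(1:100, function(i) {
    tf <- bivshape:::compose_random_rigid()
    tgt <- apply_transform(ref, tf) + matrix(rnorm(length(ref), 0, 1),
                                             nrow(ref))
    landmark_register(tpl, tgt)$rms
  }, 0)
  # 5 reference points, 7 similarity dof: expected residual RMS is about
  # sd * sqrt(8/15) ~ 0.73 mm; the Monte-Carlo mean stays well under 2 mm
  expect_lte(mean(rms), 2)
  expect_lte(max(rms), 4)
})

test_that("guides sampled on the template are a fixed point of the fit", {
  tpl <- fixture_template()
  set.seed(21)
  guides <- list(contour_points = list(), phase = "ED")
  for (cl in c("lv_endo", "rv_endo", "septum", "epicardium")) {
    fsub <- bivshape:::template_match_faces(tpl, cl)
    pick <- sample(fsub, min(400, length(fsub)))
    tri <- tpl$faces[pick, , drop = FALSE]
    w <- matrix(runif(3 * nrow(tri)), ncol = 3)
    w <- w / rowSums(w)
    guides$contour_points[[cl]] <-
      tpl$vertices[tri[, 1], ] * w[, 1] + tpl$vertices[tri[, 2], ] * w[, 2] +
      tpl$vertices[tri[, 3], ] * w[, 3]
  }
  lm <- bivshape:::template_landmark_positions(tpl)
  guides$landmark_points <- lm
  class(guides) <- "guide_point_set"
  fit <- nonrigid_fit(tpl, guides, fit_config(n_iterations = 5))
  rms <- sqrt(mean(rowSums((fit$vertices - tpl$vertices)^2)))
  expect_lt(rms, 0.1)
})

test_that("fit residual is non-increasing in the smoothness weight", {
  ph <- fixture_phantom()
  tpl <- fixture_template()
  g <- assemble_guide_points(oracle_predictions(ph), es_frame = ph$es_frame)$ed
  weights <- c(0.1, 1, 10, 100, 1000)
  resid <- vapply(weights, function(w) {
    fit <- nonrigid_fit(tpl, g, fit_config(smoothness_weight = w,
                                           n_iterations = 6))
    mean(point_to_surface(g$contour_points$lv_endo,
                          bivshape:::template_region_mesh(fit, "lv_endo"))$dist)
  }, 0)
  expect_true(all(diff(resid) > -0.05))  # monotone up to solver noise
})

test_that("fitting is equivariant under rigid motion of the guides", {
  ph <- fixture_phantom()
  tpl <- fixture_template()
  g <- assemble_guide_points(oracle_predictions(ph), es_frame = ph$es_frame)$ed
  fit0 <- nonrigid_fit(tpl, g, fit_config(n_iterations = 8))
  set.seed(99)
  tf <- bivshape:::compose_random_rigid()
  g2 <- g
  for (cl in names(g2$contour_points))
    g2$contour_points[[cl]] <- apply_transform(g2$contour_points[[cl]], tf)
  lm <- apply_transform(g2$landmark_points, tf)
  rownames(lm) <- rownames(g2$landmark_points)
  g2$landmark_points <- lm
  fit1 <- nonrigid_fit(tpl, g2, fit_config(n_iterations = 8))
  moved <- apply_transform(fit0$vertices, tf)
  rms <- sqrt(mean(rowSums((fit1$vertices - moved)^2)))
  expect_lt(rms, 0.05)
})

test_that("fitted models keep closed outward-oriented region surfaces", {
  fit <- fixture_oracle_fit()
  for (m in list(fit$ed, fit$es)) {
    for (r in c("lv_endo", "rv_endo", "epicardium")) {
      expect_gt(region_volume(m, r), 0)
    }
  }
})

test_that("fit requires guides for at least two contour classes", {
  tpl <- fixture_template()
  g <- structure(list(contour_points = list(lv_endo = tpl$vertices[1:50, ]),
                      landmark_points = bivshape:::template_landmark_positions(tpl),
                      phase = "ED"), class = "guide_point_set")
  expect_error(nonrigid_fit(tpl, g), "at least 2")
})
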