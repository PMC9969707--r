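test_that("dice matches hand counts and handles empty masks", {
  a <- matrix(FALSE, 4, 4); a[2:3, 2:3] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[2:3, 3:4] <- TRUE  # shifted one column
  expect_equal(dice(a, b), 0.5)  # |a|=|b|=4, overlap 2
  expect_equal(dice(a, !a), 0)
  expect_warning(d0 <- dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
  expect_equal(d0, 1)
  expect_error(dice(a, matrix(FALSE, 3, 3)), "shapes")
})

test_that("dice equals the brute-force definition on random masks", {
  set.seed(5)
  for (i in 1:200) {
    a <- matrix(runif(64) < 0.4, 8, 8)
    b <- matrix(runif(64) < 0.4, 8, 8)
    if (sum(a) + sum(b) == 0) next
    brute <- 2 * sum(a & b) / (sum(a) + sum(b))
    expect_identical(dice(a, b), brute)
  }
})

test_that("hausdorff matches examples and a brute-force scan", {
  a <- rbind(c(0, 0))
  expect_equal(hausdorff(a, a), 0)
  expect_equal(hausdorff(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  set.seed(6)
  for (i in 1:200) {
    x <- matrix(rnorm(40), 20, 2)
    y <- matrix(rnorm(40), 20, 2)
    d <- as.matrix(dist(rbind(x, y)))[1:20, 21:40]
    brute <- max(max(apply(d, 1, min)), max(apply(d, 2, min)))
    expect_equal(hausdorff(x, y), brute, tolerance = 1e-12)
  }
  expect_error(hausdorff(matrix(numeric(0), 0, 2), a), "empty")
})

test_that("aafd is the mean absolute frame difference", {
  expect_equal(aafd(c(5, 9), c(5, 9)), 0)
  expect_equal(aafd(c(10, 12), c(11, 14)), 1.5)
  expect_equal(aafd(1:10 + 3, 1:10), 3)
  expect_error(aafd(1:3, 1:4), "mismatch")
})

test_that("rigid alignment recovers transforms and rejects reflections", {
  tpl <- fixture_template()
  m <- template_model(tpl)
  set.seed(9)
  tf <- bivshape:::compose_random_rigid()
  moved <- m
  moved$vertices <- apply_transform(m$vertices, tf)
  res <- rigid_align_models(moved, m)
  expect_lt(sqrt(mean(rowSums((res$aligned$vertices - m$vertices)^2))), 1e-8)
  ident <- rigid_align_models(m, m)
  expect_equal(ident$transform$R, diag(3), tolerance = 1e-9)
  expect_equal(ident$transform$t, c(0, 0, 0), tolerance = 1e-9)
  # mirrored input: determinant stays +1, residual reported instead
  mir <- m
  mir$vertices[, 1] <- -mir$vertices[, 1]
  res <- rigid_align_models(mir, m)
  expect_equal(det(res$transform$R), 1, tolerance = 1e-9)
  expect_gt(res$transform$rms, 1)
})

test_that("projection distances vanish for identical models and track offsets", {
  fit <- fixture_oracle_fit()
  ed <- fit$ed
  attr(ed, "aligned") <- TRUE
  rep0 <- projection_distances(ed, ed)
  expect_equal(rep0$mae, rep(0, nrow(rep0)), tolerance = 1e-9)
  expect_true("Global" %in% rep0$region)
  expect_setequal(rep0$region,
                  c("Global", "LV Endocardium", "RV Endocardium", "Septum",
                    "Epicardium", "MV", "AV", "TV", "PV"))
  # inflate the epicardium along vertex normals by 1 mm
  tpl <- ed$template
  infl <- ed
  vn <- bivshape:::vertex_normals_region(tpl, ed$vertices, "epicardium")
  vids <- which(tpl$vertex_region == "epicardium")
  infl$vertices[vids, ] <- infl$vertices[vids, ] + vn[vids, ]
  repi <- projection_distances(infl, ed)
  row <- repi[repi$region == "Epicardium", ]
  expect_equal(row$signed_mean, 1, tolerance = 0.1)
  # global MAE is the all-point mean, not the mean of regional MAEs
  n_reg <- repi[repi$region != "Global", ]
  manual_global <- sum(n_reg$mae * n_reg$n) / sum(n_reg$n)
  expect_equal(repi$mae[repi$region == "Global"], manual_global,
               tolerance = 1e-9)
})

test_that("plane angulation error is the undirected in-plane line angle", {
  n <- c(0, 0, 1)
  p <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(plane_angulation_error(p, p, n), 0)
  q <- rbind(c(0, 0, 0), c(1, 1, 0))
  expect_equal(plane_angulation_error(p, q, n), 45)
  expect_equal(plane_angulation_error(p, q[2:1, ], n), 45)  # undirected
  expect_error(plane_angulation_error(p, rbind(c(1, 1, 1), c(1, 1, 1)), n),
               "coincident")
})

test_that("bland_altman reports bias, limits and agreement", {
  x <- c(1, 2, 3, 4, 5)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$limits_of_agreement, c(0, 0))
  expect_equal(ba$r_squared, 1)
  expect_equal(bland_altman(x, x + 2)$bias, 2)
  set.seed(12)
  x <- rnorm(1000, 50, 10)
  y <- x + rnorm(1000, 0, 1)
  ba <- bland_altman(x, y)
  expect_equal(ba$limits_of_agreement[1], ba$bias - 1.96, tolerance = 0.15)
  expect_equal(ba$limits_of_agreement[2], ba$bias + 1.96, tolerance = 0.15)
  expect_error(bland_altman(1:4, 1:5), "mismatch")
})

test_that("Holm-Bonferroni stepwise decisions follow the hand computation", {
  # p = (0.001, 0.02, 0.04) at alpha 0.05:
  # 0.001 < 0.05/3 -> reject; 0.02 < 0.05/2 -> reject; 0.04 < 0.05 -> reject
  p <- c(0.001, 0.02, 0.04)
  expect_true(all(p.adjust(p, "holm") < 0.05))
  # and a case where the cascade stops
  p2 <- c(0.001, 0.03, 0.04)
  expect_equal(p.adjust(p2, "holm") < 0.05, c(TRUE, FALSE, FALSE))
})

test_that("zscore differences are zero for identical model sets", {
  fit <- fixture_oracle_fit()
  tpl <- fixture_template()
  set.seed(31)
  pairs <- lapply(1:4, function(i) {
    ed <- fit$ed; es <- fit$es
    ed$vertices <- ed$vertices + rnorm(1, 0, 2)
    es$vertices <- es$vertices * (1 + 0.02 * i)
    list(ed = ed, es = es)
  })
  atlas <- build_atlas(pairs)
  zd <- zscore_difference(atlas, pairs, pairs, n_modes = 3)
  expect_equal(zd$mean_abs_dz, rep(0, nrow(zd)), tolerance = 1e-6)
  # perturbing one model moves at least one mode
  pert <- pairs
  pert[[2]]$ed$vertices <- pert[[2]]$ed$vertices +
    matrix(rnorm(length(pert[[2]]$ed$vertices), 0, 0.5),
           ncol = 3)
  zd2 <- zscore_difference(atlas, pairs, pert, n_modes = 3)
  expect_gt(max(zd2$mean_abs_dz), 0)
  expect_error(zscore_difference(atlas, pairs, pairs[1:2]), "unpaired")
})
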