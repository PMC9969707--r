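test_that("divergence-theorem volumes match analytic solids", {
  ico <- icosphere(10, 3)
  expect_equal(mesh_signed_volume(ico) / 1000, 4 / 3 * pi * 10^3 / 1000,
               tolerance = 0.02)
  # ellipsoid with semi-axes (30, 20, 20) mm
  ell <- icosphere(1, 4)
  ell$vertices <- sweep(ell$vertices, 2, c(30, 20, 20), `*`)
  expect_equal(mesh_signed_volume(ell) / 1000, 4 / 3 * pi * 30 * 20 * 20 / 1000,
               tolerance = 0.01)
  # orientation flip negates the signed volume
  flipped <- ico
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_equal(mesh_signed_volume(flipped), -mesh_signed_volume(ico))
})

test_that("Loop subdivision quadruples faces and smooths toward a sphere", {
  ico <- icosahedron(1)
  expect_equal(nrow(subdivide(ico, 0)$faces), 20)
  expect_identical(subdivide(ico, 0), ico)
  m1 <- subdivide(ico, 1)
  expect_equal(nrow(m1$faces), 80)
  expect_equal(nrow(subdivide(ico, 2)$faces), 320)
  expect_length(bivshape:::mesh_boundary_check(m1), 0)
  # sphericity: max deviation of face centroids from the mean vertex radius,
  # relative to that radius, decreases with each level
  dev <- function(m) {
    r0 <- mean(sqrt(rowSums(m$vertices^2)))
    ctr <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
            m$vertices[m$faces[, 3], ]) / 3
    max(abs(sqrt(rowSums(ctr^2)) - r0)) / r0
  }
  devs <- vapply(0:3, function(l) dev(subdivide(ico, l)), 0)
  expect_true(all(diff(devs) < 0))
})

test_that("subdivision propagates face labels and rejects open meshes", {
  ico <- icosahedron(1)
  labs <- rep(c("a", "b"), each = 10)
  m <- subdivide(ico, 1, face_labels = labs)
  expect_equal(attr(m, "face_labels"), rep(labs, each = 4))
  open <- tri_mesh(ico$vertices, ico$faces[-1, ])
  expect_error(subdivide(open, 1), "manifold")
})

test_that("point_to_surface equals a brute-force scan over all triangles", {
  set.seed(42)
  m <- icosphere(5, 1)  # 80 faces
  pts <- matrix(rnorm(3 * 60, 0, 6), 60, 3)
  res <- point_to_surface(pts, m)
  for (i in seq_len(nrow(pts))) {
    dmin <- min(vapply(seq_len(nrow(m$faces)), function(f)
      brute_point_tri(pts[i, ], m$vertices[m$faces[f, 1], ],
                      m$vertices[m$faces[f, 2], ], m$vertices[m$faces[f, 3], ]),
      0))
    expect_equal(res$dist[i], dmin, tolerance = 1e-9)
  }
})

test_that("OBJ write/read round trips a mesh", {
  dir <- withr::local_tempdir()
  m <- icosphere(3, 1)
  path <- file.path(dir, "m.obj")
  write_obj(m, path)
  back <- read_obj(path)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-6)
  expect_identical(back$faces, m$faces)
})
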