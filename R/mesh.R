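# Triangle-mesh utilities: construction from stacked boundary loops, signed
# (divergence-theorem) volumes, orientation fixing, Loop subdivision, exact
# point-to-surface distances, OBJ text I/O.

#' Create a triangle mesh
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, max(faces) <= nrow(vertices), min(faces) >= 1)
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("tri_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

# Stitch a stack of equal-length boundary loops (list of M x 3 matrices,
# apex-to-base order) into a closed surface.  The bottom is closed either by
# a pole vertex (`bottom` = point) or a strip cap over a crescent loop
# (`bottom_cap = "strip"`); the top by a centroid fan (`top_cap = "fan"`) or
# strip cap.  For strip caps the loop must be outer arc (1..m1) followed by
# the reversed inner arc.
mesh_stack_loops <- function(loops, bottom = NULL, bottom_cap = NULL,
                             top_cap = "fan", strip_m1 = NULL) {
  M <- nrow(loops[[1]])
  L <- length(loops)
  has_pole <- !is.null(bottom)
  verts <- do.call(rbind, loops)
  offset <- 0L
  if (has_pole) {
    verts <- rbind(bottom, verts)
    offset <- 1L
  }
  vid <- function(l, j) offset + (l - 1L) * M + ((j - 1L) %% M) + 1L
  faces <- vector("list", 4L)
  # side walls
  l <- rep(seq_len(L - 1L), each = M)
  j <- rep(seq_len(M), L - 1L)
  A <- vid(l, j); B <- vid(l, j + 1L); C <- vid(l + 1L, j + 1L); D <- vid(l + 1L, j)
  faces[[1]] <- rbind(cbind(A, B, C), cbind(A, C, D))
  if (has_pole) {
    j <- seq_len(M)
    faces[[2]] <- cbind(1L, vid(1L, j + 1L), vid(1L, j))
  } else if (identical(bottom_cap, "strip")) {
    m1 <- strip_m1
    k <- seq_len(m1 - 1L)
    O <- function(k) vid(1L, k)
    I <- function(k) vid(1L, 2L * m1 + 1L - k)
    faces[[2]] <- rbind(cbind(O(k + 1L), O(k), I(k)),
                        cbind(O(k + 1L), I(k), I(k + 1L)))
  }
  if (identical(top_cap, "fan")) {
    ctr <- colMeans(loops[[L]])
    verts <- rbind(verts, ctr)
    cid <- nrow(verts)
    j <- seq_len(M)
    faces[[3]] <- cbind(cid, vid(L, j), vid(L, j + 1L))
  } else if (identical(top_cap, "strip")) {
    m1 <- strip_m1
    k <- seq_len(m1 - 1L)
    O <- function(k) vid(L, k)
    I <- function(k) vid(L, 2L * m1 + 1L - k)
    faces[[3]] <- rbind(cbind(O(k), O(k + 1L), I(k + 1L)),
                        cbind(O(k), I(k + 1L), I(k)))
  }
  F <- do.call(rbind, faces[!vapply(faces, is.null, TRUE)])
  m <- tri_mesh(verts, F)
  attr(m, "loop_vid") <- function(l, j) vid(l, j)
  attr(m, "M") <- M
  attr(m, "L") <- L
  attr(m, "offset") <- offset
  m
}

#' Signed enclosed volume of a closed triangle mesh
#'
#' Divergence-theorem sum `V = 1/6 * sum v1 . (v2 x v3)` over faces; positive
#' for outward-oriented surfaces.
#'
#' @param mesh a [tri_mesh()].
#' @return Volume in the cube of the vertex units (mm^3 for mm vertices).
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# flip all faces if the signed volume is negative
orient_outward <- function(mesh) {
  if (mesh_signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

# check closedness/orientation: every edge used exactly twice, in opposite
# directions.  Returns character(0) if OK, else messages naming bad edges.
mesh_boundary_check <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  dirkey <- paste(he[, 1], he[, 2])
  cnt <- table(key)
  msgs <- character(0)
  if (any(cnt != 2))
    msgs <- c(msgs, paste("edges not shared by exactly 2 faces:",
                          paste(utils::head(names(cnt)[cnt != 2], 5), collapse = "; ")))
  if (anyDuplicated(dirkey))
    msgs <- c(msgs, "inconsistent winding: repeated directed edge")
  msgs
}

face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

#' Exact distances from points to a triangle mesh surface
#'
#' Brute-force exact point-to-triangle distances (with bounding-sphere
#' pruning) over all faces.
#'
#' @param points n x 3 matrix.
#' @param mesh a [tri_mesh()].
#' @return List with `dist` (n), `closest` (n x 3) and `face` (n, 1-based
#'   face index).
#' @export
point_to_surface <- function(points, mesh) {
  cpp_point_tri_dist(rbind(points), mesh$vertices, mesh$faces)
}

#' Loop subdivision of a closed triangle mesh
#'
#' Applies `levels` rounds of Loop subdivision (each level splits every face
#' into four).  Face labels passed in `face_labels` are propagated to child
#' faces; watertightness and orientation are preserved.  Errors on meshes
#' with boundary or non-manifold edges.
#'
#' @param mesh a [tri_mesh()].
#' @param levels number of subdivision rounds (>= 0).
#' @param face_labels optional vector of per-face labels to propagate.
#' @return A [tri_mesh()]; if `face_labels` was given, the refined labels are
#'   attached as attribute `"face_labels"`.
#' @export
subdivide <- function(mesh, levels = 1L, face_labels = NULL) {
  stopifnot(levels >= 0)
  labs <- face_labels
  for (i in seq_len(levels)) {
    res <- loop_subdivide_once(mesh)
    mesh <- res
    if (!is.null(labs)) labs <- rep(labs, each = 4L)
  }
  if (!is.null(face_labels)) attr(mesh, "face_labels") <- labs
  mesh
}

loop_subdivide_once <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  nf <- nrow(f)
  # undirected edges with their two opposite vertices
  he <- rbind(f[, c(1, 2, 3)], f[, c(2, 3, 1)], f[, c(3, 1, 2)])  # (a, b, opp)
  a <- pmin(he[, 1], he[, 2])
  b <- pmax(he[, 1], he[, 2])
  key <- a * (nv + 1) + b
  ord <- order(key)
  ks <- key[ord]
  runs <- rle(ks)
  if (any(runs$lengths != 2))
    stop("mesh is not a closed 2-manifold (boundary or non-manifold edge)")
  first <- cumsum(runs$lengths) - runs$lengths + 1
  e_a <- a[ord][first]
  e_b <- b[ord][first]
  opp1 <- he[ord, 3][first]
  opp2 <- he[ord, 3][first + 1]
  # odd (edge) vertices
  ev <- 0.375 * (v[e_a, , drop = FALSE] + v[e_b, , drop = FALSE]) +
    0.125 * (v[opp1, , drop = FALSE] + v[opp2, , drop = FALSE])
  # edge index lookup for each half-edge
  edge_id <- integer(length(key))
  edge_id[ord] <- rep(seq_along(runs$lengths), runs$lengths)
  e1 <- edge_id[seq_len(nf)]                 # edge (f1, f2)
  e2 <- edge_id[nf + seq_len(nf)]            # edge (f2, f3)
  e3 <- edge_id[2 * nf + seq_len(nf)]        # edge (f3, f1)
  # even (original) vertices: Loop weights by valence
  deg <- tabulate(c(e_a, e_b), nv)
  beta <- (1 / deg) * (5 / 8 - (3 / 8 + 0.25 * cos(2 * pi / deg))^2)
  nbr_sum <- matrix(0, nv, 3)
  for (d in 1:3) {
    nbr_sum[, d] <- nbr_sum[, d] +
      as.numeric(tapply(v[e_b, d], factor(e_a, levels = seq_len(nv)), sum, default = 0)) +
      as.numeric(tapply(v[e_a, d], factor(e_b, levels = seq_len(nv)), sum, default = 0))
  }
  nbr_sum[is.na(nbr_sum)] <- 0
  newv <- v * (1 - deg * beta) + nbr_sum * beta
  allv <- rbind(newv, ev)
  eoff <- nv
  newf <- rbind(cbind(f[, 1], eoff + e1, eoff + e3),
                cbind(f[, 2], eoff + e2, eoff + e1),
                cbind(f[, 3], eoff + e3, eoff + e2),
                cbind(eoff + e1, eoff + e2, eoff + e3))
  # interleave so the four children of face i are rows 4i-3 .. 4i
  ord2 <- as.vector(t(cbind(seq_len(nf), nf + seq_len(nf),
                            2 * nf + seq_len(nf), 3 * nf + seq_len(nf))))
  tri_mesh(allv, newf[ord2, , drop = FALSE])
}

#' Icosahedron mesh
#' @param r circumscribed radius.
#' @return A [tri_mesh()] with 12 vertices and 20 faces, outward oriented.
#' @export
icosahedron <- function(r = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2) * r
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  orient_outward(tri_mesh(v, f))
}

#' Icosphere: subdivided icosahedron reprojected onto the sphere
#' @param r sphere radius.
#' @param level subdivision level.
#' @return A [tri_mesh()].
#' @export
icosphere <- function(r = 1, level = 3L) {
  m <- subdivide(icosahedron(1), level)
  m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2)) * r
  m
}

#' Write a mesh as Wavefront OBJ text
#' @param mesh a [tri_mesh()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ triangle mesh
#' @param path OBJ file.
#' @return A [tri_mesh()].
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                             function(x) as.integer(sub("/.*", "", x[1:3]))))
  tri_mesh(v, f)
}
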