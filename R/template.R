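# Biventricular template mesh: a fixed-topology surface model with three
# closed regions (LV endocardium, RV endocardium, epicardium; basal openings
# closed by valve-plane caps), four valve rings (MV = LV endocardial rim,
# TV = RV basal rim, AV and PV as free-standing ring loops), and named
# landmark vertices.  The template is generated from the phantom's mean
# geometry at end-diastole; all fitted models share its topology.
#
# The septal surface is carried by the RV-endocardium region's inner sheet
# (the sheet apposed to the LV epicardial wall); its faces are flagged
# `face_septal` and are the match target for septum guide points.
# Epicardial vertices covered by the RV bulge carry a `septal_anchor` (the
# index of the nearest septal-sheet vertex), which lets measurement code
# reconstruct the LV-epicardial closed surface from any fitted model.

#' Build the biventricular template mesh
#'
#' @param params [phantom_params()] defining the mean geometry.
#' @param ntheta angular resolution of the LV/epicardial surfaces.
#' @param nz number of stacked levels for the LV/epicardial surfaces.
#' @param rv_m1 points per crescent arc (RV loop has `2 * rv_m1` points).
#' @param rv_nz number of stacked levels for the RV surface.
#' @return An object of class `biv_template`.
#' @export
biv_template <- function(params = phantom_params(), ntheta = 48L, nz = 24L,
                         rv_m1 = 25L, rv_nz = 20L) {
  g <- ph_geom(params)
  lv <- ph_surface_lv_endo(g, 0, ntheta, nz)
  epi <- ph_surface_epi(g, 0, ntheta, nz)
  rv <- ph_surface_rv_endo(g, 0, rv_m1, rv_nz)

  nv_lv <- nrow(lv$vertices)
  nv_rv <- nrow(rv$vertices)
  nv_epi <- nrow(epi$vertices)
  off_rv <- nv_lv
  off_epi <- nv_lv + nv_rv

  # cap faces reference the fan-center vertex (last vertex of lv/epi)
  lv_cap <- apply(lv$faces, 1, function(f) any(f == nv_lv))
  epi_cap <- apply(epi$faces, 1, function(f) any(f == nv_epi))
  M_rv <- 2L * rv_m1
  rv_pos <- function(v) ((v - 1L) %% M_rv) + 1L  # position within loop
  rv_level <- function(v) ((v - 1L) %/% M_rv) + 1L
  rv_inner_v <- rv_pos(seq_len(nv_rv)) > rv_m1
  rv_septal <- apply(rv$faces, 1, function(f) all(rv_inner_v[f]))
  L_rv <- rv_nz
  rv_cap <- apply(rv$faces, 1, function(f)
    all(rv_level(f) == 1L) || all(rv_level(f) == L_rv))

  # MV ring: LV endocardial rim (last stacked loop); TV ring: RV basal loop
  M_lv <- attr(lv, "M"); L_lv <- attr(lv, "L")
  mv_ring <- 1L + (L_lv - 1L) * M_lv + seq_len(M_lv)  # pole offset 1
  tv_ring <- off_rv + (L_rv - 1L) * M_rv + seq_len(M_rv)

  vertices <- rbind(lv$vertices, rv$vertices, epi$vertices)
  faces <- rbind(lv$faces, rv$faces + off_rv, epi$faces + off_epi)
  face_region <- c(rep("lv_endo", nrow(lv$faces)), rep("rv_endo", nrow(rv$faces)),
                   rep("epicardium", nrow(epi$faces)))
  face_cap <- c(lv_cap, rv_cap, epi_cap)
  face_septal <- c(rep(FALSE, nrow(lv$faces)), rv_septal,
                   rep(FALSE, nrow(epi$faces)))

  # free-standing AV / PV ring loops
  rings3d <- ph_rings(g, 0, n = 24)
  av_ring <- nrow(vertices) + seq_len(nrow(rings3d$AV))
  vertices <- rbind(vertices, rings3d$AV)
  pv_ring <- nrow(vertices) + seq_len(nrow(rings3d$PV))
  vertices <- rbind(vertices, rings3d$PV)

  vertex_region <- rep("epicardium", nrow(vertices))
  vertex_region[seq_len(nv_lv)] <- "lv_endo"
  vertex_region[off_rv + seq_len(nv_rv)] <- "rv_endo"
  vertex_region[av_ring] <- "av_ring"
  vertex_region[pv_ring] <- "pv_ring"
  vertex_septal <- rep(FALSE, nrow(vertices))
  vertex_septal[off_rv + which(rv_inner_v)] <- TRUE

  # pair RV-covered epicardial vertices with the nearest septal-sheet vertex
  bump <- attr(epi, "bump")
  bump <- c(bump, rep(0, nv_epi - length(bump)))  # cap-center vertex
  septal_anchor <- integer(nrow(vertices))
  bumped <- which(bump > PH_HMIN)
  sept_ids <- off_rv + which(rv_inner_v)
  if (length(bumped)) {
    sv <- vertices[sept_ids, , drop = FALSE]
    for (i in bumped) {
      p <- vertices[off_epi + i, ]
      septal_anchor[off_epi + i] <-
        sept_ids[which.min((sv[, 1] - p[1])^2 + (sv[, 2] - p[2])^2 +
                           (sv[, 3] - p[3])^2)]
    }
  }

  structure(list(
    vertices = vertices, faces = faces,
    face_region = face_region, face_cap = face_cap, face_septal = face_septal,
    vertex_region = vertex_region, vertex_septal = vertex_septal,
    valve_rings = list(MV = mv_ring, TV = tv_ring, AV = av_ring, PV = pv_ring),
    landmark_vertices = list(LV_APEX = 1L),
    septal_anchor = septal_anchor,
    params = params), class = "biv_template")
}

#' @export
print.biv_template <- function(x, ...) {
  cat("biv_template:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  for (r in c("lv_endo", "rv_endo", "epicardium"))
    cat(sprintf("  %-12s %d faces (%d cap)\n", r, sum(x$face_region == r),
                sum(x$face_region == r & x$face_cap)))
  cat("  valve rings:", paste(sprintf("%s(%d)", names(x$valve_rings),
                                      lengths(x$valve_rings)), collapse = " "), "\n")
  invisible(x)
}

# named reference positions used for landmark registration: the apex vertex
# and the four valve-ring centroids
template_landmark_positions <- function(tpl, vertices = tpl$vertices) {
  pos <- rbind(LV_APEX = vertices[tpl$landmark_vertices$LV_APEX, ])
  for (vn in names(tpl$valve_rings))
    pos <- rbind(pos, colMeans(vertices[tpl$valve_rings[[vn]], , drop = FALSE]))
  rownames(pos) <- c("LV_APEX", paste0(names(tpl$valve_rings), "_CENTER"))
  pos
}

# faces of the template matched by each guide-point class
template_match_faces <- function(tpl, class) {
  switch(class,
    lv_endo = which(tpl$face_region == "lv_endo" & !tpl$face_cap),
    rv_endo = which(tpl$face_region == "rv_endo" & !tpl$face_cap &
                      !tpl$face_septal),
    septum = which(tpl$face_septal),
    epicardium = which(tpl$face_region == "epicardium" & !tpl$face_cap),
    stop("unknown guide class: ", class))
}

# region vertex sets for the regional error report (rings excluded from the
# surface regions they border)
template_region_vertices <- function(tpl, region) {
  ring <- unlist(tpl$valve_rings)
  ids <- switch(region,
    lv_endo = which(tpl$vertex_region == "lv_endo"),
    rv_endo = which(tpl$vertex_region == "rv_endo" & !tpl$vertex_septal),
    septum = which(tpl$vertex_septal),
    epicardium = which(tpl$vertex_region == "epicardium"),
    stop("unknown region: ", region))
  used <- sort(unique(as.vector(tpl$faces[!tpl$face_cap, ])))  # no cap centers
  setdiff(intersect(ids, used), ring)
}

# sub-mesh of a fitted model restricted to a region's (non-cap) faces
template_region_mesh <- function(model, region) {
  tpl <- model$template
  keep <- switch(region,
    lv_endo = tpl$face_region == "lv_endo" & !tpl$face_cap,
    rv_endo = tpl$face_region == "rv_endo" & !tpl$face_cap & !tpl$face_septal,
    septum = tpl$face_septal,
    epicardium = tpl$face_region == "epicardium" & !tpl$face_cap,
    stop("unknown region: ", region))
  tri_mesh(model$vertices, tpl$faces[keep, , drop = FALSE])
}

# outward vertex normals for a region's (non-cap) faces: area-weighted mean
# of incident face normals
vertex_normals_region <- function(tpl, vertices, region) {
  keep <- tpl$face_region == region & !tpl$face_cap
  f <- tpl$faces[keep, , drop = FALSE]
  a <- vertices[f[, 1], , drop = FALSE]
  b <- vertices[f[, 2], , drop = FALSE]
  c_ <- vertices[f[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])  # area-weighted
  out <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      s <- rowsum(n[, d], f[, k])
      out[as.integer(rownames(s)), d] <- out[as.integer(rownames(s)), d] + s
    }
  }
  len <- sqrt(rowSums(out^2))
  out / pmax(len, 1e-300)
}
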