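# Synthetic biventricular cine CMR phantom.
#
# Geometry (patient coordinates: right-handed LPS, mm; LV long axis along +z,
# apex pointing to -z, base plane at z = z_base):
#   * LV cavity: thick-walled truncated ellipsoid, in-plane semi-axis `a`,
#     long semi-axis `c`, truncated at z_base = 0.35 c.  Cavity in-plane radii
#     scale over the cardiac cycle by a raised-cosine contraction s(t) whose
#     minimum sits at the end-systolic frame; the long axis is fixed and the
#     epicardial shell is static (wall thickening absorbs the contraction).
#   * RV cavity: crescent wrapped around the LV epicardium over an angular
#     extent E centred on +x, radial thickness h = s(t) hmax cos^2(pi th/E)
#     tapered toward the RV apex; RV free wall of thickness w_rv sqrt(taper)
#     outside it.  The crescent horns are the RV inserts.
#   * Valve rings: MV = LV endocardial basal rim; TV = RV basal rim; AV and PV
#     are circles above the base plane at the roots of an aortic and pulmonary
#     trunk (rendered as bright tubes).  Atria are bright ellipsoids above the
#     base; a dim elliptical torso cylinder provides background tissue.
# Intensities: blood 185, myocardium 95, torso 55, air 15 (+ Gaussian noise).

PH_INTENS <- c(air = 15, torso = 55, myo = 95, blood = 185)
PH_HMIN <- 0.5  # mm; minimum crescent thickness rendered as RV cavity

#' Phantom parameters
#'
#' Parameter set for [make_phantom()].  Defaults emulate an adult-sized
#' biventricular heart imaged with a typical cine protocol (1.5 mm in-plane,
#' 8 mm short-axis spacing, 30 phases).
#'
#' @param lv_long_axis_mm LV apex-to-base length, mm.
#' @param lv_short_radius_mm LV cavity in-plane semi-axis at end-diastole, mm.
#' @param lv_wall_mm LV wall thickness, mm (must be positive and smaller than
#'   the short radius).
#' @param rv_crescent_extent_rad angular extent of the RV crescent, rad.
#' @param rv_cavity_mm maximal radial thickness of the RV crescent at
#'   end-diastole, mm.
#' @param rv_wall_mm RV free-wall thickness, mm.
#' @param ef_target_fraction target LV ejection fraction, in (0, 1).
#' @param es_frame end-systolic frame (0-based, in `[1, n_frames)`).
#' @param n_frames number of cardiac phases (at most 30).
#' @param sax_spacing_mm short-axis slice spacing, mm.
#' @param in_plane_spacing_mm pixel spacing, mm.
#' @param img_px image matrix size (square).
#' @param noise_sd additive Gaussian intensity noise (0-255 scale).
#' @param seed integer seed controlling the rendered noise.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(lv_long_axis_mm = 85, lv_short_radius_mm = 25,
                           lv_wall_mm = 8, rv_crescent_extent_rad = 3.2,
                           rv_cavity_mm = 28, rv_wall_mm = 5,
                           ef_target_fraction = 0.5, es_frame = 12L,
                           n_frames = 30L, sax_spacing_mm = 8,
                           in_plane_spacing_mm = 1.5, img_px = 128L,
                           noise_sd = 4, seed = 1L) {
  p <- list(lv_long_axis_mm = lv_long_axis_mm,
            lv_short_radius_mm = lv_short_radius_mm, lv_wall_mm = lv_wall_mm,
            rv_crescent_extent_rad = rv_crescent_extent_rad,
            rv_cavity_mm = rv_cavity_mm, rv_wall_mm = rv_wall_mm,
            ef_target_fraction = ef_target_fraction,
            es_frame = as.integer(es_frame), n_frames = as.integer(n_frames),
            sax_spacing_mm = sax_spacing_mm,
            in_plane_spacing_mm = in_plane_spacing_mm,
            img_px = as.integer(img_px), noise_sd = noise_sd,
            seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  if (p$lv_wall_mm <= 0) stop("lv_wall_mm must be positive")
  if (p$lv_wall_mm >= p$lv_short_radius_mm)
    stop("infeasible geometry: wall thickness >= LV short radius")
  if (p$ef_target_fraction <= 0 || p$ef_target_fraction >= 1)
    stop("ef_target_fraction must lie in (0, 1)")
  if (p$n_frames < 2 || p$n_frames > 30) stop("n_frames must be in [2, 30]")
  if (p$es_frame < 1 || p$es_frame >= p$n_frames)
    stop("es_frame must lie in [1, n_frames)")
  if (p$sax_spacing_mm <= 0 || p$in_plane_spacing_mm <= 0)
    stop("spacings must be positive")
  if (p$rv_cavity_mm <= 0 || p$rv_wall_mm <= 0) stop("RV dimensions must be positive")
  invisible(p)
}

# run code with a temporarily fixed RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# ---- derived geometry ------------------------------------------------------

ph_geom <- function(p) {
  c_lv <- p$lv_long_axis_mm / 1.35
  z_base <- 0.35 * c_lv
  g <- list(
    a = p$lv_short_radius_mm, c = c_lv, w = p$lv_wall_mm,
    a_e = p$lv_short_radius_mm + p$lv_wall_mm, c_e = c_lv + p$lv_wall_mm,
    z_base = z_base,
    E = p$rv_crescent_extent_rad, hmax = p$rv_cavity_mm, w_rv = p$rv_wall_mm,
    z_rv0 = -0.75 * c_lv,
    n_frames = p$n_frames, es = p$es_frame,
    s_min = sqrt(1 - p$ef_target_fraction),
    # valve/vessel anatomy
    r_av = 8, d_av = 16, th_av = 140 * pi / 180, z_av = z_base + 6,
    r_pv = 9, d_pv = 28, th_pv = 35 * pi / 180, z_pv = z_base + 8,
    la_c = c(0, -8, z_base + 16), la_r = c(22, 22, 16),
    ra_c = c(36, 0, z_base + 14), ra_r = c(18, 18, 14),
    torso_c = c(0, 15), torso_r = c(92, 75))
  g$ramp <- 0.25 * (g$z_base - g$z_rv0)
  g
}

# contraction scale s(t), t 0-based; max 1 at t = 0, min s_min at t = es
ph_scale <- function(g, t) {
  u <- ifelse(t <= g$es, t / g$es,
              1 - (t - g$es) / (g$n_frames - g$es))
  wsys <- (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2
  1 - (1 - g$s_min) * wsys
}

ph_Rcav <- function(g, z, s) s * g$a * sqrt(pmax(0, 1 - (z / g$c)^2))
ph_Repi <- function(g, z) g$a_e * sqrt(pmax(0, 1 - (z / g$c_e)^2))

ph_bump <- function(g, theta) {
  th <- atan2(sin(theta), cos(theta))  # wrap to (-pi, pi]
  ifelse(abs(th) <= g$E / 2, cos(pi * th / g$E)^2, 0)
}

ph_taperz <- function(g, z) {
  u <- pmin(pmax((z - g$z_rv0) / g$ramp, 0), 1)
  u * u * (3 - 2 * u)
}

ph_h <- function(g, theta, z, s) s * g$hmax * ph_bump(g, theta) * ph_taperz(g, z)

# point classification; x, y, z vectors, s scalar contraction scale
# codes: 0 air, 1 LV cav, 2 LV myo, 3 RV cav, 4 RV myo, 5 other blood, 6 torso
ph_classify <- function(g, x, y, z, s) {
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  out <- integer(length(x))
  inside_torso <- ((x - g$torso_c[1]) / g$torso_r[1])^2 +
    ((y - g$torso_c[2]) / g$torso_r[2])^2 <= 1
  out[inside_torso] <- 6L
  # other blood: atria + aortic and pulmonary trunks
  la <- colSums((rbind(x, y, z) - g$la_c)^2 / g$la_r^2) <= 1
  ra <- colSums((rbind(x, y, z) - g$ra_c)^2 / g$ra_r^2) <= 1
  av_c <- g$d_av * c(cos(g$th_av), sin(g$th_av))
  ao <- (x - av_c[1])^2 + (y - av_c[2])^2 <= g$r_av^2 &
    z >= g$z_av & z <= g$z_av + 45
  pv_c <- g$d_pv * c(cos(g$th_pv), sin(g$th_pv))
  pa <- (x - pv_c[1])^2 + (y - pv_c[2])^2 <= g$r_pv^2 &
    z >= g$z_pv & z <= g$z_pv + 35
  out[la | ra | ao | pa] <- 5L
  # LV
  below_base <- z <= g$z_base
  lv_myo <- below_base & z > -g$c_e & r <= ph_Repi(g, z)
  out[lv_myo] <- 2L
  lv_cav <- below_base & abs(z) < g$c & r <= ph_Rcav(g, z, s)
  out[lv_cav] <- 1L
  # RV
  Re <- ph_Repi(g, z)
  h <- ph_h(g, theta, z, s)
  wrv <- g$w_rv * sqrt(ph_bump(g, theta) * ph_taperz(g, z))
  rv_band <- below_base & z > g$z_rv0 & h > PH_HMIN
  rv_cav <- rv_band & r > Re & r <= Re + h
  rv_myo <- below_base & z > g$z_rv0 & h > PH_HMIN & r > Re + h & r <= Re + h + wrv
  out[rv_myo] <- 4L
  out[rv_cav] <- 3L
  out
}

ph_intensity <- function(cls) {
  c(PH_INTENS[["air"]], PH_INTENS[["blood"]], PH_INTENS[["myo"]],
    PH_INTENS[["blood"]], PH_INTENS[["myo"]], PH_INTENS[["blood"]],
    PH_INTENS[["torso"]])[cls + 1L]
}

# ---- analytic volumes (mm^3) ----------------------------------------------

# truncated-ellipsoid volume from z = -c to z = zb
trunc_ellipsoid_vol <- function(a, c, zb) {
  pi * a^2 * (zb - zb^3 / (3 * c^2) + 2 * c / 3)
}

ph_volumes <- function(g, t) {
  s <- ph_scale(g, t)
  lv_cav <- trunc_ellipsoid_vol(s * g$a, g$c, min(g$z_base, g$c))
  lv_epi <- trunc_ellipsoid_vol(g$a_e, g$c_e, g$z_base)
  # RV crescent: separable quadrature over theta and z
  nz <- 2000
  z <- seq(g$z_rv0, g$z_base, length.out = nz)
  dz <- z[2] - z[1]
  gz <- ph_taperz(g, z)
  Re <- ph_Repi(g, z)
  th <- seq(-g$E / 2, g$E / 2, length.out = 1001)
  dth <- th[2] - th[1]
  b <- cos(pi * th / g$E)^2
  qb1 <- sum(b) * dth; qb2 <- sum(b^2) * dth; qb15 <- sum(b^1.5) * dth
  qbh <- sum(sqrt(b)) * dth
  hm <- s * g$hmax
  rv_cav <- hm * sum(Re * gz) * dz * qb1 + hm^2 / 2 * sum(gz^2) * dz * qb2
  rv_wall <- g$w_rv * (sum(sqrt(gz) * Re) * dz * qbh +
                       hm * sum(gz^1.5) * dz * qb15) +
    g$w_rv^2 / 2 * sum(gz) * dz * qb1
  c(lv_cavity = lv_cav, lv_wall = lv_epi - lv_cav,
    rv_cavity = rv_cav, rv_wall = rv_wall)
}

# ---- true surfaces ---------------------------------------------------------

# LV endocardium: truncated ellipsoid, apex pole + basal cap
ph_surface_lv_endo <- function(g, t, ntheta = 96, nz = 48) {
  s <- ph_scale(g, t)
  zs <- -g$c + (g$z_base + g$c) * (1 - cos(seq(0.04, 1, length.out = nz) * pi / 2))^0.7
  loops <- lapply(zs, function(z) {
    th <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
    r <- ph_Rcav(g, z, s)
    cbind(r * cos(th), r * sin(th), z)
  })
  mesh_stack_loops(loops, bottom = c(0, 0, -g$c), top_cap = "fan")
}

# epicardium: LV epicardial ellipsoid plus RV bulge, apex pole + basal cap.
# Returns, via attribute "bump", the crescent bump height at each vertex
# (used by the template builder to pair bulged vertices with the septal sheet).
ph_surface_epi <- function(g, t, ntheta = 96, nz = 48) {
  s <- ph_scale(g, t)
  zs <- -g$c_e + (g$z_base + g$c_e) *
    (1 - cos(seq(0.04, 1, length.out = nz) * pi / 2))^0.7
  th <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  bumps <- numeric(0)
  loops <- lapply(zs, function(z) {
    h <- ph_h(g, th, z, s)
    wrv <- g$w_rv * sqrt(ph_bump(g, th) * ph_taperz(g, z))
    r <- ph_Repi(g, z) + ifelse(h > PH_HMIN, h + wrv, 0)
    bumps <<- c(bumps, ifelse(h > PH_HMIN, h, 0))
    cbind(r * cos(th), r * sin(th), z)
  })
  m <- mesh_stack_loops(loops, bottom = c(0, 0, -g$c_e), top_cap = "fan")
  attr(m, "bump") <- c(0, bumps)  # pole vertex first
  m
}

# RV endocardial crescent boundary loop at height z: outer arc then inner arc
ph_rv_loop <- function(g, z, s, m1 = 49) {
  th <- seq(-g$E / 2 * 0.96, g$E / 2 * 0.96, length.out = m1)
  Re <- ph_Repi(g, z)
  h <- ph_h(g, th, z, s)
  outer <- cbind((Re + h) * cos(th), (Re + h) * sin(th), z)
  inner <- cbind(Re * cos(rev(th)), Re * sin(rev(th)), z)
  rbind(outer, inner)
}

ph_surface_rv_endo <- function(g, t, m1 = 49, nz = 40) {
  s <- ph_scale(g, t)
  z0 <- g$z_rv0 + 0.08 * g$ramp
  zs <- seq(z0, g$z_base, length.out = nz)
  loops <- lapply(zs, function(z) ph_rv_loop(g, z, s, m1))
  mesh_stack_loops(loops, bottom_cap = "strip", top_cap = "strip",
                   strip_m1 = m1)
}

ph_true_surfaces <- function(g, t) {
  list(lv_endo = orient_outward(ph_surface_lv_endo(g, t)),
       rv_endo = orient_outward(ph_surface_rv_endo(g, t)),
       epicardium = orient_outward(ph_surface_epi(g, t)))
}

# ---- valve rings and 3D landmarks -----------------------------------------

ph_rings <- function(g, t, n = 48) {
  s <- ph_scale(g, t)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r_mv <- ph_Rcav(g, g$z_base, s)
  mv <- cbind(r_mv * cos(th), r_mv * sin(th), g$z_base)
  tv <- ph_rv_loop(g, g$z_base, s, m1 = n / 2 + 1)
  av_c <- c(g$d_av * cos(g$th_av), g$d_av * sin(g$th_av), g$z_av)
  av <- cbind(av_c[1] + g$r_av * cos(th), av_c[2] + g$r_av * sin(th), av_c[3])
  pv_c <- c(g$d_pv * cos(g$th_pv), g$d_pv * sin(g$th_pv), g$z_pv)
  pv <- cbind(pv_c[1] + g$r_pv * cos(th), pv_c[2] + g$r_pv * sin(th), pv_c[3])
  list(MV = mv, TV = tv, AV = av, PV = pv)
}

# named 3D landmark points for a given view, frame t (list name -> point)
ph_landmarks_3d <- function(g, t, view, plane = NULL) {
  s <- ph_scale(g, t)
  r_mv <- ph_Rcav(g, g$z_base, s)
  zb <- g$z_base
  u <- function(th) c(cos(th), sin(th), 0)
  if (view == "4Ch") {
    Re_b <- ph_Repi(g, zb)
    h0 <- ph_h(g, 0, zb, s)
    return(list(MV1 = c(-r_mv, 0, zb), MV2 = c(r_mv, 0, zb),
                TV1 = c(Re_b, 0, zb), TV2 = c(Re_b + h0, 0, zb),
                LV_APEX = c(0, 0, -g$c)))
  }
  if (view == "3Ch") {
    d <- u(g$th_av)
    return(list(MV1 = -r_mv * d + c(0, 0, zb), MV2 = r_mv * d + c(0, 0, zb),
                AV1 = (g$d_av - g$r_av) * d + c(0, 0, g$z_av),
                AV2 = (g$d_av + g$r_av) * d + c(0, 0, g$z_av)))
  }
  if (view == "RVOT") {
    # intersections of the PV ring with the RVOT plane (through the z-axis)
    th_r <- 20 * pi / 180
    rhs <- g$d_pv * sin(th_r - g$th_pv) / g$r_pv
    phi <- c(th_r - asin(-rhs), th_r - (pi - asin(-rhs)))
    ctr <- g$d_pv * u(g$th_pv) + c(0, 0, g$z_pv)
    return(list(PV1 = ctr + g$r_pv * u(phi[1]), PV2 = ctr + g$r_pv * u(phi[2])))
  }
  if (view == "SAx") {
    z <- plane$origin_mm[3]
    if (z <= g$z_rv0 + 0.05 * g$ramp || z > g$z_base) return(list())
    Re <- ph_Repi(g, z)
    return(list(RV1 = Re * u(-g$E / 2) + c(0, 0, z),
                RV2 = Re * u(g$E / 2) + c(0, 0, z)))
  }
  list()
}

# ---- imaging planes --------------------------------------------------------

ph_center_plane <- function(center, row_dir, col_dir, npx, sp, thick = 8) {
  origin <- center - ((npx - 1) / 2) * sp * row_dir -
    ((npx - 1) / 2) * sp * col_dir
  plane_meta(origin, row_dir, col_dir, sp, sp, thick)
}

# long-axis plane through the z-axis at polar angle theta, optionally tilted
# about its in-plane horizontal axis
ph_la_plane <- function(theta, tilt, npx, sp, center_z = -8) {
  col_dir <- c(cos(theta), sin(theta), 0)
  row0 <- c(0, 0, -1)
  if (tilt != 0) {
    # rotate row axis about col_dir
    k <- col_dir
    v <- row0
    ct <- cos(tilt); st <- sin(tilt)
    row0 <- v * ct + vcross(k, v) * st + k * sum(k * v) * (1 - ct)
  }
  ph_center_plane(c(0, 0, center_z), row0, col_dir, npx, sp)
}

ph_planes <- function(g, p) {
  npx <- p$img_px
  sp <- p$in_plane_spacing_mm
  planes <- list()
  views <- character()
  add <- function(id, view, meta) {
    planes[[id]] <<- meta
    views[id] <<- view
  }
  add("LAX_2CHLT", "2Ch LT", ph_la_plane(pi / 2, 0, npx, sp))
  add("LAX_2CHRT", "2Ch RT",
      ph_center_plane(c(42, 0, -8), c(0, 0, -1), c(0, 1, 0), npx, sp))
  add("LAX_3CH", "3Ch", ph_la_plane(g$th_av, 0, npx, sp))
  add("LAX_4CH", "4Ch", ph_la_plane(0, 0, npx, sp))
  add("LAX_LVOT", "LVOT", ph_la_plane(g$th_av, 25 * pi / 180, npx, sp))
  add("LAX_RVOT", "RVOT", ph_la_plane(20 * pi / 180, 0, npx, sp))
  zs <- seq(-g$c_e - 10, g$z_base + 18, by = p$sax_spacing_mm)
  for (i in seq_along(zs))
    add(sprintf("SAX%02d", i), "SAx",
        ph_center_plane(c(0, 0, zs[i]), c(0, 1, 0), c(1, 0, 0), npx, sp,
                        thick = p$sax_spacing_mm))
  add("OTHER1", "OTHER",
      ph_center_plane(c(0, 0, g$z_base + 50), c(0, 1, 0), c(1, 0, 0), npx, sp))
  add("OTHER2", "OTHER",
      ph_center_plane(c(0, 0, -g$c_e - 30), c(0, 1, 0), c(1, 0, 0), npx, sp))
  list(planes = planes, views = views)
}

# views that receive segmentation masks
PH_SEGMENTED_VIEWS <- c("2Ch LT", "2Ch RT", "3Ch", "4Ch", "RVOT", "SAx")

# map internal class codes to the view's label integers
ph_mask_from_codes <- function(codes, view) {
  cmap <- encode_segmentation_classes(view)
  lab <- integer(length(codes))
  if ("LV cavity" %in% names(cmap)) lab[codes == 1L] <- cmap[["LV cavity"]]
  if ("LV myocardium" %in% names(cmap)) lab[codes == 2L] <- cmap[["LV myocardium"]]
  if ("RV cavity" %in% names(cmap)) lab[codes == 3L] <- cmap[["RV cavity"]]
  if ("RV myocardium" %in% names(cmap)) lab[codes == 4L] <- cmap[["RV myocardium"]]
  lab
}

#' Generate a synthetic biventricular cine CMR study with ground truth
#'
#' Renders a full multi-view study (one series per long-axis view, a
#' short-axis stack spanning beyond apex and base, and two non-cardiac
#' "other" series) together with complete ground truth: view labels,
#' short-axis optimality flags, the end-systolic frame, per-view landmark
#' pixel (and 3D) coordinates, segmentation masks, analytic cavity/wall
#' volumes per frame, and sampled true surface meshes.
#'
#' @param params a [phantom_params()] object.
#' @param render logical; if `FALSE`, skip pixel rendering (images and masks)
#'   and return only geometry-level truth.
#' @param render_images logical; if `FALSE`, render only the label masks
#'   (no intensity images, `study` is NULL) — the memory-lean configuration
#'   for oracle-guided fitting experiments.
#' @param render_frames optional integer vector of 0-based frames to render
#'   (default: all frames), or `"edes"` for frames 0 and `es_frame` only.
#' @param series optional character vector of view names to generate
#'   (default: all views).
#' @return An object of class `phantom_truth` with elements `study`,
#'   `view_labels`, `optimal_flags`, `es_frame`, `landmarks_px`,
#'   `landmarks_3d`, `masks`, `analytic_volumes` (frames x regions, mL),
#'   `true_surfaces`, `rings`, `params`, `planes`.
#' @export
make_phantom <- function(params = phantom_params(), render = TRUE,
                         render_frames = NULL, series = NULL,
                         render_images = TRUE) {
  stopifnot(inherits(params, "phantom_params"))
  g <- ph_geom(params)
  nfr <- params$n_frames
  frames0 <- if (is.null(render_frames)) 0:(nfr - 1)
             else if (identical(render_frames, "edes")) c(0L, params$es_frame)
             else as.integer(render_frames)
  stopifnot(all(frames0 >= 0), all(frames0 < nfr))
  pl <- ph_planes(g, params)
  if (!is.null(series)) {
    keep <- names(pl$views)[pl$views %in% series]
    pl$planes <- pl$planes[keep]
    pl$views <- pl$views[keep]
  }
  s_of_t <- ph_scale(g, 0:(nfr - 1))

  # analytic volumes, mL
  vols <- t(vapply(0:(nfr - 1), function(t) ph_volumes(g, t), numeric(4))) / 1000
  rownames(vols) <- paste0("frame", 0:(nfr - 1))

  # optimality flags for SAx slices: plane intersects the LV cavity strictly
  # between apex and base plane
  optimal_flags <- logical(0)
  for (id in names(pl$planes)) {
    if (pl$views[[id]] != "SAx") next
    z <- pl$planes[[id]]$origin_mm[3]
    optimal_flags[id] <- (z > -g$c) && (z < g$z_base)
  }

  # landmarks (both pixel and 3D), per series and rendered frame
  landmarks_px <- list()
  landmarks_3d <- list()
  for (id in names(pl$planes)) {
    view <- pl$views[[id]]
    if (!view %in% c("3Ch", "4Ch", "RVOT", "SAx")) next
    if (view == "SAx" && !isTRUE(optimal_flags[id])) next
    meta <- pl$planes[[id]]
    per_frame_px <- list()
    per_frame_3d <- list()
    for (t in frames0) {
      lm <- ph_landmarks_3d(g, t, view, meta)
      if (!length(lm)) next
      m3 <- do.call(rbind, lm)
      rownames(m3) <- names(lm)
      px <- patient_to_pixel(meta, m3)
      rownames(px) <- names(lm)
      per_frame_px[[as.character(t)]] <- px
      per_frame_3d[[as.character(t)]] <- m3
    }
    if (length(per_frame_px)) {
      landmarks_px[[id]] <- per_frame_px
      landmarks_3d[[id]] <- per_frame_3d
    }
  }

  # rendering
  series_list <- list()
  masks <- list()
  if (render) {
    with_seed(params$seed, {
      for (id in names(pl$planes)) {
        meta <- pl$planes[[id]]
        view <- pl$views[[id]]
        npx <- params$img_px
        grid <- as.matrix(expand.grid(row = 0:(npx - 1), col = 0:(npx - 1)))
        pts <- pixel_to_patient(meta, grid)
        frames <- if (render_images) array(0, c(nfr, npx, npx))
        mk <- if (view %in% PH_SEGMENTED_VIEWS)
          array(0L, c(nfr, npx, npx)) else NULL
        if (is.null(frames) && is.null(mk)) next
        for (t in frames0) {
          codes <- ph_classify(g, pts[, 1], pts[, 2], pts[, 3], s_of_t[t + 1])
          if (render_images) {
            img <- matrix(ph_intensity(codes), npx, npx)
            if (params$noise_sd > 0)
              img <- img + matrix(rnorm(npx * npx, 0, params$noise_sd), npx, npx)
            frames[t + 1, , ] <- img
          }
          if (!is.null(mk))
            mk[t + 1, , ] <- matrix(ph_mask_from_codes(codes, view), npx, npx)
        }
        if (render_images) series_list[[id]] <- cine_series(frames, meta, id)
        if (!is.null(mk)) masks[[id]] <- mk
      }
    })
  }

  # true surfaces and rings at rendered frames
  true_surfaces <- list()
  rings <- list()
  for (t in frames0) {
    true_surfaces[[as.character(t)]] <- ph_true_surfaces(g, t)
    rings[[as.character(t)]] <- ph_rings(g, t)
  }

  study <- if (render && render_images)
    cine_study(unname(series_list), paste0("phantom", params$seed))
  else NULL
  structure(list(study = study, view_labels = pl$views,
                 optimal_flags = optimal_flags, es_frame = params$es_frame,
                 landmarks_px = landmarks_px, landmarks_3d = landmarks_3d,
                 masks = masks, analytic_volumes = vols,
                 true_surfaces = true_surfaces, rings = rings,
                 params = params, planes = pl$planes, geom = g),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth:", length(x$view_labels), "series; ES frame", x$es_frame, "\n")
  ed <- x$analytic_volumes[1, "lv_cavity"]
  es <- min(x$analytic_volumes[, "lv_cavity"])
  cat(sprintf("  LV EDV %.1f mL, ESV %.1f mL, EF %.1f%%\n", ed, es,
              100 * (ed - es) / ed))
  invisible(x)
}

#' Sample a population of phantoms
#'
#' Draws `n` parameter sets uniformly within the given per-field ranges
#' (fields not listed keep their defaults) and generates one phantom per
#' draw.  Reproducible under `seed`.
#'
#' @param n number of phantoms (>= 1).
#' @param param_ranges named list `field -> c(low, high)`; degenerate ranges
#'   (low == high) pin a field.
#' @param seed integer seed for the parameter draw; phantom `i` renders with
#'   seed `seed + i`.
#' @param ... passed to [make_phantom()] (e.g. `render`, `render_frames`,
#'   `series`, `render_images`).
#' @param generate if `FALSE`, draw and return only the parameter table
#'   (callers can then build phantoms one at a time to bound memory).
#' @return List with `phantoms` (list of `phantom_truth`, or NULL) and
#'   `params` (data.frame of drawn parameters, one row per phantom).
#' @export
sample_population <- function(n, param_ranges = list(), seed = 1L, ...,
                              generate = TRUE) {
  stopifnot(n >= 1)
  base <- phantom_params()
  for (f in names(param_ranges)) {
    rg <- param_ranges[[f]]
    if (length(rg) != 2 || rg[2] < rg[1]) stop("invalid range for ", f)
    if (!f %in% names(base)) stop("unknown parameter: ", f)
  }
  draws <- with_seed(seed, {
    out <- as.data.frame(base[setdiff(names(base), "seed")])[rep(1, n), ]
    for (f in names(param_ranges)) {
      rg <- param_ranges[[f]]
      v <- runif(n, rg[1], rg[2])
      if (is.integer(base[[f]])) v <- as.integer(round(v))
      out[[f]] <- v
    }
    out
  })
  draws$seed <- seed + seq_len(n)
  rownames(draws) <- NULL
  phantoms <- if (generate)
    lapply(seq_len(n), function(i) make_phantom(population_params(draws, i), ...))
  list(phantoms = phantoms, params = draws)
}

#' Rebuild the parameter object for one row of a drawn parameter table
#' @param params_table the `params` data.frame from [sample_population()].
#' @param i row index.
#' @return A [phantom_params()] object.
#' @export
population_params <- function(params_table, i) {
  do.call(phantom_params, as.list(params_table[i, ]))
}
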