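# Global ventricular measurements from fitted models and the ED/ES PCA shape
# atlas with Z-score projection.

MYO_DENSITY_G_PER_ML <- 1.05  # standard CMR myocardial density convention

#' Enclosed volume of a fitted model region
#'
#' Divergence-theorem volume of a region's closed surface (its faces plus
#' valve-plane caps), in mL; positive for outward orientation, negated by an
#' orientation flip.  Errors (naming boundary edges) if the region surface
#' is open.
#'
#' @param model a [biv_model].
#' @param region one of `"lv_endo"`, `"rv_endo"`, `"epicardium"`.
#' @return Signed volume in mL.
#' @export
region_volume <- function(model, region) {
  tpl <- model$template
  keep <- tpl$face_region == region
  if (!any(keep)) stop("unknown region: ", region)
  m <- tri_mesh(model$vertices, tpl$faces[keep, , drop = FALSE])
  bad <- mesh_boundary_check(m)
  if (length(bad)) stop("region surface is not closed: ", paste(bad, collapse = "; "))
  mesh_signed_volume(m) / 1000
}

# LV-epicardial closed surface volume: epicardial faces with RV-covered
# vertices replaced by their paired septal-sheet positions (see biv_template)
lv_epi_volume <- function(model) {
  tpl <- model$template
  v <- model$vertices
  anch <- tpl$septal_anchor
  repl <- which(anch > 0)
  v[repl, ] <- v[anch[repl], ]
  keep <- tpl$face_region == "epicardium"
  mesh_signed_volume(tri_mesh(v, tpl$faces[keep, , drop = FALSE])) / 1000
}

#' Global ventricular measurements from an ED/ES model pair
#'
#' Cavity volumes by mesh-volume integration of the closed LV/RV endocardial
#' regions; LV mass as (LV epicardial-wall volume including the septum) and
#' RV mass as the RV free-wall volume, both at ED and converted with
#' myocardial density 1.05 g/mL; stroke volumes and ejection fractions by
#' `SV = EDV - ESV`, `EF = 100 SV / EDV`.
#'
#' @param ed,es fitted [biv_model] objects sharing a template.
#' @return An object of class `global_measures`: named list with lv_edv,
#'   lv_esv, lv_sv (mL), lv_ef (percent), lv_mass (g), and the rv_
#'   counterparts.
#' @export
global_measures <- function(ed, es) {
  check_same_topology(ed, es)
  lv_edv <- region_volume(ed, "lv_endo")
  lv_esv <- region_volume(es, "lv_endo")
  rv_edv <- region_volume(ed, "rv_endo")
  rv_esv <- region_volume(es, "rv_endo")
  epi_ed <- region_volume(ed, "epicardium")
  lvepi_ed <- lv_epi_volume(ed)
  lv_wall <- lvepi_ed - lv_edv
  rv_wall <- epi_ed - lvepi_ed - rv_edv
  if (lv_edv < lv_esv || rv_edv < rv_esv)
    warning("EDV <= ESV: negative ejection fraction (dysfunction representable)")
  out <- list(
    lv_edv = lv_edv, lv_esv = lv_esv, lv_sv = lv_edv - lv_esv,
    lv_ef = 100 * (lv_edv - lv_esv) / lv_edv,
    lv_mass = lv_wall * MYO_DENSITY_G_PER_ML,
    rv_edv = rv_edv, rv_esv = rv_esv, rv_sv = rv_edv - rv_esv,
    rv_ef = 100 * (rv_edv - rv_esv) / rv_edv,
    rv_mass = rv_wall * MYO_DENSITY_G_PER_ML)
  structure(out, class = "global_measures")
}

#' @export
print.global_measures <- function(x, ...) {
  lab <- c(lv_edv = "LV EDV (mL)", lv_esv = "LV ESV (mL)", lv_sv = "LV SV (mL)",
           lv_ef = "LV EF (%)", lv_mass = "LV Mass (g)",
           rv_edv = "RV EDV (mL)", rv_esv = "RV ESV (mL)", rv_sv = "RV SV (mL)",
           rv_ef = "RV EF (%)", rv_mass = "RV Mass (g)")
  for (k in names(lab)) cat(sprintf("%-12s %8.1f\n", lab[k], x[[k]]))
  invisible(x)
}

#' Write global measures as CSV (one row per measure)
#' @param x a `global_measures` object (or list of them, written as columns).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_measures_csv <- function(x, path) {
  if (inherits(x, "global_measures")) x <- list(model = x)
  rows <- c("LV EDV (mL)", "LV ESV (mL)", "LV SV (mL)", "LV EF (%)",
            "LV Mass (g)", "RV EDV (mL)", "RV ESV (mL)", "RV SV (mL)",
            "RV EF (%)", "RV Mass (g)")
  keys <- c("lv_edv", "lv_esv", "lv_sv", "lv_ef", "lv_mass",
            "rv_edv", "rv_esv", "rv_sv", "rv_ef", "rv_mass")
  df <- data.frame(Measure = rows)
  for (nm in names(x)) df[[nm]] <- vapply(keys, function(k) x[[nm]][[k]], 0)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# shape vector of an (ED, ES) pair: concatenated xyz coordinates
shape_vector <- function(ed, es) c(as.vector(ed$vertices), as.vector(es$vertices))

# rigidly align (no scale) an ED/ES pair to a reference ED vertex matrix,
# using the ED correspondence and applying the same transform to ES
align_pair_to <- function(ed_v, es_v, ref_ed_v) {
  tf <- procrustes_fit(ed_v, ref_ed_v, scale = FALSE)
  list(ed = apply_transform(ed_v, tf), es = apply_transform(es_v, tf))
}

#' Build an ED/ES statistical shape atlas
#'
#' Each subject's ED model is rigidly Procrustes-aligned (rotation and
#' translation, no scaling: heart size is a real shape feature) to the
#' population mean (estimated by a few alternating passes), the same
#' transform is applied to the ES model, and the concatenated ED+ES vertex
#' coordinates form the subject's shape vector.  Principal component
#' analysis with the 1/(n-1) covariance convention yields orthonormal modes
#' and descending eigenvalues.
#'
#' @param pairs list of `list(ed =, es =)` fitted [biv_model] pairs sharing
#'   one template (>= 3 subjects).
#' @param n_mean_iter alternating mean/alignment passes (default 3).
#' @return An object of class `shape_atlas` with `mean_shape`, `modes`
#'   (columns), `eigenvalues`, `n_subjects`, `template`, and the aligned
#'   training `scores`.
#' @export
build_atlas <- function(pairs, n_mean_iter = 3L) {
  if (length(pairs) < 3) stop("need at least 3 subjects")
  for (p in pairs) check_same_topology(p$ed, p$es)
  nvert <- nrow(pairs[[1]]$ed$vertices)
  ref <- pairs[[1]]$ed$vertices
  aligned <- pairs
  for (iter in seq_len(n_mean_iter)) {
    aligned <- lapply(pairs, function(p) {
      al <- align_pair_to(p$ed$vertices, p$es$vertices, ref)
      list(ed = al$ed, es = al$es)
    })
    ref <- Reduce(`+`, lapply(aligned, `[[`, "ed")) / length(aligned)
  }
  X <- t(vapply(aligned, function(p) c(as.vector(p$ed), as.vector(p$es)),
                numeric(6 * nvert)))
  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2, mean_shape)
  sv <- svd(Xc, nu = 0)
  k <- min(nrow(X) - 1, ncol(sv$v))
  modes <- sv$v[, seq_len(k), drop = FALSE]
  eig <- (sv$d[seq_len(k)]^2) / (nrow(X) - 1)
  scores <- Xc %*% modes
  structure(list(mean_shape = mean_shape, modes = modes, eigenvalues = eig,
                 n_subjects = length(pairs),
                 template = pairs[[1]]$ed$template,
                 mean_ed = matrix(mean_shape[seq_len(3 * nvert)], nvert, 3),
                 scores = scores),
            class = "shape_atlas")
}

#' @export
print.shape_atlas <- function(x, ...) {
  cat("shape_atlas:", x$n_subjects, "subjects,", length(x$eigenvalues), "modes\n")
  k <- min(5, length(x$eigenvalues))
  cat("  variance explained by first", k, "modes:",
      sprintf("%.1f%%", 100 * variance_explained(x, k)), "\n")
  invisible(x)
}

#' @export
summary.shape_atlas <- function(object, ...) {
  ve <- cumsum(object$eigenvalues) / sum(object$eigenvalues)
  df <- data.frame(mode = seq_along(object$eigenvalues),
                   eigenvalue = object$eigenvalues, cum_var = ve)
  print(utils::head(df, 10))
  invisible(df)
}

#' Project a model pair onto the atlas (Z-scores)
#'
#' Aligns the pair to the atlas mean with the same rule used during
#' construction, then returns per-mode scores in training-population
#' standard deviations: `z_k = phi_k' (s - s_mean) / sqrt(lambda_k)`.
#' Modes with eigenvalue below `1e-12` are excluded (z set to NA) with a
#' warning.
#'
#' @param atlas a [shape_atlas].
#' @param ed,es fitted [biv_model] objects with the atlas topology.
#' @return List with `z` (per retained mode), `raw` (unscaled scores `b_k`)
#'   and `excluded` (indices of dropped modes).
#' @export
project <- function(atlas, ed, es) {
  if (!identical(dim(ed$vertices), dim(atlas$mean_ed)))
    stop("model topology does not match atlas")
  al <- align_pair_to(ed$vertices, es$vertices, atlas$mean_ed)
  s <- c(as.vector(al$ed), as.vector(al$es))
  b <- drop(crossprod(atlas$modes, s - atlas$mean_shape))
  lam <- atlas$eigenvalues
  bad <- which(lam < 1e-12)
  z <- b / sqrt(pmax(lam, 1e-300))
  if (length(bad)) {
    warning("excluding ", length(bad), " mode(s) with near-zero eigenvalue")
    z[bad] <- NA_real_
  }
  list(z = z, raw = b, excluded = bad)
}

#' @export
predict.shape_atlas <- function(object, ed, es, ...) project(object, ed, es)

#' Reconstruct a shape vector from atlas scores
#' @param atlas a [shape_atlas].
#' @param raw unscaled scores `b_k` (as returned in `project()$raw`).
#' @return Shape vector (mean + modes %*% b).
#' @export
atlas_reconstruct <- function(atlas, raw) {
  drop(atlas$mean_shape + atlas$modes %*% raw)
}

#' Cumulative fraction of shape variance explained
#' @param atlas a [shape_atlas].
#' @param k number of leading modes.
#' @return Fraction in `[0, 1]`.
#' @export
variance_explained <- function(atlas, k) {
  stopifnot(k >= 1, k <= length(atlas$eigenvalues))
  sum(atlas$eigenvalues[seq_len(k)]) / sum(atlas$eigenvalues)
}
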