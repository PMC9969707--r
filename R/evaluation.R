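# Comparison metrics: Dice, Hausdorff, AAFD, classification scores, rigid
# model alignment, regional signed projection distances, plane angulation
# errors, Bland-Altman agreement, and per-mode atlas Z-score differences.

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`.  Two empty masks are defined as Dice 1 (with a
#' warning).
#'
#' @param a,b logical (or 0/1) arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / denom
}

#' Hausdorff distance between two point sets
#'
#' The symmetric Hausdorff distance `max(sup_a inf_b d, sup_b inf_a d)` in
#' Euclidean metric; optionally the percentile variant (e.g. `percentile =
#' 0.95` for HD95).
#'
#' @param a,b n x d point matrices (same d), nonempty.
#' @param percentile directed-distance quantile in (0, 1]; 1 gives the
#'   classical maximum.
#' @return Distance in the units of the inputs.
#' @export
hausdorff <- function(a, b, percentile = 1) {
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty point set")
  if (percentile >= 1) return(cpp_hausdorff(a, b))
  d_ab <- apply(a, 1, function(p) sqrt(min(colSums((t(b) - p)^2))))
  d_ba <- apply(b, 1, function(p) sqrt(min(colSums((t(a) - p)^2))))
  max(quantile(d_ab, percentile), quantile(d_ba, percentile))
}

#' Average absolute frame difference
#'
#' Mean absolute difference between predicted and reference cardiac phase
#' indices.
#'
#' @param predicted,truth equal-length numeric vectors of frame indices.
#' @return Mean `|p_i - t_i|` in frames.
#' @export
aafd <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  stopifnot(length(predicted) >= 1)
  mean(abs(predicted - truth))
}

#' Per-class precision, recall and F1
#'
#' @param predicted,truth equal-length vectors of class labels.
#' @param labels optional label set (defaults to the union observed).
#' @return data.frame with one row per class plus macro averages as
#'   attributes `macro_f1`, `macro_precision`, `macro_recall`.
#' @export
classification_report <- function(predicted, truth, labels = NULL) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  predicted[is.na(predicted)] <- "<none>"
  if (is.null(labels)) labels <- sort(unique(truth)) else labels <- as.character(labels)
  rows <- lapply(labels, function(l) {
    tp <- sum(predicted == l & truth == l)
    fp <- sum(predicted == l & truth != l)
    fn <- sum(predicted != l & truth == l)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = l, n = tp + fn, precision = prec, recall = rec, f1 = f1)
  })
  out <- do.call(rbind, rows)
  attr(out, "macro_precision") <- mean(out$precision)
  attr(out, "macro_recall") <- mean(out$recall)
  attr(out, "macro_f1") <- mean(out$f1)
  out
}

#' Rigidly align one fitted model to another
#'
#' Closed-form least-squares rotation + translation (no scale) over
#' corresponding vertices; reflections are rejected (proper rotation).
#'
#' @param moving,fixed [biv_model] objects sharing a template.
#' @return List with `transform` (R, s = 1, t, rms) and `aligned` (the moved
#'   model, flagged as aligned).
#' @export
rigid_align_models <- function(moving, fixed) {
  check_same_topology(moving, fixed)
  tf <- procrustes_fit(moving$vertices, fixed$vertices, scale = FALSE)
  out <- moving
  out$vertices <- apply_transform(moving$vertices, tf)
  attr(out, "aligned") <- TRUE
  list(transform = tf, aligned = out)
}

check_same_topology <- function(a, b) {
  if (!inherits(a, "biv_model") || !inherits(b, "biv_model"))
    stop("expected biv_model objects")
  if (!identical(dim(a$vertices), dim(b$vertices)) ||
      !identical(a$template$faces, b$template$faces))
    stop("models do not share template topology")
  invisible(TRUE)
}

#' Regional signed projection distances between two fitted models
#'
#' For every vertex of the automatic model, the exact point-to-triangle
#' distance to the manual model's surface of the same region, signed
#' positive when the vertex lies outside the manual surface (along its
#' outward normal).  Valve regions use the ring vertices, measured to the
#' manual ring polyline (unsigned).  The global row is the mean over all
#' surface vertices, not the mean of regional means.
#'
#' @param auto,manual [biv_model] objects sharing a template; align with
#'   [rigid_align_models()] first.
#' @return A data.frame of class `regional_error_report` with columns
#'   `region`, `mae`, `sd`, `signed_mean`, `n`; per-vertex signed distances
#'   for surface regions are attached as attribute `signed_distances`.
#' @export
projection_distances <- function(auto, manual) {
  check_same_topology(auto, manual)
  if (!isTRUE(attr(auto, "aligned")))
    warning("models not flagged as rigidly aligned; distances may include pose")
  tpl <- auto$template
  surface_regions <- c("LV Endocardium" = "lv_endo", "RV Endocardium" = "rv_endo",
                       "Septum" = "septum", "Epicardium" = "epicardium")
  rows <- list()
  all_abs <- numeric(0)
  signed_all <- rep(NA_real_, nrow(auto$vertices))
  for (rn in names(surface_regions)) {
    reg <- surface_regions[[rn]]
    vids <- template_region_vertices(tpl, reg)
    sub <- template_region_mesh(manual, reg)
    res <- point_to_surface(auto$vertices[vids, , drop = FALSE], sub)
    nrm <- face_normals(sub$vertices, sub$faces)[res$face, , drop = FALSE]
    sgn <- sign(rowSums((auto$vertices[vids, , drop = FALSE] - res$closest) * nrm))
    sgn[sgn == 0] <- 1
    signed <- res$dist * sgn
    signed_all[vids] <- signed
    rows[[rn]] <- data.frame(region = rn, mae = mean(res$dist), sd = sd(res$dist),
                             signed_mean = mean(signed), n = length(vids))
    all_abs <- c(all_abs, res$dist)
  }
  for (vn in c("MV", "AV", "TV", "PV")) {
    vids <- tpl$valve_rings[[vn]]
    d <- point_to_polyline(auto$vertices[vids, , drop = FALSE],
                           manual$vertices[vids, , drop = FALSE], closed = TRUE)
    rows[[vn]] <- data.frame(region = vn, mae = mean(d), sd = sd(d),
                             signed_mean = NA_real_, n = length(vids))
    all_abs <- c(all_abs, d)
  }
  out <- rbind(data.frame(region = "Global", mae = mean(all_abs),
                          sd = sd(all_abs), signed_mean = NA_real_,
                          n = length(all_abs)),
               do.call(rbind, rows))
  rownames(out) <- NULL
  attr(out, "signed_distances") <- signed_all
  class(out) <- c("regional_error_report", class(out))
  out
}

# min distance from points to a (closed) polyline
point_to_polyline <- function(points, poly, closed = TRUE) {
  pts <- rbind(points)
  segs <- if (closed) rbind(cbind(seq_len(nrow(poly)),
                                  c(seq_len(nrow(poly))[-1], 1L)))
          else cbind(seq_len(nrow(poly) - 1), seq_len(nrow(poly))[-1])
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    min(vapply(seq_len(nrow(segs)), function(k) {
      a <- poly[segs[k, 1], ]; b <- poly[segs[k, 2], ]
      ab <- b - a
      tt <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
      tt <- min(max(tt, 0), 1)
      sqrt(sum((a + tt * ab - p)^2))
    }, 0))
  }, 0)
}

#' Angulation error between predicted and true valve (or septal) planes
#'
#' The angle between the in-plane lines joining each insert pair, after
#' projecting both onto the imaging plane; undirected, in `[0, 90]` degrees.
#'
#' @param pred,truth 2 x 3 matrices (two insert points each).
#' @param plane_normal normal of the imaging plane.
#' @return Angle in degrees.
#' @export
plane_angulation_error <- function(pred, truth, plane_normal) {
  proj <- function(pair) {
    d <- pair[2, ] - pair[1, ]
    if (sqrt(sum(d^2)) < 1e-12) stop("coincident insert points")
    n <- plane_normal / sqrt(sum(plane_normal^2))
    d <- d - sum(d * n) * n
    if (sqrt(sum(d^2)) < 1e-12) stop("insert pair perpendicular to plane")
    d / sqrt(sum(d^2))
  }
  ca <- abs(sum(proj(rbind(pred)) * proj(rbind(truth))))
  acos(min(ca, 1)) * 180 / pi
}

#' Bland-Altman agreement between paired measurements
#'
#' Bias (mean of `y - x`), 95% limits of agreement (bias +/- 1.96 sd),
#' coefficient of determination of `y` on `x`, and the paired-t p-value.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return An object of class `bland_altman_summary`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  stopifnot(length(x) >= 3)
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  r2 <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)^2
  p <- if (s == 0) NA_real_ else t.test(y, x, paired = TRUE)$p.value
  structure(list(bias = bias,
                 limits_of_agreement = c(bias - 1.96 * s, bias + 1.96 * s),
                 r_squared = r2, p_value = p, n = length(x)),
            class = "bland_altman_summary")
}

#' @export
print.bland_altman_summary <- function(x, ...) {
  cat(sprintf("bias %.3f, LoA [%.3f, %.3f], R^2 %.3f, paired-t p %.3g (n=%d)\n",
              x$bias, x$limits_of_agreement[1], x$limits_of_agreement[2],
              x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Per-mode Z-score differences between two sets of shape models
#'
#' Projects both paired lists of (ED, ES) models onto the atlas and reports,
#' for each of the first `n_modes` modes, the mean absolute Z-score
#' difference, plus a two-sample Kolmogorov-Smirnov test of the score
#' distributions with Holm-Bonferroni-adjusted decisions at `alpha`.
#'
#' @param atlas a [shape_atlas] object.
#' @param pairs_a,pairs_b equal-length lists of `list(ed =, es =)` model
#'   pairs.
#' @param n_modes number of leading modes to compare (default 20).
#' @param alpha significance level for the KS decisions.
#' @return data.frame with columns `mode`, `mean_abs_dz`, `ks_stat`, `ks_p`,
#'   `p_holm`, `reject`.
#' @export
zscore_difference <- function(atlas, pairs_a, pairs_b, n_modes = 20L,
                              alpha = 0.05) {
  if (length(pairs_a) != length(pairs_b)) stop("unpaired model lists")
  za <- t(vapply(pairs_a, function(p)
    suppressWarnings(project(atlas, p$ed, p$es))$z,
    numeric(length(atlas$eigenvalues))))
  zb <- t(vapply(pairs_b, function(p)
    suppressWarnings(project(atlas, p$ed, p$es))$z,
    numeric(length(atlas$eigenvalues))))
  modes <- which(atlas$eigenvalues > 1e-12)  # excluded modes have no score
  modes <- utils::head(modes, n_modes)
  rows <- lapply(modes, function(m) {
    ks <- suppressWarnings(ks.test(za[, m], zb[, m]))
    data.frame(mode = m, mean_abs_dz = mean(abs(za[, m] - zb[, m])),
               ks_stat = unname(ks$statistic), ks_p = ks$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$ks_p, method = "holm")
  out$reject <- out$p_holm < alpha
  out
}
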