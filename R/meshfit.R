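# Template-mesh fitting: similarity landmark registration for global pose
# and scale, followed by regularized non-rigid fitting of the template
# surfaces to labeled guide points (iterative closest-point correspondences
# against the matching surface class, linear least-squares displacement field
# with a graph-Laplacian smoothness penalty, per-iteration step cap).

#' Fitting configuration
#'
#' @param smoothness_weight non-negative weight of the Laplacian smoothness
#'   penalty on the displacement field (default 1).
#' @param landmark_weight weight of landmark guide points relative to contour
#'   points (default 10; landmarks are sparse but authoritative).
#' @param n_iterations maximum correspondence iterations (default 20).
#' @param max_step_mm per-iteration cap on vertex displacement, mm.
#' @param tol_mm RMS vertex-change convergence threshold, mm.
#' @param anchor_weight small ridge weight tying every vertex to its
#'   registered template position; pins the otherwise unconstrained
#'   low-frequency modes of regions without nearby guide points.
#' @param gate_mm correspondences farther than this from the surface are
#'   ignored (robustness against stray guide points).
#' @param seed integer seed (reserved for stochastic extensions; the fit
#'   itself is deterministic).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(smoothness_weight = 1, landmark_weight = 10,
                       n_iterations = 20L, max_step_mm = 2, tol_mm = 0.01,
                       anchor_weight = 0.01, gate_mm = 15,
                       seed = 1L) {
  if (smoothness_weight < 0) stop("smoothness_weight must be non-negative")
  stopifnot(n_iterations >= 1, max_step_mm > 0, anchor_weight >= 0)
  structure(list(smoothness_weight = smoothness_weight,
                 landmark_weight = landmark_weight,
                 n_iterations = as.integer(n_iterations),
                 max_step_mm = max_step_mm, tol_mm = tol_mm,
                 anchor_weight = anchor_weight, gate_mm = gate_mm,
                 seed = as.integer(seed)), class = "fit_config")
}

# aggregate raw insert landmarks (MV1, MV2, ... possibly from several views)
# into the registration target set: LV apex + valve-ring centers
registration_targets <- function(landmarks) {
  lm <- rbind(landmarks)
  out <- NULL
  nms <- character(0)
  if ("LV_APEX" %in% rownames(lm)) {
    out <- rbind(out, colMeans(lm[rownames(lm) == "LV_APEX", , drop = FALSE]))
    nms <- c(nms, "LV_APEX")
  }
  for (vn in c("MV", "TV", "AV", "PV")) {
    # raw inserts (MV1, MV2, ...) or pre-aggregated centers (MV_CENTER)
    sel <- grepl(paste0("^", vn, "([0-9]+|_CENTER)$"), rownames(lm))
    if (any(sel)) {
      out <- rbind(out, colMeans(lm[sel, , drop = FALSE]))
      nms <- c(nms, paste0(vn, "_CENTER"))
    }
  }
  rownames(out) <- nms
  out
}

#' Similarity registration of the template to named landmarks
#'
#' Closed-form orthogonal-Procrustes fit (rotation, translation, isotropic
#' scale) of the template's landmark positions (LV apex and valve-ring
#' centers) to the supplied named landmark points.  Raw insert names (MV1,
#' MV2, ...) are aggregated to ring centers automatically.
#'
#' @param template a [biv_template()].
#' @param landmarks named n x 3 matrix of target landmark points (patient mm).
#' @return List with `transform` (R, s, t) and `rms` residual (mm).
#' @export
landmark_register <- function(template, landmarks) {
  tgt <- registration_targets(landmarks)
  ref <- template_landmark_positions(template)
  common <- intersect(rownames(ref), rownames(tgt))
  if (length(common) < 3)
    stop("need at least 3 shared landmark names, got ", length(common))
  A <- ref[common, , drop = FALSE]
  for (m in list(A, tgt[common, , drop = FALSE])) {
    sv <- svd(sweep(m, 2, colMeans(m)))
    if (sv$d[2] < 1e-6 * max(sv$d[1], 1))
      stop("landmarks are collinear; registration is degenerate")
  }
  tf <- procrustes_fit(A, tgt[common, , drop = FALSE], scale = TRUE)
  list(transform = tf[c("R", "s", "t")], rms = tf$rms)
}

# random-walk-normalized graph Laplacian over template edges, with the
# free-standing valve rings connected as cycles
template_laplacian <- function(tpl) {
  f <- tpl$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  for (vn in c("AV", "PV")) {
    r <- tpl$valve_rings[[vn]]
    e <- rbind(e, cbind(r, c(r[-1], r[1])))
  }
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  n <- nrow(tpl$vertices)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  Matrix::Diagonal(n) - Matrix::Diagonal(n, 1 / deg) %*% A
}

# barycentric weights of points `q` (already the closest points) within the
# triangles `faces[fid, ]`
bary_weights <- function(q, vertices, faces, fid) {
  a <- vertices[faces[fid, 1], , drop = FALSE]
  b <- vertices[faces[fid, 2], , drop = FALSE]
  c_ <- vertices[faces[fid, 3], , drop = FALSE]
  v0 <- b - a; v1 <- c_ - a; v2 <- q - a
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- pmax(d00 * d11 - d01 * d01, 1e-300)
  w1 <- (d11 * d20 - d01 * d21) / den
  w2 <- (d00 * d21 - d01 * d20) / den
  w1 <- pmin(pmax(w1, 0), 1); w2 <- pmin(pmax(w2, 0), 1)
  cbind(pmax(1 - w1 - w2, 0), w1, w2)
}

#' Fit the biventricular template to guide points
#'
#' Registers the template to the guide landmarks (similarity transform),
#' then iteratively (a) matches every contour guide point to the closest
#' point on the template surface of the same class (septum guides match the
#' septal sheet, valve inserts their ring vertices), (b) solves a sparse
#' linear least-squares problem for all vertex positions with a Laplacian
#' smoothness penalty on the total displacement field, and (c) caps the
#' per-iteration vertex displacement.  Stops after `n_iterations` or when
#' the RMS vertex change drops below `tol_mm`.
#'
#' @param template a [biv_template()].
#' @param guides a `guide_point_set` (see [assemble_guide_points()]).
#' @param config a [fit_config()].
#' @param transform optional pre-computed registration (from
#'   [landmark_register()]); computed from the guide landmarks when `NULL`.
#' @return A fitted model of class `biv_model`.
#' @export
nonrigid_fit <- function(template, guides, config = fit_config(),
                         transform = NULL) {
  classes <- intersect(names(guides$contour_points),
                       c("lv_endo", "rv_endo", "septum", "epicardium"))
  classes <- classes[vapply(classes,
                            function(cl) nrow(guides$contour_points[[cl]]) > 0, TRUE)]
  if (length(classes) < 2)
    stop("need guide points for at least 2 contour classes")
  if (is.null(transform))
    transform <- landmark_register(template, guides$landmark_points)$transform
  V0 <- apply_transform(template$vertices, transform)
  n <- nrow(V0)
  L <- template_laplacian(template)
  LtL <- Matrix::crossprod(L)
  lam <- config$smoothness_weight
  mu <- config$anchor_weight
  reg <- lam * LtL + mu * Matrix::Diagonal(n)
  reg_rhs <- reg %*% V0

  # landmark guide -> template vertex (ring vertices re-matched each pass)
  lm <- rbind(guides$landmark_points)
  lm_ring <- sub("[0-9]+$", "", rownames(lm))
  V <- V0
  prev_change <- Inf
  history <- numeric(0)
  warm <- list()  # per-class previous matched faces (warm start)
  for (it in seq_len(config$n_iterations)) {
    ii <- jj <- xx <- list()
    rhs_pts <- list()
    wts <- list()
    row0 <- 0L
    for (cl in classes) {
      P <- guides$contour_points[[cl]]
      fsub <- template_match_faces(template, cl)
      res <- cpp_point_tri_dist(P, V, template$faces[fsub, , drop = FALSE],
                                warm[[cl]])
      warm[[cl]] <- res$face
      ok <- res$dist <= config$gate_mm
      if (!any(ok)) next
      P <- P[ok, , drop = FALSE]
      fid <- fsub[res$face[ok]]
      bw <- bary_weights(res$closest[ok, , drop = FALSE], V,
                         template$faces[fsub, , drop = FALSE], res$face[ok])
      m <- nrow(P)
      tri <- template$faces[fid, , drop = FALSE]
      ii[[cl]] <- rep(row0 + seq_len(m), 3)
      jj[[cl]] <- as.vector(tri)
      xx[[cl]] <- as.vector(bw)
      rhs_pts[[cl]] <- P
      wts[[cl]] <- rep(1, m)
      row0 <- row0 + m
    }
    if (nrow(lm) > 0) {
      tgt_v <- integer(nrow(lm))
      for (k in seq_len(nrow(lm))) {
        if (lm_ring[k] == "LV_APEX" || rownames(lm)[k] == "LV_APEX") {
          tgt_v[k] <- template$landmark_vertices$LV_APEX
        } else if (lm_ring[k] %in% names(template$valve_rings)) {
          ring <- template$valve_rings[[lm_ring[k]]]
          d2 <- rowSums(sweep(V[ring, , drop = FALSE], 2, lm[k, ])^2)
          tgt_v[k] <- ring[which.min(d2)]
        } else next
      }
      keep <- tgt_v > 0
      m <- sum(keep)
      if (m > 0) {
        ii$lm <- row0 + seq_len(m)
        jj$lm <- tgt_v[keep]
        xx$lm <- rep(1, m)
        rhs_pts$lm <- lm[keep, , drop = FALSE]
        wts$lm <- rep(config$landmark_weight, m)
        row0 <- row0 + m
      }
    }
    A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(row0, n))
    P <- do.call(rbind, rhs_pts)
    w <- unlist(wts)
    AtW <- Matrix::t(Matrix::Diagonal(x = w) %*% A)
    M <- Matrix::forceSymmetric(AtW %*% A + reg)
    rhs <- as.matrix(AtW %*% P + reg_rhs)
    Vnew <- tryCatch(as.matrix(Matrix::solve(M, rhs)),
                     error = function(e)
                       stop("fitting system is ill-conditioned (", conditionMessage(e),
                            "); use a positive smoothness_weight"))
    step <- Vnew - V
    sn <- sqrt(rowSums(step^2))
    over <- sn > config$max_step_mm
    if (any(over))
      step[over, ] <- step[over, ] * (config$max_step_mm / sn[over])
    V <- V + step
    change <- sqrt(mean(rowSums(step^2)))
    history <- c(history, change)
    if (change < config$tol_mm) break
    prev_change <- change
  }
  new_biv_model(template, V, guides$phase, transform = transform,
                history = history)
}

new_biv_model <- function(template, vertices, phase = "ED", transform = NULL,
                          history = NULL) {
  structure(list(template = template, vertices = vertices, phase = phase,
                 transform = transform, history = history),
            class = "biv_model")
}

#' Instantiate an (unfitted) model at the template's own geometry
#' @param template a [biv_template()].
#' @param phase phase tag ("ED" or "ES").
#' @return A `biv_model`.
#' @export
template_model <- function(template, phase = "ED") {
  new_biv_model(template, template$vertices, phase)
}

#' @export
print.biv_model <- function(x, ...) {
  cat("biv_model (", x$phase, "): ", nrow(x$vertices), " vertices\n", sep = "")
  if (!is.null(x$history))
    cat(sprintf("  fitted in %d iterations (final RMS change %.4f mm)\n",
                length(x$history), x$history[length(x$history)]))
  invisible(x)
}

#' @export
summary.biv_model <- function(object, ...) {
  vols <- c(lv_cavity = region_volume(object, "lv_endo"),
            rv_cavity = region_volume(object, "rv_endo"),
            total_epi = region_volume(object, "epicardium"))
  cat("biv_model (", object$phase, ") region volumes (mL):\n", sep = "")
  print(round(vols, 1))
  invisible(vols)
}

#' @export
plot.biv_model <- function(x, regions = c("lv_endo", "rv_endo", "epicardium"),
                           ...) {
  cols <- c(lv_endo = "forestgreen", rv_endo = "steelblue",
            epicardium = "firebrick", av_ring = "orange", pv_ring = "purple")
  vr <- x$template$vertex_region
  keep <- vr %in% regions | vr %in% c("av_ring", "pv_ring")
  v <- x$vertices[keep, , drop = FALSE]
  graphics::par(mfrow = c(1, 2))
  graphics::plot(v[, 1], v[, 3], col = cols[vr[keep]], pch = ".", asp = 1,
                 xlab = "x (mm)", ylab = "z (mm)", main = "long-axis", ...)
  graphics::plot(v[, 1], v[, 2], col = cols[vr[keep]], pch = ".", asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", main = "short-axis", ...)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}
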