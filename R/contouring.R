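# Contour extraction from per-view segmentation masks and assembly of
# labeled 3D guide points for mesh fitting.
#
# Conventions: LV endocardium = boundary of the (hole-filled) LV cavity;
# epicardium = outer boundary of the union of all labeled structures; septum
# = LV-side interface points adjacent to the RV; RV endocardium = RV cavity
# boundary excluding the septal interface.  Papillary-like islands inside
# cavities are merged into the cavity before tracing.  Contours are traced
# as ordered subpixel polylines (marching-squares isolines at level 0.5).

# fill interior holes of a binary mask (morphological reconstruction of the
# background from the image border)
fill_holes <- function(m) {
  bg <- !m
  reach <- matrix(FALSE, nrow(m), ncol(m))
  reach[1, ] <- bg[1, ]; reach[nrow(m), ] <- bg[nrow(m), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(m)] <- bg[, ncol(m)]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(m), ]
    grown[-nrow(m), ] <- grown[-nrow(m), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(m)]
    grown[, -ncol(m)] <- grown[, -ncol(m)] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  m | (bg & !reach)
}

# ordered subpixel boundary of a binary mask: the longest closed 0.5-isoline,
# as 0-based (row, col) coordinates
trace_boundary <- function(m) {
  if (!any(m)) return(matrix(numeric(0), 0, 2))
  cl <- contourLines(x = 0:(nrow(m) - 1), y = 0:(ncol(m) - 1),
                     z = matrix(as.numeric(m), nrow(m)), levels = 0.5)
  if (!length(cl)) return(matrix(numeric(0), 0, 2))
  best <- cl[[which.max(vapply(cl, function(s) length(s$x), 0L))]]
  cbind(best$x, best$y)
}

# minimum distance (in px) from each point to the set of TRUE pixel centers
dist_to_pixels <- function(points, mask) {
  px <- which(mask, arr.ind = TRUE) - 1
  if (nrow(px) == 0 || nrow(points) == 0)
    return(rep(Inf, nrow(points)))
  vapply(seq_len(nrow(points)), function(i)
    sqrt(min((px[, 1] - points[i, 1])^2 + (px[, 2] - points[i, 2])^2)), 0)
}

#' Extract labeled contours from a segmentation mask
#'
#' @param mask integer label image following the view's class map
#'   ([encode_segmentation_classes()]).
#' @param view the view name.
#' @param adjacency_px distance threshold (px) defining "adjacent to RV" for
#'   the septal interface (default 1.3, i.e. 8-connectivity of the underlying
#'   pixels plus the half-pixel offset of subpixel boundaries).
#' @return An object of class `contour_set`: list of ordered point matrices
#'   (0-based row, col) per available contour class (`lv_endo`, `rv_endo`,
#'   `septum`, `epicardium`), plus `view`.  Missing structures yield absent
#'   classes with a warning.
#' @export
extract_contours <- function(mask, view, adjacency_px = 1.3) {
  cmap <- encode_segmentation_classes(view)
  get <- function(nm) if (nm %in% names(cmap)) mask == cmap[[nm]]
                      else matrix(FALSE, nrow(mask), ncol(mask))
  lv_cav <- get("LV cavity"); lv_myo <- get("LV myocardium")
  rv_cav <- get("RV cavity"); rv_myo <- get("RV myocardium")
  rv_any <- rv_cav | rv_myo
  out <- list()
  has_lv <- "LV cavity" %in% names(cmap)
  has_rv <- "RV cavity" %in% names(cmap)
  if (has_lv) {
    if (any(lv_cav)) out$lv_endo <- trace_boundary(fill_holes(lv_cav))
    else warning("no LV cavity pixels in ", view, " mask")
  }
  if (has_rv) {
    if (any(rv_cav)) {
      rvb <- trace_boundary(fill_holes(rv_cav))
      keep <- dist_to_pixels(rvb, lv_myo) > adjacency_px
      out$rv_endo <- rvb[keep, , drop = FALSE]
    } else warning("no RV cavity pixels in ", view, " mask")
  }
  union <- lv_cav | lv_myo | rv_any
  if (any(union)) {
    out$epicardium <- trace_boundary(fill_holes(union))
  } else warning("empty mask in ", view)
  if (has_lv && has_rv && any(lv_myo) && any(rv_any)) {
    lvb <- trace_boundary(fill_holes(lv_cav | lv_myo))
    sept <- dist_to_pixels(lvb, rv_any) <= adjacency_px
    if (any(sept)) {
      sp <- lvb[sept, , drop = FALSE]
      if (!is.null(out$epicardium) && nrow(out$epicardium)) {
        # the classes are disjoint: junction points where the LV boundary
        # coincides with the outer boundary stay epicardial
        keep <- vapply(seq_len(nrow(sp)), function(i)
          min(sqrt(rowSums(sweep(out$epicardium, 2, sp[i, ])^2))) > 0.75, TRUE)
        sp <- sp[keep, , drop = FALSE]
      }
      if (nrow(sp)) out$septum <- sp
    }
  }
  structure(c(out, list(view = view)), class = "contour_set")
}

# resample an ordered polyline to approximately `spacing` arc length.
# Polylines may carry gaps (e.g. the septal interface removed from an RV
# loop): runs separated by jumps larger than `gap` are resampled
# independently, never bridged.
polyline_resample <- function(pts, spacing, gap = 3) {
  if (nrow(pts) < 3) return(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  breaks <- which(seg > gap)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, nrow(pts))
  out <- lapply(seq_along(starts), function(k) {
    piece <- pts[starts[k]:ends[k], , drop = FALSE]
    if (nrow(piece) < 2) return(piece)
    sg <- sqrt(rowSums((piece[-1, , drop = FALSE] -
                        piece[-nrow(piece), , drop = FALSE])^2))
    s <- c(0, cumsum(sg))
    total <- s[length(s)]
    if (total <= spacing) return(piece[c(1, nrow(piece)), , drop = FALSE])
    targets <- seq(0, total, by = spacing)
    idx <- pmin(findInterval(targets, s, rightmost.closed = TRUE), nrow(piece) - 1)
    t0 <- (targets - s[idx]) / pmax(s[idx + 1] - s[idx], 1e-12)
    piece[idx, , drop = FALSE] * (1 - t0) +
      piece[idx + 1, , drop = FALSE] * t0
  })
  do.call(rbind, out)
}

#' Lift 2D contours and landmarks into patient coordinates
#'
#' Maps every contour point and named landmark through the series' affine
#' image-to-patient transform, preserving class and name labels.
#'
#' @param contours a `contour_set` (or NULL).
#' @param landmarks_px optional named n x 2 matrix of 0-based pixel points.
#' @param meta the series' [plane_meta()].
#' @return List with `contour_points` (class -> n x 3 mm) and
#'   `landmark_points` (named n x 3 mm matrix).
#' @export
lift_to_3d <- function(contours, landmarks_px = NULL, meta) {
  cp <- list()
  if (!is.null(contours)) {
    for (cl in intersect(names(contours),
                         c("lv_endo", "rv_endo", "septum", "epicardium"))) {
      pts <- contours[[cl]]
      if (is.matrix(pts) && nrow(pts) > 0)
        cp[[cl]] <- rbind(pixel_to_patient(meta, pts))
    }
  }
  lp <- NULL
  if (!is.null(landmarks_px) && nrow(rbind(landmarks_px)) > 0) {
    lp <- rbind(pixel_to_patient(meta, rbind(landmarks_px)))
    rownames(lp) <- rownames(rbind(landmarks_px))
  }
  list(contour_points = cp, landmark_points = lp)
}

#' Assemble guide points for the ED and ES phases
#'
#' Merges per-view contours (from segmentation masks) and landmarks across
#' series into two phase-tagged guide point sets.  ED is fixed at frame 0
#' (ECG-gated acquisition starts at end-diastole); ES is the supplied frame.
#' Contours are traced per view, lifted to patient coordinates, trimmed at
#' the valve base plane (estimated from the MV/TV landmarks and the LV
#' apex), and resampled to ~2 mm arc-length spacing.
#'
#' @param predictions named list (per series) of lists with elements `view`,
#'   `meta`, optionally `optimal` (SAx), `masks` (named list frame -> label
#'   image) and `landmarks` (named list frame -> named n x 2 pixel matrix).
#' @param es_frame 0-based end-systolic frame.
#' @param contour_spacing_mm target guide-point spacing along contours.
#' @return List with elements `ed` and `es`, each a `guide_point_set`:
#'   `contour_points` (class -> n x 3), `landmark_points` (named matrix),
#'   `phase`, `provenance` (data.frame item/series).
#' @export
assemble_guide_points <- function(predictions, es_frame,
                                  contour_spacing_mm = 2) {
  sax_ok <- vapply(predictions, function(p)
    identical(p$view, "SAx") && isTRUE(p$optimal), TRUE)
  if (!any(sax_ok)) stop("no optimal SAx slices: model cannot be fitted")
  build_phase <- function(frame, tag) {
    cp <- list()
    lp <- NULL
    prov <- list()
    key <- as.character(frame)
    for (sid in names(predictions)) {
      p <- predictions[[sid]]
      if (identical(p$view, "SAx") && !isTRUE(p$optimal)) next
      spacing_px <- contour_spacing_mm / p$meta$row_spacing_mm
      ctr <- NULL
      if (!is.null(p$masks) && !is.null(p$masks[[key]]))
        ctr <- suppressWarnings(extract_contours(p$masks[[key]], p$view))
      lmk <- if (!is.null(p$landmarks)) p$landmarks[[key]] else NULL
      if (is.null(ctr) && is.null(lmk)) next
      if (!is.null(ctr))
        for (cl in intersect(names(ctr), c("lv_endo", "rv_endo", "septum",
                                           "epicardium")))
          ctr[[cl]] <- polyline_resample(ctr[[cl]], spacing_px)
      lifted <- lift_to_3d(ctr, lmk, p$meta)
      for (cl in names(lifted$contour_points)) {
        cp[[cl]] <- rbind(cp[[cl]], lifted$contour_points[[cl]])
        prov[[length(prov) + 1]] <- data.frame(
          item = cl, series = sid, n = nrow(lifted$contour_points[[cl]]))
      }
      if (!is.null(lifted$landmark_points)) {
        lp <- rbind(lp, lifted$landmark_points)
        prov[[length(prov) + 1]] <- data.frame(
          item = paste(rownames(lifted$landmark_points), collapse = ","),
          series = sid, n = nrow(lifted$landmark_points))
      }
    }
    # trim contour points above the valve base plane
    if (!is.null(lp) && any(grepl("^(MV|TV)[0-9]$", rownames(lp)))) {
      base_pts <- lp[grepl("^(MV|TV)[0-9]$", rownames(lp)), , drop = FALSE]
      ctr_base <- colMeans(base_pts)
      apex <- if ("LV_APEX" %in% rownames(lp))
        colMeans(lp[rownames(lp) == "LV_APEX", , drop = FALSE])
      else ctr_base - c(0, 0, 1)
      ax <- ctr_base - apex
      ax <- ax / sqrt(sum(ax^2))
      for (cl in names(cp)) {
        d <- drop(sweep(cp[[cl]], 2, ctr_base) %*% ax)
        cp[[cl]] <- cp[[cl]][d < -1, , drop = FALSE]
      }
    }
    structure(list(contour_points = cp, landmark_points = lp, phase = tag,
                   provenance = do.call(rbind, prov)),
              class = "guide_point_set")
  }
  list(ed = build_phase(0L, "ED"), es = build_phase(es_frame, "ES"))
}

#' @export
print.guide_point_set <- function(x, ...) {
  cat("guide_point_set (", x$phase, "):\n", sep = "")
  for (cl in names(x$contour_points))
    cat(sprintf("  %-12s %5d points\n", cl, nrow(x$contour_points[[cl]])))
  if (!is.null(x$landmark_points))
    cat("  landmarks:", paste(sort(unique(rownames(x$landmark_points))),
                              collapse = " "), "\n")
  invisible(x)
}
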