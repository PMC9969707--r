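# Label codecs for the five pipeline stages.  "Normalized" Gaussians are
# peak-normalized to 1 (the phase value rises to 1 during systole), not
# unit-sum.

#' The eight cine view categories
#' @export
VIEW_LABELS <- c("2Ch LT", "2Ch RT", "3Ch", "4Ch", "LVOT", "RVOT", "SAx", "OTHER")

#' Encode an end-systolic frame as a Gaussian phase curve
#'
#' Per-frame supervision for phase selection: a peak-normalized Gaussian
#' centred on the end-systolic frame, `values[t] = exp(-(t-es)^2/(2 sigma^2))`,
#' rising to 1 during systole and falling toward 0 during diastole.
#'
#' @param es_frame 0-based end-systolic frame index.
#' @param n_frames number of cardiac phases.
#' @param sigma Gaussian width in frames (default 4).
#' @return Numeric vector of length `n_frames` in `[0, 1]` (class
#'   `phase_curve`), with `values[es_frame + 1] == 1`.
#' @export
encode_phase_curve <- function(es_frame, n_frames, sigma = 4) {
  if (sigma <= 0) stop("sigma must be positive")
  stopifnot(es_frame >= 0, es_frame < n_frames)
  t <- 0:(n_frames - 1)
  structure(exp(-(t - es_frame)^2 / (2 * sigma^2)), class = "phase_curve")
}

#' Decode the end-systolic frame from one or more phase curves
#'
#' Averages the curves (restricted to valid frames, e.g. before zero-padding)
#' over slices and returns the 0-based argmax.  Ties break toward the
#' earliest frame; an all-flat average warns about low confidence.
#'
#' @param curves a numeric vector or list of equal-length phase curves.
#' @param validity optional logical vector (or list of vectors) marking valid
#'   frames.
#' @return 0-based frame index.
#' @export
decode_es_phase <- function(curves, validity = NULL) {
  if (!is.list(curves)) curves <- list(curves)
  if (!length(curves)) stop("no phase curves supplied")
  n <- length(curves[[1]])
  stopifnot(all(vapply(curves, length, 0L) == n))
  if (is.null(validity)) validity <- rep(TRUE, n)
  if (!is.list(validity)) validity <- rep(list(validity), length(curves))
  num <- den <- numeric(n)
  for (i in seq_along(curves)) {
    v <- validity[[i]]
    num[v] <- num[v] + as.numeric(curves[[i]])[v]
    den[v] <- den[v] + 1
  }
  if (all(den == 0)) stop("all frames invalid")
  avg <- ifelse(den > 0, num / den, -Inf)
  if (diff(range(avg[is.finite(avg)])) == 0)
    warning("flat phase curve: low-confidence ES estimate")
  which.max(avg) - 1L
}

#' Encode landmarks as Gaussian heatmaps
#'
#' One peak-normalized Gaussian map per landmark:
#' `H(x) = exp(-||x - x_L||^2 / (2 sigma^2))`, maximum 1 at the landmark
#' pixel.
#'
#' @param points named n x 2 matrix of 0-based `(row, col)` landmark
#'   positions (fractional allowed).
#' @param shape integer(2) `(H, W)`.
#' @param sigma Gaussian width in pixels (default 12).
#' @return `H x W x n` array with landmark names on the third dimension.
#' @export
encode_landmark_heatmap <- function(points, shape, sigma = 12) {
  points <- rbind(points)
  if (any(points[, 1] < 0) || any(points[, 1] > shape[1] - 1) ||
      any(points[, 2] < 0) || any(points[, 2] > shape[2] - 1))
    stop("landmark outside image bounds")
  H <- shape[1]; W <- shape[2]
  out <- array(0, c(H, W, nrow(points)),
               dimnames = list(NULL, NULL, rownames(points)))
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  for (i in seq_len(nrow(points)))
    out[, , i] <- exp(-((rr - points[i, 1])^2 + (cc - points[i, 2])^2) /
                      (2 * sigma^2))
  out
}

#' Decode a landmark heatmap to a sub-pixel location
#'
#' Finds the global maximum and refines it to sub-pixel precision by a
#' log-parabolic fit through the maximum and its axis neighbours (exact for
#' Gaussian peaks, including peaks clipped by the image border).  Where the
#' fit is undefined (border maxima, plateaus, non-positive neighbours) the
#' estimate falls back to the intensity-weighted centroid of the pixels at
#' or above half maximum inside the maximum's 8-connected component.
#' Confidence is the maximum value; an all-zero map decodes as absent (NA
#' location, confidence 0).
#'
#' @param map non-negative 2D matrix.
#' @return List with `point` (0-based fractional `(row, col)` or `c(NA, NA)`)
#'   and `confidence`.
#' @export
decode_heatmap <- function(map) {
  if (any(map < 0)) stop("heatmap must be non-negative")
  mx <- max(map)
  if (mx == 0) return(list(point = c(NA_real_, NA_real_), confidence = 0))
  pk <- unname(which(map == mx, arr.ind = TRUE)[1, ])
  comp <- cpp_flood_component(map >= 0.5 * mx, pk[1], pk[2])
  idx <- which(comp, arr.ind = TRUE)
  wts <- map[comp] - 0.5 * mx
  if (sum(wts) == 0) wts <- wts + 1  # single-pixel plateau
  ctr <- c(sum((idx[, 1] - 1) * wts), sum((idx[, 2] - 1) * wts)) / sum(wts)
  # log-parabolic sub-pixel refinement along each axis
  refine <- function(vm, v0, vp, x0) {
    if (vm <= 0 || vp <= 0 || v0 <= 0) return(NA_real_)
    den <- log(vm) - 2 * log(v0) + log(vp)
    if (den >= 0) return(NA_real_)
    off <- 0.5 * (log(vm) - log(vp)) / den
    if (abs(off) > 1) return(NA_real_)
    x0 + off
  }
  pt <- ctr
  if (pk[1] > 1 && pk[1] < nrow(map) && pk[2] > 1 && pk[2] < ncol(map)) {
    r <- refine(map[pk[1] - 1, pk[2]], mx, map[pk[1] + 1, pk[2]], pk[1] - 1)
    c_ <- refine(map[pk[1], pk[2] - 1], mx, map[pk[1], pk[2] + 1], pk[2] - 1)
    if (!is.na(r) && !is.na(c_)) pt <- c(r, c_)
  }
  list(point = pt, confidence = mx)
}

#' Segmentation class map for a cine view
#'
#' Which myocardial structures are labeled in each segmented view: LV cavity
#' and myocardium in 2Ch LT; RV cavity and myocardium in 2Ch RT and RVOT;
#' all four in 3Ch, 4Ch and SAx.  Papillary muscles and trabeculae are part
#' of the blood pool by convention.  LVOT and OTHER views are not segmented.
#'
#' @param view one of the segmented view names.
#' @return Named integer vector structure -> label (background is 0).
#' @export
encode_segmentation_classes <- function(view) {
  switch(view,
    "2Ch LT" = c(background = 0L, "LV cavity" = 1L, "LV myocardium" = 2L),
    "2Ch RT" = ,
    "RVOT"   = c(background = 0L, "RV cavity" = 1L, "RV myocardium" = 2L),
    "3Ch" = ,
    "4Ch" = ,
    "SAx" = c(background = 0L, "LV cavity" = 1L, "LV myocardium" = 2L,
              "RV cavity" = 3L, "RV myocardium" = 4L),
    stop("view '", view, "' is not segmented"))
}

#' Landmark set localized in a cine view
#'
#' Mitral and aortic valve inserts in 3Ch; mitral and tricuspid inserts plus
#' the LV apex in 4Ch; pulmonary valve inserts in RVOT; RV inserts in SAx.
#'
#' @param view one of `"3Ch"`, `"4Ch"`, `"RVOT"`, `"SAx"`.
#' @return Character vector of landmark names.
#' @export
landmark_set_for_view <- function(view) {
  switch(view,
    "3Ch" = c("MV1", "MV2", "AV1", "AV2"),
    "4Ch" = c("MV1", "MV2", "TV1", "TV2", "LV_APEX"),
    "RVOT" = c("PV1", "PV2"),
    "SAx" = c("RV1", "RV2"),
    stop("no landmarks are localized in view '", view, "'"))
}
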