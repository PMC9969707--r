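#' Image-plane geometry metadata
#'
#' Describes how a 2D pixel grid sits in the patient coordinate system
#' (right-handed LPS, millimetres, following the DICOM convention).  Pixel
#' indices are 0-based `(row, col)` and refer to pixel centers; `origin_mm`
#' is the patient position of the center of pixel (0, 0).
#'
#' @param origin_mm numeric(3), position of pixel (0,0) center, mm.
#' @param row_dir,col_dir unit numeric(3) direction cosines of increasing row
#'   and column index; must be orthonormal.
#' @param row_spacing_mm,col_spacing_mm pixel spacing along rows/columns, mm.
#' @param slice_thickness_mm slice thickness, mm.
#' @return An object of class `plane_meta`.
#' @export
plane_meta <- function(origin_mm, row_dir, col_dir,
                       row_spacing_mm, col_spacing_mm, slice_thickness_mm = 8) {
  origin_mm <- as.numeric(origin_mm)
  row_dir <- as.numeric(row_dir)
  col_dir <- as.numeric(col_dir)
  stopifnot(length(origin_mm) == 3, length(row_dir) == 3, length(col_dir) == 3,
            row_spacing_mm > 0, col_spacing_mm > 0, slice_thickness_mm > 0)
  if (abs(sqrt(sum(row_dir^2)) - 1) > 1e-6 || abs(sqrt(sum(col_dir^2)) - 1) > 1e-6)
    stop("row_dir and col_dir must be unit vectors")
  if (abs(sum(row_dir * col_dir)) > 1e-6)
    stop("row_dir and col_dir must be orthogonal")
  structure(list(origin_mm = origin_mm, row_dir = row_dir, col_dir = col_dir,
                 row_spacing_mm = row_spacing_mm, col_spacing_mm = col_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm),
            class = "plane_meta")
}

#' Map 0-based pixel coordinates to patient coordinates
#'
#' The affine image-to-patient map: `origin + row * row_spacing * row_dir +
#' col * col_spacing * col_dir`.  Accepts a single `(row, col)` pair or an
#' n x 2 matrix; coordinates may be fractional (sub-pixel).
#'
#' @param meta a [plane_meta()] object.
#' @param p numeric(2) `(row, col)` or an n x 2 matrix of such pairs.
#' @return numeric(3) point, or an n x 3 matrix, in patient mm.
#' @export
pixel_to_patient <- function(meta, p) {
  p <- rbind(p)
  if (!all(is.finite(p))) stop("non-finite pixel coordinates")
  out <- meta$origin_mm[col(matrix(0, nrow(p), 3))] +
    outer(p[, 1] * meta$row_spacing_mm, meta$row_dir) +
    outer(p[, 2] * meta$col_spacing_mm, meta$col_dir)
  if (nrow(out) == 1) drop(out) else out
}

#' Map patient coordinates back to in-plane pixel coordinates
#'
#' Inverse of [pixel_to_patient()] for points lying in (or projected onto)
#' the image plane.
#'
#' @param meta a [plane_meta()] object.
#' @param x numeric(3) patient point or n x 3 matrix.
#' @return numeric(2) `(row, col)` or n x 2 matrix (0-based, fractional).
#' @export
patient_to_pixel <- function(meta, x) {
  x <- rbind(x)
  if (!all(is.finite(x))) stop("non-finite patient coordinates")
  d <- sweep(x, 2, meta$origin_mm)
  out <- cbind(d %*% meta$row_dir / meta$row_spacing_mm,
               d %*% meta$col_dir / meta$col_spacing_mm)
  if (nrow(out) == 1) drop(out) else out
}

# signed distance of patient points from the image plane, mm
plane_offset <- function(meta, x) {
  n <- vcross(meta$row_dir, meta$col_dir)
  drop(sweep(rbind(x), 2, meta$origin_mm) %*% n)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Cine image series
#'
#' A single-plane cine acquisition: an `n_frames x rows x cols` intensity
#' array plus its plane geometry.
#'
#' @param frames 3D numeric array `(n_frames, rows, cols)` or a single 2D image.
#' @param meta a [plane_meta()] object.
#' @param series_id character identifier, unique within a study.
#' @return An object of class `cine_series`.
#' @export
cine_series <- function(frames, meta, series_id) {
  if (length(dim(frames)) == 2) frames <- array(frames, c(1, dim(frames)))
  stopifnot(length(dim(frames)) == 3, dim(frames)[1] >= 1,
            inherits(meta, "plane_meta"), is.character(series_id))
  structure(list(frames = frames, meta = meta, series_id = series_id),
            class = "cine_series")
}

#' Number of frames in a cine series
#' @param series a [cine_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(series) dim(series$frames)[1]

#' Extract one frame of a cine series
#' @param series a [cine_series()].
#' @param t 1-based frame position in the array (cardiac phase `t0` is at
#'   position `t0 + 1`).
#' @return 2D image matrix.
#' @export
frame_of <- function(series, t) series$frames[t, , ]

#' Cine MR study
#'
#' A collection of [cine_series()] objects with unique series ids.
#'
#' @param series list of `cine_series`.
#' @param study_id character identifier.
#' @return An object of class `cine_study`.
#' @export
cine_study <- function(series, study_id = "study") {
  ids <- vapply(series, `[[`, "", "series_id")
  if (anyDuplicated(ids)) stop("series ids must be unique")
  names(series) <- ids
  structure(list(series = series, study_id = study_id), class = "cine_study")
}

#' @export
print.cine_study <- function(x, ...) {
  cat("cine_study", x$study_id, "with", length(x$series), "series\n")
  for (s in x$series)
    cat(sprintf("  %-12s %d frames, %d x %d px, spacing %.2f mm\n", s$series_id,
                n_frames(s), dim(s$frames)[2], dim(s$frames)[3],
                s$meta$row_spacing_mm))
  invisible(x)
}

#' Resize a 2D image by bicubic interpolation
#'
#' Direct resize to the target shape (aspect ratio is not preserved by
#' cropping), using the Keys cubic kernel.  Deterministic; a constant image
#' stays constant.
#'
#' @param image 2D numeric matrix.
#' @param target integer(2) `(H, W)`.
#' @return `H x W` matrix.
#' @export
resize_bicubic <- function(image, target) {
  stopifnot(is.matrix(image), length(target) == 2, all(target > 0))
  cpp_resize_bicubic(image, as.integer(target[1]), as.integer(target[2]))
}

#' Min-max normalize an image to [0, 1]
#'
#' Affine map of intensities to minimum 0, maximum 1.  A constant image maps
#' to all zeros with a warning.
#'
#' @param image numeric array.
#' @return Array of the same shape with min 0 and max 1.
#' @export
minmax_normalize <- function(image) {
  r <- range(image)
  if (diff(r) == 0) {
    warning("constant image: returning all zeros")
    return(image * 0)
  }
  (image - r[1]) / diff(r)
}

# per-image standardization (mean 0, sd 1); zero-centered network input
standardize_image <- function(image) {
  s <- sd(image)
  if (s == 0) return(image * 0)
  (image - mean(image)) / s
}

#' Zero-pad a cine series along time
#'
#' Pads the frame axis with all-zero frames up to `n` frames so that inputs
#' with fewer cardiac phases share a consistent temporal size, and returns a
#' validity mask marking the true frames.
#'
#' @param cine a [cine_series()].
#' @param n target frame count (default 30).
#' @return List with `frames` (`n x rows x cols`) and `valid` (logical n).
#' @export
pad_cine <- function(cine, n = 30L) {
  nf <- n_frames(cine)
  if (nf > n) stop("series has more than ", n, " frames; refusing to truncate")
  d <- dim(cine$frames)
  out <- array(0, c(n, d[2], d[3]))
  out[seq_len(nf), , ] <- cine$frames
  list(frames = out, valid = seq_len(n) <= nf)
}

#' Stack temporally adjacent frames as channels
#'
#' Builds the 5-channel temporal input for landmark localization: frames
#' `(t-2, t-1, t, t+1, t+2)` with cyclic indexing modulo the frame count
#' (the cine loop is periodic).
#'
#' @param cine a [cine_series()].
#' @param t 0-based frame index (cardiac phase numbering).
#' @return `rows x cols x 5` array, channels in temporal order.
#' @export
stack_temporal_channels <- function(cine, t) {
  nf <- n_frames(cine)
  stopifnot(t >= 0, t < nf)
  idx <- ((t + c(-2, -1, 0, 1, 2)) %% nf) + 1
  d <- dim(cine$frames)
  out <- array(0, c(d[2], d[3], 5))
  for (k in 1:5) out[, , k] <- cine$frames[idx[k], , ]
  out
}

# ---- study I/O: NIfTI per series + JSON manifest ---------------------------

meta_to_list <- function(meta) {
  lapply(unclass(meta), as.numeric)
}

list_to_meta <- function(l) {
  plane_meta(l$origin_mm, l$row_dir, l$col_dir,
             l$row_spacing_mm, l$col_spacing_mm, l$slice_thickness_mm)
}

#' Write a cine study to disk
#'
#' One NIfTI (.nii.gz) volume per series (frames stored along the third
#' dimension) plus a JSON manifest recording, for every series, its file,
#' plane geometry and (optionally) known view label.
#'
#' @param study a [cine_study()].
#' @param dir output directory (created if needed).
#' @param view_labels optional named character vector series_id -> view label.
#' @return Invisibly, the manifest path.
#' @export
write_study <- function(study, dir, view_labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(study_id = study$study_id, series = list())
  for (s in study$series) {
    file <- paste0(s$series_id, ".nii.gz")
    vol <- aperm(s$frames, c(2, 3, 1))  # rows x cols x frames
    RNifti::writeNifti(RNifti::asNifti(vol), file.path(dir, file))
    entry <- c(list(series_id = s$series_id, file = file,
                    n_frames = n_frames(s)), meta_to_list(s$meta))
    if (!is.null(view_labels) && s$series_id %in% names(view_labels))
      entry$view <- unname(view_labels[[s$series_id]])
    manifest$series[[s$series_id]] <- entry
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cine study written by [write_study()]
#'
#' @param dir directory containing `manifest.json` and the NIfTI series.
#' @return List with `study` (a [cine_study()]) and `view_labels` (named
#'   character vector, possibly empty).
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE, simplifyDataFrame = FALSE)
  series <- list()
  labels <- character()
  for (entry in manifest$series) {
    vol <- as.array(RNifti::readNifti(file.path(dir, entry$file)))
    if (length(dim(vol)) == 2) vol <- array(vol, c(dim(vol), 1))
    frames <- aperm(vol, c(3, 1, 2))
    series[[entry$series_id]] <-
      cine_series(frames, list_to_meta(entry), entry$series_id)
    if (!is.null(entry$view)) labels[entry$series_id] <- entry$view
  }
  list(study = cine_study(unname(series), manifest$study_id),
       view_labels = labels)
}
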