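# Training and inference for the five pipeline stages, plus phantom dataset
# builders and the data augmentation used during training.

#' Training configuration for a pipeline stage
#'
#' Loss functions follow the stage definitions (categorical cross-entropy
#' for view/slice, mean squared error for phase curves and landmark
#' heatmaps, cross-entropy plus Dice for segmentation); the optimizer is
#' stochastic gradient descent with momentum.  Defaults are sized for the
#' package's small from-scratch networks.
#'
#' @param stage one of `"view"`, `"slice"`, `"phase"`, `"landmark"`,
#'   `"segment"`.
#' @param epochs training epochs (>= 1).
#' @param batch_size gradient-accumulation batch size.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum in `[0, 1)`.
#' @param seed integer seed: weight initialization, shuffling, augmentation.
#' @param augmentation named list of augmentation magnitudes (see
#'   [augment()]); `NULL` disables augmentation.
#' @param input_px network input size (square).
#' @param clip_norm global gradient-norm clip (stabilizes SGD on the small
#'   networks).
#' @param max_restarts seeded re-initializations allowed when a trained
#'   network fails its training-set quality gate (the sparse-target stages
#'   occasionally settle into a constant-output optimum; restarts are the
#'   standard remedy for small from-scratch networks).  Deterministic:
#'   attempt `k` uses `seed + 1000 k`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(stage, epochs = NULL, batch_size = NULL,
                         learning_rate = NULL, momentum = 0.9, seed = 1L,
                         augmentation = NULL, input_px = NULL,
                         clip_norm = 5, max_restarts = NULL) {
  stage <- match.arg(stage, c("view", "slice", "phase", "landmark", "segment"))
  defaults <- list(
    view = list(epochs = 16L, batch_size = 8L, learning_rate = 0.02,
                input_px = 128L,
                augmentation = list(rotation = 10, zoom = 0.1, translation = 0.05)),
    slice = list(epochs = 16L, batch_size = 8L, learning_rate = 0.02,
                 input_px = 128L,
                 augmentation = list(rotation = 10, zoom = 0.1, translation = 0.05)),
    phase = list(epochs = 40L, batch_size = 4L, learning_rate = 0.05,
                 input_px = 32L, augmentation = list(time_roll = TRUE)),
    landmark = list(epochs = 20L, batch_size = 4L, learning_rate = 0.05,
                    input_px = 128L, augmentation = NULL),
    segment = list(epochs = 20L, batch_size = 4L, learning_rate = 0.05,
                   input_px = 128L, augmentation = NULL))
  d <- defaults[[stage]]
  cfg <- list(stage = stage,
              epochs = as.integer(epochs %||% d$epochs),
              batch_size = as.integer(batch_size %||% d$batch_size),
              learning_rate = learning_rate %||% d$learning_rate,
              momentum = momentum, seed = as.integer(seed),
              augmentation = if (missing(augmentation)) d$augmentation
                             else augmentation,
              input_px = as.integer(input_px %||% d$input_px),
              clip_norm = clip_norm,
              max_restarts = as.integer(max_restarts %||%
                switch(stage, phase = 3L, landmark = 3L, 0L)))
  stopifnot(cfg$epochs >= 1, cfg$momentum >= 0, cfg$momentum < 1)
  structure(cfg, class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AUGMENT_NAMES <- c("rotation", "zoom", "translation", "brightness", "contrast",
                   "noise", "crop", "time_roll", "mirror")

#' Randomly augment an image (and its spatial/temporal label)
#'
#' Geometric transforms (rotation in degrees, zoom fraction, translation
#' fraction, mirroring) are applied identically to the image and to spatial
#' labels (masks by nearest-neighbour, heatmaps bilinearly, point labels
#' analytically); `time_roll` cyclically shifts a cine stack together with
#' its end-systolic frame label; photometric transforms (brightness,
#' contrast, noise) affect only the image.  Deterministic under `seed`.
#'
#' @param image 2D matrix, `H x W x C` channel array, or `n x H x W` cine
#'   stack (for `time_roll`).
#' @param label `NULL`, or a list with `type` in `"class"`, `"points"`,
#'   `"mask"`, `"heatmap"`, `"es"` and the corresponding payload.
#' @param spec named list of magnitudes, a subset of `rotation` (deg),
#'   `zoom`, `translation`, `brightness`, `contrast`, `noise` (sd),
#'   `crop`, `time_roll` (logical), `mirror` (logical).
#' @param seed integer seed.
#' @return List with transformed `image` and `label`.
#' @export
augment <- function(image, label = NULL, spec = list(), seed = 1L) {
  unknown <- setdiff(names(spec), AUGMENT_NAMES)
  if (length(unknown)) stop("unknown augmentation(s): ", paste(unknown, collapse = ", "))
  with_seed(seed, {
    cine <- length(dim(image)) == 3 && !is.null(label) &&
      identical(label$type, "es")
    if (isTRUE(spec$time_roll) && cine) {
      n <- dim(image)[1]
      k <- sample(0:(n - 1), 1)
      if (k > 0) {
        image <- image[((seq_len(n) - 1 - k) %% n) + 1, , , drop = FALSE]
        label$es <- (label$es + k) %% n
      }
    }
    theta <- if (!is.null(spec$rotation)) runif(1, -1, 1) * spec$rotation * pi / 180 else 0
    zoom <- if (!is.null(spec$zoom)) 1 + runif(1, -1, 1) * spec$zoom else 1
    if (!is.null(spec$crop)) zoom <- zoom * runif(1, 1, 1 + spec$crop)
    hw <- if (length(dim(image)) == 3) dim(image)[if (cine) c(2, 3) else c(1, 2)]
          else dim(image)
    tr <- if (!is.null(spec$translation))
      runif(2, -1, 1) * spec$translation * hw else c(0, 0)
    mirror <- isTRUE(spec$mirror) && runif(1) < 0.5
    geom <- abs(theta) > 0 || zoom != 1 || any(tr != 0) || mirror

    flip_img <- function(m) m[, rev(seq_len(ncol(m)))]
    warp <- function(m, interp) {
      if (mirror) m <- flip_img(m)
      if (abs(theta) > 0 || zoom != 1 || any(tr != 0)) {
        Rinv <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2) / zoom
        m <- cpp_affine_warp(m, Rinv, as.numeric(-Rinv %*% tr), interp,
                             fill = m[1, 1])
      }
      m
    }
    map_points <- function(p) {
      # forward map matching warp(): mirror, then rotate/zoom about center + t
      ctr <- (hw - 1) / 2
      p <- rbind(p)
      if (mirror) p[, 2] <- (hw[2] - 1) - p[, 2]
      Rf <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2) * zoom
      sweep(sweep(p, 2, ctr) %*% t(Rf), 2, ctr + tr, `+`)
    }

    if (geom) {
      if (length(dim(image)) == 3) {
        d <- dim(image)
        if (cine) {
          for (t in seq_len(d[1])) image[t, , ] <- warp(image[t, , ], 1L)
        } else {
          for (ch in seq_len(d[3])) image[, , ch] <- warp(image[, , ch], 1L)
        }
      } else image <- warp(image, 1L)
      if (!is.null(label)) {
        if (identical(label$type, "mask")) label$mask <- warp(label$mask, 0L)
        if (identical(label$type, "heatmap"))
          for (ch in seq_len(dim(label$maps)[3]))
            label$maps[, , ch] <- warp(label$maps[, , ch], 1L)
        if (identical(label$type, "points")) label$points <- map_points(label$points)
      }
    }
    if (!is.null(spec$brightness))
      image <- image + runif(1, -1, 1) * spec$brightness * diff(range(image))
    if (!is.null(spec$contrast))
      image <- mean(image) + (image - mean(image)) *
        (1 + runif(1, -1, 1) * spec$contrast)
    if (!is.null(spec$noise) && spec$noise > 0)
      image <- image + array(rnorm(length(image), 0, spec$noise), dim(image))
    list(image = image, label = label)
  })
}

# ---- input preprocessing ---------------------------------------------------

prep_image <- function(img, px, normalize = c("standardize", "minmax")) {
  normalize <- match.arg(normalize)
  if (!all(dim(img) == c(px, px))) img <- resize_bicubic(img, c(px, px))
  if (normalize == "standardize") standardize_image(img)
  else suppressWarnings(minmax_normalize(img))
}

prep_stack <- function(stack, px) {
  # 5 temporal channels plus two normalized coordinate channels: symmetric
  # landmarks (the two inserts of a valve) are locally similar, and the
  # coordinate channels give the network the global left/right context a
  # small receptive field cannot supply
  d <- dim(stack)
  out <- array(0, c(px, px, d[3] + 2L))
  for (ch in seq_len(d[3]))
    out[, , ch] <- if (all(d[1:2] == px)) stack[, , ch]
                   else resize_bicubic(stack[, , ch], c(px, px))
  r <- range(out[, , seq_len(d[3])])
  if (diff(r) > 0)
    out[, , seq_len(d[3])] <- (out[, , seq_len(d[3])] - r[1]) / diff(r)
  out[, , d[3] + 1L] <- matrix(seq(0, 1, length.out = px), px, px)
  out[, , d[3] + 2L] <- matrix(seq(0, 1, length.out = px), px, px, byrow = TRUE)
  out
}

prep_cine <- function(cine_frames, px, n = 30L, crop = 0.5) {
  # center-crop before resizing: mid-ventricular SAx frames are heart-
  # centred, and cropping quadruples the fraction of the frame occupied by
  # the contracting blood pool (the signal the phase network needs)
  nf <- dim(cine_frames)[1]
  stopifnot(nf <= n)
  d <- dim(cine_frames)[2:3]
  keep_r <- round(d[1] / 2 + c(-1, 1) * d[1] * crop / 2)
  keep_c <- round(d[2] / 2 + c(-1, 1) * d[2] * crop / 2)
  keep_r <- max(1, keep_r[1]):min(d[1], keep_r[2])
  keep_c <- max(1, keep_c[1]):min(d[2], keep_c[2])
  cropped <- cine_frames[, keep_r, keep_c, drop = FALSE]
  out <- array(0, c(n, px, px))
  r <- range(cropped)
  for (t in seq_len(nf)) {
    f <- if (all(dim(cropped)[2:3] == px)) cropped[t, , ]
         else resize_bicubic(cropped[t, , ], c(px, px))
    out[t, , ] <- if (diff(r) > 0) (f - r[1]) / diff(r) else f * 0
  }
  # subtract the temporal mean frame: static anatomy cancels and the
  # contracting blood pool becomes the dominant per-frame signal
  mean_frame <- apply(out[seq_len(nf), , , drop = FALSE], c(2, 3), mean)
  for (t in seq_len(nf)) out[t, , ] <- out[t, , ] - mean_frame
  list(frames = out, valid = seq_len(n) <= nf)
}

# ---- losses ----------------------------------------------------------------

softmax_pixelwise <- function(logits) {
  m <- apply(logits, c(1, 2), max)
  e <- exp(sweep(logits, c(1, 2), m))
  sweep(e, c(1, 2), apply(e, c(1, 2), sum), "/")
}

segment_loss_grad <- function(logits, mask) {
  # cross-entropy + soft Dice over all classes; mask is 0-based labels
  C <- dim(logits)[3]
  p <- softmax_pixelwise(logits)
  npix <- dim(logits)[1] * dim(logits)[2]
  onehot <- array(0, dim(logits))
  for (c_ in seq_len(C)) onehot[, , c_] <- (mask == c_ - 1)
  ce <- -sum(onehot * log(pmax(p, 1e-12))) / npix
  dLdp_ce <- -onehot / pmax(p, 1e-12) / npix
  # soft dice per class
  dLdp_d <- array(0, dim(p))
  dsum <- 0
  for (c_ in seq_len(C)) {
    pc <- p[, , c_]; yc <- onehot[, , c_]
    num <- 2 * sum(pc * yc); den <- sum(pc) + sum(yc) + 1e-8
    dsum <- dsum + num / den
    dLdp_d[, , c_] <- -(2 * yc * den - num) / den^2 / C
  }
  dice_loss <- 1 - dsum / C
  dLdp <- dLdp_ce + dLdp_d
  inner <- apply(dLdp * p, c(1, 2), sum)
  dlogits <- p * sweep(dLdp, c(1, 2), inner)
  list(loss = ce + dice_loss, dlogits = dlogits, probs = p)
}

# ---- training --------------------------------------------------------------

#' Train a pipeline stage network
#'
#' Builds the stage's small network, checks the dataset against the stage
#' contract, and optimizes it by seeded SGD with momentum.  Examples are
#' lists per stage: view/slice `list(image, label)` (label: view name or
#' logical `optimal`); phase `list(cine, es)` (cine `n x H x W`, `es`
#' 0-based); landmark `list(stack, points)` (5-channel stack, named 0-based
#' pixel points); segment `list(image, mask)` (0-based label mask).
#'
#' @param stage stage name (see [train_config()]).
#' @param dataset nonempty list of examples.
#' @param config a [train_config()] (defaults to `train_config(stage)`).
#' @param view for landmark/segment stages, the cine view the network serves
#'   (fixes the landmark set / class map).
#' @param quiet suppress progress output.
#' @return An object of class `stage_model` with the trained network and a
#'   per-epoch loss log.
#' @export
train_stage <- function(stage, dataset, config = train_config(stage),
                        view = NULL, quiet = TRUE) {
  stopifnot(length(dataset) >= 1)
  stage <- match.arg(stage, c("view", "slice", "phase", "landmark", "segment"))
  check_stage_dataset(stage, dataset, view)
  best <- NULL
  best_q <- Inf
  for (attempt in 0:config$max_restarts) {
    model <- train_stage_once(stage, dataset, config,
                              seed = config$seed + 1000L * attempt,
                              view = view, quiet = quiet)
    q <- stage_train_quality(model, dataset)
    if (q$value <= q$gate) return(model)
    if (q$value < best_q) { best <- model; best_q <- q$value }
    if (!quiet) message(sprintf("[%s] attempt %d failed its quality gate (%.3f > %.3f)",
                                stage, attempt + 1, q$value, q$gate))
  }
  warning("stage '", stage, "' did not pass its training-set quality gate ",
          "after ", config$max_restarts + 1, " attempt(s); returning the best")
  best
}

train_stage_once <- function(stage, dataset, config, seed, view, quiet) {
  px <- config$input_px
  with_seed(seed, {
    net <- switch(stage,
      view = nn_classifier_init(8L, px),
      slice = nn_classifier_init(2L, px),
      phase = nn_phase_init(frame_px = px),
      landmark = nn_unet_init(7L, length(landmark_set_for_view(view)), px),
      segment = nn_unet_init(1L, max(encode_segmentation_classes(view)) + 1L, px))
    vel <- list()
    log <- numeric(0)
    aug_counter <- 0L
    for (epoch in seq_len(config$epochs)) {
      # step decay: halve the learning rate at 1/3 and 2/3 of training
      lr <- config$learning_rate *
        0.5^(findInterval(epoch, config$epochs * c(1 / 3, 2 / 3) + 1))
      ord <- sample(seq_along(dataset))
      total <- 0
      acc <- NULL
      nacc <- 0L
      chmax <- NULL
      for (i in ord) {
        ex <- dataset[[i]]
        aug_counter <- aug_counter + 1L
        fb <- stage_forward_backward(stage, net, ex, config, view, aug_counter)
        total <- total + fb$loss
        if (!is.null(fb$chmax))
          chmax <- if (is.null(chmax)) fb$chmax else pmax(chmax, fb$chmax)
        acc <- if (is.null(acc)) fb$grads else add_grads(acc, fb$grads)
        nacc <- nacc + 1L
        if (nacc == config$batch_size || i == ord[length(ord)]) {
          acc <- scale_grads(acc, 1 / nacc)
          gn <- sqrt(sum(vapply(nn_leaves(acc), function(v) sum(v^2), 0)))
          if (!is.finite(gn)) { acc <- NULL; nacc <- 0L; next }
          if (gn > config$clip_norm)
            acc <- scale_grads(acc, config$clip_norm / gn)
          upd <- nn_update_sgd(net, acc, vel, lr, config$momentum)
          net <- upd$net
          vel <- upd$vel
          acc <- NULL
          nacc <- 0L
        }
      }
      log[epoch] <- total / length(dataset)
      if (!quiet) message(sprintf("[%s] epoch %d/%d loss %.4f", stage, epoch,
                                  config$epochs, log[epoch]))
      # dead-channel rescue: a channel whose map stayed (near-)constant for
      # a whole epoch (peak prominence below 0.25 in every sample) gets its
      # head weights re-initialized; the other channels and the shared
      # encoder go on training undisturbed
      if (stage == "landmark" && !is.null(chmax) && epoch >= 2 &&
          epoch <= 6) {
        dead <- which(chmax < 0.15)
        for (k in dead) {
          net$head$w[, k] <- rnorm(nrow(net$head$w), 0,
                                   sqrt(2 / nrow(net$head$w)))
          net$head$b[k] <- 0
          if (!is.null(vel[["head$w"]])) vel[["head$w"]][, k] <- 0
          if (!is.null(vel[["head$b"]])) vel[["head$b"]][k] <- 0
          if (!quiet) message(sprintf("[%s] reset dead channel %d", stage, k))
        }
      }
    }
    structure(list(stage = stage, net = net, config = config, view = view,
                   loss_log = log), class = "stage_model")
  })
}

# training-set quality gates used by the restart logic; a gate of Inf means
# the first attempt is always accepted
stage_train_quality <- function(model, dataset) {
  stage <- model$stage
  if (stage == "phase") {
    aafd_tr <- mean(vapply(dataset, function(ex)
      abs(decode_es_phase(predict(model, ex$cine)$curve) - ex$es), 0))
    return(list(value = aafd_tr, gate = 1.5))
  }
  if (stage == "landmark") {
    take <- utils::head(seq_along(dataset), 40)
    errs <- unlist(lapply(take, function(i) {
      ex <- dataset[[i]]
      pr <- predict(model, ex$stack)
      sqrt(rowSums((pr$points[rownames(ex$points), , drop = FALSE] -
                    ex$points)^2))
    }))
    return(list(value = mean(errs), gate = 5))
  }
  list(value = 0, gate = Inf)
}

check_stage_dataset <- function(stage, dataset, view) {
  ex <- dataset[[1]]
  ok <- switch(stage,
    view = is.matrix(ex$image) && ex$label %in% VIEW_LABELS,
    slice = is.matrix(ex$image) && is.logical(ex$optimal),
    phase = length(dim(ex$cine)) == 3 && is.numeric(ex$es),
    landmark = length(dim(ex$stack)) == 3 && dim(ex$stack)[3] == 5 &&
      is.matrix(ex$points) && !is.null(view) &&
      setequal(rownames(ex$points), landmark_set_for_view(view)),
    segment = is.matrix(ex$image) && is.matrix(ex$mask) && !is.null(view))
  if (!isTRUE(ok)) stop("dataset does not match the '", stage, "' stage contract")
  invisible(TRUE)
}

add_grads <- function(a, b) {
  la <- nn_leaves(a); lb <- nn_leaves(b)
  for (k in names(la)) {
    a <- nn_assign(a, strsplit(k, "$", fixed = TRUE)[[1]], la[[k]] + lb[[k]])
  }
  a
}

scale_grads <- function(a, f) {
  la <- nn_leaves(a)
  for (k in names(la))
    a <- nn_assign(a, strsplit(k, "$", fixed = TRUE)[[1]], la[[k]] * f)
  a
}

stage_forward_backward <- function(stage, net, ex, config, view, aug_seed) {
  aug <- config$augmentation
  if (stage %in% c("view", "slice")) {
    img <- ex$image
    if (!is.null(aug)) img <- augment(img, NULL, aug, seed = aug_seed)$image
    x <- prep_image(img, config$input_px, "standardize")
    fw <- nn_classifier_fw(net, x)
    lab <- if (stage == "view") match(ex$label, VIEW_LABELS)
           else as.integer(ex$optimal) + 1L  # 1 non-optimal, 2 optimal
    loss <- -log(max(fw$probs[lab], 1e-12))
    dlog <- fw$probs
    dlog[lab] <- dlog[lab] - 1
    grads <- nn_classifier_bw(net, fw$cache, dlog)
    return(list(loss = loss, grads = grads))
  }
  if (stage == "phase") {
    cine <- ex$cine
    es <- ex$es
    if (!is.null(aug)) {
      a <- augment(cine, list(type = "es", es = es), aug, seed = aug_seed)
      cine <- a$image
      es <- a$label$es
    }
    pc <- prep_cine(cine, config$input_px)
    y <- as.numeric(encode_phase_curve(es, dim(cine)[1]))
    yfull <- numeric(30)
    yfull[seq_along(y)] <- y
    fw <- nn_phase_fw(net, pc$frames)
    res <- (fw$curve - yfull) * pc$valid
    w <- (1 + 5 * yfull) * pc$valid  # emphasize the systolic peak
    loss <- sum(w * res^2) / sum(w)
    dcurve <- 2 * w * res / sum(w)
    grads <- nn_phase_bw(net, pc$frames, fw$cache, dcurve)
    return(list(loss = loss, grads = grads))
  }
  if (stage == "landmark") {
    px <- config$input_px
    sc <- px / dim(ex$stack)[1]
    x <- prep_stack(ex$stack, px)
    pts <- ex$points * sc
    if (!is.null(aug)) {
      a <- augment(x, list(type = "points", points = pts), aug, seed = aug_seed)
      x <- a$image
      pts <- a$label$points
      rownames(pts) <- rownames(ex$points)
    }
    pts[, 1] <- pmin(pmax(pts[, 1], 0), px - 1)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), px - 1)
    names_order <- landmark_set_for_view(view)
    y <- encode_landmark_heatmap(pts[names_order, , drop = FALSE], c(px, px),
                                 sigma = 12)
    fw <- nn_unet_fw(net, x)
    sig <- 1 / (1 + exp(-fw$out))
    res <- sig - y
    # MSE weighted toward the Gaussian peaks: the targets are sparse and the
    # unweighted loss has a strong constant-map local optimum.  Attempts
    # that still collapse into it are caught by the training-set quality
    # gate and re-initialized (see train_stage).
    w <- 1 + 30 * y
    loss <- sum(w * res^2) / sum(w)
    dout <- 2 * w * res * sig * (1 - sig) / sum(w)
    grads <- nn_unet_bw(net, fw$cache, dout)
    # per-channel peak prominence: a healthy channel peaks near 1 over a
    # low background; a collapsed one is (near-)constant
    return(list(loss = loss, grads = grads,
                chmax = apply(sig, 3, max) - apply(sig, 3, mean)))
  }
  # segment
  px <- config$input_px
  x <- prep_image(ex$image, px, "minmax")
  mask <- if (all(dim(ex$mask) == px)) ex$mask else resize_mask(ex$mask, px)
  if (!is.null(aug)) {
    a <- augment(x, list(type = "mask", mask = mask), aug, seed = aug_seed)
    x <- a$image
    mask <- a$label$mask
  }
  fw <- nn_unet_fw(net, x)
  lg <- segment_loss_grad(fw$out, mask)
  grads <- nn_unet_bw(net, fw$cache, lg$dlogits)
  list(loss = lg$loss, grads = grads)
}

resize_mask <- function(mask, px) {
  idx_r <- pmin(pmax(round((seq_len(px) - 0.5) * nrow(mask) / px + 0.5), 1),
                nrow(mask))
  idx_c <- pmin(pmax(round((seq_len(px) - 0.5) * ncol(mask) / px + 0.5), 1),
                ncol(mask))
  mask[idx_r, idx_c]
}

#' @export
print.stage_model <- function(x, ...) {
  cat("stage_model [", x$stage, "]", sep = "")
  if (!is.null(x$view)) cat(" view =", x$view)
  cat(": final training loss",
      sprintf("%.4f", x$loss_log[length(x$loss_log)]), "\n")
  invisible(x)
}

# ---- inference -------------------------------------------------------------

#' Predict with a trained stage model
#'
#' @param object a [train_stage()] model.
#' @param x stage input: an image (view/slice), a cine array or
#'   [cine_series()] (phase), a 5-channel stack (landmark), or an image
#'   (segment).
#' @param ... unused.
#' @return Stage-specific prediction: view label + probabilities; slice
#'   optimality (ties resolve to non-optimal) + probabilities; phase curve +
#'   validity; named landmark points (original pixel scale) + confidences;
#'   or a label map at the input resolution.
#' @export
predict.stage_model <- function(object, x, ...) {
  stage <- object$stage
  px <- object$config$input_px
  if (stage %in% c("view", "slice")) {
    fw <- nn_classifier_fw(object$net, prep_image(x, px, "standardize"))
    if (stage == "view")
      return(list(label = VIEW_LABELS[which.max(fw$probs)], probs = fw$probs))
    optimal <- fw$probs[2] > fw$probs[1]  # tie -> non-optimal (conservative)
    return(list(optimal = optimal, probs = fw$probs))
  }
  if (stage == "phase") {
    frames <- if (inherits(x, "cine_series")) x$frames else x
    pc <- prep_cine(frames, px)
    fw <- nn_phase_fw(object$net, pc$frames)
    return(list(curve = fw$curve, valid = pc$valid))
  }
  if (stage == "landmark") {
    orig <- dim(x)[1]
    fw <- nn_unet_fw(object$net, prep_stack(x, px))
    maps <- 1 / (1 + exp(-fw$out))
    nms <- landmark_set_for_view(object$view)
    pts <- matrix(NA_real_, length(nms), 2, dimnames = list(nms, NULL))
    conf <- numeric(length(nms))
    margin <- 4L  # convolution-padding artifacts live at the border
    clean <- function(k) {
      m <- maps[, , k]
      m[c(seq_len(margin), px - seq_len(margin) + 1L), ] <- 0
      m[, c(seq_len(margin), px - seq_len(margin) + 1L)] <- 0
      m
    }
    for (k in seq_along(nms)) {
      dec <- decode_heatmap(clean(k))
      pts[k, ] <- dec$point
      conf[k] <- dec$confidence
    }
    # mutual exclusion: distinct landmarks cannot share a location; when a
    # channel's dominant mode was stolen by a more confident sibling, the
    # loser is re-decoded with the winner's neighbourhood suppressed
    for (k in order(conf)) {
      for (l in seq_along(nms)) {
        if (l == k || conf[l] <= conf[k]) next
        if (sqrt(sum((pts[k, ] - pts[l, ])^2)) < 8) {
          m <- clean(k)
          rr <- matrix(seq_len(px) - 1, px, px)
          cc <- t(rr)
          m[(rr - pts[l, 1])^2 + (cc - pts[l, 2])^2 < 14^2] <- 0
          dec <- decode_heatmap(m)
          pts[k, ] <- dec$point
          conf[k] <- dec$confidence
        }
      }
    }
    pts <- pts * orig / px
    return(list(points = pts, confidence = conf, heatmaps = maps))
  }
  # segment
  orig <- dim(x)
  fw <- nn_unet_fw(object$net, prep_image(x, px, "minmax"))
  p <- softmax_pixelwise(fw$out)
  lab <- apply(p, c(1, 2), which.max) - 1L
  if (!all(orig == px)) lab <- resize_mask(lab, orig[1])
  lab
}

#' Save / load a stage model as JSON (weights + sidecar metadata)
#' @param model a `stage_model`.
#' @param path output .json file.
#' @return Invisibly, `path`.
#' @export
save_stage_model <- function(model, path) {
  leaves <- nn_leaves(model$net)
  ser <- lapply(leaves, function(v) list(dim = dim(v) %||% length(v),
                                         data = as.vector(v)))
  obj <- list(sidecar = list(stage = model$stage, view = model$view,
                             config = unclass(model$config),
                             loss_log = model$loss_log),
              shape = model$net[c("type", "n_classes", "input_px", "cin",
                                  "cout", "n_frames", "frame_px", "hidden",
                                  "feat")],
              weights = ser)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_stage_model
#' @export
load_stage_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$sidecar$config
  cfg$stage <- cfg$stage
  config <- do.call(train_config, cfg[c("stage", "epochs", "batch_size",
                                        "learning_rate", "momentum", "seed",
                                        "input_px")])
  view <- obj$sidecar$view
  px <- config$input_px
  net <- switch(config$stage,
    view = nn_classifier_init(8L, px),
    slice = nn_classifier_init(2L, px),
    phase = nn_phase_init(frame_px = px),
    landmark = nn_unet_init(7L, length(landmark_set_for_view(view)), px),
    segment = nn_unet_init(1L, max(encode_segmentation_classes(view)) + 1L, px))
  for (key in names(obj$weights)) {
    w <- obj$weights[[key]]
    v <- w$data
    if (length(w$dim) == 2) v <- matrix(v, w$dim[1], w$dim[2])
    net <- nn_assign(net, strsplit(key, "$", fixed = TRUE)[[1]], v)
  }
  structure(list(stage = config$stage, net = net, config = config,
                 view = view, loss_log = obj$sidecar$loss_log),
            class = "stage_model")
}

# ---- phantom dataset builders ----------------------------------------------

#' Build stage training datasets from phantoms
#'
#' Convenience constructors turning [make_phantom()] output into the example
#' lists consumed by [train_stage()].
#'
#' @param phantoms list of `phantom_truth` objects.
#' @param frames 0-based frames to sample (default: ED and the mid-systolic
#'   frame for images; all rendered frames for landmarks).
#' @name phantom_datasets
#' @param max_sax_per_phantom cap on SAx series sampled per phantom (class
#'   balance: a full stack would otherwise dominate the view classes).
#' @export
phantom_view_dataset <- function(phantoms, frames = c(0L, 6L),
                                 max_sax_per_phantom = 4L) {
  out <- list()
  for (ph in phantoms) {
    sax <- names(ph$view_labels)[ph$view_labels == "SAx"]
    keep_sax <- sax[unique(pmax(1, round(seq(1, length(sax),
                                             length.out = max_sax_per_phantom))))]
    for (sid in names(ph$study$series)) {
      if (ph$view_labels[[sid]] == "SAx" && !sid %in% keep_sax) next
      for (t in frames)
        out[[length(out) + 1]] <- list(
          image = frame_of(ph$study$series[[sid]], t + 1L),
          label = unname(ph$view_labels[[sid]]))
    }
  }
  out
}

#' @rdname phantom_datasets
#' @export
phantom_slice_dataset <- function(phantoms, frames = c(0L, 6L)) {
  out <- list()
  for (ph in phantoms)
    for (sid in names(ph$study$series)) {
      if (ph$view_labels[[sid]] != "SAx") next
      for (t in frames)
        out[[length(out) + 1]] <- list(
          image = frame_of(ph$study$series[[sid]], t + 1L),
          optimal = unname(ph$optimal_flags[[sid]]))
    }
  out
}

#' @rdname phantom_datasets
#' @param max_slices_per_phantom cap on SAx slices sampled per phantom.
#' @export
phantom_phase_dataset <- function(phantoms, max_slices_per_phantom = 4L) {
  out <- list()
  for (ph in phantoms) {
    sids <- names(which(ph$optimal_flags))
    mid <- sids[order(abs(seq_along(sids) - length(sids) / 2))]
    for (sid in utils::head(mid, max_slices_per_phantom))
      out[[length(out) + 1]] <- list(cine = ph$study$series[[sid]]$frames,
                                     es = ph$es_frame)
  }
  out
}

#' @rdname phantom_datasets
#' @param view the cine view whose landmark/segmentation net is trained.
#' @export
phantom_landmark_dataset <- function(phantoms, view, frames = NULL) {
  out <- list()
  for (ph in phantoms) {
    for (sid in names(ph$landmarks_px)) {
      if (ph$view_labels[[sid]] != view) next
      fr <- names(ph$landmarks_px[[sid]])
      if (!is.null(frames)) fr <- intersect(fr, as.character(frames))
      for (tt in fr) {
        pts <- ph$landmarks_px[[sid]][[tt]]
        if (!setequal(rownames(pts), landmark_set_for_view(view))) next
        out[[length(out) + 1]] <- list(
          stack = stack_temporal_channels(ph$study$series[[sid]], as.integer(tt)),
          points = pts)
      }
    }
  }
  out
}

#' @rdname phantom_datasets
#' @export
phantom_segment_dataset <- function(phantoms, view, frames = NULL) {
  out <- list()
  for (ph in phantoms) {
    if (is.null(frames)) frames <- c(0L, ph$es_frame)
    for (sid in names(ph$masks)) {
      if (ph$view_labels[[sid]] != view) next
      if (view == "SAx" && !isTRUE(ph$optimal_flags[[sid]])) next
      for (t in frames)
        out[[length(out) + 1]] <- list(
          image = frame_of(ph$study$series[[sid]], t + 1L),
          mask = ph$masks[[sid]][t + 1L, , ])
    }
  }
  out
}
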