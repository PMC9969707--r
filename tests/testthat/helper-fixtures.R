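# Shared fixtures, built once per test run.  Kept deliberately small: a
# single mid-sized phantom rendered at ED and ES only, plus the default
# template.  Heavier populations are generated inside the tests that need
# them.

fixture_env <- new.env(parent = emptyenv())

fixture_template <- function() {
  if (is.null(fixture_env$tpl)) fixture_env$tpl <- biv_template()
  fixture_env$tpl
}

fixture_phantom <- function() {
  if (is.null(fixture_env$ph)) {
    fixture_env$ph <- make_phantom(
      phantom_params(seed = 11, lv_short_radius_mm = 26, lv_wall_mm = 8.5,
                     ef_target_fraction = 0.55, es_frame = 12L),
      render_frames = c(0L, 12L),
      series = c("SAx", "4Ch", "3Ch", "RVOT", "2Ch LT", "2Ch RT"))
  }
  fixture_env$ph
}

# oracle per-series predictions for assemble_guide_points()
oracle_predictions <- function(truth, frames = c(0L, truth$es_frame)) {
  preds <- list()
  keys <- as.character(frames)
  for (sid in names(truth$view_labels)) {
    if (!sid %in% names(truth$planes)) next
    masks <- NULL
    if (!is.null(truth$masks[[sid]])) {
      masks <- lapply(keys, function(k)
        truth$masks[[sid]][as.integer(k) + 1L, , ])
      names(masks) <- keys
    }
    lmk <- truth$landmarks_px[[sid]]
    if (!is.null(lmk)) lmk <- lmk[intersect(names(lmk), keys)]
    preds[[sid]] <- list(view = unname(truth$view_labels[[sid]]),
                         meta = truth$planes[[sid]],
                         optimal = unname(truth$optimal_flags[sid]),
                         masks = masks, landmarks = lmk)
  }
  preds
}

# oracle-guided ED/ES fit of a phantom
fixture_oracle_fit <- function() {
  if (is.null(fixture_env$fit)) {
    ph <- fixture_phantom()
    tpl <- fixture_template()
    g <- assemble_guide_points(oracle_predictions(ph), es_frame = ph$es_frame)
    fixture_env$fit <- list(
      ed = nonrigid_fit(tpl, g$ed),
      es = nonrigid_fit(tpl, g$es),
      guides = g)
  }
  fixture_env$fit
}

# global point-to-true-surface MAE of a fitted phantom model
phantom_fit_mae <- function(fit, truth, frame) {
  tpl <- fit$template
  ts <- truth$true_surfaces[[as.character(frame)]]
  all <- c()
  for (r in c("lv_endo", "rv_endo", "epicardium", "septum")) {
    vids <- bivshape:::template_region_vertices(tpl, r)
    key <- if (r == "septum") "rv_endo" else r
    all <- c(all, point_to_surface(fit$vertices[vids, , drop = FALSE],
                                   ts[[key]])$dist)
  }
  mean(all)
}

# independent exact point-to-triangle distance: minimum over the candidate
# set {unconstrained plane projection if interior, 3 clamped edge
# projections, 3 vertices}; used as the brute-force oracle for distances
brute_point_tri <- function(p, a, b, c_) {
  cands <- list(a, b, c_)
  edges <- list(list(a, b), list(b, c_), list(c_, a))
  for (e in edges) {
    d <- e[[2]] - e[[1]]
    t <- sum((p - e[[1]]) * d) / sum(d * d)
    cands[[length(cands) + 1]] <- e[[1]] + min(max(t, 0), 1) * d
  }
  E0 <- b - a; E1 <- c_ - a
  n <- c(E0[2] * E1[3] - E0[3] * E1[2], E0[3] * E1[1] - E0[1] * E1[3],
         E0[1] * E1[2] - E0[2] * E1[1])
  q <- p - sum((p - a) * n) / sum(n * n) * n
  # barycentric test for interior
  M <- cbind(E0, E1)
  uv <- solve(crossprod(M), crossprod(M, q - a))
  if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
    cands[[length(cands) + 1]] <- q
  sqrt(min(vapply(cands, function(x) sum((x - p)^2), 0)))
}
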