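# End-to-end orchestration: view classification -> slice selection -> phase
# selection -> landmark localization -> segmentation -> guide points ->
# template fit -> measurements (-> atlas projection), with file-free manual
# overrides at every stage and an override ledger.

#' Pipeline configuration
#'
#' @param template a [biv_template()].
#' @param models named list of stage models: `view`, `slice`, `phase`
#'   ([train_stage()] outputs), `landmark` and `segment` (named lists
#'   view -> model).  Any stage model may be omitted if the corresponding
#'   stage output is supplied via overrides.
#' @param fit a [fit_config()].
#' @param atlas optional [shape_atlas] for Z-score projection.
#' @param out_dir optional directory; when set, intermediate artifacts
#'   (guide points JSON, fitted meshes OBJ, measures CSV, report JSON) are
#'   persisted there.
#' @param seed integer seed recorded with the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(template, models = list(), fit = fit_config(),
                            atlas = NULL, out_dir = NULL, seed = 1L) {
  structure(list(template = template, models = models, fit = fit,
                 atlas = atlas, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Oracle overrides from phantom ground truth
#'
#' Builds an override bundle that replaces every stage prediction with the
#' phantom's ground truth (view labels, slice flags, ES frame, landmark
#' pixels, masks) — the oracle round-trip configuration.
#'
#' @param truth a `phantom_truth`.
#' @return Named list understood by [run_pipeline()]'s `overrides` argument.
#' @export
oracle_overrides <- function(truth) {
  list(view = truth$view_labels,
       slice = truth$optimal_flags,
       es_frame = truth$es_frame,
       landmarks = truth$landmarks_px,
       masks = truth$masks,
       source = "oracle")
}

ledger_add <- function(ledger, step, item, original, override, source) {
  rbind(ledger, data.frame(step = step, item = item,
                           original = as.character(original),
                           override = as.character(override),
                           source = source, stringsAsFactors = FALSE))
}

#' Run the automated shape-modeling pipeline on a study
#'
#' Executes the five stages in order, then assembles guide points, fits the
#' ED and ES biventricular models, and computes global measurements (and
#' atlas Z-scores when an atlas is configured).  Each stage's output can be
#' replaced by a supplied override before the next stage runs; every
#' override is recorded in the returned ledger.  Deterministic given the
#' models and seed.
#'
#' @param study a [cine_study()].
#' @param config a [pipeline_config()].
#' @param overrides optional named list: `view` (series -> label), `slice`
#'   (series -> logical), `es_frame` (0-based), `landmarks` (series ->
#'   frame -> named px matrix), `masks` (series -> frame x H x W array),
#'   `source` tag.
#' @return List with `ed_model`, `es_model`, `measures`, `zscores` (or
#'   NULL), `ledger` (data.frame), `stages` (per-stage outputs), `guides`.
#' @export
run_pipeline <- function(study, config, overrides = NULL) {
  ov <- overrides %||% list()
  src <- ov$source %||% "manual"
  ledger <- data.frame()
  models <- config$models
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- stage 1: view classification ----------------------------------------
  views <- run_stage("view", {
    out <- character()
    conf <- numeric()
    for (sid in names(study$series)) {
      if (!is.null(ov$view) && sid %in% names(ov$view)) {
        pred <- if (!is.null(models$view))
          predict(models$view, frame_of(study$series[[sid]], 1L))$label
        else NA_character_
        out[sid] <- ov$view[[sid]]
        conf[sid] <- 1
        if (!identical(pred, unname(out[sid])))
          ledger <- ledger_add(ledger, "view", sid, pred, out[sid], src)
      } else {
        if (is.null(models$view)) stop("no view model and no override")
        p <- predict(models$view, frame_of(study$series[[sid]], 1L))
        out[sid] <- p$label
        conf[sid] <- max(p$probs)
      }
    }
    # duplicate long-axis predictions: keep the highest-confidence series
    for (v in setdiff(VIEW_LABELS, c("SAx", "OTHER"))) {
      sids <- names(out)[out == v]
      if (length(sids) > 1) {
        keep <- sids[which.max(conf[sids])]
        drop <- setdiff(sids, keep)
        out[drop] <- "OTHER"
        for (d in drop)
          ledger <- ledger_add(ledger, "view", d, v, "OTHER (duplicate)",
                                "pipeline")
      }
    }
    out
  })
  sax_ids <- names(views)[views == "SAx"]
  if (!length(sax_ids))
    stop("pipeline stage 'slice' failed: study has no SAx series", call. = FALSE)

  # --- stage 2: slice selection --------------------------------------------
  optimal <- run_stage("slice", {
    out <- logical()
    for (sid in sax_ids) {
      if (!is.null(ov$slice) && sid %in% names(ov$slice)) {
        out[sid] <- ov$slice[[sid]]
      } else {
        if (is.null(models$slice)) stop("no slice model and no override")
        out[sid] <- predict(models$slice, frame_of(study$series[[sid]], 1L))$optimal
      }
    }
    if (!any(out)) stop("no optimal SAx slices selected")
    out
  })

  # --- stage 3: phase selection --------------------------------------------
  es_frame <- run_stage("phase", {
    if (!is.null(ov$es_frame)) {
      pred <- NA_integer_
      if (!is.null(models$phase)) {
        curves <- list(); valids <- list()
        for (sid in names(which(optimal))) {
          pr <- predict(models$phase, study$series[[sid]])
          curves[[sid]] <- pr$curve
          valids[[sid]] <- pr$valid
        }
        pred <- decode_es_phase(curves, valids)
      }
      if (!is.na(pred) && pred != ov$es_frame)
        ledger <- ledger_add(ledger, "phase", "es_frame", pred, ov$es_frame, src)
      as.integer(ov$es_frame)
    } else {
      if (is.null(models$phase)) stop("no phase model and no override")
      curves <- list(); valids <- list()
      for (sid in names(which(optimal))) {
        pr <- predict(models$phase, study$series[[sid]])
        curves[[sid]] <- pr$curve
        valids[[sid]] <- pr$valid
      }
      decode_es_phase(curves, valids)
    }
  })
  frames <- c(0L, es_frame)

  # --- stage 4: landmark localization --------------------------------------
  landmark_views <- c("3Ch", "4Ch", "RVOT")
  lm_total <- 0L
  lm_overridden <- character(0)
  landmarks <- run_stage("landmark", {
    out <- list()
    for (sid in names(views)) {
      v <- views[[sid]]
      eligible <- v %in% landmark_views || (v == "SAx" && isTRUE(optimal[sid]))
      if (!eligible) next
      per <- list()
      for (t in frames) {
        key <- as.character(t)
        pred <- NULL
        if (!is.null(models$landmark[[v]]))
          pred <- predict(models$landmark[[v]],
                          stack_temporal_channels(study$series[[sid]], t))$points
        ovr <- ov$landmarks[[sid]][[key]]
        use <- ovr %||% pred
        if (is.null(use)) {
          # an override bundle without an entry means this item genuinely has
          # no landmarks (e.g. an apical SAx slice below the RV)
          if (!is.null(ov$landmarks)) next
          stop("no landmark model for view ", v, " and no override")
        }
        lm_total <- lm_total + nrow(use)
        if (!is.null(ovr) && !is.null(pred)) {
          moved <- rownames(ovr)[rowSums(abs(ovr - pred[rownames(ovr), ])) > 1]
          lm_overridden <- c(lm_overridden, moved)
          for (nm in moved)
            ledger <- ledger_add(ledger, "landmark", paste(sid, key, nm),
                                  paste(round(pred[nm, ], 1), collapse = ","),
                                  paste(round(ovr[nm, ], 1), collapse = ","), src)
        } else if (!is.null(ovr) && is.null(pred)) {
          lm_overridden <- c(lm_overridden, rownames(ovr))
        }
        per[[key]] <- use
      }
      out[[sid]] <- per
    }
    out
  })

  # --- stage 5: segmentation -----------------------------------------------
  masks <- run_stage("segment", {
    out <- list()
    for (sid in names(views)) {
      v <- views[[sid]]
      seg <- v %in% PH_SEGMENTED_VIEWS && (v != "SAx" || isTRUE(optimal[sid]))
      if (!seg) next
      per <- list()
      for (t in frames) {
        key <- as.character(t)
        if (!is.null(ov$masks[[sid]])) {
          per[[key]] <- ov$masks[[sid]][t + 1L, , ]
        } else {
          if (is.null(models$segment[[v]]))
            stop("no segmentation model for view ", v, " and no override")
          per[[key]] <- predict(models$segment[[v]],
                                frame_of(study$series[[sid]], t + 1L))
        }
      }
      out[[sid]] <- per
    }
    out
  })

  # --- guide points and fitting --------------------------------------------
  predictions <- list()
  for (sid in names(views)) {
    predictions[[sid]] <- list(view = unname(views[[sid]]),
                               meta = study$series[[sid]]$meta,
                               optimal = unname(optimal[sid] %||% NA),
                               masks = masks[[sid]],
                               landmarks = landmarks[[sid]])
  }
  guides <- run_stage("fit", assemble_guide_points(predictions, es_frame))
  ed_model <- run_stage("fit", nonrigid_fit(config$template, guides$ed, config$fit))
  es_model <- run_stage("fit", nonrigid_fit(config$template, guides$es, config$fit))
  measures <- run_stage("measures", global_measures(ed_model, es_model))
  zs <- if (!is.null(config$atlas))
    run_stage("atlas", project(config$atlas, ed_model, es_model)) else NULL

  ledger_summary <- summarize_overrides(lm_overridden, lm_total)
  out <- list(ed_model = ed_model, es_model = es_model, measures = measures,
              zscores = zs,
              ledger = list(entries = ledger, landmark_overrides = ledger_summary),
              stages = list(views = views, optimal = optimal,
                            es_frame = es_frame),
              guides = guides, seed = config$seed)
  if (!is.null(config$out_dir)) persist_pipeline_output(out, config)
  out
}

# Table-11-style override summary: per landmark group, "k of n (pct)"
summarize_overrides <- function(overridden, total) {
  groups <- c("AV Inserts" = "^AV", "PV Inserts" = "^PV", "MV Inserts" = "^MV",
              "TV Inserts" = "^TV", "RV Inserts" = "^RV", "LV Apex" = "^LV_APEX")
  rows <- lapply(names(groups), function(gn) {
    k <- sum(grepl(groups[[gn]], overridden))
    data.frame(landmark = gn, overrides = k, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$total <- total
  df$summary <- sprintf("%d of %d (%.0f)", df$overrides, df$total,
                        ifelse(df$total > 0, 100 * df$overrides / df$total, 0))
  df
}

persist_pipeline_output <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_obj(tri_mesh(out$ed_model$vertices, out$ed_model$template$faces),
            file.path(config$out_dir, "model_ed.obj"))
  write_obj(tri_mesh(out$es_model$vertices, out$es_model$template$faces),
            file.path(config$out_dir, "model_es.obj"))
  write_measures_csv(out$measures, file.path(config$out_dir, "measures.csv"))
  rep <- list(seed = config$seed, stages = out$stages,
              measures = unclass(out$measures),
              zscores = if (!is.null(out$zscores)) out$zscores$z,
              landmark_overrides = out$ledger$landmark_overrides)
  jsonlite::write_json(rep, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (phase in c("ed", "es")) {
    g <- out$guides[[phase]]
    gl <- list(phase = g$phase,
               contour_points = lapply(g$contour_points, unname),
               landmark_points = if (!is.null(g$landmark_points))
                 list(names = rownames(g$landmark_points),
                      xyz = unname(g$landmark_points)))
    jsonlite::write_json(gl, file.path(config$out_dir,
                                       paste0("guides_", phase, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(NULL)
}

#' Compare pipeline results against reference models
#'
#' Rigidly aligns each automatic model to its reference, computes regional
#' projection-distance reports, compares global measurements (Bland-Altman
#' across subjects), and, when an atlas is supplied, per-mode Z-score
#' differences.
#'
#' @param results list of pipeline outputs (each with `ed_model`,
#'   `es_model`, `measures`).
#' @param reference list of the same length with reference `ed_model`,
#'   `es_model` (and optionally `measures`).
#' @param atlas optional [shape_atlas].
#' @param n_modes modes for the Z-score comparison.
#' @return List with `regional` (per subject/phase error reports),
#'   `measures` (per-measure Bland-Altman), `zscores` (or NULL).
#' @export
evaluate_against_reference <- function(results, reference, atlas = NULL,
                                       n_modes = 20L) {
  if (length(results) != length(reference) || !length(results))
    stop("results and reference must be nonempty lists of equal length")
  regional <- lapply(seq_along(results), function(i) {
    lapply(c(ed = "ed_model", es = "es_model"), function(ph) {
      al <- rigid_align_models(results[[i]][[ph]], reference[[i]][[ph]])
      projection_distances(al$aligned, reference[[i]][[ph]])
    })
  })
  meas <- NULL
  if (!is.null(results[[1]]$measures) && !is.null(reference[[1]]$measures) &&
      length(results) >= 3) {
    keys <- names(unclass(results[[1]]$measures))
    meas <- lapply(stats::setNames(keys, keys), function(k) {
      bland_altman(vapply(reference, function(r) r$measures[[k]], 0),
                   vapply(results, function(r) r$measures[[k]], 0))
    })
  }
  zs <- if (!is.null(atlas))
    zscore_difference(atlas,
                      lapply(results, function(r) list(ed = r$ed_model, es = r$es_model)),
                      lapply(reference, function(r) list(ed = r$ed_model, es = r$es_model)),
                      n_modes = n_modes)
  list(regional = regional, measures = meas, zscores = zs)
}
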