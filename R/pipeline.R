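# End-to-end pipeline: segment -> classify -> filter (border, stage,
# length, fluorescence gate) -> profile -> aggregate -> average shapes,
# with a per-cell audit log of every exclusion.

#' Build a pipeline configuration
#'
#' Defaults are the analysis constants used throughout: 256-px tiles at 50%
#' overlap, 3-px membrane compensation, N = 21 profile positions, max
#' reduction, sigma = 5 px gate blur, 0.102 um/px, 64 shape vertices with at
#' most 1000 averaging iterations and 1e-8 early stop.
#'
#' @param phase_channel Name of the phase-contrast channel.
#' @param orient_channel Channel driving the left-orientation rule (e.g.
#'   `"C9"`); `NULL` skips orientation.
#' @param gate_channel Channel for positivity gating (e.g. `"Sytox"`);
#'   `NULL` skips gating.
#' @param gate_keep Keep only gate-positive cells (`TRUE`, e.g. selecting
#'   inner-membrane-damaged cells).
#' @param tile_size,overlap Tiling parameters.
#' @param n_positions Profile positions per cell.
#' @param reduction `"max"` or `"mean"` perpendicular reduction.
#' @param sigma_blur Gate blur sigma (px).
#' @param keep_stages Growth stages retained for analysis.
#' @param length_filter Apply the Otsu length filter to rod/dividing labels.
#' @param min_iou Minimum detection-association IoU (strict bound).
#' @param pixel_size Pixel size in um.
#' @param shape_vertices Vertex count for average shapes (`0` disables
#'   shape averaging).
#' @param shape_max_iter,shape_tol Average-shape optimizer settings.
#' @param seed Seed for any stochastic backend.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(phase_channel = "phase", orient_channel = NULL,
                            gate_channel = NULL, gate_keep = TRUE,
                            tile_size = 256, overlap = 0.5, n_positions = 21,
                            reduction = c("max", "mean"), sigma_blur = 5,
                            keep_stages = c("dividing", "rod"),
                            length_filter = TRUE, min_iou = 0,
                            pixel_size = 0.102, shape_vertices = 64,
                            shape_max_iter = 1000, shape_tol = 1e-8,
                            seed = 1L) {
  reduction <- match.arg(reduction)
  structure(list(phase_channel = phase_channel, orient_channel = orient_channel,
                 gate_channel = gate_channel, gate_keep = gate_keep,
                 tile_size = tile_size, overlap = overlap,
                 n_positions = n_positions, reduction = reduction,
                 sigma_blur = sigma_blur, keep_stages = keep_stages,
                 length_filter = length_filter, min_iou = min_iou,
                 pixel_size = pixel_size, shape_vertices = shape_vertices,
                 shape_max_iter = shape_max_iter, shape_tol = shape_tol,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path File path.
#' @param config A [pipeline_config()].
#' @name config-io
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(pipeline_config, lst)
}

#' @rdname config-io
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full single-cell profiling pipeline
#'
#' Per frame: tiled semantic segmentation, instance extraction, border
#' filtering, detector association and stage filtering, fluorescence
#' gating; then (pooled over frames) the Otsu length filter, per-cell
#' long-axis profiles (oriented and normalized), per-class profile
#' distributions, and average shapes per class. Deterministic given the
#' inputs and config; every excluded cell is logged with its reason.
#'
#' @param frames A single frame or list of frames; each frame is a named
#'   list of numeric channel matrices including the phase channel.
#' @param config A [pipeline_config()].
#' @param backends Optional list of semantic backends, one per frame (see
#'   [backends]); default classical thresholding on the phase channel.
#' @param detections Optional list of detection tibbles, one per frame;
#'   default runs the geometric stage classifier on the instances.
#' @return A `bactaxis_result` list: `cells` (instance table with stage,
#'   gate flag and axis length), `profiles` (long tibble of oriented,
#'   normalized per-cell profiles), `profile_summary` (a `profile_set`),
#'   `shapes` (named list of `average_shape` per class), `log` (exclusion
#'   audit trail), `length_threshold`, `config`.
#' @export
run_pipeline <- function(frames, config = pipeline_config(), backends = NULL,
                         detections = NULL) {
  if (!is.null(names(frames)) && config$phase_channel %in% names(frames))
    frames <- list(frames)
  n_frames <- length(frames)
  log_rows <- list()
  all_inst <- list()
  note <- function(frame, id, reason) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(frame = frame, id = id, reason = reason)
  }
  for (f in seq_len(n_frames)) {
    frame <- frames[[f]]
    if (!config$phase_channel %in% names(frame))
      stop("frame ", f, " lacks phase channel '", config$phase_channel, "'", call. = FALSE)
    phase <- frame[[config$phase_channel]]
    backend <- if (!is.null(backends)) backends[[f]] else backend_classical(phase)
    sem <- predict_semantic(phase, backend, config$tile_size, config$overlap)
    inst <- extract_instances(sem)
    if (!nrow(inst)) next
    for (i in inst$id[inst$border_touching]) note(f, i, "border")
    inst <- filter_border_instances(inst)
    det <- if (!is.null(detections)) detections[[f]] else detect_stages_geometric(inst)
    inst <- match_instances(inst, det, config$min_iou)
    drop <- !(inst$stage %in% config$keep_stages)
    for (i in inst$id[drop]) note(f, i, paste0("stage:", inst$stage[match(i, inst$id)]))
    inst <- filter_stages(inst, config$keep_stages)
    if (!nrow(inst)) next
    if (!is.null(config$gate_channel)) {
      if (!config$gate_channel %in% names(frame))
        stop("frame ", f, " lacks gate channel '", config$gate_channel, "'", call. = FALSE)
      gate <- fluorescence_gate(frame[[config$gate_channel]], inst,
                                sigma = config$sigma_blur)
      inst$gate_positive <- gate$positive[match(inst$id, gate$id)]
      if (config$gate_keep) {
        for (i in inst$id[!inst$gate_positive]) note(f, i, "gate:negative")
        inst <- dplyr::filter(inst, .data$gate_positive)
      }
    } else {
      inst$gate_positive <- NA
    }
    if (nrow(inst)) {
      inst$frame <- f
      all_inst[[length(all_inst) + 1]] <- inst
    }
  }
  empty <- function() {
    warning("no cells survived the filters", call. = FALSE)
    structure(list(cells = tibble::tibble(), profiles = tibble::tibble(),
                   profile_summary = suppressWarnings(aggregate_profiles(tibble::tibble())),
                   shapes = list(),
                   log = if (length(log_rows)) dplyr::bind_rows(log_rows) else tibble::tibble(),
                   length_threshold = NA_real_, config = config),
              class = "bactaxis_result")
  }
  if (!length(all_inst)) return(empty())
  cells <- dplyr::bind_rows(all_inst)
  cells$length_um <- cells$length * config$pixel_size
  length_threshold <- NA_real_
  if (config$length_filter && nrow(cells) >= 2) {
    kept <- otsu_length_filter(cells)
    length_threshold <- attr(kept, "threshold")
    dropped <- dplyr::anti_join(cells, kept, by = c("frame", "id"))
    for (k in seq_len(nrow(dropped)))
      note(dropped$frame[k], dropped$id[k], "length:otsu")
    cells <- kept
  }
  if (!nrow(cells)) return(empty())

  fluor_names <- setdiff(names(frames[[1]]), config$phase_channel)
  prof_rows <- vector("list", nrow(cells))
  keep_row <- rep(TRUE, nrow(cells))
  for (k in seq_len(nrow(cells))) {
    f <- cells$frame[k]
    m <- cells$mask[[k]]
    rows <- cells$row0[k] + seq_len(nrow(m)) - 1
    cols <- cells$col0[k] + seq_len(ncol(m)) - 1
    chans <- lapply(frames[[f]][fluor_names], function(img) img[rows, cols, drop = FALSE])
    prof <- tryCatch(
      sample_profile(m, chans, n_positions = config$n_positions,
                     reduction = config$reduction),
      error = function(e) NULL)
    if (is.null(prof)) {
      note(f, cells$id[k], "profile:failed")
      keep_row[k] <- FALSE
      next
    }
    if (!is.null(config$orient_channel) && config$orient_channel %in% fluor_names)
      prof <- orient_profile(prof, config$orient_channel)
    else prof$flipped <- NA
    prof <- normalize_profile(prof)
    prof$frame <- f
    prof$id <- cells$id[k]
    prof$stage <- cells$stage[k]
    prof_rows[[k]] <- prof
  }
  cells <- cells[keep_row, , drop = FALSE]
  profiles <- dplyr::bind_rows(prof_rows)
  if (!nrow(profiles)) return(empty())
  profile_summary <- aggregate_profiles(profiles)

  shapes <- list()
  if (config$shape_vertices >= 4) {
    for (st in unique(cells$stage)) {
      sub <- cells[cells$stage == st, ]
      ctrs <- list()
      for (k in seq_len(nrow(sub))) {
        nc <- tryCatch(
          resample_contour(normalize_contour(sub$contour[[k]]), config$shape_vertices),
          error = function(e) NULL)
        if (!is.null(nc)) ctrs[[length(ctrs) + 1]] <- nc
      }
      if (length(ctrs))
        shapes[[st]] <- average_shape(ctrs, max_iter = config$shape_max_iter,
                                      tol = config$shape_tol)
    }
  }
  structure(list(cells = cells, profiles = profiles,
                 profile_summary = profile_summary, shapes = shapes,
                 log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
                   tibble::tibble(frame = integer(), id = integer(), reason = character()),
                 length_threshold = length_threshold, config = config),
            class = "bactaxis_result")
}

#' @export
print.bactaxis_result <- function(x, ...) {
  cat(sprintf("<bactaxis_result> %d cells (%s), %d excluded\n",
              nrow(x$cells),
              paste(sprintf("%s: %d", names(table(x$cells$stage)),
                            as.integer(table(x$cells$stage))), collapse = ", "),
              nrow(x$log)))
  invisible(x)
}

#' Cell divisions from a founder's final cell count
#'
#' A founder that grew into `count` cells underwent `count - 1` divisions.
#'
#' @param counts Integer vector of cells per founder at the end of imaging
#'   (>= 1).
#' @return Integer vector of division counts.
#' @export
count_divisions <- function(counts) {
  if (any(counts < 1)) stop("each founder must yield at least 1 cell", call. = FALSE)
  counts - 1
}

# --- file I/O ---------------------------------------------------------------

#' Write a rendered scene to disk
#'
#' The frame goes to a multipage TIFF (one 32-bit float page per channel,
#' page order = channel order), ground truth to a JSON sidecar (channel
#' names, boxes, per-cell metadata) and per-instance masks to PNG files.
#'
#' @param scene_render A `bact_scene` from [render_scene()].
#' @param dir Output directory (created if missing).
#' @param name Basename for the files (default `"scene"`).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene_render, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chans <- scene_render$frame
  # 32-bit float pages; noisy channels may dip slightly below 0, which the
  # float format stores faithfully (the [0,1]-range warning is moot here)
  suppressWarnings(tiff::writeTIFF(unname(chans), file.path(dir, paste0(name, ".tif")),
                                   bits.per.sample = 32L))
  cells <- scene_render$truth$cells
  mask_files <- character(0)
  if (nrow(cells)) {
    mask_dir <- file.path(dir, paste0(name, "_masks"))
    dir.create(mask_dir, showWarnings = FALSE)
    mask_files <- vapply(seq_len(nrow(cells)), function(i) {
      fp <- file.path(mask_dir, sprintf("cell_%03d.png", cells$id[i]))
      png::writePNG(matrix(as.numeric(cells$mask[[i]]), nrow(cells$mask[[i]])), fp)
      basename(fp)
    }, character(1))
  }
  meta <- list(
    channels = names(chans),
    width = scene_render$scene$width, height = scene_render$scene$height,
    pixel_size = scene_render$scene$pixel_size,
    seed = scene_render$scene$seed,
    boxes = scene_render$truth$boxes,
    cells = dplyr::select(cells, -dplyr::any_of(c("mask", "signal_kinds"))),
    signal_kinds = lapply(cells$signal_kinds, as.list),
    mask_files = mask_files
  )
  jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a multipage TIFF stack as named channel matrices
#'
#' @param path TIFF path.
#' @param channels Character vector naming the pages in order.
#' @return Named list of numeric matrices.
#' @export
read_stack <- function(path, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(channels)) channels <- paste0("channel", seq_along(pages))
  if (length(channels) != length(pages))
    stop("stack has ", length(pages), " pages but ", length(channels),
         " channel names were given", call. = FALSE)
  stats::setNames(lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    matrix(as.numeric(p), nrow(p))
  }), channels)
}

#' Write detections as a YOLO-style text file
#'
#' One line per box: `class_id cx cy w h confidence`, center/size normalized
#' by the frame dimensions.
#'
#' @param detections Detection tibble.
#' @param path Output path.
#' @param width,height Frame size used for normalization.
#' @param classes Class-name order defining the integer ids.
#' @name detections-io
#' @return `path` (write) / detection tibble (read).
#' @export
write_detections_yolo <- function(detections, path, width, height,
                                  classes = c("dividing", "rod", "intermediate",
                                              "defocused", "microcolony")) {
  id <- match(detections$label, classes) - 1L
  if (anyNA(id)) stop("unknown class label", call. = FALSE)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f %.4f", id,
                   (detections$xmin + detections$xmax) / 2 / width,
                   (detections$ymin + detections$ymax) / 2 / height,
                   (detections$xmax - detections$xmin) / width,
                   (detections$ymax - detections$ymin) / height,
                   detections$confidence)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname detections-io
#' @export
read_detections_yolo <- function(path, width, height,
                                 classes = c("dividing", "rod", "intermediate",
                                             "defocused", "microcolony")) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(xmin = numeric(), ymin = numeric(), xmax = numeric(),
                          ymax = numeric(), label = character(), confidence = numeric()))
  }
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  conf <- if (ncol(m) >= 6) m[, 6] else 1
  cx <- m[, 2] * width; cy <- m[, 3] * height
  w <- m[, 4] * width; h <- m[, 5] * height
  tibble::tibble(xmin = cx - w / 2, ymin = cy - h / 2,
                 xmax = cx + w / 2, ymax = cy + h / 2,
                 label = classes[m[, 1] + 1], confidence = conf)
}

#' Export pipeline tables to CSV
#'
#' Writes the per-cell table (without list-columns), the tidy profile table
#' and the aggregated profile distributions.
#'
#' @param result A `bactaxis_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_result_tables <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- dplyr::select(result$cells, -dplyr::any_of(c("mask", "contour", "signal_kinds")))
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(result$profiles, file.path(dir, "profiles.csv"), row.names = FALSE)
  utils::write.csv(result$profile_summary, file.path(dir, "profile_summary.csv"),
                   row.names = FALSE)
  if (length(result$shapes)) {
    shp <- dplyr::bind_rows(lapply(names(result$shapes), function(st) {
      df <- tidy(result$shapes[[st]])
      df$stage <- st
      df
    }))
    utils::write.csv(shp, file.path(dir, "average_shapes.csv"), row.names = FALSE)
  }
  invisible(dir)
}
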