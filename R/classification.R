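# Growth-stage assignment: associate instance masks with detector boxes by
# highest IoU (confidence as tie-break), keep only the desired stages, and
# clean residual rod/dividing confusions with an Otsu threshold on the
# pooled cell-length histogram.

#' Intersection over union of two boxes
#'
#' Boxes are `(xmin, ymin, xmax, ymax)` in pixel-edge (half-open)
#' coordinates, so areas are `(xmax - xmin) * (ymax - ymin)`.
#'
#' @param a,b Numeric length-4 vectors or 4-column matrices of boxes.
#' @return IoU in `[0, 1]` (vectorized over rows).
#' @export
box_iou <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 4)
  b <- matrix(as.numeric(b), ncol = 4)
  ix <- pmax(pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]), 0)
  iy <- pmax(pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]), 0)
  inter <- ix * iy
  union <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
    (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Match instances to detections by highest IoU
#'
#' Each instance receives the label and confidence of the detection
#' maximizing box IoU against the instance's bounding box; ties break by
#' higher confidence, then lower detection index. Detections may serve
#' several instances (no exclusivity). Instances whose best IoU does not
#' exceed `min_iou` stay `"unassigned"`.
#'
#' @param instances Instance tibble (needs `xmin`/`ymin`/`xmax`/`ymax`).
#' @param detections Tibble with `xmin`, `ymin`, `xmax`, `ymax`, `label`,
#'   `confidence`.
#' @param min_iou Strict lower bound on the accepted IoU (default 0: any
#'   positive overlap).
#' @return `instances` with `stage`, `confidence`, `match_iou` and
#'   `detection` (matched row index, NA if unassigned) filled in.
#' @export
match_instances <- function(instances, detections, min_iou = 0) {
  n <- nrow(instances)
  instances$match_iou <- rep(NA_real_, n)
  instances$detection <- rep(NA_integer_, n)
  if (!n) return(instances)
  if (is.null(detections) || !nrow(detections)) {
    instances$stage <- "unassigned"
    return(instances)
  }
  db <- as.matrix(detections[, c("xmin", "ymin", "xmax", "ymax")])
  for (i in seq_len(n)) {
    ib <- c(instances$xmin[i], instances$ymin[i], instances$xmax[i], instances$ymax[i])
    ious <- box_iou(matrix(ib, nrow(db), 4, byrow = TRUE), db)
    ord <- order(-ious, -detections$confidence, seq_along(ious))
    j <- ord[1]
    if (ious[j] > min_iou) {
      instances$stage[i] <- as.character(detections$label[j])
      instances$confidence[i] <- detections$confidence[j]
      instances$match_iou[i] <- ious[j]
      instances$detection[i] <- j
    } else {
      instances$stage[i] <- "unassigned"
    }
  }
  instances
}

#' Keep only the desired growth stages
#'
#' Removes unassigned instances and those labeled with rejection classes
#' (intermediate, defocused, microcolony by default).
#'
#' @param instances Labeled instance tibble.
#' @param keep Character vector of stages to retain.
#' @return Filtered tibble.
#' @export
filter_stages <- function(instances, keep = c("dividing", "rod")) {
  dplyr::filter(instances, .data$stage %in% keep)
}

#' Filter rod/dividing misclassifications by an Otsu length threshold
#'
#' An Otsu threshold `T` on the pooled length histogram of rod + dividing
#' instances separates the two length distributions; rods longer than `T`
#' and dividing cells no longer than `T` are discarded (not relabeled).
#'
#' @param instances Labeled instance tibble with `length` populated.
#' @param nbins Histogram bins for the Otsu computation (default 64).
#' @return Filtered tibble with the threshold in `attr(, "threshold")`
#'   (`NA` with a warning when no threshold exists).
#' @export
otsu_length_filter <- function(instances, nbins = 64) {
  sel <- instances$stage %in% c("rod", "dividing") & is.finite(instances$length)
  lens <- instances$length[sel]
  if (length(lens) < 2 || diff(range(lens)) == 0) {
    warning("cell lengths carry no separable threshold; passing instances through")
    attr(instances, "threshold") <- NA_real_
    return(instances)
  }
  thr <- otsu_threshold(lens, nbins)
  drop <- sel & ((instances$stage == "rod" & instances$length > thr) |
                   (instances$stage == "dividing" & instances$length <= thr))
  out <- instances[!drop, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Geometric growth-stage classifier
#'
#' Reference detector stand-in requiring no trained model: the cell's width
#' profile along its long axis is measured by perpendicular marching; a cell
#' is `"dividing"` when the profile has an interior minimum below 85% of the
#' median width near mid-cell, `"intermediate"` when such a minimum sits
#' off-center, and `"rod"` otherwise. Confidence maps the constriction depth
#' into `[0.5, 1]`.
#'
#' @param mask Logical instance mask (cropped or full-frame).
#' @param n_samples Width-profile sampling positions (default 41).
#' @return One-row detection tibble (`xmin`, `ymin`, `xmax`, `ymax`,
#'   `label`, `confidence`).
#' @export
classify_stage_geometric <- function(mask, n_samples = 41) {
  bb <- mask_bbox(mask)
  if (is.null(bb)) stop("empty mask", call. = FALSE)
  ax <- axis_from_moments(mask)
  pos <- seq(0.05, 0.95, length.out = n_samples)
  widths <- vapply(pos, function(p) {
    pt <- axis_point(ax, p)
    perp_extent(mask, pt, ax$theta)
  }, numeric(1))
  med <- stats::median(widths, na.rm = TRUE)
  interior <- pos > 0.2 & pos < 0.8
  ratio <- widths / med
  label <- "rod"
  conf <- 0.6
  if (any(interior & ratio < 0.85, na.rm = TRUE)) {
    k <- which(interior)[which.min(ratio[interior])]
    conf <- 0.5 + 0.5 * min(1, (0.85 - ratio[k]) / 0.35)
    label <- if (abs(pos[k] - 0.5) <= 0.2) "dividing" else "intermediate"
  }
  tibble::tibble(xmin = bb$xmin, ymin = bb$ymin, xmax = bb$xmax, ymax = bb$ymax,
                 label = label, confidence = conf)
}

#' Run the geometric classifier over an instance table
#'
#' @param instances Instance tibble from [extract_instances()].
#' @return Detection tibble, one row per instance (in instance order).
#' @export
detect_stages_geometric <- function(instances) {
  if (!nrow(instances)) {
    return(tibble::tibble(xmin = numeric(), ymin = numeric(), xmax = numeric(),
                          ymax = numeric(), label = character(), confidence = numeric()))
  }
  rows <- lapply(seq_len(nrow(instances)), function(i) {
    det <- classify_stage_geometric(instances$mask[[i]])
    # bbox back to frame coordinates
    det$xmin <- det$xmin + instances$col0[i] - 1
    det$xmax <- det$xmax + instances$col0[i] - 1
    det$ymin <- det$ymin + instances$row0[i] - 1
    det$ymax <- det$ymax + instances$row0[i] - 1
    det
  })
  dplyr::bind_rows(rows)
}
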