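# Tiled three-class semantic segmentation and instance extraction.
# The full frame is reflect-padded and cut into overlapping square tiles;
# a pluggable backend scores each tile into background / membrane / body;
# tile scores are blended back with a separable squared-triangle
# ("second-order spline") window; body components become instances after
# an exact 3-px dilation compensating the membrane class.

#' Build a tile grid over a frame
#'
#' Tile origins sit at multiples of the stride in padded coordinates with
#' `count_axis = ceiling(dim / stride) + 1` tiles per axis; padding is split
#' as evenly as possible. A 1392 x 1040 frame at 256 px tiles and 50%
#' overlap yields 12 x 10 = 120 tiles.
#'
#' @param width,height Frame size in pixels.
#' @param tile_size Square tile side (even, default 256).
#' @param overlap Fractional overlap between neighboring tiles in `[0, 1)`,
#'   default 0.5.
#' @return A `tile_grid` list: tile size, stride, per-axis counts, 1-based
#'   tile origins in padded coordinates, and padding extents.
#' @export
tile_grid <- function(width, height, tile_size = 256, overlap = 0.5) {
  stopifnot(width >= 2, height >= 2, tile_size %% 2 == 0, overlap >= 0, overlap < 1)
  stride <- as.integer(round(tile_size * (1 - overlap)))
  if (stride < 1) stop("overlap too large: stride rounds to 0", call. = FALSE)
  nx <- as.integer(ceiling(width / stride) + 1)
  ny <- as.integer(ceiling(height / stride) + 1)
  padded_w <- (nx - 1L) * stride + tile_size
  padded_h <- (ny - 1L) * stride + tile_size
  pad_x <- padded_w - width
  pad_y <- padded_h - height
  structure(list(
    width = as.integer(width), height = as.integer(height),
    tile_size = as.integer(tile_size), overlap = overlap, stride = stride,
    nx = nx, ny = ny, n_tiles = nx * ny,
    origin_x = (seq_len(nx) - 1L) * stride + 1L,
    origin_y = (seq_len(ny) - 1L) * stride + 1L,
    pad_left = pad_x %/% 2L, pad_right = pad_x - pad_x %/% 2L,
    pad_top = pad_y %/% 2L, pad_bottom = pad_y - pad_y %/% 2L
  ), class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d frame, %d px tiles, %.0f%% overlap: %d x %d = %d tiles\n",
              x$width, x$height, x$tile_size, 100 * x$overlap, x$nx, x$ny, x$n_tiles))
  invisible(x)
}

#' Cut a frame into overlapping tiles
#'
#' @param frame Numeric matrix `[height, width]`.
#' @inheritParams tile_grid
#' @return List with `grid` (a [tile_grid()]) and `tiles` (list of
#'   `tile_size` x `tile_size` matrices in row-major tile order: x fastest).
#' @export
tile_image <- function(frame, tile_size = 256, overlap = 0.5) {
  grid <- tile_grid(ncol(frame), nrow(frame), tile_size, overlap)
  padded <- pad_reflect(frame, grid$pad_top, grid$pad_bottom, grid$pad_left, grid$pad_right)
  ts <- grid$tile_size
  tiles <- vector("list", grid$n_tiles)
  k <- 1L
  for (iy in seq_len(grid$ny)) {
    for (ix in seq_len(grid$nx)) {
      oy <- grid$origin_y[iy]; ox <- grid$origin_x[ix]
      tiles[[k]] <- padded[oy:(oy + ts - 1), ox:(ox + ts - 1)]
      k <- k + 1L
    }
  }
  list(grid = grid, tiles = tiles)
}

# Squared-triangle window along one tile axis, length n; strictly positive.
spline_window <- function(n) {
  u <- (seq_len(n) - 0.5) / n
  (1 - abs(2 * u - 1))^2
}

#' Blend predicted tiles back to a full frame
#'
#' Per-pixel weighted average with a separable squared-triangle window,
#' renormalized so weights sum to 1 everywhere (interior and edges alike);
#' the result is cropped back to the original frame size. Constant tiles
#' reproduce a constant frame exactly and smooth fields round-trip through
#' [tile_image()] to within floating-point error.
#'
#' @param grid A [tile_grid()].
#' @param tiles List of predictions, one per tile: matrices
#'   (`tile_size^2`) or arrays `tile_size x tile_size x C` for C classes.
#' @return Matrix `[height, width]` or array `[height, width, C]`.
#' @export
blend_tiles <- function(grid, tiles) {
  stopifnot(inherits(grid, "tile_grid"))
  if (length(tiles) != grid$n_tiles)
    stop("expected ", grid$n_tiles, " tiles, got ", length(tiles), call. = FALSE)
  ts <- grid$tile_size
  first <- tiles[[1]]
  nc_classes <- if (length(dim(first)) == 3) dim(first)[3] else 1L
  ph <- (grid$ny - 1L) * grid$stride + ts
  pw <- (grid$nx - 1L) * grid$stride + ts
  w1 <- spline_window(ts)
  wt <- outer(w1, w1)
  num <- array(0, c(ph, pw, nc_classes))
  den <- matrix(0, ph, pw)
  k <- 1L
  for (iy in seq_len(grid$ny)) {
    for (ix in seq_len(grid$nx)) {
      oy <- grid$origin_y[iy]; ox <- grid$origin_x[ix]
      rows <- oy:(oy + ts - 1); cols <- ox:(ox + ts - 1)
      tl <- tiles[[k]]
      if (length(dim(tl)) != 3) tl <- array(tl, c(ts, ts, 1L))
      if (!all(dim(tl) == c(ts, ts, nc_classes)))
        stop("tile ", k, " has wrong shape", call. = FALSE)
      for (cc in seq_len(nc_classes))
        num[rows, cols, cc] <- num[rows, cols, cc] + tl[, , cc] * wt
      den[rows, cols] <- den[rows, cols] + wt
      k <- k + 1L
    }
  }
  rows <- grid$pad_top + seq_len(grid$height)
  cols <- grid$pad_left + seq_len(grid$width)
  out <- array(0, c(grid$height, grid$width, nc_classes))
  for (cc in seq_len(nc_classes))
    out[, , cc] <- num[rows, cols, cc] / den[rows, cols]
  if (nc_classes == 1L) out[, , 1] else out
}

#' Prediction backends for semantic segmentation
#'
#' A backend is a function `(tiles, grid) -> list of tile_size x tile_size x 3`
#' class-score arrays (classes ordered background, membrane, body).
#' `backend_oracle()` replays a known semantic mask (e.g. synthetic ground
#' truth); `backend_classical()` thresholds the phase-contrast frame (Otsu),
#' fills holes, and assigns the 3-px inner rim to the membrane class — a
#' dependency-free stand-in for a trained model on clean images.
#'
#' @param semantic Integer matrix with values 0/1/2 (oracle backend).
#' @param frame Phase-contrast matrix the classical backend will segment.
#' @return A backend function.
#' @name backends
#' @export
backend_oracle <- function(semantic) {
  onehot <- lapply(0:2, function(v) matrix(as.numeric(semantic == v), nrow(semantic)))
  function(tiles, grid) {
    planes <- lapply(onehot, function(p) tile_image(p, grid$tile_size, grid$overlap)$tiles)
    lapply(seq_len(grid$n_tiles), function(k) {
      a <- array(0, c(grid$tile_size, grid$tile_size, 3))
      for (cc in 1:3) a[, , cc] <- planes[[cc]][[k]]
      a
    })
  }
}

#' @rdname backends
#' @export
backend_classical <- function(frame) {
  rg <- range(frame)
  sem <- if (diff(rg) == 0) {
    matrix(0L, nrow(frame), ncol(frame))
  } else {
    scaled <- (frame - rg[1]) / diff(rg)
    thr <- EBImage::otsu(EBImage::Image(scaled))
    cells <- scaled < thr  # dark cells on bright background
    cells <- matrix(as.logical(EBImage::fillHull(matrix(as.integer(cells), nrow(cells)))),
                    nrow(cells))
    make_semantic_from_foreground(cells)
  }
  backend_oracle(sem)
}

# Foreground mask -> 3-class semantic (per-component 3-px rim as membrane).
make_semantic_from_foreground <- function(fg) {
  sem <- matrix(0L, nrow(fg), ncol(fg))
  body <- erode_disc(fg, 3)
  sem[fg] <- 1L
  sem[body] <- 2L
  sem
}

#' Predict the 3-class semantic mask of a frame
#'
#' Composition tile -> backend -> blend -> argmax. Ties in the blended class
#' scores resolve with priority body > membrane > background, so borderline
#' pixels do not split cells.
#'
#' @param frame Numeric matrix (phase-contrast channel).
#' @param backend A backend function (see [backends]); default is
#'   [backend_classical()] on `frame`.
#' @inheritParams tile_grid
#' @return Integer semantic matrix (0 background, 1 membrane, 2 body).
#' @export
predict_semantic <- function(frame, backend = NULL, tile_size = 256, overlap = 0.5) {
  if (is.null(backend)) backend <- backend_classical(frame)
  ti <- tile_image(frame, tile_size, overlap)
  grid <- ti$grid
  tiles <- backend(ti$tiles, grid)
  if (length(tiles) != grid$n_tiles)
    stop("backend returned ", length(tiles), " tiles, expected ", grid$n_tiles, call. = FALSE)
  if (length(dim(tiles[[1]])) != 3 || dim(tiles[[1]])[3] != 3)
    stop("backend must emit 3 class planes per tile", call. = FALSE)
  scores <- blend_tiles(grid, tiles)
  # argmax with priority body > membrane > background
  best <- scores[, , 3]
  lab <- matrix(2L, nrow(best), ncol(best))
  upd <- scores[, , 2] > best
  lab[upd] <- 1L
  best[upd] <- scores[, , 2][upd]
  upd <- scores[, , 1] > best
  lab[upd] <- 0L
  lab
}

# Moments-based long-axis length of a cropped mask; NA if degenerate.
mask_axis_length <- function(mask) {
  ax <- tryCatch(axis_from_moments(mask), error = function(e) NULL)
  if (is.null(ax)) NA_real_ else ax$length
}

#' Extract cell instances from a semantic mask
#'
#' One instance per 8-connected component of the body class; each instance
#' mask is its body component dilated by exactly 3 px (Euclidean disc) and
#' clipped to the frame, compensating the 3-px membrane class. Dilation
#' never merges instances: every body component keeps its own mask even if
#' dilated masks overlap.
#'
#' @param sem Integer semantic matrix (values 0/1/2).
#' @param min_area Discard body components smaller than this many pixels
#'   (default 5; sub-resolution specks).
#' @return Tibble with one row per instance: `id`, cropped logical `mask`
#'   (list-column) with offsets `row0`/`col0`, pixel-edge bbox
#'   `xmin`/`ymin`/`xmax`/`ymax`, `area` (px of the dilated mask), `length`
#'   (moments long-axis, px), `contour` (list of (x, y) vertex matrices in
#'   frame coordinates), `stage` (`"unassigned"`), `confidence`,
#'   `border_touching`.
#' @export
extract_instances <- function(sem, min_area = 5) {
  H <- nrow(sem); W <- ncol(sem)
  lab <- label_components(sem == 2L)
  n <- max(lab)
  rows <- list()
  if (n > 0) {
    px <- which(lab > 0L)
    comp <- split(px, lab[px])
    id <- 0L
    for (key in names(comp)) {
      idx <- comp[[key]]
      if (length(idx) < min_area) next
      rr <- range((idx - 1L) %% H + 1L)
      cc <- range((idx - 1L) %/% H + 1L)
      r0 <- max(1L, rr[1] - 4L); r1 <- min(H, rr[2] + 4L)
      c0 <- max(1L, cc[1] - 4L); c1 <- min(W, cc[2] + 4L)
      crop <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
      crop[cbind((idx - 1L) %% H + 1L - r0 + 1L, (idx - 1L) %/% H + 1L - c0 + 1L)] <- TRUE
      dil <- dilate_disc(crop, 3)
      w <- which(dil, arr.ind = TRUE)
      rr2 <- range(w[, 1]) + r0 - 1L
      cc2 <- range(w[, 2]) + c0 - 1L
      ctr <- mask_contour(dil)
      ctr[, "x"] <- ctr[, "x"] + c0 - 1L
      ctr[, "y"] <- ctr[, "y"] + r0 - 1L
      id <- id + 1L
      rows[[id]] <- tibble::tibble(
        id = id,
        mask = list(dil), row0 = r0, col0 = c0,
        xmin = cc2[1] - 1, ymin = rr2[1] - 1, xmax = cc2[2], ymax = rr2[2],
        area = sum(dil), length = mask_axis_length(dil),
        contour = list(ctr), stage = "unassigned", confidence = NA_real_,
        border_touching = rr2[1] == 1 || cc2[1] == 1 || rr2[2] == H || cc2[2] == W
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(id = integer(), mask = list(), row0 = integer(),
                          col0 = integer(), xmin = numeric(), ymin = numeric(),
                          xmax = numeric(), ymax = numeric(), area = numeric(),
                          length = numeric(), contour = list(), stage = character(),
                          confidence = numeric(), border_touching = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Drop instances touching the frame border
#'
#' Applied to the final (dilated) masks, so cells whose profile would be
#' truncated never enter the analysis.
#'
#' @param instances Instance tibble from [extract_instances()].
#' @return Filtered tibble.
#' @export
filter_border_instances <- function(instances) {
  dplyr::filter(instances, !.data$border_touching)
}

#' Reconstruct an instance mask at full frame size
#'
#' @param instances Instance tibble.
#' @param id Instance id.
#' @param width,height Frame size.
#' @return Logical matrix.
#' @export
instance_mask <- function(instances, id, width, height) {
  i <- match(id, instances$id)
  if (is.na(i)) stop("no instance with id ", id, call. = FALSE)
  m <- matrix(FALSE, height, width)
  cm <- instances$mask[[i]]
  m[instances$row0[i] + seq_len(nrow(cm)) - 1,
    instances$col0[i] + seq_len(ncol(cm)) - 1] <- cm
  m
}
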