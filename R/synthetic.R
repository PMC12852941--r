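# Synthetic microscopy scenes with full ground truth. Cells are
# spherocylinders (rods) optionally constricted at mid-cell (dividing);
# the phase channel shows dark cells on a bright background and each
# fluorescence channel renders a per-cell spatial signal model on the
# 3-px membrane rim, the region the segmentation's membrane class mirrors.

#' Describe a per-channel fluorescence signal model
#'
#' @param kind One of `"uniform"` (whole rim), `"polar"` (Gaussian cap at one
#'   pole), `"septal"` (Gaussian band at mid-cell), `"random_speckle"`
#'   (random rim pixels), `"none"`.
#' @param pole `"left"` or `"right"`; polar kind only.
#' @param amplitude Peak intensity (arbitrary units, >= 0).
#' @param spread Gaussian falloff in pixels (polar/septal).
#' @param noise_sd Additive Gaussian noise s.d. for this channel contribution.
#' @return A `signal_model` list.
#' @export
signal_model <- function(kind = c("uniform", "polar", "septal", "random_speckle", "none"),
                         pole = c("left", "right"), amplitude = 1,
                         spread = 5, noise_sd = 0) {
  kind <- match.arg(kind)
  pole <- match.arg(pole)
  stopifnot(amplitude >= 0, noise_sd >= 0)
  if (kind %in% c("polar", "septal") && spread <= 0)
    stop("`spread` must be > 0 for polar/septal models", call. = FALSE)
  structure(list(kind = kind, pole = pole, amplitude = amplitude,
                 spread = spread, noise_sd = noise_sd), class = "signal_model")
}

#' Specify one synthetic cell
#'
#' @param center Numeric (x, y) center in pixels.
#' @param angle Long-axis angle in radians, in `[0, pi)`.
#' @param length Pole-to-pole length in pixels.
#' @param width Cell width (diameter) in pixels; `length > width > 0`.
#' @param stage `"rod"`, `"dividing"` or `"intermediate"`.
#' @param septum_depth Mid-cell constriction depth in `[0, 1]`; the minimal
#'   neck width is `width * (1 - septum_depth)`. Must be 0 for rods and > 0
#'   for dividing cells.
#' @param signal_models Named list of [signal_model()]s, one per
#'   fluorescence channel.
#' @param sytox_positive Does this cell carry inner-membrane damage signal?
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(center, angle = 0, length = 30, width = 10,
                      stage = c("rod", "dividing", "intermediate"),
                      septum_depth = 0, signal_models = list(),
                      sytox_positive = FALSE) {
  stage <- match.arg(stage)
  stopifnot(length(center) == 2, length >= width, width > 0,
            septum_depth >= 0, septum_depth <= 1)
  angle <- angle %% pi
  if (stage == "rod" && septum_depth != 0)
    stop("rod cells must have septum_depth = 0", call. = FALSE)
  if (stage == "dividing" && septum_depth <= 0)
    stop("dividing cells must have septum_depth > 0", call. = FALSE)
  structure(list(center = as.numeric(center), angle = angle, length = length,
                 width = width, stage = stage, septum_depth = septum_depth,
                 signal_models = signal_models, sytox_positive = sytox_positive),
            class = "cell_spec")
}

#' Specify a synthetic scene
#'
#' Defaults follow the reference acquisition geometry: 1392 x 1040 px at
#' 0.102 um/px.
#'
#' @param cells List of [cell_spec()]s.
#' @param width,height Frame size in pixels.
#' @param pixel_size Pixel size in um.
#' @param background_level Phase-contrast background intensity.
#' @param background_noise_sd Additive Gaussian noise s.d. on every channel.
#' @param seed Integer seed; rendering is bit-reproducible given the spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(cells, width = 1392, height = 1040, pixel_size = 0.102,
                       background_level = 0.75, background_noise_sd = 0.02,
                       seed = 1L) {
  stopifnot(width >= 2, height >= 2, pixel_size > 0)
  structure(list(cells = cells, width = as.integer(width),
                 height = as.integer(height), pixel_size = pixel_size,
                 background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)), class = "scene_spec")
}

# Cropped rasterization of one cell: logical matrix plus its frame offset.
# Geometry: distance to the central segment of half-length (length-width)/2,
# compared against a local half-width that dips to width/2*(1-septum_depth)
# at mid-cell (Gaussian constriction, sigma = width/3).
rasterize_cell <- function(spec, width, height, clip = FALSE) {
  cx <- spec$center[1]; cy <- spec$center[2]
  hl <- spec$length / 2
  r <- spec$width / 2
  pad <- 3
  x0 <- floor(cx - hl - pad); x1 <- ceiling(cx + hl + pad)
  y0 <- floor(cy - hl - pad); y1 <- ceiling(cy + hl + pad)
  if (!clip && (x0 < 1 || y0 < 1 || x1 > width || y1 > height)) {
    # only an error if the cell itself (not the loose bbox) leaves the frame
    tight <- cell_extent(spec)
    if (tight[1] < 0.5 || tight[2] < 0.5 || tight[3] > width + 0.5 || tight[4] > height + 0.5)
      stop("cell extends beyond image bounds; use clip = TRUE to truncate", call. = FALSE)
  }
  x0 <- max(1, x0); y0 <- max(1, y0); x1 <- min(width, x1); y1 <- min(height, y1)
  xs <- x0:x1; ys <- y0:y1
  dx <- rep(xs - cx, each = length(ys))
  dy <- rep(ys - cy, times = length(xs))
  ca <- cos(spec$angle); sa <- sin(spec$angle)
  u <- dx * ca + dy * sa
  v <- -dx * sa + dy * ca
  a <- pmax(hl - r, 0)
  du <- pmax(abs(u) - a, 0)
  d <- sqrt(du^2 + v^2)
  halfw <- r
  if (spec$septum_depth > 0) {
    sigma <- spec$width / 3
    halfw <- r * (1 - spec$septum_depth * exp(-u^2 / (2 * sigma^2)))
  }
  inside <- d <= halfw
  m <- matrix(inside, nrow = length(ys), ncol = length(xs))
  list(m = m, row0 = y0, col0 = x0)
}

# Conservative tight extent (xmin, ymin, xmax, ymax) of a cell in pixel units.
cell_extent <- function(spec) {
  ca <- abs(cos(spec$angle)); sa <- abs(sin(spec$angle))
  hl <- spec$length / 2; r <- spec$width / 2
  ex <- (hl - r) * ca + r
  ey <- (hl - r) * sa + r
  c(spec$center[1] - ex, spec$center[2] - ey,
    spec$center[1] + ex, spec$center[2] + ey)
}

#' Rasterize one cell to a binary mask
#'
#' Rods become spherocylinders (a rectangle capped by two half-discs);
#' dividing cells additionally carry a symmetric mid-cell constriction whose
#' minimal width is `width * (1 - septum_depth)`.
#'
#' @param spec A [cell_spec()].
#' @param width,height Frame size in pixels.
#' @param clip Truncate cells extending beyond the frame instead of erroring.
#' @return Logical matrix `[height, width]`.
#' @export
make_cell_mask <- function(spec, width, height, clip = FALSE) {
  cr <- rasterize_cell(spec, width, height, clip = clip)
  m <- matrix(FALSE, height, width)
  m[cr$row0 + seq_len(nrow(cr$m)) - 1, cr$col0 + seq_len(ncol(cr$m)) - 1] <- cr$m
  m
}

#' Build the 3-class semantic mask from instance masks
#'
#' Class 1 (membrane) is the 3-px-wide inner rim of each instance, class 2
#' (body) the eroded interior, class 0 background — mirroring the annotation
#' convention the segmentation model is trained against.
#'
#' @param instance_masks List of full-frame logical matrices, pairwise
#'   non-overlapping.
#' @param rim_width Rim width in pixels (default 3).
#' @return Integer matrix with values 0/1/2.
#' @export
make_semantic_mask <- function(instance_masks, rim_width = 3) {
  if (!length(instance_masks)) stop("no instance masks; supply at least an empty frame", call. = FALSE)
  d <- dim(instance_masks[[1]])
  sem <- matrix(0L, d[1], d[2])
  occ <- matrix(FALSE, d[1], d[2])
  for (m in instance_masks) {
    m <- matrix(as.logical(m), d[1], d[2])
    if (any(occ & m)) stop("overlapping instance masks", call. = FALSE)
    occ <- occ | m
    body <- erode_disc(m, rim_width)
    sem[m] <- 1L
    sem[body] <- 2L
  }
  sem
}

# Membrane rim of a cropped mask (crop must not touch the mask).
rim_of <- function(mask, rim_width = 3) mask & !erode_disc(mask, rim_width)

# Render one signal model onto a cropped cell; returns numeric matrix (crop).
render_signal <- function(model, spec, crop) {
  m <- crop$m
  out <- matrix(0, nrow(m), ncol(m))
  if (model$kind == "none" || model$amplitude == 0) return(out)
  rim <- rim_of(m)
  if (!any(rim)) rim <- m
  idx <- which(rim, arr.ind = TRUE)
  x <- crop$col0 + idx[, 2] - 1
  y <- crop$row0 + idx[, 1] - 1
  val <- switch(model$kind,
    uniform = rep(model$amplitude, nrow(idx)),
    polar = {
      dirv <- c(cos(spec$angle), sin(spec$angle))
      if (dirv[1] < 0) dirv <- -dirv
      tip <- spec$center + (if (model$pole == "left") -1 else 1) * (spec$length / 2) * dirv
      dd2 <- (x - tip[1])^2 + (y - tip[2])^2
      model$amplitude * exp(-dd2 / (2 * model$spread^2))
    },
    septal = {
      u <- (x - spec$center[1]) * cos(spec$angle) + (y - spec$center[2]) * sin(spec$angle)
      model$amplitude * exp(-u^2 / (2 * model$spread^2))
    },
    random_speckle = model$amplitude * (stats::runif(nrow(idx)) < 0.15),
    stop("unknown signal model kind: ", model$kind, call. = FALSE)
  )
  out[rim] <- val
  if (model$noise_sd > 0) out[rim] <- pmax(out[rim] + stats::rnorm(sum(rim), 0, model$noise_sd), 0)
  out
}

#' Render a scene to multichannel frame plus ground truth
#'
#' The phase channel shows dark cells on a bright noisy background; each
#' fluorescence channel accumulates the cells' signal models on their
#' membrane rims. Rendering is deterministic given the scene spec (seed
#' included).
#'
#' @param scene A [scene_spec()].
#' @return A `bact_scene` list with elements `frame` (named list of numeric
#'   channel matrices, `"phase"` first), `truth` (list: `cells` tibble with
#'   cropped masks and per-cell metadata, `semantic` 3-class matrix, `boxes`
#'   detection tibble with confidence 1), and `scene` (the input spec).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(scene$seed)
  W <- scene$width; H <- scene$height
  channels <- unique(unlist(lapply(scene$cells, function(s) names(s$signal_models))))
  frame <- c(list(phase = matrix(scene$background_level, H, W)),
             stats::setNames(lapply(channels, function(ch) matrix(0, H, W)), channels))

  crops <- lapply(scene$cells, rasterize_cell, width = W, height = H)
  occ <- matrix(FALSE, H, W)
  rows <- vector("list", length(scene$cells))
  sem <- matrix(0L, H, W)
  for (i in seq_along(scene$cells)) {
    sp <- scene$cells[[i]]
    cr <- crops[[i]]
    ri <- cr$row0 + seq_len(nrow(cr$m)) - 1
    ci <- cr$col0 + seq_len(ncol(cr$m)) - 1
    if (any(occ[ri, ci] & cr$m)) stop("cells overlap in scene", call. = FALSE)
    occ[ri, ci] <- occ[ri, ci] | cr$m
    # phase: dark interior
    ph <- frame$phase[ri, ci]
    ph[cr$m] <- scene$background_level * 0.35
    frame$phase[ri, ci] <- ph
    # semantic
    body <- erode_disc(cr$m, 3)
    sblk <- sem[ri, ci]
    sblk[cr$m] <- 1L
    sblk[body] <- 2L
    sem[ri, ci] <- sblk
    # fluorescence
    for (ch in names(sp$signal_models)) {
      blk <- render_signal(sp$signal_models[[ch]], sp, cr)
      frame[[ch]][ri, ci] <- frame[[ch]][ri, ci] + blk
    }
    idx <- which(cr$m, arr.ind = TRUE)
    rr <- range(ri[idx[, 1]]); cc <- range(ci[idx[, 2]])
    border <- rr[1] == 1 || cc[1] == 1 || rr[2] == H || cc[2] == W
    rows[[i]] <- tibble::tibble(
      id = i, stage = sp$stage, sytox_positive = sp$sytox_positive,
      center_x = sp$center[1], center_y = sp$center[2], angle = sp$angle,
      length = sp$length, width = sp$width, septum_depth = sp$septum_depth,
      xmin = cc[1] - 1, ymin = rr[1] - 1, xmax = cc[2], ymax = rr[2],
      border_touching = border,
      mask = list(cr$m), row0 = cr$row0, col0 = cr$col0,
      signal_kinds = list(vapply(sp$signal_models, `[[`, "", "kind"))
    )
  }
  # frame noise
  if (scene$background_noise_sd > 0)
    for (ch in names(frame))
      frame[[ch]] <- frame[[ch]] + matrix(stats::rnorm(H * W, 0, scene$background_noise_sd), H, W)

  cells <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  boxes <- if (nrow(cells)) {
    tibble::tibble(xmin = cells$xmin, ymin = cells$ymin, xmax = cells$xmax,
                   ymax = cells$ymax, label = cells$stage, confidence = 1)
  } else tibble::tibble(xmin = numeric(), ymin = numeric(), xmax = numeric(),
                        ymax = numeric(), label = character(), confidence = numeric())
  structure(list(frame = frame,
                 truth = list(cells = cells, semantic = sem, boxes = boxes),
                 scene = scene),
            class = "bact_scene")
}

#' Reconstruct a ground-truth instance mask at full frame size
#'
#' @param scene_render A rendered scene from [render_scene()].
#' @param id Ground-truth cell id.
#' @return Logical matrix `[height, width]`.
#' @export
truth_mask <- function(scene_render, id) {
  cells <- scene_render$truth$cells
  i <- match(id, cells$id)
  if (is.na(i)) stop("no ground-truth cell with id ", id, call. = FALSE)
  m <- matrix(FALSE, scene_render$scene$height, scene_render$scene$width)
  cm <- cells$mask[[i]]
  m[cells$row0[i] + seq_len(nrow(cm)) - 1, cells$col0[i] + seq_len(ncol(cm)) - 1] <- cm
  m
}

#' Sample a random synthetic scene of rods and dividing cells
#'
#' Cells are placed by rejection sampling with a minimum 2-px gap between
#' masks (up to `max_attempts` draws, then an error). Morphology defaults
#' emulate exponentially growing E. coli at 0.102 um/px: width ~11 px,
#' newly divided rods ~22 px, dividing cells ~40 px with septum depth
#' 0.3-0.45. Fluorescence channels (and which cells are Sytox-positive) come
#' from the `channel_models` generator.
#'
#' @param n_rods,n_dividing Number of cells per stage.
#' @param width,height Frame size.
#' @param seed Integer seed (drives placement and rendering).
#' @param channel_models Function `(stage, sytox_positive)` returning a named
#'   list of [signal_model()]s for one cell. The default paints a uniform
#'   membrane marker (`"C9"`) plus a `"Sytox"` channel on positive cells.
#' @param sytox_fraction Fraction of cells rendered Sytox-positive.
#' @param snr Signal-to-noise ratio; channel noise s.d. = amplitude / snr.
#' @param max_attempts Placement attempt cap.
#' @inheritParams scene_spec
#' @return A rendered `bact_scene` (see [render_scene()]).
#' @export
synth_scene <- function(n_rods = 10, n_dividing = 10, width = 1392, height = 1040,
                        seed = 1L, channel_models = NULL, sytox_fraction = 1,
                        snr = 10, pixel_size = 0.102, background_noise_sd = 0.02,
                        max_attempts = 1e4) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  if (is.null(channel_models)) {
    channel_models <- function(stage, sytox_positive) {
      mods <- list(C9 = signal_model("uniform", amplitude = 1, noise_sd = 1 / snr))
      if (sytox_positive)
        mods$Sytox <- signal_model("uniform", amplitude = 1, noise_sd = 1 / snr)
      mods
    }
  }
  stages <- c(rep("rod", n_rods), rep("dividing", n_dividing))
  occ <- matrix(FALSE, height, width)
  cells <- list()
  attempts <- 0
  for (stage in stages) {
    placed <- FALSE
    while (!placed) {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("could not place all cells within ", max_attempts, " attempts", call. = FALSE)
      w <- max(stats::rnorm(1, 11, 0.5), 10.2)
      len <- if (stage == "rod") stats::rnorm(1, 22, 2.5) else stats::rnorm(1, 40, 3)
      len <- max(len, w * 1.4)
      # septum stays shallower than the 3-px membrane rim (neck half-width
      # >= 3.5 px) so the body class of a dividing cell remains connected
      sd_ <- if (stage == "dividing") stats::runif(1, 0.25, min(0.35, 1 - 7.2 / w)) else 0
      ang <- stats::runif(1, 0, pi)
      margin <- len / 2 + 4
      if (width - 2 * margin < 1 || height - 2 * margin < 1)
        stop("frame too small for requested cell sizes", call. = FALSE)
      ctr <- c(stats::runif(1, margin, width - margin),
               stats::runif(1, margin, height - margin))
      syt <- stats::runif(1) < sytox_fraction
      sp <- cell_spec(ctr, ang, len, w, stage, septum_depth = sd_,
                      signal_models = channel_models(stage, syt),
                      sytox_positive = syt)
      cr <- rasterize_cell(sp, width, height)
      cand <- dilate_disc(cr$m, 2)  # enforce the 2-px gap
      ri <- cr$row0 + seq_len(nrow(cand)) - 1
      ci <- cr$col0 + seq_len(ncol(cand)) - 1
      if (!any(occ[ri, ci] & cand)) {
        occ[ri, ci] <- occ[ri, ci] | cand
        cells[[length(cells) + 1]] <- sp
        placed <- TRUE
      }
    }
  }
  render_scene(scene_spec(cells, width = width, height = height,
                          pixel_size = pixel_size,
                          background_noise_sd = background_noise_sd,
                          seed = seed))
}
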