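# Long-axis fluorescence intensity profiling. The cell's orientation comes
# from image moments (theta = 1/2 * atan2(2*mu11, mu20 - mu02)); a line at
# that angle is projected from the centroid to the mask border, N positions
# are spread from 5% to 95% of its length, and at each position the
# perpendicular chord through the mask is sampled at half-pixel spacing with
# bilinear interpolation and reduced by max (default) or mean.

#' Image moments of a binary mask
#'
#' Raw spatial moments, centroid and the long-axis angle
#' `theta = 1/2 * atan2(2*mu11, mu20 - mu02)` from the central second
#' moments, with `cx = m10/m00`, `cy = m01/m00`.
#'
#' @param mask Logical or 0/1 matrix.
#' @return A `moment_set` list: `m00`, `m10`, `m01`, `mu11`, `mu20`, `mu02`,
#'   `cx`, `cy`, `theta` (radians in `(-pi/2, pi/2]`).
#' @export
compute_moments <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(w)) stop("empty mask", call. = FALSE)
  x <- w[, 2]; y <- w[, 1]
  m00 <- length(x)
  m10 <- sum(x); m01 <- sum(y)
  cx <- m10 / m00; cy <- m01 / m00
  mu11 <- sum((x - cx) * (y - cy)) / m00
  mu20 <- sum((x - cx)^2) / m00
  mu02 <- sum((y - cy)^2) / m00
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  structure(list(m00 = m00, m10 = m10, m01 = m01, mu11 = mu11, mu20 = mu20,
                 mu02 = mu02, cx = cx, cy = cy, theta = theta),
            class = "moment_set")
}

# March from (x0, y0) along (dx, dy) at `step` px while inside the mask;
# returns the last inside position (the start must be inside).
march_to_border <- function(mask, x0, y0, dx, dy, step = 0.25) {
  # generous upper bound on travel: the mask diagonal
  n_max <- ceiling(sqrt(nrow(mask)^2 + ncol(mask)^2) / step) + 2
  t <- seq(0, by = step, length.out = n_max)
  xs <- x0 + t * dx; ys <- y0 + t * dy
  inside <- points_in_mask(mask, xs, ys)
  k <- which(!inside)[1]
  if (is.na(k)) k <- length(t) + 1
  if (k == 1) return(NULL)
  c(xs[k - 1], ys[k - 1])
}

#' Long axis of a cell from image moments
#'
#' A line at the moments angle is projected from the centroid in both
#' directions until leaving the mask (subpixel marching); the axis is the
#' degree-1 spline (straight segment) through the two border points.
#'
#' @param mask Logical instance mask.
#' @param moments Optional precomputed [compute_moments()] result.
#' @param step Marching step in pixels (default 0.25).
#' @param pixel_size Pixel size in um for `length_um`.
#' @return A `long_axis` list: `points` (k x 2 polyline, here k = 2),
#'   `theta`, `length` (px), `length_um`, `method`.
#' @export
axis_from_moments <- function(mask, moments = NULL, step = 0.25, pixel_size = 0.102) {
  if (is.null(moments)) moments <- compute_moments(mask)
  if (moments$m00 < 2) stop("degenerate mask: needs at least 2 pixels", call. = FALSE)
  if (!points_in_mask(mask, moments$cx, moments$cy))
    stop("centroid lies outside the mask (strongly concave cell); skipping", call. = FALSE)
  d <- c(cos(moments$theta), sin(moments$theta))
  p1 <- march_to_border(mask, moments$cx, moments$cy, -d[1], -d[2], step)
  p2 <- march_to_border(mask, moments$cx, moments$cy, d[1], d[2], step)
  if (is.null(p1) || is.null(p2)) stop("degenerate mask: axis collapsed", call. = FALSE)
  new_axis(rbind(p1, p2), moments$theta, "moments", pixel_size)
}

new_axis <- function(points, theta, method, pixel_size = 0.102) {
  seg <- diff(points)
  len <- sum(sqrt(rowSums(seg^2)))
  if (len <= 0) stop("degenerate mask: axis has zero length", call. = FALSE)
  structure(list(points = unname(points), theta = theta, length = len,
                 length_um = len * pixel_size, method = method,
                 pixel_size = pixel_size), class = "long_axis")
}

#' @export
print.long_axis <- function(x, ...) {
  cat(sprintf("<long_axis> method=%s, length=%.2f px (%.3f um), theta=%.1f deg\n",
              x$method, x$length, x$length_um, x$theta * 180 / pi))
  invisible(x)
}

# Point at fraction t in [0, 1] of the axis arc length.
axis_point <- function(axis, t) {
  pts <- axis$points
  seg <- diff(pts)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  s <- t * cum[length(cum)]
  k <- max(1, min(findInterval(s, cum, rightmost.closed = TRUE), nrow(seg)))
  f <- (s - cum[k]) / seglen[k]
  pts[k, ] + f * seg[k, ]
}

# Local tangent angle at fraction t of the axis.
axis_tangent <- function(axis, t) {
  pts <- axis$points
  seg <- diff(pts)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  s <- t * cum[length(cum)]
  k <- max(1, min(findInterval(s, cum, rightmost.closed = TRUE), nrow(seg)))
  atan2(seg[k, 2], seg[k, 1])
}

# Total extent (px) of the perpendicular chord through the mask at `pt`.
perp_extent <- function(mask, pt, theta, step = 0.5) {
  d <- c(-sin(theta), cos(theta))
  a <- march_to_border(mask, pt[1], pt[2], d[1], d[2], step)
  b <- march_to_border(mask, pt[1], pt[2], -d[1], -d[2], step)
  if (is.null(a) || is.null(b)) return(NA_real_)
  sqrt(sum((a - b)^2))
}

#' Long axis by an alternative method
#'
#' Same contract as [axis_from_moments()]: `"pca"` uses the leading
#' eigenvector of the pixel-coordinate covariance, `"ellipse"` the fitted
#' ellipse's major axis (both then march from the centroid), `"skeleton"`
#' the longest medial path of the thinned mask, spline-smoothed and extended
#' to the mask border. On straight cells all methods agree; on bent cells
#' the skeleton tracks the midline and is the longer axis.
#'
#' @param mask Logical instance mask.
#' @param method One of `"moments"`, `"pca"`, `"ellipse"`, `"skeleton"`.
#' @inheritParams axis_from_moments
#' @return A `long_axis`.
#' @export
cell_axis <- function(mask, method = c("moments", "pca", "ellipse", "skeleton"),
                      step = 0.25, pixel_size = 0.102) {
  method <- match.arg(method)
  if (method == "moments") return(axis_from_moments(mask, step = step, pixel_size = pixel_size))
  if (method == "skeleton") return(axis_skeleton(mask, pixel_size = pixel_size))
  mo <- compute_moments(mask)
  theta <- if (method == "pca") {
    w <- which(mask != 0, arr.ind = TRUE)
    cv <- stats::cov(cbind(w[, 2], w[, 1]))
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    ((atan2(ev[2], ev[1]) + pi / 2) %% pi) - pi / 2
  } else {
    ctr <- mask_contour(mask)
    fe <- fit_ellipse(ctr)
    fe$angle
  }
  if (!points_in_mask(mask, mo$cx, mo$cy))
    stop("centroid lies outside the mask", call. = FALSE)
  d <- c(cos(theta), sin(theta))
  p1 <- march_to_border(mask, mo$cx, mo$cy, -d[1], -d[2], step)
  p2 <- march_to_border(mask, mo$cx, mo$cy, d[1], d[2], step)
  if (is.null(p1) || is.null(p2)) stop("degenerate mask", call. = FALSE)
  new_axis(rbind(p1, p2), theta, method, pixel_size)
}

#' Direct least-squares ellipse fit
#'
#' Fitzgibbon-style conic fit with the ellipse constraint, returning center,
#' semi-axes (major first) and major-axis angle.
#'
#' @param points Two-column (x, y) matrix, at least 5 points.
#' @return List `center`, `axes` (semi-axis lengths, major first), `angle`
#'   (radians in `(-pi/2, pi/2]`).
#' @export
fit_ellipse <- function(points) {
  if (nrow(points) < 5) stop("ellipse fit needs >= 5 points", call. = FALSE)
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  x <- points[, 1] - mx
  y <- points[, 2] - my
  # Halir & Flusser's numerically stable partitioning of Fitzgibbon's fit
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) stop("degenerate contour: ellipse fit failed", call. = FALSE)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  k <- which(cond > 0)
  if (!length(k)) stop("degenerate contour: ellipse fit failed", call. = FALSE)
  a1 <- vecs[, k[1]]
  coef <- c(a1, Tm %*% a1)
  A <- coef[1]; B <- coef[2]; Cc <- coef[3]; Dd <- coef[4]; E <- coef[5]; F <- coef[6]
  disc <- B^2 - 4 * A * Cc
  cx <- (2 * Cc * Dd - B * E) / disc
  cy <- (2 * A * E - B * Dd) / disc
  num <- 2 * (A * E^2 + Cc * Dd^2 - B * Dd * E + disc * F)
  sq <- sqrt((A - Cc)^2 + B^2)
  ax1 <- -sqrt(num * (A + Cc + sq)) / disc
  ax2 <- -sqrt(num * (A + Cc - sq)) / disc
  # ax1 belongs to the angle below; if it is the minor axis, rotate by 90 deg
  ang <- 0.5 * atan2(-B, Cc - A)
  if (ax1 < ax2) ang <- ang + pi / 2
  ang <- ((ang + pi / 2) %% pi) - pi / 2
  if (ang <= -pi / 2 + 1e-12) ang <- pi / 2
  list(center = c(mx + cx, my + cy),
       axes = sort(c(ax1, ax2), decreasing = TRUE), angle = ang)
}

# --- skeleton axis -----------------------------------------------------------

# Zhang-Suen thinning of a (cropped) logical mask.
zhang_suen_thin <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask))
  # pad to keep neighborhoods in bounds
  p <- matrix(0L, nrow(img) + 2, ncol(img) + 2)
  p[2:(nrow(img) + 1), 2:(ncol(img) + 1)] <- img
  nbr <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0L, nr, nc)
    rs <- (1 + max(0, dr)):(nr + min(0, dr))
    cs <- (1 + max(0, dc)):(nc + min(0, dc))
    out[rs - dr, cs - dc] <- m[rs, cs]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      P2 <- nbr(p, -1, 0); P3 <- nbr(p, -1, 1); P4 <- nbr(p, 0, 1)
      P5 <- nbr(p, 1, 1); P6 <- nbr(p, 1, 0); P7 <- nbr(p, 1, -1)
      P8 <- nbr(p, 0, -1); P9 <- nbr(p, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      seqs <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- Reduce(`+`, lapply(1:8, function(i) (seqs[[i]] == 0) * (seqs[[i + 1]] == 1)))
      if (phase == 1) {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        p[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nrow(img) + 1), 2:(ncol(img) + 1)] == 1L
}

# Longest path through the skeleton's 8-connected pixel graph via double BFS.
skeleton_longest_path <- function(skel) {
  w <- which(skel, arr.ind = TRUE)
  n <- nrow(w)
  if (n == 0) return(NULL)
  if (n == 1) return(cbind(x = w[1, 2], y = w[1, 1]))
  key <- paste(w[, 1], w[, 2])
  id <- stats::setNames(seq_len(n), key)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    r <- w[i, 1]; c <- w[i, 2]
    nb <- expand.grid(r = r + (-1:1), c = c + (-1:1))
    nb <- nb[!(nb$r == r & nb$c == c), ]
    hit <- id[paste(nb$r, nb$c)]
    adj[[i]] <- unname(hit[!is.na(hit)])
  }
  bfs <- function(start) {
    dist <- rep(-1L, n); prev <- rep(NA_integer_, n)
    dist[start] <- 0L
    q <- c(start); head <- 1L
    while (head <= length(q)) {
      u <- q[head]; head <- head + 1L
      for (v in adj[[u]]) if (dist[v] < 0) {
        dist[v] <- dist[u] + 1L
        prev[v] <- u
        q <- c(q, v)
      }
    }
    list(dist = dist, prev = prev)
  }
  b1 <- bfs(1L)
  s <- which.max(b1$dist)
  b2 <- bfs(s)
  e <- which.max(b2$dist)
  path <- integer(0)
  v <- e
  while (!is.na(v)) {
    path <- c(v, path)
    v <- b2$prev[v]
  }
  cbind(x = w[path, 2], y = w[path, 1])
}

# Skeleton-based long axis: thin, take the longest medial path, smooth it,
# and extend both ends along the terminal direction to the mask border.
axis_skeleton <- function(mask, pixel_size = 0.102) {
  skel <- zhang_suen_thin(mask)
  path <- skeleton_longest_path(skel)
  if (is.null(path) || nrow(path) < 2) {
    # near-isotropic mask thins to a point: fall back to the moments line
    ax <- axis_from_moments(mask, pixel_size = pixel_size)
    ax$method <- "skeleton"
    return(ax)
  }
  pts <- path
  if (nrow(pts) >= 8) {
    t <- seq_len(nrow(pts))
    fx <- stats::smooth.spline(t, pts[, 1], df = min(6, nrow(pts) - 1))
    fy <- stats::smooth.spline(t, pts[, 2], df = min(6, nrow(pts) - 1))
    tt <- seq(1, nrow(pts), length.out = max(16, nrow(pts)))
    pts <- cbind(stats::predict(fx, tt)$y, stats::predict(fy, tt)$y)
  }
  # extend the tips to the border along the averaged terminal direction
  # (a single zigzag segment would bias the tip angle)
  k <- max(2, min(nrow(pts) - 1, round(nrow(pts) / 4)))
  d_head <- pts[1, ] - pts[k + 1, ]
  d_tail <- pts[nrow(pts), ] - pts[nrow(pts) - k, ]
  ext <- function(p0, d) {
    d <- d / sqrt(sum(d^2))
    hit <- march_to_border(mask, p0[1], p0[2], d[1], d[2], 0.25)
    if (is.null(hit)) p0 else hit
  }
  pts <- rbind(ext(pts[1, ], d_head), pts, ext(pts[nrow(pts), ], d_tail))
  mo <- compute_moments(mask)
  new_axis(pts, mo$theta, "skeleton", pixel_size)
}

# --- sampling ---------------------------------------------------------------

#' Equidistant sampling positions along the axis
#'
#' `p_i = 0.05 + (i - 1) * 0.90 / (N - 1)`: N positions from 5% to 95% of the
#' axis length (for N = 21: 5%, 9.5%, ..., 90.5%, 95%).
#'
#' @param n Number of positions (>= 2).
#' @return Numeric vector of axis-length fractions.
#' @export
sample_positions <- function(n = 21) {
  if (n < 2) stop("need at least 2 sampling positions", call. = FALSE)
  (5 + (seq_len(n) - 1) * 90 / (n - 1)) / 100
}

#' Sample per-channel intensity profiles along a cell's long axis
#'
#' At each sampling position the chord perpendicular to the axis is clipped
#' to the mask, sampled at `step`-pixel spacing with bilinear interpolation,
#' and reduced to one value per channel by `max` (default) or `mean`.
#'
#' @param mask Logical instance mask (full frame, or cropped with channels
#'   cropped identically).
#' @param channels Named list of numeric channel matrices, same shape as
#'   `mask`.
#' @param axis Optional [axis_from_moments()]/[cell_axis()] result; computed
#'   from the mask when missing.
#' @param n_positions Number of axis positions (default 21).
#' @param reduction `"max"` or `"mean"`.
#' @param step Perpendicular sampling step in px (default 0.5).
#' @return Tibble: `channel`, `index`, `position` (axis fraction), `value`,
#'   plus `reduction`; the axis is attached as `attr(, "axis")`.
#' @export
sample_profile <- function(mask, channels, axis = NULL, n_positions = 21,
                           reduction = c("max", "mean"), step = 0.5) {
  reduction <- match.arg(reduction)
  stopifnot(is.list(channels), length(channels) > 0, !is.null(names(channels)))
  if (is.null(axis)) axis <- axis_from_moments(mask)
  pos <- sample_positions(n_positions)
  redfun <- if (reduction == "max") max else mean
  vals <- matrix(NA_real_, length(pos), length(channels),
                 dimnames = list(NULL, names(channels)))
  for (i in seq_along(pos)) {
    pt <- axis_point(axis, pos[i])
    th <- axis_tangent(axis, pos[i])
    d <- c(-sin(th), cos(th))
    up <- march_steps(mask, pt, d, step)
    dn <- march_steps(mask, pt, -d, step)
    xs <- c(rev(dn$x), pt[1], up$x)
    ys <- c(rev(dn$y), pt[2], up$y)
    for (ch in names(channels))
      vals[i, ch] <- redfun(interp_bilinear(channels[[ch]], xs, ys))
  }
  out <- tidyr::expand_grid(channel = names(channels), index = seq_along(pos))
  out$position <- pos[out$index]
  out$value <- vals[cbind(out$index, match(out$channel, colnames(vals)))]
  out$reduction <- reduction
  attr(out, "axis") <- axis
  out
}

# Coordinates of the marching samples (excluding the start) while inside.
march_steps <- function(mask, pt, d, step) {
  n_max <- ceiling(sqrt(nrow(mask)^2 + ncol(mask)^2) / step) + 2
  t <- seq(step, by = step, length.out = n_max)
  xs <- pt[1] + t * d[1]; ys <- pt[2] + t * d[2]
  inside <- points_in_mask(mask, xs, ys)
  k <- which(!inside)[1]
  if (is.na(k)) k <- length(t) + 1
  list(x = xs[seq_len(k - 1)], y = ys[seq_len(k - 1)])
}

#' Orient a profile so the brighter half sits on the left
#'
#' If the right half of the orientation channel has higher mean intensity
#' than the left half (middle position excluded for odd N), the value order
#' of every channel is reversed. Idempotent.
#'
#' @param profile Single-cell profile tibble from [sample_profile()].
#' @param orient_channel Channel driving the decision (e.g. `"C9"` or
#'   `"HADA"`); defaults to the first channel.
#' @param value_col Column to compare and reorder (default `"value"`).
#' @return The profile with values possibly reversed and a logical `flipped`
#'   column.
#' @export
orient_profile <- function(profile, orient_channel = NULL, value_col = "value") {
  n <- max(profile$index)
  if (is.null(orient_channel)) orient_channel <- profile$channel[1]
  if (!orient_channel %in% profile$channel)
    stop("orientation channel '", orient_channel, "' not in profile", call. = FALSE)
  oc <- profile[profile$channel == orient_channel, ]
  oc <- oc[order(oc$index), ]
  half <- floor(n / 2)
  left <- mean(oc[[value_col]][seq_len(half)])
  right <- mean(oc[[value_col]][(n - half + 1):n])
  flip <- right > left
  out <- profile
  if (flip) {
    cols <- intersect(unique(c(value_col, "value", "rel_intensity")), names(out))
    for (ch in unique(out$channel)) {
      sel <- which(out$channel == ch)
      sel <- sel[order(out$index[sel])]
      for (vc in cols) out[[vc]][sel] <- rev(out[[vc]][sel])
    }
  }
  out$flipped <- flip
  out
}

#' Normalize a profile to a per-channel maximum of 1
#'
#' Each channel is divided by its own maximum so different fluorophores can
#' be compared on a relative-intensity scale; an all-zero channel stays zero
#' with a warning.
#'
#' @param profile Profile tibble.
#' @param value_col Column to normalize (default `"value"`).
#' @return Profile with an added `rel_intensity` column.
#' @export
normalize_profile <- function(profile, value_col = "value") {
  out <- dplyr::group_by(profile, .data$channel)
  out <- dplyr::mutate(out, rel_intensity = {
    v <- .data[[value_col]]
    m <- max(v)
    if (m <= 0) {
      warning("channel with no signal left unnormalized (all zeros)", call. = FALSE)
      v
    } else v / m
  })
  dplyr::ungroup(out)
}

#' Gate cells on fluorescence positivity
#'
#' The channel is Gaussian-blurred (sigma = 5 px), triangle-thresholded on
#' its intensity histogram, and a cell is positive when at least one pixel
#' of its mask exceeds the threshold. Used to select Sytox-positive
#' (inner-membrane-damaged) cells and to drop signal-free cells.
#'
#' @param channel Numeric fluorescence matrix (full frame).
#' @param instances Instance tibble (cropped masks + offsets).
#' @param sigma Blur sigma in px (default 5).
#' @param nbins Histogram bins for the threshold (default 256).
#' @return Tibble `id`, `positive`; threshold in `attr(, "threshold")`
#'   (`NA` with all-negative cells and a warning for a flat image).
#' @export
fluorescence_gate <- function(channel, instances, sigma = 5, nbins = 256) {
  blurred <- gaussian_blur(channel, sigma)
  thr <- triangle_threshold_image(blurred, nbins)
  if (is.na(thr)) {
    warning("flat fluorescence image: threshold undefined, all cells negative", call. = FALSE)
    out <- tibble::tibble(id = instances$id, positive = FALSE)
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  pos <- vapply(seq_len(nrow(instances)), function(i) {
    m <- instances$mask[[i]]
    blk <- blurred[instances$row0[i] + seq_len(nrow(m)) - 1,
                   instances$col0[i] + seq_len(ncol(m)) - 1, drop = FALSE]
    any(blk[m] > thr)
  }, logical(1))
  out <- tibble::tibble(id = instances$id, positive = pos)
  attr(out, "threshold") <- thr
  out
}

# Gaussian blur via EBImage (sigma in px).
gaussian_blur <- function(img, sigma) {
  matrix(as.numeric(EBImage::gblur(img, sigma = sigma)), nrow(img))
}

#' Aggregate oriented, normalized profiles into per-class distributions
#'
#' Per (class, channel, position): median, quartiles (type-7 linear
#' interpolation) and Tukey whiskers at the most extreme values within
#' 1.5 x IQR of the quartiles — the statistics drawn in the profile box
#' plots.
#'
#' @param profiles Tibble of pooled profiles with columns `stage`,
#'   `channel`, `index`, `position` and the value column.
#' @param value_col Column to summarize (default `"rel_intensity"`).
#' @return A `profile_set` tibble: `stage`, `channel`, `index`, `position`,
#'   `n`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`.
#' @export
aggregate_profiles <- function(profiles, value_col = "rel_intensity") {
  if (!nrow(profiles)) {
    warning("no profiles to aggregate", call. = FALSE)
    return(structure(tibble::tibble(), class = c("profile_set", class(tibble::tibble()))))
  }
  out <- dplyr::group_by(profiles, .data$stage, .data$channel, .data$index, .data$position)
  out <- dplyr::summarise(
    out,
    n = dplyr::n(),
    q1 = stats::quantile(.data[[value_col]], 0.25, type = 7, names = FALSE),
    median = stats::quantile(.data[[value_col]], 0.5, type = 7, names = FALSE),
    q3 = stats::quantile(.data[[value_col]], 0.75, type = 7, names = FALSE),
    whisker_lo = min(.data[[value_col]][.data[[value_col]] >= .data$q1 - 1.5 * (.data$q3 - .data$q1)]),
    whisker_hi = max(.data[[value_col]][.data[[value_col]] <= .data$q3 + 1.5 * (.data$q3 - .data$q1)]),
    .groups = "drop"
  )
  structure(out, class = c("profile_set", class(out)))
}

#' Min-max normalize log10 geometric mean fluorescence intensities
#'
#' `y = 100 * (log10(v) - min) / (max - min)`: maps the smallest value to 0
#' and the largest to 100 on a log scale, for plotting different channels'
#' flow-cytometry time courses together.
#'
#' @param values Positive numeric vector (>= 2 values, not all equal).
#' @return Numeric vector on the 0-100 scale.
#' @export
normalize_geomfi <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(values <= 0)) stop("GeoMFI values must be positive", call. = FALSE)
  lg <- log10(values)
  rg <- range(lg)
  if (diff(rg) == 0) stop("all values equal: normalization undefined", call. = FALSE)
  100 * (lg - rg[1]) / diff(rg)
}
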