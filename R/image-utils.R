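#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
#' @import tibble
NULL

# Images are plain numeric matrices indexed [row = y, col = x]; pixel (x, y)
# has its center at coordinate (x, y), 1-based. Bounding boxes are kept in
# pixel-edge coordinates (xmin = first column - 1, xmax = last column) so that
# widths equal pixel counts.

#' Euclidean disc structuring element
#'
#' Binary kernel containing every pixel whose center lies within `radius`
#' (Euclidean distance) of the origin. Used for the exact 3-px
#' dilation/erosion that compensates the 3-px membrane class.
#'
#' @param radius Disc radius in pixels.
#' @return A square 0/1 matrix of odd side length.
#' @export
disc_kernel <- function(radius = 3) {
  stopifnot(radius >= 0)
  r <- ceiling(radius)
  d <- seq(-r, r)
  k <- outer(d, d, function(y, x) as.numeric(x^2 + y^2 <= radius^2))
  k
}

#' Dilate or erode a binary mask by a Euclidean disc
#'
#' @param mask Logical or 0/1 matrix.
#' @param radius Disc radius in pixels.
#' @name mask-morphology
#' @return Logical matrix of the same shape.
#' @export
dilate_disc <- function(mask, radius = 3) {
  m <- EBImage::dilate(matrix(as.numeric(mask), nrow(mask)), disc_kernel(radius))
  matrix(m > 0.5, nrow(mask))
}

#' @rdname mask-morphology
#' @export
erode_disc <- function(mask, radius = 3) {
  m <- EBImage::erode(matrix(as.numeric(mask), nrow(mask)), disc_kernel(radius))
  matrix(m > 0.5, nrow(mask))
}

#' Label connected components with 8-connectivity
#'
#' Thin bodies must not fragment across diagonals, so components are joined
#' through corner contacts as well as edges.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of labels (0 = background), labels consecutive from 1.
#' @export
label_components <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m))
  n <- max(lab)
  if (n <= 1L) return(lab)
  # EBImage::bwlabel is 4-connected; union labels that touch diagonally.
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]),  as.vector(lab[-nr, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Bilinear interpolation of image values at subpixel points
#'
#' Points outside the image are clamped to the border pixel centers.
#'
#' @param img Numeric matrix `[y, x]`.
#' @param x,y Numeric vectors of coordinates (pixel centers at integers).
#' @return Numeric vector of interpolated values.
#' @export
interp_bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(y), nr - 1L); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  idx <- function(yy, xx) (xx - 1) * nr + yy
  v00 <- img[idx(y0, x0)]; v10 <- img[idx(y0, x1)]
  v01 <- img[idx(y1, x0)]; v11 <- img[idx(y1, x1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

#' Test whether subpixel points fall inside a binary mask
#'
#' A point belongs to the mask if its nearest pixel center is foreground.
#'
#' @param mask Logical matrix.
#' @param x,y Coordinates.
#' @return Logical vector.
#' @keywords internal
points_in_mask <- function(mask, x, y) {
  nr <- nrow(mask); nc <- ncol(mask)
  xi <- round(x); yi <- round(y)
  ok <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
  out <- logical(length(x))
  out[ok] <- mask[(xi[ok] - 1) * nr + yi[ok]]
  out
}

#' Reflect-pad a matrix
#'
#' Mirror padding that excludes the edge pixel (as in half-sample-symmetric
#' reflection about the border pixel), matching the tiling convention.
#'
#' @param m Matrix.
#' @param top,bottom,left,right Pad widths in pixels.
#' @return Padded matrix.
#' @export
pad_reflect <- function(m, top = 0, bottom = 0, left = 0, right = 0) {
  nr <- nrow(m); nc <- ncol(m)
  reflect_idx <- function(t, n) {
    if (n == 1) return(rep(1L, length(t)))
    p <- (t - 1) %% (2 * n - 2)
    as.integer(ifelse(p < n, p + 1, 2 * n - 1 - p))
  }
  ridx <- reflect_idx(seq(1 - top, nr + bottom), nr)
  cidx <- reflect_idx(seq(1 - left, nc + right), nc)
  m[ridx, cidx, drop = FALSE]
}

# Tight bounding box of a logical mask, in pixel-edge coordinates.
# Returns list(xmin, ymin, xmax, ymax, rows, cols) or NULL for empty masks.
mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (!nrow(w)) return(NULL)
  rr <- range(w[, 1]); cc <- range(w[, 2])
  list(xmin = cc[1] - 1, ymin = rr[1] - 1, xmax = cc[2], ymax = rr[2],
       rows = rr, cols = cc)
}

# Crop a mask to its bbox with an optional margin (clipped to the frame).
crop_to_bbox <- function(mask, bb, margin = 0) {
  r0 <- max(1, bb$rows[1] - margin); r1 <- min(nrow(mask), bb$rows[2] + margin)
  c0 <- max(1, bb$cols[1] - margin); c1 <- min(ncol(mask), bb$cols[2] + margin)
  list(m = mask[r0:r1, c0:c1, drop = FALSE], row0 = r0, col0 = c0)
}

#' Trace the outer contour of a binary mask
#'
#' Ordered boundary vertices (x, y) of the largest foreground object,
#' in the package's 1-based pixel-center coordinates.
#'
#' @param mask Logical matrix containing a single object.
#' @return A two-column matrix of (x, y) vertices.
#' @export
mask_contour <- function(mask) {
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask)))
  if (!length(oc)) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  v <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  # EBImage returns 0-based coords with column 1 indexing the first array
  # dimension (our y / row).
  cbind(x = v[, 2] + 1, y = v[, 1] + 1)
}
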