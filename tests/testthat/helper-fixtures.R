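# Shared fixtures: small deterministic cells and scenes built in code.

rod_mask <- function(length = 40, width = 10, angle = 0, dim = c(100, 80),
                     center = dim / 2) {
  make_cell_mask(cell_spec(center, angle, length, width), dim[1], dim[2])
}

dividing_mask <- function(length = 40, width = 11, depth = 0.5, angle = 0,
                          dim = c(100, 80), center = dim / 2) {
  make_cell_mask(cell_spec(center, angle, length, width, stage = "dividing",
                           septum_depth = depth), dim[1], dim[2])
}

# Dense sub-pixel rasterization oracle for the spherocylinder area:
# fraction of `k^2` sub-samples per pixel inside the ideal shape.
spherocylinder_area_oracle <- function(length, width, k = 8) {
  hl <- length / 2; r <- width / 2; a <- hl - r
  off <- (seq_len(k) - 0.5) / k - 0.5
  xs <- seq(-hl - 1, hl + 1, by = 1)
  ys <- seq(-r - 1, r + 1, by = 1)
  total <- 0
  for (x in xs) for (y in ys) {
    sx <- x + off
    sy <- y + off
    du <- pmax(abs(rep(sx, each = k)) - a, 0)
    d <- sqrt(du^2 + rep(sy, k)^2)
    total <- total + mean(d <= r)
  }
  total
}

# Brute-force Otsu oracle: exhaustively maximize between-class variance over
# every bin split of the same histogram the implementation uses.
otsu_oracle <- function(x, nbins = 64) {
  edges <- seq(min(x), max(x), length.out = nbins + 1)
  bins <- pmin(findInterval(x, edges, rightmost.closed = TRUE), nbins)
  counts <- tabulate(bins, nbins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  sb <- rep(-Inf, nbins - 1)
  for (k in seq_len(nbins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):nbins] * mids[(k + 1):nbins]) / n1
    w0 <- n0 / sum(counts)
    sb[k] <- w0 * (1 - w0) * (mu0 - mu1)^2
  }
  # same plateau convention as the implementation contract: middle of the
  # flat maximum (empty-gap bins leave the criterion constant)
  top <- which(sb >= max(sb) - 1e-12 * max(1, abs(max(sb))))
  edges[top[ceiling(length(top) / 2)] + 1]
}

# Brute-force triangle-threshold oracle: true point-to-line perpendicular
# distance for every bin between the peak and the far tail end.
triangle_oracle <- function(counts) {
  n <- length(counts)
  nz <- which(counts > 0)
  if (length(nz) < 2) return(NA_integer_)
  peak <- which.max(counts)
  lo <- nz[1]; hi <- nz[length(nz)]
  flipped <- (peak - lo) > (hi - peak)
  cts <- counts
  if (flipped) {
    cts <- rev(counts)
    peak <- n - peak + 1
    hi <- n - lo + 1
  }
  if (hi <= peak) return(NA_integer_)
  p1 <- c(peak, cts[peak]); p2 <- c(hi, cts[hi])
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  dist <- vapply(peak:hi, function(i) {
    w <- c(i, cts[i]) - p1
    abs(v[1] * w[2] - v[2] * w[1]) / nv
  }, numeric(1))
  k <- (peak:hi)[which.max(dist)]
  if (flipped) k <- n - k + 1
  as.integer(k)
}

# Lattice-counting IoU oracle for integer-coordinate boxes.
iou_lattice_oracle <- function(a, b) {
  cells_in <- function(box) {
    if (box[3] <= box[1] || box[4] <= box[2]) return(matrix(numeric(0), ncol = 2))
    as.matrix(expand.grid(x = seq(box[1], box[3] - 1), y = seq(box[2], box[4] - 1)))
  }
  ca <- cells_in(a); cb <- cells_in(b)
  key <- function(m) paste(m[, 1], m[, 2])
  inter <- length(intersect(key(ca), key(cb)))
  un <- length(union(key(ca), key(cb)))
  if (un == 0) 0 else inter / un
}

# Full-frame IoU between a ground-truth cell and its best-matching instance.
best_instance_iou <- function(scene_render, instances, cell_id) {
  W <- scene_render$scene$width; H <- scene_render$scene$height
  tm <- truth_mask(scene_render, cell_id)
  if (!nrow(instances)) return(0)
  max(vapply(instances$id, function(j) {
    im <- instance_mask(instances, j, W, H)
    sum(tm & im) / sum(tm | im)
  }, numeric(1)))
}
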