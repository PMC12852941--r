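# Average cell shapes. Instance contours are normalized into [-1, 1]^2 with
# the long axis along x (via an ellipse fit), resampled to a common vertex
# count by arc length, and averaged by minimizing the mean over members of
# the symmetric mean-Hausdorff distance with adaptive-moment gradient steps,
# initialized at the member contour closest to all others.

#' Normalize a contour into `[-1, 1]^2` with the major axis along x
#'
#' An ellipse is fitted to the vertices; the contour is translated to the
#' ellipse center, rotated by minus the ellipse angle, and each axis scaled
#' by its own extent (anisotropic) so the shape spans `[-1, 1]` per axis.
#'
#' @param contour Two-column (x, y) vertex matrix (>= 5 vertices).
#' @param isotropic Scale both axes by the larger extent instead, preserving
#'   aspect ratio.
#' @return Normalized (x, y) vertex matrix.
#' @export
normalize_contour <- function(contour, isotropic = FALSE) {
  contour <- as.matrix(contour)
  fe <- fit_ellipse(contour)
  x <- contour[, 1] - fe$center[1]
  y <- contour[, 2] - fe$center[2]
  ca <- cos(-fe$angle); sa <- sin(-fe$angle)
  xr <- x * ca - y * sa
  yr <- x * sa + y * ca
  if (max(abs(yr)) > max(abs(xr))) {  # ellipse angle ambiguity: enforce x-major
    tmp <- xr; xr <- -yr; yr <- tmp
  }
  sx <- max(abs(xr)); sy <- max(abs(yr))
  if (sx == 0 || sy == 0) stop("degenerate (collinear) contour", call. = FALSE)
  if (isotropic) sx <- sy <- max(sx, sy)
  out <- cbind(x = xr / sx, y = yr / sy)
  out
}

#' Resample a closed contour to M vertices equally spaced by arc length
#'
#' Orientation is preserved and the parameterization starts at the vertex
#' whose angle about the centroid is closest to 0, so resampled batches stay
#' in correspondence.
#'
#' @param contour Two-column (x, y) vertex matrix (closed polygon; the
#'   closing edge back to the first vertex is implied).
#' @param m Target vertex count (>= 4).
#' @return `m` x 2 vertex matrix.
#' @export
resample_contour <- function(contour, m = 64) {
  if (m < 4) stop("need at least 4 vertices", call. = FALSE)
  v <- as.matrix(contour)
  if (nrow(v) < 3) stop("contour needs at least 3 vertices", call. = FALSE)
  # drop a duplicated closing vertex
  if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  ctr <- colMeans(v)
  ang <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
  start <- which.min(abs(ang))
  v <- v[c(start:nrow(v), seq_len(start - 1)), , drop = FALSE]
  closed <- rbind(v, v[1, ])
  seg <- diff(closed)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate contour: zero perimeter", call. = FALSE)
  s <- (seq_len(m) - 1) * total / m
  k <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(seg))
  f <- (s - cum[k]) / seglen[k]
  out <- closed[k, , drop = FALSE] + seg[k, , drop = FALSE] * f
  colnames(out) <- c("x", "y")
  out
}

#' Symmetric mean Hausdorff distance between two vertex sets
#'
#' `1/2 * (mean_a min_b d(a, b) + mean_b min_a d(a, b))`: the average
#' nearest-vertex distance, symmetrized. Used both as the averaging loss and
#' to pick the initial estimate.
#'
#' @param a,b Two-column vertex matrices (counts may differ).
#' @return Non-negative distance.
#' @export
hausdorff_mean <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) stop("empty contour", call. = FALSE)
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  0.5 * (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min))))
}

# Loss and subgradient of mean_k hausdorff_mean(V, members[[k]]) wrt V.
avg_shape_loss_grad <- function(V, members) {
  M <- nrow(V)
  K <- length(members)
  grad <- matrix(0, M, 2)
  loss <- 0
  for (Cm in members) {
    n <- nrow(Cm)
    dx <- outer(V[, 1], Cm[, 1], `-`)
    dy <- outer(V[, 2], Cm[, 2], `-`)
    d <- sqrt(dx^2 + dy^2)
    # directed V -> C
    j1 <- max.col(-d, ties.method = "first")
    d1 <- d[cbind(seq_len(M), j1)]
    loss <- loss + 0.5 * mean(d1)
    nz <- d1 > 1e-12
    grad[nz, 1] <- grad[nz, 1] + 0.5 * dx[cbind(seq_len(M), j1)][nz] / (d1[nz] * M * K)
    grad[nz, 2] <- grad[nz, 2] + 0.5 * dy[cbind(seq_len(M), j1)][nz] / (d1[nz] * M * K)
    # directed C -> V
    i2 <- max.col(-t(d), ties.method = "first")
    d2 <- d[cbind(i2, seq_len(n))]
    loss <- loss + 0.5 * mean(d2)
    nz <- d2 > 1e-12
    if (any(nz)) {
      gx <- 0.5 * dx[cbind(i2, seq_len(n))][nz] / (d2[nz] * n * K)
      gy <- 0.5 * dy[cbind(i2, seq_len(n))][nz] / (d2[nz] * n * K)
      ii <- i2[nz]
      for (t in seq_along(ii)) {
        grad[ii[t], 1] <- grad[ii[t], 1] + gx[t]
        grad[ii[t], 2] <- grad[ii[t], 2] + gy[t]
      }
    }
  }
  list(loss = loss / K, grad = grad)
}

#' Optimize the average shape of a contour batch
#'
#' Starting from the member contour with the lowest summed mean-Hausdorff
#' distance to all others, vertex positions are refined by adaptive-moment
#' gradient descent on the loss `mean_k hausdorff_mean(shape, member_k)`,
#' for at most `max_iter` iterations with early stop when the loss changes
#' by less than `tol`. The incumbent best iterate is tracked, so the
#' reported loss trace is non-increasing and the result never falls behind
#' the initialization.
#'
#' @param contours List of normalized, vertex-equalized (x, y) matrices.
#' @param max_iter Iteration cap (default 1000).
#' @param tol Early-stop loss-change tolerance (default 1e-8).
#' @param lr Adaptive-moment step size (default 1e-2).
#' @return An `average_shape` object: `vertices`, `final_loss`,
#'   `iterations_used`, `converged`, `trace` (incumbent loss per accepted
#'   iteration), `initial_loss`, `n_contours`.
#' @export
average_shape <- function(contours, max_iter = 1000, tol = 1e-8, lr = 1e-2) {
  if (!length(contours)) stop("no contours", call. = FALSE)
  members <- lapply(contours, as.matrix)
  K <- length(members)
  if (K == 1) {
    return(structure(list(vertices = members[[1]], final_loss = 0,
                          iterations_used = 0L, converged = TRUE,
                          trace = numeric(0), initial_loss = 0, n_contours = 1L),
                     class = "average_shape"))
  }
  # initialization: member with the lowest summed mean-Hausdorff distance
  dsum <- numeric(K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    h <- hausdorff_mean(members[[i]], members[[j]])
    dsum[i] <- dsum[i] + h
    dsum[j] <- dsum[j] + h
  }
  V <- members[[which.min(dsum)]]
  lg <- avg_shape_loss_grad(V, members)
  best_loss <- lg$loss
  initial_loss <- lg$loss
  best_V <- V
  prev_loss <- lg$loss
  trace <- numeric(0)
  m1 <- matrix(0, nrow(V), 2)
  m2 <- matrix(0, nrow(V), 2)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    m1 <- b1 * m1 + (1 - b1) * lg$grad
    m2 <- b2 * m2 + (1 - b2) * lg$grad^2
    m1h <- m1 / (1 - b1^iter)
    m2h <- m2 / (1 - b2^iter)
    V <- V - lr * m1h / (sqrt(m2h) + eps)
    lg <- avg_shape_loss_grad(V, members)
    if (lg$loss < best_loss) {
      best_loss <- lg$loss
      best_V <- V
    }
    trace <- c(trace, best_loss)
    if (abs(lg$loss - prev_loss) < tol) {
      converged <- TRUE
      break
    }
    prev_loss <- lg$loss
  }
  structure(list(vertices = best_V, final_loss = best_loss,
                 iterations_used = iter, converged = converged,
                 trace = trace, initial_loss = initial_loss,
                 n_contours = K),
            class = "average_shape")
}

#' @export
print.average_shape <- function(x, ...) {
  cat(sprintf("<average_shape> %d contours, %d vertices, loss %.3g (%s after %d iterations)\n",
              x$n_contours, nrow(x$vertices), x$final_loss,
              if (x$converged) "converged" else "iteration cap reached",
              x$iterations_used))
  invisible(x)
}

#' Tidy an average shape into a vertex tibble
#'
#' @param x An `average_shape`.
#' @param ... Unused.
#' @return Tibble `vertex`, `x`, `y`.
#' @export
tidy.average_shape <- function(x, ...) {
  v <- x$vertices
  tibble::tibble(vertex = seq_len(nrow(v)), x = v[, 1], y = v[, 2])
}

#' One-row summary of an average-shape fit
#'
#' @param x An `average_shape`.
#' @param ... Unused.
#' @return Tibble with `n_contours`, `n_vertices`, `final_loss`,
#'   `initial_loss`, `iterations_used`, `converged`.
#' @export
glance.average_shape <- function(x, ...) {
  tibble::tibble(n_contours = x$n_contours, n_vertices = nrow(x$vertices),
                 final_loss = x$final_loss, initial_loss = x$initial_loss,
                 iterations_used = x$iterations_used, converged = x$converged)
}

#' Generic tidiers
#'
#' `tidy()` turns a fitted object into a per-component tibble; `glance()`
#' into a one-row fit summary.
#'
#' @param x Object.
#' @param ... Method arguments.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot an average shape as a closed polygon
#'
#' @param object An `average_shape`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.average_shape <- function(object, ...) {
  df <- tidy(object)
  df <- rbind(df, df[1, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "normalized x (long axis)", y = "normalized y") +
    ggplot2::theme_minimal()
}
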