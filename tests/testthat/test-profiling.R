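test_that("moments of axis-aligned rectangles give exact angle and centroid", {
  m <- matrix(FALSE, 40, 60)
  m[17:23, 20:40] <- TRUE  # 21 x 7, long axis horizontal
  mo <- compute_moments(m)
  expect_equal(mo$theta, 0)
  expect_equal(mo$cx, 30)
  expect_equal(mo$cy, 20)
  mt <- t(m)
  expect_equal(compute_moments(mt)$theta, pi / 2)
})

test_that("moments angle matches PCA within 1 degree on rotated shapes", {
  set.seed(12)
  for (rep in 1:100) {
    ang <- runif(1, 0, pi)
    len <- runif(1, 28, 46)
    wid <- runif(1, 8, 14)
    m <- make_cell_mask(cell_spec(c(60, 50), ang, len, wid), 120, 100)
    mo <- compute_moments(m)
    w <- which(m, arr.ind = TRUE)
    ev <- eigen(stats::cov(cbind(w[, 2], w[, 1])), symmetric = TRUE)$vectors[, 1]
    pca <- ((atan2(ev[2], ev[1]) + pi / 2) %% pi) - pi / 2
    d <- abs(mo$theta - pca) %% pi
    expect_lt(min(d, pi - d) * 180 / pi, 1)
  }
})

test_that("the moments axis spans the rod's pole-to-pole extent", {
  m <- rod_mask(40, 10)
  ax <- axis_from_moments(m)
  expect_lt(abs(ax$length - 40), 1.5)
  expect_equal(ax$length_um, ax$length * 0.102)
  # disc: any direction, length = diameter
  dm <- make_cell_mask(cell_spec(c(30, 30), length = 20, width = 20), 60, 60)
  expect_lt(abs(axis_from_moments(dm)$length - 20), 1.5)
})

test_that("a 1-px mask is skipped as degenerate", {
  m <- matrix(FALSE, 10, 10)
  m[5, 5] <- TRUE
  expect_error(axis_from_moments(m), "degenerate|axis")
})

test_that("all four axis methods agree on a straight rod within 2 degrees", {
  m <- make_cell_mask(cell_spec(c(60, 45), 0.6, 44, 11), 120, 90)
  angs <- vapply(c("moments", "pca", "ellipse", "skeleton"), function(meth) {
    ax <- cell_axis(m, meth)
    p <- ax$points
    a <- atan2(p[nrow(p), 2] - p[1, 2], p[nrow(p), 1] - p[1, 1])
    ((a + pi / 2) %% pi) - pi / 2
  }, numeric(1))
  d <- abs(angs - 0.6)
  expect_true(all(pmin(d, pi - d) < 2 * pi / 180))
  lens <- vapply(c("moments", "pca", "ellipse", "skeleton"),
                 function(meth) cell_axis(m, meth)$length, numeric(1))
  expect_lt(diff(range(lens)), 2.5)
})

test_that("the skeleton axis out-measures the moments line on a bent cell", {
  th <- seq(-0.7, 0.7, length.out = 160)
  bm <- matrix(FALSE, 90, 110)
  for (k in seq_along(th)) {
    cx <- 55 + 38 * sin(th[k]); cy <- 35 + 30 * (1 - cos(th[k]))
    ys <- pmax(1, pmin(90, round(cy) + (-5:5)))
    xs <- pmax(1, pmin(110, round(cx) + (-5:5)))
    bm[as.matrix(expand.grid(ys, xs))] <- TRUE
  }
  expect_gte(cell_axis(bm, "skeleton")$length, axis_from_moments(bm)$length)
})

test_that("sampling positions follow the 5%-95% equidistant rule", {
  p <- sample_positions(21)
  expect_equal(p[1], 0.05)
  expect_equal(p[2], 0.095)
  expect_equal(p[20], 0.905)
  expect_equal(p[21], 0.95)
  expect_equal(sample_positions(2), c(0.05, 0.95))
  expect_true(all(abs(diff(diff(p))) < 1e-12))
  expect_error(sample_positions(1), "2")
})

test_that("a constant channel yields a constant profile for both reductions", {
  m <- rod_mask(36, 10)
  ch <- list(A = matrix(2.5, 80, 100))
  for (red in c("max", "mean")) {
    pr <- sample_profile(m, ch, reduction = red)
    expect_true(all(abs(pr$value - 2.5) < 1e-12))
  }
})

test_that("a uniform membrane signal gives a flat max-reduced profile", {
  sp <- cell_spec(c(50, 40), 0.3, 40, 11,
                  signal_models = list(C9 = signal_model("uniform", amplitude = 1)))
  sc <- render_scene(scene_spec(list(sp), width = 100, height = 80,
                                background_noise_sd = 0, seed = 1))
  pr <- sample_profile(truth_mask(sc, 1), list(C9 = sc$frame$C9))
  expect_lt(max(abs(pr$value - mean(pr$value))) / mean(pr$value), 0.15)
})

test_that("a bright pixel at one end shows up at the matching profile end", {
  m <- rod_mask(40, 10, dim = c(100, 80))
  ch <- matrix(0, 80, 100)
  ch[40, 32] <- 5  # near the left pole (cell spans x ~ 30..70)
  pr <- sample_profile(m, list(A = ch))
  expect_gt(pr$value[1], pr$value[21])
})

test_that("orientation flips right-heavy profiles and is idempotent", {
  base <- tidyr::expand_grid(channel = c("C9", "Sytox"), index = 1:21)
  base$position <- sample_positions(21)[base$index]
  base$value <- ifelse(base$channel == "C9", base$index / 21, (22 - base$index) / 21)
  o1 <- orient_profile(base, "C9")
  expect_true(o1$flipped[1])
  # C9 now left-heavy; Sytox flipped in the same direction
  c9 <- o1$value[o1$channel == "C9"][order(o1$index[o1$channel == "C9"])]
  expect_equal(c9, rev(base$value[base$channel == "C9"]))
  o2 <- orient_profile(o1, "C9")
  expect_false(o2$flipped[1])
  expect_equal(o2$value, o1$value)
  # left-heavy and symmetric profiles stay unchanged
  sym <- base
  sym$value <- rep(1, nrow(sym))
  expect_false(orient_profile(sym, "C9")$flipped[1])
})

test_that("normalization scales each channel to max 1", {
  pr <- tibble::tibble(channel = rep(c("A", "B"), each = 3), index = rep(1:3, 2),
                       position = rep(c(0.05, 0.5, 0.95), 2),
                       value = c(2, 4, 8, 1, 1, 1))
  out <- normalize_profile(pr)
  expect_equal(out$rel_intensity[out$channel == "A"], c(0.25, 0.5, 1))
  expect_equal(out$rel_intensity[out$channel == "B"], c(1, 1, 1))
  expect_equal(normalize_profile(out, "rel_intensity")$rel_intensity,
               out$rel_intensity)
  pr0 <- tibble::tibble(channel = "Z", index = 1:3, position = c(0.05, 0.5, 0.95),
                        value = c(0, 0, 0))
  expect_warning(out0 <- normalize_profile(pr0), "zero")
  expect_equal(out0$rel_intensity, c(0, 0, 0))
})

test_that("rotating a scene by 90 degrees leaves normalized profiles unchanged", {
  sp <- cell_spec(c(50, 40), 0, 40, 11,
                  signal_models = list(C9 = signal_model("polar", pole = "left",
                                                         amplitude = 1, spread = 5)))
  sc <- render_scene(scene_spec(list(sp), width = 100, height = 80,
                                background_noise_sd = 0, seed = 1))
  m <- truth_mask(sc, 1)
  prof <- function(mask, img) {
    p <- normalize_profile(orient_profile(sample_profile(mask, list(C9 = img)), "C9"))
    p$rel_intensity[order(p$index)]
  }
  a <- prof(m, sc$frame$C9)
  rot <- function(x) t(x)[, rev(seq_len(nrow(x))), drop = FALSE]  # 90 deg CCW
  b <- prof(rot(m) > 0, rot(sc$frame$C9))
  expect_lt(max(abs(a - b)), 0.02)
})

test_that("polar cells peak in the leftmost quarter after orientation", {
  set.seed(5)
  hits <- 0
  n <- 40
  for (k in seq_len(n)) {
    pole <- sample(c("left", "right"), 1)
    sp <- cell_spec(c(60, 45), runif(1, 0, pi), runif(1, 30, 44), runif(1, 10, 12),
                    signal_models = list(C9 = signal_model("polar", pole = pole,
                                                           amplitude = 1, spread = 5,
                                                           noise_sd = 0.1)))
    sc <- render_scene(scene_spec(list(sp), width = 120, height = 90,
                                  background_noise_sd = 0.02, seed = k))
    pr <- normalize_profile(orient_profile(
      sample_profile(truth_mask(sc, 1), list(C9 = sc$frame$C9)), "C9"))
    pr <- pr[order(pr$index), ]
    hits <- hits + (which.max(pr$rel_intensity) <= ceiling(0.25 * 21))
  }
  expect_gte(hits / n, 0.95)
})

test_that("fluorescence gate flags only cells containing supra-threshold signal", {
  sp1 <- cell_spec(c(30, 30), 0, 30, 10,
                   signal_models = list(S = signal_model("uniform", amplitude = 2)))
  sp2 <- cell_spec(c(85, 60), 0, 30, 10, signal_models = list(S = signal_model("none")))
  sc <- render_scene(scene_spec(list(sp1, sp2), width = 120, height = 90,
                                background_noise_sd = 0.01, seed = 2))
  inst <- extract_instances(predict_semantic(sc$frame$phase,
                                             backend_oracle(sc$truth$semantic)))
  g <- fluorescence_gate(sc$frame$S, inst)
  expect_equal(sort(g$positive), c(FALSE, TRUE))
  # blob outside every mask: all negative
  img <- matrix(0.01, 90, 120)
  img[5:10, 100:110] <- 3
  g2 <- fluorescence_gate(img, inst)
  expect_false(any(g2$positive))
  # zero image: all negative with warning
  expect_warning(g3 <- fluorescence_gate(matrix(0, 90, 120), inst), "flat")
  expect_false(any(g3$positive))
})

test_that("profile aggregation uses type-7 quartiles and 1.5 IQR whiskers", {
  prof <- tibble::tibble(stage = "rod", channel = "C9", index = 1, position = 0.05,
                         rel_intensity = c(1, 2, 3, 4, 100))
  ps <- aggregate_profiles(prof)
  expect_equal(ps$median, 3)
  expect_equal(ps$q1, 2)
  expect_equal(ps$q3, 4)
  expect_equal(ps$whisker_hi, 4)  # 100 lies outside q3 + 1.5 * IQR
  expect_equal(ps$whisker_lo, 1)
  # single profile: median = value, IQR = 0
  single <- tibble::tibble(stage = "rod", channel = "C9", index = 1:3,
                           position = c(0.05, 0.5, 0.95),
                           rel_intensity = c(0.2, 0.9, 1))
  ps1 <- aggregate_profiles(single)
  expect_equal(ps1$median, single$rel_intensity)
  expect_equal(ps1$q3 - ps1$q1, rep(0, 3))
  # identical profiles: IQR = 0 everywhere
  two <- dplyr::bind_rows(single, single)
  ps2 <- aggregate_profiles(two)
  expect_true(all(ps2$q3 - ps2$q1 == 0))
  expect_equal(ps2$n, rep(2L, 3))
})

test_that("GeoMFI normalization is log-linear onto 0-100", {
  expect_equal(normalize_geomfi(c(10, 1000, 100000)), c(0, 50, 100))
  expect_equal(normalize_geomfi(c(1, 10, 100)), c(0, 50, 100))
  expect_equal(normalize_geomfi(c(7, 700)), c(0, 100))
  expect_error(normalize_geomfi(c(-1, 10)), "positive")
  expect_error(normalize_geomfi(c(5, 5)), "equal")
  expect_error(normalize_geomfi(3), "2")
})
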