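test_that("rod mask area matches the dense sub-pixel rasterization oracle", {
  # half-integer centers avoid the measure-zero case of the shape boundary
  # running exactly through pixel centers
  for (p in list(c(40, 10), c(30, 8), c(50, 12))) {
    m <- rod_mask(p[1], p[2], center = c(50.5, 40.5))
    oracle <- spherocylinder_area_oracle(p[1], p[2])
    expect_lt(abs(sum(m) - oracle) / oracle, 0.05)
  }
})

test_that("degenerate spherocylinder (length = width) is a disc", {
  m <- make_cell_mask(cell_spec(c(30, 30), length = 20, width = 20), 60, 60)
  oracle <- pi * 100
  expect_lt(abs(sum(m) - oracle) / oracle, 0.05)
  # isotropy: bounding box is square
  bb <- which(m, arr.ind = TRUE)
  expect_equal(diff(range(bb[, 1])), diff(range(bb[, 2])))
})

test_that("zero septum depth reproduces the rod mask", {
  # septum_depth 0 only differs by the stage tag, not geometry
  a <- make_cell_mask(cell_spec(c(50, 40), 0.3, 40, 10), 100, 80)
  b <- make_cell_mask(cell_spec(c(50, 40), 0.3, 40, 10, stage = "intermediate",
                                septum_depth = 0), 100, 80)
  expect_identical(a, b)
})

test_that("dividing mask narrows at mid-cell by the septum depth", {
  m <- dividing_mask(depth = 0.5, width = 12)
  widths <- colSums(m)[colSums(m) > 0]
  interior <- widths[5:(length(widths) - 4)]
  # continuous neck ratio is 0.5; a pixel of discretization on either side
  expect_lt(min(interior) / max(widths), 0.7)
  # and the neck plateau is centered at mid-cell
  neck <- mean(which(interior == min(interior))) + 4
  expect_lt(abs(neck - (length(widths) + 1) / 2), 2)
})

test_that("cells beyond the frame error unless clipped", {
  sp <- cell_spec(c(5, 5), 0, 40, 10)
  expect_error(make_cell_mask(sp, 100, 80), "bounds")
  m <- make_cell_mask(sp, 100, 80, clip = TRUE)
  expect_gt(sum(m), 0)
})

test_that("cell_spec enforces stage/septum invariants", {
  expect_error(cell_spec(c(0, 0), 0, 30, 10, stage = "rod", septum_depth = 0.2), "rod")
  expect_error(cell_spec(c(0, 0), 0, 30, 10, stage = "dividing", septum_depth = 0), "dividing")
  expect_error(cell_spec(c(0, 0), 0, 5, 10))  # length < width
})

test_that("scene rendering is deterministic given the spec", {
  mk <- function() synth_scene(n_rods = 3, n_dividing = 2, width = 300, height = 240, seed = 5)
  a <- mk(); b <- mk()
  expect_identical(a$frame, b$frame)
  expect_identical(a$truth$semantic, b$truth$semantic)
  expect_identical(a$truth$boxes, b$truth$boxes)
})

test_that("uniform signal covers every membrane pixel at the stated amplitude", {
  sp <- cell_spec(c(40, 30), 0.5, 36, 10,
                  signal_models = list(C9 = signal_model("uniform", amplitude = 2)))
  sc <- render_scene(scene_spec(list(sp), width = 80, height = 60,
                                background_noise_sd = 0, seed = 1))
  m <- truth_mask(sc, 1)
  rim <- m & !erode_disc(m, 3)
  expect_true(all(sc$frame$C9[rim] == 2))
  expect_true(all(sc$frame$C9[!m] == 0))
})

test_that("polar signal concentrates at the stated pole", {
  for (pole in c("left", "right")) {
    sp <- cell_spec(c(50, 40), 0, 44, 11,
                    signal_models = list(C9 = signal_model("polar", pole = pole,
                                                           amplitude = 1, spread = 5)))
    sc <- render_scene(scene_spec(list(sp), width = 100, height = 80,
                                  background_noise_sd = 0, seed = 1))
    img <- sc$frame$C9
    w <- which(img > 0, arr.ind = TRUE)
    cx <- sum(img[w] * w[, 2]) / sum(img[w])
    if (pole == "left") expect_lt(cx, 50) else expect_gt(cx, 50)
    # >= 90% of total fluorescence within 25% axis length of the pole
    tip_x <- if (pole == "left") 50 - 22 else 50 + 22
    near <- abs(w[, 2] - tip_x) <= 0.25 * 44
    expect_gte(sum(img[w][near]) / sum(img[w]), 0.9)
  }
})

test_that("semantic mask uses a 3-px rim and erosion-based body", {
  m <- matrix(FALSE, 60, 60)
  m[10:50, 10:50] <- outer(1:41, 1:41, function(i, j) (i - 21)^2 + (j - 21)^2 <= 400)
  sem <- make_semantic_mask(list(m))
  body <- erode_disc(m, 3)
  expect_identical(sem == 2, body)
  expect_identical(sem > 0, m)
})

test_that("semantic mask construction rejects overlapping instances", {
  m1 <- matrix(FALSE, 40, 40); m1[10:20, 10:20] <- TRUE
  m2 <- matrix(FALSE, 40, 40); m2[15:25, 15:25] <- TRUE
  expect_error(make_semantic_mask(list(m1, m2)), "overlap")
})

test_that("separated cells give disjoint body components", {
  m1 <- matrix(FALSE, 60, 90); m1[20:40, 10:40] <- TRUE
  m2 <- matrix(FALSE, 60, 90); m2[20:40, 50:80] <- TRUE
  sem <- make_semantic_mask(list(m1, m2))
  expect_equal(max(label_components(sem == 2)), 2)
})

test_that("ground truth recovers through segmentation at IoU >= 0.95", {
  sc <- synth_scene(n_rods = 5, n_dividing = 5, width = 512, height = 400, seed = 21)
  inst <- extract_instances(predict_semantic(sc$frame$phase,
                                             backend_oracle(sc$truth$semantic)))
  expect_equal(nrow(inst), nrow(sc$truth$cells))
  for (i in sc$truth$cells$id[!sc$truth$cells$border_touching]) {
    expect_gte(best_instance_iou(sc, inst, i), 0.95)
  }
})

test_that("scene I/O round-trips through TIFF + JSON sidecar", {
  sc <- synth_scene(n_rods = 2, n_dividing = 1, width = 220, height = 180, seed = 3)
  d <- withr::local_tempdir()
  write_scene(sc, d)
  meta <- jsonlite::read_json(file.path(d, "scene.json"), simplifyVector = TRUE)
  st <- read_stack(file.path(d, "scene.tif"), meta$channels)
  expect_identical(names(st), names(sc$frame))
  expect_lt(max(abs(st$phase - sc$frame$phase)), 1e-6)  # float32 pages
  expect_equal(nrow(meta$boxes), 3)
  expect_length(list.files(file.path(d, "scene_masks")), 3)
})
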