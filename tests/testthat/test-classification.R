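test_that("box IoU matches hand-computed and lattice-counted values", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  set.seed(17)
  for (rep in 1:100) {
    a <- c(sort(sample.int(20, 2)), 0, 0)[c(1, 3, 2, 4)]
    a[c(2, 4)] <- sort(sample.int(20, 2))
    b <- c(sort(sample.int(20, 2)), 0, 0)[c(1, 3, 2, 4)]
    b[c(2, 4)] <- sort(sample.int(20, 2))
    expect_equal(box_iou(a, b), iou_lattice_oracle(a, b))
  }
})

test_that("instances take the label of the highest-IoU detection", {
  inst <- tibble::tibble(id = 1L, xmin = 10, ymin = 10, xmax = 30, ymax = 20,
                         stage = "unassigned", confidence = NA_real_)
  det <- tibble::tibble(
    xmin = c(10, 25), ymin = c(10, 10), xmax = c(30, 60), ymax = c(20, 20),
    label = c("rod", "dividing"), confidence = c(0.7, 0.9))
  out <- match_instances(inst, det)
  expect_equal(out$stage, "rod")
  expect_equal(out$confidence, 0.7)
  expect_gt(out$match_iou, 0.5)
})

test_that("IoU ties break by confidence then index", {
  inst <- tibble::tibble(id = 1L, xmin = 0, ymin = 0, xmax = 10, ymax = 10,
                         stage = "unassigned", confidence = NA_real_)
  det <- tibble::tibble(
    xmin = c(0, 0), ymin = c(0, 0), xmax = c(10, 10), ymax = c(10, 10),
    label = c("rod", "dividing"), confidence = c(0.6, 0.9))
  expect_equal(match_instances(inst, det)$stage, "dividing")
  det$confidence <- c(0.8, 0.8)
  expect_equal(match_instances(inst, det)$stage, "rod")  # lower index wins
})

test_that("matching is permutation-invariant up to the tie-break", {
  set.seed(23)
  inst <- tibble::tibble(id = 1:4,
                         xmin = c(0, 20, 40, 60), ymin = 0,
                         xmax = c(10, 30, 50, 70), ymax = 10,
                         stage = "unassigned", confidence = NA_real_)
  det <- tibble::tibble(xmin = c(1, 21, 41, 61), ymin = 0,
                        xmax = c(11, 31, 51, 71), ymax = 10,
                        label = c("rod", "dividing", "rod", "intermediate"),
                        confidence = c(0.9, 0.8, 0.7, 0.6))
  base <- match_instances(inst, det)
  perm <- sample(4)
  out <- match_instances(inst, det[perm, ])
  expect_equal(out$stage, base$stage)
  expect_equal(out$match_iou, base$match_iou)
})

test_that("non-overlapping instances stay unassigned", {
  inst <- tibble::tibble(id = 1L, xmin = 0, ymin = 0, xmax = 10, ymax = 10,
                         stage = "unassigned", confidence = NA_real_)
  det <- tibble::tibble(xmin = 50, ymin = 50, xmax = 60, ymax = 60,
                        label = "rod", confidence = 1)
  out <- match_instances(inst, det)
  expect_equal(out$stage, "unassigned")
  expect_true(is.na(out$detection))
})

test_that("stage filtering keeps only assigned, desired classes", {
  inst <- tibble::tibble(id = 1:4, stage = c("rod", "microcolony", "dividing", "unassigned"))
  expect_equal(filter_stages(inst)$id, c(1L, 3L))
  all5 <- c("dividing", "rod", "intermediate", "defocused", "microcolony")
  expect_equal(filter_stages(inst, all5)$id, 1:3)
})

test_that("Otsu length filter discards mislabeled cells, keeping >= 95%", {
  set.seed(9)
  n <- 120
  lens <- c(rnorm(n, 20, 2), rnorm(n, 40, 2))
  inst <- tibble::tibble(id = seq_len(2 * n),
                         stage = rep(c("rod", "dividing"), each = n),
                         length = lens)
  out <- otsu_length_filter(inst)
  thr <- attr(out, "threshold")
  expect_gt(thr, 26)
  expect_lt(thr, 34)
  expect_gte(nrow(out) / nrow(inst), 0.95)
  # rule: a 50-px rod is discarded, a 50-px dividing cell kept
  probe <- tibble::tibble(id = 1:2, stage = c("rod", "dividing"), length = c(50, 50))
  out2 <- otsu_length_filter(dplyr::bind_rows(inst, probe))
  expect_false(1L %in% out2$id[out2$length == 50 & out2$stage == "rod"])
})

test_that("a single length population passes through with a warning", {
  inst <- tibble::tibble(id = 1:3, stage = "rod", length = c(20, 20, 20))
  expect_warning(out <- otsu_length_filter(inst), "threshold")
  expect_equal(nrow(out), 3)
  expect_true(is.na(attr(out, "threshold")))
})

test_that("geometric classifier reads the stage off the mask geometry", {
  expect_equal(classify_stage_geometric(rod_mask(36, 10))$label, "rod")
  d <- classify_stage_geometric(dividing_mask(44, 11, depth = 0.5))
  expect_equal(d$label, "dividing")
  expect_gte(d$confidence, 0.5)
  # elongated cell without septum must not be called dividing
  e <- classify_stage_geometric(rod_mask(60, 10, dim = c(120, 80)))
  expect_false(e$label == "dividing")
  # off-center constriction is intermediate, not dividing
  m <- rod_mask(60, 12, dim = c(120, 80))
  m[, 52:55] <- m[, 52:55] & matrix(rep(abs(seq_len(80) - 40) > 3, 4), 80, 4) == FALSE
  cl <- classify_stage_geometric(m)
  expect_false(cl$label == "rod")
})

test_that("stage accuracy on synthetic scenes reaches 0.9 at depth >= 0.4", {
  set.seed(3)
  correct <- 0; total <- 0
  for (k in 1:30) {
    stage <- if (k %% 2 == 0) "rod" else "dividing"
    len <- if (stage == "rod") runif(1, 18, 26) else runif(1, 36, 46)
    sp <- cell_spec(c(60, 45), runif(1, 0, pi), len, runif(1, 10, 12), stage,
                    septum_depth = if (stage == "dividing") runif(1, 0.4, 0.55) else 0)
    m <- make_cell_mask(sp, 120, 90)
    total <- total + 1
    correct <- correct + (classify_stage_geometric(m)$label == stage)
  }
  expect_gte(correct / total, 0.9)
})
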