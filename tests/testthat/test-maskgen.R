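test_that("boxIoU matches hand arithmetic", {
  expect_equal(boxIoU(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(boxIoU(c(0, 0, 2, 2), c(10, 10, 2, 2)), 0)
  expect_equal(boxIoU(c(0, 0, 2, 2), c(1, 1, 2, 2)), 1 / 7)
  expect_error(boxIoU(c(0, 0, 0, 2), c(0, 0, 2, 2)),
               class = "cryopickValidationError")
})

test_that("greedy NMS keeps the higher-scored of overlapping boxes", {
  two <- data.frame(bbox_x = c(10, 10), bbox_y = c(10, 10),
                    bbox_w = 20, bbox_h = 20, pred_iou = c(0.9, 0.8),
                    confidence = 95, mask_area = 300)
  out <- nmsProposals(two, 0.7)
  expect_identical(nrow(out), 1L)
  expect_equal(out$pred_iou, 0.9)

  disj <- data.frame(bbox_x = c(0, 100, 200), bbox_y = c(0, 100, 200),
                     bbox_w = 20, bbox_h = 20, pred_iou = c(0.9, 0.8, 0.7),
                     confidence = 95, mask_area = 300)
  expect_identical(nrow(nmsProposals(disj, 0.7)), 3L)
})

test_that("NMS agrees with an exhaustive oracle and bounds pairwise IoU", {
  oracleNms <- function(props, thr) {
    ord <- order(-props$pred_iou, -props$confidence, props$bbox_x,
                 props$bbox_y)
    kept <- integer(0)
    for (i in ord) {
      ok <- TRUE
      for (j in kept) {
        if (boxIoU(as.numeric(props[i, 1:4]), as.numeric(props[j, 1:4])) > thr)
          ok <- FALSE
      }
      if (ok) kept <- c(kept, i)
    }
    props[kept, , drop = FALSE]
  }
  for (trial in 1:50) {
    props <- randomProposals(10, frame = 120, seed = 500 + trial)
    got <- nmsProposals(props, 0.3)
    want <- oracleNms(props, 0.3)
    expect_equal(got, want, ignore_attr = TRUE)
    if (nrow(got) > 1) {
      for (i in 1:(nrow(got) - 1)) for (j in (i + 1):nrow(got))
        expect_lte(boxIoU(as.numeric(got[i, 1:4]), as.numeric(got[j, 1:4])),
                   0.3)
    }
  }
})

test_that("refineMask fills holes and removes small artifacts", {
  m <- matrix(0, 40, 40)
  m[10:20, 10:20] <- 1
  m[15, 15] <- 0                       # 1-px hole
  m[35, 35] <- 1; m[35, 36] <- 1       # 2-px speck
  out <- refineMask(m, maskGenConfig(min_area = 16))
  expect_equal(out[15, 15], 1)
  expect_equal(sum(out[30:40, 30:40]), 0)
  expect_equal(sum(out), 121)
})

test_that("proposal extraction handles degenerate and hard-disc maps", {
  expect_identical(nrow(proposeMasks(matrix(0, 64, 64))), 0L)

  v <- matrix(0, 64, 64)
  xs <- matrix(rep(0:63, each = 64), 64); ys <- matrix(rep(0:63, 64), 64)
  v[(xs - 30)^2 + (ys - 30)^2 <= 100] <- 1
  props <- proposeMasks(v, maskGenConfig())
  expect_identical(nrow(props), 1L)
  expect_equal(props$pred_iou, 1)
  expect_equal(props$confidence, 100)
  # tight bbox around the disc: x in [20, 40] -> x0 = 20, w = 21
  expect_equal(props$bbox_x, 20)
  expect_equal(props$bbox_y, 20)
  expect_equal(props$bbox_w, 21)
  expect_equal(props$bbox_h, 21)
})

test_that("low mean probability fails the confidence cut", {
  v <- matrix(0, 96, 96)
  xs <- matrix(rep(0:95, each = 96), 96); ys <- matrix(rep(0:95, 96), 96)
  v[(xs - 25)^2 + (ys - 25)^2 <= 81] <- 1.0
  v[(xs - 70)^2 + (ys - 70)^2 <= 81] <- 0.6
  props <- proposeMasks(v, maskGenConfig(min_confidence = 88))
  expect_identical(nrow(props), 1L)
  expect_lt(abs(props$bbox_x + props$bbox_w / 2 - 25), 2)
})

test_that("k well-separated high-probability discs give exactly k proposals", {
  centers <- cbind(c(30, 30, 90, 90, 60), c(30, 90, 30, 90, 60))
  v <- matrix(0, 128, 128)
  xs <- matrix(rep(0:127, each = 128), 128)
  ys <- matrix(rep(0:127, 128), 128)
  for (k in seq_len(nrow(centers)))
    v[(xs - centers[k, 1])^2 + (ys - centers[k, 2])^2 <= 64] <- 1
  props <- proposeMasks(v, maskGenConfig())
  expect_identical(nrow(props), nrow(centers))
  # determinism: identical call, identical result
  expect_identical(props, proposeMasks(v, maskGenConfig()))
})

test_that("proposal JSON-lines round trip", {
  props <- randomProposals(15, seed = 77)
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeProposals(props, f)
  expect_equal(readProposals(f), props, tolerance = 1e-12)
})
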