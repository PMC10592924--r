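test_that("predicted-IoU filtering is strict", {
  props <- randomProposals(3, seed = 1)
  props$pred_iou <- c(0.95, 0.94, 0.93)
  kept <- filterByPredIoU(props, 0.94)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$pred_iou, 0.95)
  expect_identical(nrow(filterByPredIoU(props[0, ], 0.94)), 0L)
  props$pred_iou <- 1
  expect_identical(nrow(filterByPredIoU(props, 0.94)), 3L)
})

test_that("modeDimension rounds, takes the mode and breaks ties low", {
  expect_identical(modeDimension(c(30, 30, 41)), 30L)
  expect_identical(modeDimension(c(30, 40)), 30L)
  expect_identical(modeDimension(c(29.6, 30.4, 30.2)), 30L)
  expect_error(modeDimension(numeric(0)), class = "cryopickEmptyError")
})

test_that("particleDiameter is the Euclidean norm of the rescaled sides", {
  expect_equal(particleDiameter(40, 30, 4096, 4096), 200)
  expect_equal(particleDiameter(30, 40, 1024, 1024), 50)
  # symmetry: square micrograph, equal sides
  expect_equal(particleDiameter(32, 32, 2048, 2048),
               32 * sqrt(2) * 2048 / 1024)
  # invariance under the simultaneous swap (m_w, o_w) <-> (m_h, o_h)
  expect_equal(particleDiameter(30, 40, 4096, 2048),
               particleDiameter(40, 30, 2048, 4096))
  expect_error(particleDiameter(0, 30, 1024, 1024),
               class = "cryopickValidationError")
})

test_that("sizeThreshold is the stated fraction of the diameter", {
  expect_equal(sizeThreshold(200), 20)
  expect_equal(sizeThreshold(50, th_fraction = 0.2), 10)
  expect_error(sizeThreshold(0), class = "cryopickValidationError")
})

test_that("sizeFilter applies strict asymmetric bounds", {
  mk <- function(w, h) data.frame(bbox_x = 0, bbox_y = 0, bbox_w = w,
                                  bbox_h = h, pred_iou = 1, confidence = 100,
                                  mask_area = w * h)
  # m = 40, th = 6, divisor 3: bounds are (38, 46)
  expect_identical(nrow(sizeFilter(mk(39, 41), 40, 40, 6)), 1L)
  expect_identical(nrow(sizeFilter(mk(38, 40), 40, 40, 6)), 0L)
  expect_identical(nrow(sizeFilter(mk(40, 46), 40, 40, 6)), 0L)
  expect_identical(nrow(sizeFilter(mk(40, 40)[0, ], 40, 40, 6)), 0L)
})

test_that("rescaleCenter reproduces hand arithmetic", {
  p <- data.frame(bbox_x = 100, bbox_y = 200, bbox_w = 24, bbox_h = 24)
  got <- rescaleCenter(p, 4096, 4096)
  expect_equal(got$new_x, 448)
  expect_equal(got$new_y, 848)
  p2 <- data.frame(bbox_x = 10, bbox_y = 20, bbox_w = 6, bbox_h = 8)
  expect_equal(rescaleCenter(p2, 1024, 1024),
               data.frame(new_x = 13, new_y = 24))
  full <- data.frame(bbox_x = 0, bbox_y = 0, bbox_w = 1024, bbox_h = 1024)
  expect_equal(rescaleCenter(full, 3000, 5000),
               data.frame(new_x = 1500, new_y = 2500))
})

test_that("uniform proposals survive with a shared consensus diameter", {
  props <- data.frame(bbox_x = c(10, 200, 400, 600, 800),
                      bbox_y = c(10, 220, 430, 610, 820),
                      bbox_w = 40, bbox_h = 40, pred_iou = 0.99,
                      confidence = 99, mask_area = 1200)
  ps <- postprocessMicrograph(props, 4096, 4096, postprocessParams(), "m")
  expect_identical(nParticles(ps), 5L)
  expect_length(unique(particles(ps)$d), 1L)
  expect_equal(unique(particles(ps)$d), sqrt(2) * 40 * 4)
})

test_that("boxes far from the modal size are rejected", {
  props <- data.frame(bbox_x = c(10, 200, 400, 600),
                      bbox_y = c(10, 220, 430, 610),
                      bbox_w = c(40, 40, 40, 120),
                      bbox_h = c(40, 40, 40, 120), pred_iou = 0.99,
                      confidence = 99, mask_area = 1200)
  ps <- postprocessMicrograph(props, 2048, 2048, postprocessParams(), "m")
  expect_identical(nParticles(ps), 3L)
  # the 120-px box (center x = 660 in the model frame -> 1320 in-frame)
  # must be absent
  expect_false(any(abs(particles(ps)$new_x - 1320) < 1e-9))
})

test_that("an empty survivor set yields an empty ParticleSet with a warning", {
  props <- randomProposals(5, seed = 2)
  props$pred_iou <- 0.5
  expect_warning(ps <- postprocessMicrograph(props, 1024, 1024,
                                             postprocessParams(), "m"),
                 "predicted-IoU")
  expect_identical(nParticles(ps), 0L)
})

test_that("postprocessing agrees with a straight-line oracle on random input", {
  for (trial in 1:100) {
    props <- randomProposals(20, seed = 9000 + trial)
    o_w <- sample(c(1024, 2048, 4096, 5760), 1)
    o_h <- sample(c(1024, 2048, 4092), 1)
    got <- particles(suppressWarnings(
      postprocessMicrograph(props, o_w, o_h, postprocessParams(), "m")))
    want <- oraclePostprocess(props, o_w, o_h)
    expect_equal(got, want, ignore_attr = TRUE,
                 label = sprintf("trial %d", trial))
  }
})

test_that("identical proposals give byte-identical .star output", {
  props <- randomProposals(30, seed = 31)
  f1 <- withr::local_tempfile(fileext = ".star")
  f2 <- withr::local_tempfile(fileext = ".star")
  writeStar(suppressWarnings(
    postprocessMicrograph(props, 4096, 4096, postprocessParams(), "m")), f1)
  writeStar(suppressWarnings(
    postprocessMicrograph(props, 4096, 4096, postprocessParams(), "m")), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
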