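test_that("matching handles exact, empty and crowded cases", {
  gt <- ParticleSet("g", new_x = c(10, 50, 90), new_y = c(10, 50, 90), d = 10)
  m <- matchParticles(gt, gt)
  expect_identical(m$TP, 3L)
  expect_identical(m$FP, 0L)
  expect_identical(m$FN, 0L)

  m0 <- matchParticles(ParticleSet("p"), gt)
  expect_identical(m0$TP, 0L)
  expect_identical(m0$FN, 3L)

  # two gt near one pred, one pred far from everything
  pred <- ParticleSet("p", new_x = c(11, 200, 210), new_y = c(11, 200, 210),
                      d = 10)
  gt2 <- ParticleSet("g", new_x = c(10, 13, 400), new_y = c(10, 13, 400),
                     d = 10)
  m2 <- matchParticles(pred, gt2)
  expect_identical(m2$TP, 1L)
  expect_identical(m2$FP, 2L)
  expect_identical(m2$FN, 2L)
  expect_identical(m2$pairs$gt, 1L)  # nearest-first: (11,11) -> (10,10)
})

test_that("greedy matching agrees with an exhaustive oracle on small sets", {
  oracleMatch <- function(px, py, gx, gy, gd, frac) {
    cand <- expand.grid(p = seq_along(px), g = seq_along(gx))
    cand$dist <- sqrt((px[cand$p] - gx[cand$g])^2 +
                      (py[cand$p] - gy[cand$g])^2)
    cand <- cand[cand$dist <= frac * gd[cand$g], , drop = FALSE]
    cand <- cand[order(cand$dist, cand$g, cand$p), , drop = FALSE]
    up <- rep(FALSE, length(px)); ug <- rep(FALSE, length(gx)); tp <- 0L
    for (r in seq_len(nrow(cand))) {
      i <- cand$p[r]; j <- cand$g[r]
      if (!up[i] && !ug[j]) { up[i] <- ug[j] <- TRUE; tp <- tp + 1L }
    }
    tp
  }
  for (trial in 1:500) {
    set.seed(3000 + trial)
    np <- sample(0:6, 1); ng <- sample(0:6, 1)
    px <- runif(np, 0, 60); py <- runif(np, 0, 60)
    gx <- runif(ng, 0, 60); gy <- runif(ng, 0, 60)
    gd <- runif(ng, 8, 30)
    pred <- ParticleSet("p", new_x = px, new_y = py,
                        d = rep(10, np))
    gt <- ParticleSet("g", new_x = gx, new_y = gy, d = gd)
    got <- matchParticles(pred, gt, matchConfig(0.5))
    expect_identical(got$TP, oracleMatch(px, py, gx, gy, gd, 0.5),
                     info = sprintf("trial %d", trial))
    expect_identical(got$FP, np - got$TP)
    expect_identical(got$FN, ng - got$TP)
  }
})

test_that("TP is symmetric under swapping predictions and ground truth", {
  for (trial in 1:20) {
    set.seed(4000 + trial)
    a <- ParticleSet("a", new_x = runif(5, 0, 50), new_y = runif(5, 0, 50),
                     d = 12)
    b <- ParticleSet("b", new_x = runif(6, 0, 50), new_y = runif(6, 0, 50),
                     d = 12)
    ab <- matchParticles(a, b)
    ba <- matchParticles(b, a)
    expect_identical(ab$TP, ba$TP)
    expect_identical(ab$FP, ba$FN)
    expect_identical(ab$FN, ba$FP)
  }
})

test_that("picking scores follow the stated conventions", {
  expect_equal(pickingScores(2, 1, 1),
               c(precision = 2 / 3, recall = 2 / 3, f1 = 2 / 3))
  expect_equal(pickingScores(0, 0, 0), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(pickingScores(0, 5, 5), c(precision = 0, recall = 0, f1 = 0))
  sc <- pickingScores(3, 2, 7)
  expect_lte(sc["f1"], max(sc["precision"], sc["recall"]))
})

test_that("mask Dice matches hand arithmetic and the IoU identity", {
  a <- matrix(0, 20, 20); a[1:10, ] <- 1
  expect_equal(maskDice(a, a), 1)
  b <- matrix(0, 20, 20); b[11:20, ] <- 1
  expect_equal(maskDice(a, b), 0)
  cc <- matrix(0, 20, 20); cc[6:15, ] <- 1  # |a|=|b|=200, overlap 100
  expect_equal(maskDice(a, cc), 0.5)
  expect_equal(maskDice(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  expect_error(maskDice(a, matrix(0, 4, 4)), class = "cryopickShapeError")

  # dice = 2*IoU/(1+IoU) for random masks
  withr::local_seed(5)
  for (k in 1:10) {
    x <- matrix(rbinom(400, 1, 0.4), 20, 20)
    y <- matrix(rbinom(400, 1, 0.4), 20, 20)
    iou <- sum(x & y) / max(sum(x | y), 1)
    expect_equal(maskDice(x, y), 2 * iou / (1 + iou), tolerance = 1e-12)
  }
})

test_that("aggregation is the unweighted mean to three decimals", {
  r1 <- evalRecord("a", 10, 10, 0.5, 0.5, 0.5, 0.5)
  expect_equal(aggregateTable(r1),
               c(precision = 0.5, recall = 0.5, f1 = 0.5, dice = 0.5))
  r2 <- rbind(evalRecord("a", 1, 1, 0.9, 0.9, 0.2, 0.1),
              evalRecord("b", 1, 1, 0.1, 0.1, 0.8, 0.3))
  expect_equal(aggregateTable(r2)[["f1"]], 0.5)
  expect_error(aggregateTable(r1[0, ]), class = "cryopickEmptyError")
})

test_that("pearsonR behaves on exact linear relations and rejects degeneracy", {
  xs <- c(1, 2, 3, 5)
  expect_equal(pearsonR(xs, 2 * xs + 1), 1)
  expect_equal(pearsonR(xs, -xs), -1)
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)),
               class = "cryopickValidationError")
  expect_error(pearsonR(1:2, 1:2), class = "cryopickValidationError")
})

test_that("benchmark fixtures load with the expected structure", {
  tb <- benchmarkTables()
  expect_named(tb, c("picking", "reconstruction_test",
                     "reconstruction_fullset"))
  expect_identical(nrow(tb$picking), 21L)
  expect_setequal(unique(tb$picking$method),
                  c("CryoSegNet", "crYOLO", "Topaz"))
  expect_identical(nrow(tb$reconstruction_test), 21L)
  expect_identical(nrow(tb$reconstruction_fullset), 15L)
})
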