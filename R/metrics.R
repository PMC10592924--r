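# Particle-level evaluation: greedy center matching, precision/recall/F1,
# mask Dice, table aggregation and correlation.

#' Particle matching configuration
#'
#' A predicted particle matches a ground-truth particle when their center
#' distance is at most `match_radius_fraction` times the ground-truth
#' diameter.  Matching is greedy nearest-first and one-to-one.
#'
#' @param match_radius_fraction fraction of the ground-truth diameter
#'   (default 0.5, i.e. within the particle radius).
#' @return A list of class `MatchConfig`.
#' @export
matchConfig <- function(match_radius_fraction = 0.5) {
  if (match_radius_fraction <= 0 || match_radius_fraction > 1)
    stopf("match_radius_fraction must be in (0, 1]",
          class = "cryopickConfigError")
  structure(list(match_radius_fraction = match_radius_fraction),
            class = c("MatchConfig", "list"))
}

#' Match predicted particles against ground truth
#'
#' Candidate pairs within the match radius are sorted by ascending center
#' distance (ties by ground-truth index, then prediction index) and
#' consumed greedily, skipping already-matched members.  TP = matched
#' pairs, FP = unmatched predictions, FN = unmatched ground truth.
#'
#' @param pred a [ParticleSet-class] of predictions.
#' @param gt a [ParticleSet-class] of ground truth (same coordinate frame).
#' @param mc a [matchConfig()].
#' @return `list(TP, FP, FN, pairs)` where `pairs` is a data.frame with
#'   columns `pred`, `gt`, `dist` (1-based row indices).
#' @export
matchParticles <- function(pred, gt, mc = matchConfig()) {
  dp <- particles(pred); dg <- particles(gt)
  np <- nrow(dp); ng <- nrow(dg)
  empty <- data.frame(pred = integer(0), gt = integer(0), dist = numeric(0))
  if (np == 0L || ng == 0L)
    return(list(TP = 0L, FP = np, FN = ng, pairs = empty))
  dx <- outer(dp$new_x, dg$new_x, "-")
  dy <- outer(dp$new_y, dg$new_y, "-")
  dist <- sqrt(dx^2 + dy^2)
  lim <- matrix(mc$match_radius_fraction * dg$d, np, ng, byrow = TRUE)
  cand <- which(dist <= lim, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(list(TP = 0L, FP = np, FN = ng, pairs = empty))
  dd <- dist[cand]
  ord <- order(dd, cand[, 2L], cand[, 1L])
  cand <- cand[ord, , drop = FALSE]
  dd <- dd[ord]
  usedP <- logical(np); usedG <- logical(ng)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!usedP[i] && !usedG[j]) {
      usedP[i] <- TRUE; usedG[j] <- TRUE; keep[k] <- TRUE
    }
  }
  pairs <- data.frame(pred = cand[keep, 1L], gt = cand[keep, 2L],
                      dist = dd[keep])
  list(TP = sum(keep), FP = np - sum(keep), FN = ng - sum(keep),
       pairs = pairs)
}

#' Precision, recall and F1 from match counts
#'
#' Conventions for degenerate counts: with no predictions and no ground
#' truth all three scores are 1 (vacuous perfection); with no predictions
#' but some ground truth precision is 0; with no ground truth recall is 1
#' only when nothing was predicted either.
#'
#' @param TP,FP,FN non-negative counts.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
pickingScores <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  precision <- if (TP + FP == 0) { if (FN == 0) 1 else 0 } else TP / (TP + FP)
  recall <- if (TP + FN == 0) 1 else TP / (TP + FN)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Dice similarity of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b binary matrices of identical shape (or
#'   [SegmentationMask-class] objects, thresholded at 0.5).
#' @return Dice score in \eqn{[0, 1]}.
#' @export
maskDice <- function(a, b) {
  if (is(a, "SegmentationMask")) a <- maskValues(a) > 0.5
  if (is(b, "SegmentationMask")) b <- maskValues(b) > 0.5
  if (!identical(dim(a), dim(b)))
    stopf("mask shapes differ", class = "cryopickShapeError")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) 1 else 2 * sum(a & b) / denom
}

#' One evaluation record
#'
#' @param dataset_id label of the evaluated image set.
#' @param n_gt,n_pred ground-truth and predicted particle counts.
#' @param precision,recall,f1,dice scores in \eqn{[0, 1]}.
#' @return one-row data.frame.
#' @export
evalRecord <- function(dataset_id, n_gt, n_pred, precision, recall, f1,
                       dice = NA_real_) {
  data.frame(dataset_id = dataset_id, n_gt = n_gt, n_pred = n_pred,
             precision = precision, recall = recall, f1 = f1, dice = dice)
}

#' Aggregate evaluation records into unweighted averages
#'
#' The arithmetic mean of each metric across records, reported to three
#' decimals (the convention of published picking benchmarks, whose table
#' averages are unweighted across protein types).
#'
#' @param records data.frame of [evalRecord()] rows.
#' @return named numeric vector of means (`precision`, `recall`, `f1`,
#'   `dice`), rounded to 3 decimals.
#' @export
aggregateTable <- function(records) {
  if (nrow(records) == 0L)
    stopf("no records to aggregate", class = "cryopickEmptyError")
  cols <- intersect(c("precision", "recall", "f1", "dice"), names(records))
  round(colMeans(records[cols]), 3)
}

#' Pearson correlation
#'
#' Sample Pearson correlation between two equal-length vectors
#' (length >= 3, both with non-zero variance).
#'
#' @param xs,ys numeric vectors.
#' @return correlation coefficient in \eqn{[-1, 1]}.
#' @export
pearsonR <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3L)
    stopf("need equal lengths >= 3", class = "cryopickValidationError")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stopf("constant input has no defined correlation",
          class = "cryopickValidationError")
  stats::cor(xs, ys)
}

#' Published particle-picking benchmark tables
#'
#' Loads the packaged benchmark fixtures: per-protein picking metrics
#' (precision/recall/F1/Dice) of three automated pickers on a labelled
#' cryo-EM test corpus, and the 3-D reconstruction summaries (picked
#' particle counts and map resolutions, with and without 2-D class
#' filtering) on the test corpus and on the full public image sets.
#'
#' @return `list(picking, reconstruction_test, reconstruction_fullset)` of
#'   data.frames.
#' @examples
#' tb <- benchmarkTables()
#' aggregateTable(subset(tb$picking, method == "CryoSegNet"))
#' @export
benchmarkTables <- function() {
  rd <- function(f) utils::read.delim(
    system.file("extdata", f, package = "cryopick", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(picking = rd("benchmark_picking_metrics.tsv"),
       reconstruction_test = rd("benchmark_reconstruction_test.tsv"),
       reconstruction_fullset = rd("benchmark_reconstruction_fullset.tsv"))
}

#' Evaluate picked particles against ground truth
#'
#' Matches each predicted [ParticleSet-class] to its ground-truth
#' counterpart (paired by list position), accumulates TP/FP/FN over the
#' collection, and also reports the Dice similarity of the rendered
#' particle masks at `mask_size`.
#'
#' @param preds list of predicted [ParticleSet-class] objects.
#' @param gts list of ground-truth [ParticleSet-class] objects.
#' @param o_w,o_h micrograph dimensions (shared across the collection).
#' @param mc a [matchConfig()].
#' @param dataset_id label for the record.
#' @param mask_size rendering size for the Dice computation (default 1024).
#' @return one-row [evalRecord()] data.frame.
#' @export
evaluatePicking <- function(preds, gts, o_w, o_h, mc = matchConfig(),
                            dataset_id = "dataset", mask_size = 1024L) {
  stopifnot(length(preds) == length(gts))
  TP <- FP <- FN <- 0L
  dice_num <- dice_den <- 0
  for (k in seq_along(preds)) {
    m <- matchParticles(preds[[k]], gts[[k]], mc)
    TP <- TP + m$TP; FP <- FP + m$FP; FN <- FN + m$FN
    pm <- maskValues(renderMask(preds[[k]], o_w, o_h, mask_size)) > 0.5
    gm <- maskValues(renderMask(gts[[k]], o_w, o_h, mask_size)) > 0.5
    dice_num <- dice_num + 2 * sum(pm & gm)
    dice_den <- dice_den + sum(pm) + sum(gm)
  }
  sc <- pickingScores(TP, FP, FN)
  evalRecord(dataset_id,
             n_gt = sum(vapply(gts, nParticles, integer(1))),
             n_pred = sum(vapply(preds, nParticles, integer(1))),
             precision = sc["precision"], recall = sc["recall"],
             f1 = sc["f1"],
             dice = if (dice_den == 0) 1 else dice_num / dice_den)
}
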