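test_that("precision and recall follow the TP/FP/FN definitions", {
  expect_equal(precision_score(confusion_counts(3, 1, 0)), 0.75)
  expect_equal(precision_score(confusion_counts(0, 0, 2)), 0)
  expect_equal(precision_score(confusion_counts(5, 0, 0)), 1)
  expect_equal(recall_score(confusion_counts(4, 0, 1)), 0.8)
  expect_equal(recall_score(confusion_counts(0, 0, 0)), 0)
  expect_equal(recall_score(confusion_counts(0, 2, 3)), 0)
  expect_error(confusion_counts(-1, 0, 0), "non-negative")
})

test_that("F1 is the harmonic mean on the input scale", {
  expect_equal(f1_score(50, 50), 50)
  expect_equal(f1_score(1, 1, digits = NULL), 1)
  # harmonic mean lies between its arguments
  for (i in 1:20) {
    pr <- withr::with_seed(i, runif(2, 1, 100))
    v <- f1_score(pr[1], pr[2], digits = NULL)
    expect_gte(v, min(pr)); expect_lte(v, max(pr))
  }
  expect_error(f1_score(0, 0), "undefined")
})

test_that("IoU handles boxes and masks", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[2:3, 2:3] <- TRUE
  expect_equal(iou(a, b), 1 / 7)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, !a & FALSE), 0)
})

test_that("detections validate their invariants", {
  expect_error(detection(c(0, 0, 1, 1), 1.5), "confidence")
  expect_error(detection(c(2, 2, 1, 1), 0.5), "non-empty")
  expect_error(detection(matrix(FALSE, 2, 2), 0.5), "non-empty")
})

test_that("matching is one-to-one and confidence-ordered", {
  gt <- list(c(0, 0, 4, 4))
  exact <- list(detection(c(0, 0, 4, 4), 0.9))
  m <- match_detections(exact, gt)
  expect_equal(unlist(m$counts), c(tp = 1L, fp = 0L, fn = 0L))

  dup <- list(detection(c(0, 0, 4, 4), 0.9), detection(c(0, 0, 4, 4), 0.8))
  m2 <- match_detections(dup, gt)
  expect_equal(unlist(m2$counts), c(tp = 1L, fp = 1L, fn = 0L))
  expect_equal(m2$matches$tp, c(TRUE, FALSE))

  m3 <- match_detections(list(), gt)
  expect_equal(unlist(m3$counts), c(tp = 0L, fp = 0L, fn = 1L))
  expect_error(match_detections(exact, gt, iou_threshold = 0), "0, 1")
})

test_that("greedy matching equals exhaustive optimal assignment on small scenes", {
  set.seed(314)
  for (t in 1:200) {
    np <- sample(0:3, 1); ng <- sample(0:3, 1)
    gts <- replicate(ng, rand_box(), simplify = FALSE)
    preds <- lapply(seq_len(np), function(i) detection(rand_box(), runif(1)))
    m <- match_detections(preds, gts, 0.5)
    expect_equal(m$counts$tp,
                 brute_force_tp(lapply(preds, `[[`, "region"), gts, 0.5))
    expect_equal(m$counts$fp, np - m$counts$tp)
    expect_equal(m$counts$fn, ng - m$counts$tp)
  }
})

test_that("average precision integrates the precision envelope", {
  expect_equal(average_precision(TRUE, 0.9, n_gt = 1), 1)
  expect_equal(average_precision(logical(0), numeric(0), n_gt = 1), 0)
  expect_equal(average_precision(logical(0), numeric(0), n_gt = 0), 0)
  # flags TP, FP, TP over 2 ground truths: hand-built PR points give
  # recall 0.5, 0.5, 1 and envelope 1, 2/3, 2/3 -> AP = 0.5 + 0.5 * 2/3
  flags <- c(TRUE, FALSE, TRUE); conf <- c(0.9, 0.8, 0.7)
  expect_equal(average_precision(flags, conf, n_gt = 2), 0.5 + 0.5 * 2 / 3)
  expect_equal(average_precision(flags, conf, n_gt = 2),
               hand_ap(flags, conf, 2))
})

test_that("AP matches the hand oracle and survives confidence rescaling", {
  for (i in 1:30) {
    n <- withr::with_seed(i, sample(1:6, 1))
    flags <- withr::with_seed(i * 2, runif(n) > 0.4)
    conf <- withr::with_seed(i * 3, runif(n))
    n_gt <- max(sum(flags), withr::with_seed(i * 5, sample(1:4, 1)))
    ap <- average_precision(flags, conf, n_gt)
    expect_equal(ap, hand_ap(flags, conf, n_gt))
    expect_gte(ap, 0); expect_lte(ap, 1)
    # order-preserving rescale leaves AP unchanged
    expect_equal(average_precision(flags, conf * 0.5 + 0.1, n_gt), ap)
  }
})

test_that("mAP is the mean of class APs", {
  expect_equal(map50(1), 1)
  expect_equal(map50(c(1, 0)), 0.5)
  expect_error(map50(numeric(0)), "at least one")
})

test_that("FLOPs is the layer-wise product sum", {
  expect_equal(conv_flops(3, 16, 32, 8, 8), 294912)
  expect_equal(conv_flops(1, 1, 1, 1, 1), 1)
  expect_equal(conv_flops(c(3, 3), c(16, 16), c(32, 32), c(8, 8), c(8, 8)),
               2 * 294912)
  expect_error(conv_flops(0, 1, 1, 1, 1), "positive")
})

test_that("detection_report composes the metrics", {
  gts <- list(c(0, 0, 4, 4), c(10, 10, 14, 14))
  preds <- list(detection(c(0, 0, 4, 4), 0.9),
                detection(c(10, 10, 14, 14), 0.7),
                detection(c(20, 20, 24, 24), 0.6))
  rep <- detection_report(preds, gts, conf_cutoff = 0.5)
  expect_equal(rep$counts$tp, 2L)
  expect_equal(rep$recall, 1)
  expect_equal(rep$precision, 2 / 3)
  expect_equal(rep$ap, 1)
  expect_equal(rep$f1_pct, f1_score(100 * 2 / 3, 100))
})
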