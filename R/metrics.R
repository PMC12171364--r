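#' Confusion counts
#'
#' True-positive, false-positive and false-negative counts for a detection
#' task.
#'
#' @param tp,fp,fn non-negative integers.
#' @return A \code{confusion_counts} list.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, fn = 0L) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Precision: TP / (TP + FP)
#'
#' Defined as 0 when no positives were predicted.
#'
#' @param counts a [confusion_counts()].
#' @return fraction in [0, 1].
#' @export
precision_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  d <- counts$tp + counts$fp
  if (d == 0) 0 else counts$tp / d
}

#' Recall: TP / (TP + FN)
#'
#' Defined as 0 when there are no actual positives.
#'
#' @inheritParams precision_score
#' @return fraction in [0, 1].
#' @export
recall_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  d <- counts$tp + counts$fn
  if (d == 0) 0 else counts$tp / d
}

#' F1 score: harmonic mean of precision and recall
#'
#' Inputs and output are on the same scale (fractions or percent).
#' Rounded to `digits` decimals for reporting; pass \code{digits = NULL}
#' for the raw value.
#'
#' @param p,r precision and recall, >= 0, not both 0.
#' @param digits decimals for reporting (default 2), or \code{NULL}.
#' @return harmonic mean on the input scale.
#' @examples
#' f1_score(92.8, 87)  # 89.81
#' @export
f1_score <- function(p, r, digits = 2) {
  if (any(p < 0) || any(r < 0)) stop("precision and recall must be >= 0")
  if (any(p + r == 0)) stop("F1 undefined when precision + recall = 0")
  v <- 2 * p * r / (p + r)
  if (is.null(digits)) v else round(v, digits)
}

#' Intersection over union of two regions
#'
#' Regions are either axis-aligned boxes \code{c(x0, y0, x1, y1)} in
#' half-open pixel coordinates, or logical mask matrices of equal size.
#'
#' @param a,b two regions of the same kind.
#' @return IoU fraction in [0, 1].
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  if (is.matrix(a) && is.matrix(b)) {
    stopifnot(identical(dim(a), dim(b)))
    a <- a > 0; b <- b > 0
    u <- sum(a | b)
    if (u == 0) return(0)
    return(sum(a & b) / u)
  }
  if (length(a) == 4L && length(b) == 4L) {
    area <- function(r) max(0, r[3] - r[1]) * max(0, r[4] - r[2])
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    u <- area(a) + area(b) - inter
    if (u == 0) return(0)
    return(inter / u)
  }
  stop("regions must both be boxes c(x0, y0, x1, y1) or mask matrices")
}

#' A single detection
#'
#' @param region a box \code{c(x0, y0, x1, y1)} (half-open pixel coords)
#'   or a logical mask matrix; must be non-empty.
#' @param confidence score in [0, 1].
#' @param class_id integer class label.
#' @return A \code{detection} list.
#' @export
detection <- function(region, confidence, class_id = 1L) {
  if (confidence < 0 || confidence > 1)
    stop("`confidence` must lie in [0, 1]")
  empty <- if (is.matrix(region)) sum(region > 0) == 0
           else region[3] <= region[1] || region[4] <= region[2]
  if (empty) stop("`region` must be non-empty")
  structure(list(region = region, confidence = confidence,
                 class_id = as.integer(class_id)),
            class = "detection")
}

#' Greedy confidence-ordered matching of detections to ground truth
#'
#' Predictions are processed in descending confidence; each claims the
#' unmatched ground-truth region of highest IoU provided IoU >= threshold.
#' Unclaimed predictions are false positives; unclaimed ground truths are
#' false negatives. This is the standard matching rule behind
#' average-precision evaluation at a fixed IoU threshold.
#'
#' @param preds list of [detection()] objects.
#' @param gts list of ground-truth regions (same kind as the predictions').
#' @param iou_threshold match threshold in (0, 1]; default 0.5.
#' @return list with \code{counts} (a [confusion_counts()]), and
#'   \code{matches}: a data frame in descending-confidence order with
#'   columns \code{pred_index}, \code{confidence}, \code{tp},
#'   \code{matched_gt} (NA for FPs).
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("`iou_threshold` must lie in (0, 1]")
  stopifnot(all(vapply(preds, inherits, logical(1), "detection")))
  conf <- vapply(preds, `[[`, numeric(1), "confidence")
  ord <- order(-conf, seq_along(preds))  # ties broken by original order
  taken <- logical(length(gts))
  tp <- logical(length(preds))
  matched <- rep(NA_integer_, length(preds))
  for (k in ord) {
    if (length(gts) == 0L) break
    ious <- vapply(gts, function(g) iou(preds[[k]]$region, g), numeric(1))
    ious[taken] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_threshold) {
      tp[k] <- TRUE
      taken[j] <- TRUE
      matched[k] <- j
    }
  }
  counts <- confusion_counts(tp = sum(tp), fp = sum(!tp),
                             fn = sum(!taken))
  list(counts = counts,
       matches = data.frame(pred_index = ord, confidence = conf[ord],
                            tp = tp[ord], matched_gt = matched[ord]))
}

#' Average precision at a fixed IoU threshold
#'
#' Area under the precision-recall curve using all-point interpolation:
#' precision is replaced by its running maximum from the right (the
#' envelope) and integrated over recall. With
#' \code{interpolation = "101-point"} the envelope is instead sampled at
#' recalls 0, 0.01, ..., 1 and averaged (the COCO convention).
#'
#' @param tp_flags logical vector, TRUE for true-positive predictions.
#' @param confidences matching numeric scores; sorted internally.
#' @param n_gt number of ground-truth objects, >= 0.
#' @param interpolation \code{"all-point"} (default) or \code{"101-point"}.
#' @return AP fraction in [0, 1]; 0 when \code{n_gt} is 0.
#' @export
average_precision <- function(tp_flags, confidences, n_gt,
                              interpolation = c("all-point", "101-point")) {
  interpolation <- match.arg(interpolation)
  if (n_gt < 0) stop("`n_gt` must be >= 0")
  if (length(tp_flags) != length(confidences))
    stop("`tp_flags` and `confidences` must have equal length")
  if (n_gt == 0 || length(tp_flags) == 0) return(0)
  ord <- order(-confidences, seq_along(confidences))
  tp <- cumsum(tp_flags[ord])
  fp <- cumsum(!tp_flags[ord])
  rec <- tp / n_gt
  prec <- tp / (tp + fp)
  env <- rev(cummax(rev(prec)))
  if (interpolation == "all-point") {
    sum(diff(c(0, rec)) * env)
  } else {
    grid <- seq(0, 1, by = 0.01)
    pr <- vapply(grid, function(g) {
      i <- which(rec >= g)
      if (length(i)) env[i[1]] else 0
    }, numeric(1))
    mean(pr)
  }
}

#' Mean average precision over classes (mAP at IoU 0.5 when the per-class
#' APs were computed at threshold 0.5)
#'
#' @param per_class_ap numeric vector of per-class AP values, length >= 1.
#' @return arithmetic mean.
#' @export
map50 <- function(per_class_ap) {
  if (length(per_class_ap) < 1L) stop("need at least one class AP")
  mean(per_class_ap)
}

#' Convolution FLOPs
#'
#' Computational cost of stride-1 convolution layers:
#' \code{sum(K^2 * Cin * Cout * H * W)} over layers, where H x W is the
#' output feature-map size. Vector arguments describe multiple layers and
#' are summed.
#'
#' @param K kernel sizes; @param c_in,c_out channel counts;
#' @param h,w output sizes.
#' @return total multiply-accumulate count.
#' @export
conv_flops <- function(K, c_in, c_out, h, w) {
  if (any(c(K, c_in, c_out, h, w) <= 0)) stop("all arguments must be positive")
  sum(K * K * c_in * c_out * h * w)
}

#' Evaluate one class of detections against ground truth
#'
#' Convenience wrapper producing the full metric report at a stated IoU
#' threshold: confusion counts at the confidence cutoff, precision, recall,
#' F1 (reported in percent) and average precision over all predictions.
#'
#' @inheritParams match_detections
#' @param conf_cutoff predictions below this confidence are ignored for
#'   P/R/F1 (AP always uses all predictions).
#' @return list with \code{counts}, \code{precision}, \code{recall},
#'   \code{f1_pct}, \code{ap}.
#' @export
detection_report <- function(preds, gts, iou_threshold = 0.5,
                             conf_cutoff = 0.25) {
  all_m <- match_detections(preds, gts, iou_threshold)
  ap <- average_precision(all_m$matches$tp, all_m$matches$confidence,
                          n_gt = length(gts))
  keep <- vapply(preds, `[[`, numeric(1), "confidence") >= conf_cutoff
  cut_m <- match_detections(preds[keep], gts, iou_threshold)
  p <- precision_score(cut_m$counts)
  r <- recall_score(cut_m$counts)
  f1 <- if (p + r > 0) f1_score(100 * p, 100 * r) else 0
  list(counts = cut_m$counts, precision = p, recall = r,
       f1_pct = f1, ap = ap)
}
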