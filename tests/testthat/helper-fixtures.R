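# Shared fixtures and independent oracles used across test files.

# A small single-leaf plant spec, fast to render.
small_plant <- function(dead_fraction = 0.5, noise_sigma = 0,
                        seed = 11L, pattern = "tip_down") {
  leaf <- synthetic_leaf_spec(centroid = c(100, 80), orientation = 30,
                              length = 90, width = 12,
                              dead_fraction = dead_fraction,
                              dead_pattern = pattern)
  synthetic_plant_spec(list(leaf), image_size = c(160L, 200L),
                       noise_sigma = noise_sigma, seed = seed)
}

# Random axis-aligned box in a 20x20 scene, half-open coords.
rand_box <- function() {
  x0 <- runif(1, 0, 20); y0 <- runif(1, 0, 20)
  c(x0, y0, x0 + runif(1, 2, 10), y0 + runif(1, 2, 10))
}

# Independent oracle for detection matching: exhaustive search over all
# one-to-one assignments of predictions to ground truths with pairwise
# IoU >= thr, maximising match count (ties: total IoU). Returns the TP
# count of the optimal assignment.
brute_force_tp <- function(pred_regions, gt_regions, thr) {
  np <- length(pred_regions); ng <- length(gt_regions)
  best_tp <- 0L; best_iou <- -1
  rec <- function(k, used, tp, tot) {
    if (k > np) {
      if (tp > best_tp || (tp == best_tp && tot > best_iou)) {
        best_tp <<- tp; best_iou <<- tot
      }
      return(invisible())
    }
    rec(k + 1L, used, tp, tot)
    for (j in seq_len(ng)) {
      if (used[j]) next
      v <- iou(pred_regions[[k]], gt_regions[[j]])
      if (v >= thr) {
        used[j] <- TRUE
        rec(k + 1L, used, tp + 1L, tot + v)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(ng), 0L, 0)
  best_tp
}

# Independent AP oracle: build the PR curve point by point from
# confidence-sorted flags, take the running-maximum-from-the-right
# precision envelope, and integrate it over recall with a plain loop.
hand_ap <- function(tp_flags, confidences, n_gt) {
  ord <- order(-confidences)
  flags <- tp_flags[ord]
  tp <- 0; fp <- 0
  rec <- prec <- numeric(length(flags))
  for (i in seq_along(flags)) {
    if (flags[i]) tp <- tp + 1 else fp <- fp + 1
    rec[i] <- tp / n_gt
    prec[i] <- tp / (tp + fp)
  }
  env <- prec
  for (i in rev(seq_len(length(env) - 1)))
    env[i] <- max(env[i], env[i + 1])
  ap <- 0
  prev <- 0
  for (i in seq_along(rec)) {
    ap <- ap + (rec[i] - prev) * env[i]
    prev <- rec[i]
  }
  ap
}

# Direct triple-loop convolution on one image plane set, used as a
# textbook oracle against reference_forward. x: [c, h, w]; W: [o, c, k, k].
loop_conv <- function(x, W, bias, pad) {
  ci <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  o <- dim(W)[1]; k <- dim(W)[3]
  xp <- array(0, dim = c(ci, h + 2 * pad, w + 2 * pad))
  xp[, pad + seq_len(h), pad + seq_len(w)] <- x
  ho <- h + 2 * pad - k + 1; wo <- w + 2 * pad - k + 1
  out <- array(0, dim = c(o, ho, wo))
  for (oo in seq_len(o)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- bias[oo]
    for (cc in seq_len(ci)) for (dh in seq_len(k)) for (dw in seq_len(k))
      acc <- acc + W[oo, cc, dh, dw] * xp[cc, i + dh - 1, j + dw - 1]
    out[oo, i, j] <- acc
  }
  out
}
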