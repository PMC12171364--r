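#' Specify one synthetic leaf
#'
#' A leaf is rendered as a rotated ellipse (an elongated blade). A
#' `dead_fraction` of its area is rendered in the yellow (dead-tissue) hue
#' band, the rest in the green band. With `dead_pattern = "tip_down"` the
#' dead region grows from the leaf tip downward, the way salt damage
#' progresses; `"random_patches"` scatters dead patches over the blade.
#'
#' @param centroid length-2 numeric, leaf centre in pixel coordinates
#'   (x, y), 0-based.
#' @param orientation blade angle in degrees (0 = horizontal).
#' @param length,width blade axes in pixels; \code{length >= width >= 1}.
#' @param dead_fraction fraction of leaf area that is dead, in [0, 1].
#' @param dead_pattern \code{"tip_down"} or \code{"random_patches"}.
#' @return A \code{synthetic_leaf_spec} list.
#' @export
synthetic_leaf_spec <- function(centroid, orientation = 0, length = 100,
                                width = 14, dead_fraction = 0,
                                dead_pattern = c("tip_down",
                                                 "random_patches")) {
  dead_pattern <- match.arg(dead_pattern)
  if (base::length(centroid) != 2L || !is.numeric(centroid))
    stop("`centroid` must be numeric (x, y)")
  if (!(length >= width && width >= 1))
    stop("need length >= width >= 1")
  if (dead_fraction < 0 || dead_fraction > 1)
    stop("`dead_fraction` must lie in [0, 1]")
  structure(list(centroid = as.numeric(centroid),
                 orientation = as.numeric(orientation),
                 length = as.numeric(length), width = as.numeric(width),
                 dead_fraction = as.numeric(dead_fraction),
                 dead_pattern = dead_pattern),
            class = "synthetic_leaf_spec")
}

#' Specify a synthetic seedling image
#'
#' Emulates the acquisition setup of a single potted seedling photographed
#' against a black background cloth: a near-black canvas with 1-10
#' elongated leaves, each split into green and dead regions.
#'
#' @param leaves list of [synthetic_leaf_spec()], length >= 1.
#' @param image_size length-2 integer (H, W) in pixels; default 640 x 640,
#'   the working resolution of the detection pipeline.
#' @param background_rgb near-black background colour, values in [0, 1].
#' @param noise_sigma sd of additive Gaussian colour noise (image scale
#'   [0, 1]); 0 disables noise.
#' @param seed integer; the same spec and seed give bit-identical output.
#' @return A \code{synthetic_plant_spec} list.
#' @export
synthetic_plant_spec <- function(leaves, image_size = c(640L, 640L),
                                 background_rgb = c(0.030, 0.036, 0.030),
                                 noise_sigma = 0.008, seed = 1L) {
  if (!is.list(leaves) || length(leaves) < 1L ||
      !all(vapply(leaves, inherits, logical(1), "synthetic_leaf_spec")))
    stop("`leaves` must be a non-empty list of synthetic_leaf_spec")
  if (length(image_size) != 2L || any(image_size < 1))
    stop("`image_size` must be positive (H, W)")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  structure(list(leaves = leaves,
                 image_size = as.integer(image_size),
                 background_rgb = as.numeric(background_rgb),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "synthetic_plant_spec")
}

# Pixel membership of one leaf ellipse on an H x W canvas. Returns a list
# with linear indices `idx` and the axial coordinate `u` of each pixel
# (u = +length/2 at the tip).
leaf_pixels <- function(leaf, H, W) {
  cx <- leaf$centroid[1]; cy <- leaf$centroid[2]
  a <- leaf$length / 2; b <- leaf$width / 2
  th <- leaf$orientation * pi / 180
  r <- ceiling(a) + 1L
  rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r + 1))
  cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r + 1))
  if (length(rows) == 0L || length(cols) == 0L)
    return(list(idx = integer(0), u = numeric(0)))
  px <- rep(cols - 0.5, each = length(rows))  # pixel centres, 0-based coords
  py <- rep(rows - 0.5, times = length(cols))
  dx <- px - cx; dy <- py - cy
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  rr <- rep(rows, times = length(cols))[inside]
  cc <- rep(cols, each = length(rows))[inside]
  list(idx = (cc - 1L) * H + rr, u = u[inside])
}

#' Render a synthetic seedling image with exact ground truth
#'
#' Rasterizes every leaf, splits each into green and dead pixels to match
#' its `dead_fraction` (to within one pixel), colours leaf pixels with
#' jittered hues — green band 90-150 degrees, dead band 40-70 degrees —
#' and adds background and Gaussian colour noise. The returned ground
#' truth is computed from the rendered maps themselves, so it is exact by
#' construction.
#'
#' If leaves overlap, later leaves overwrite earlier ones; ground truth
#' reflects the final maps. Cohort generation places leaves so they never
#' touch (see [generate_cohort()]).
#'
#' @param spec a [synthetic_plant_spec()].
#' @return list with \code{image} (numeric \code{H x W x 3}) and
#'   \code{truth}, a \code{ground_truth} list: \code{instance_map} (integer
#'   matrix, 0 = background), \code{class_map} (a \code{pixel_class_map}),
#'   \code{per_leaf_green_fraction}, \code{death_rate_pct}.
#' @export
render_plant <- function(spec) {
  stopifnot(inherits(spec, "synthetic_plant_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  with_seed(spec$seed, {
    inst <- matrix(0L, H, W)
    cls <- matrix(0L, H, W)
    for (i in seq_along(spec$leaves)) {
      leaf <- spec$leaves[[i]]
      lp <- leaf_pixels(leaf, H, W)
      n <- length(lp$idx)
      if (n == 0L)
        stop(sprintf("leaf %d lies entirely outside the canvas", i))
      n_dead <- round(leaf$dead_fraction * n)
      dead_sel <- logical(n)
      if (n_dead > 0L) {
        if (leaf$dead_pattern == "tip_down") {
          ord <- order(lp$u, lp$idx, decreasing = TRUE)
          dead_sel[ord[seq_len(n_dead)]] <- TRUE
        } else {
          k <- max(1L, min(3L, n_dead))
          centres <- sample.int(n, k)
          rr <- ((lp$idx - 1L) %% H) + 1L
          cc <- ((lp$idx - 1L) %/% H) + 1L
          d2 <- matrix(Inf, n, k)
          for (j in seq_len(k))
            d2[, j] <- (rr - rr[centres[j]])^2 + (cc - cc[centres[j]])^2
          ord <- order(apply(d2, 1, min), lp$idx)
          dead_sel[ord[seq_len(n_dead)]] <- TRUE
        }
      }
      inst[lp$idx] <- i
      cls[lp$idx] <- ifelse(dead_sel, 2L, 1L)
    }
    # colour the canvas
    img <- array(rep(spec$background_rgb, each = H * W), dim = c(H, W, 3))
    fg <- which(cls > 0L)
    if (length(fg)) {
      is_dead <- cls[fg] == 2L
      hue <- numeric(length(fg))
      hue[!is_dead] <- stats::runif(sum(!is_dead), 90, 150)
      hue[is_dead] <- stats::runif(sum(is_dead), 40, 70)
      s <- stats::runif(length(fg), 0.65, 0.95)
      v <- stats::runif(length(fg), 0.55, 0.95)
      rgb <- hsv_to_rgb(hue, s, v)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[fg] <- rgb[, ch]
        img[, , ch] <- plane
      }
    }
    if (spec$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma),
                         dim = dim(img))
    img <- clip01(img)

    n_leaf <- sum(cls > 0L)
    n_dead_px <- sum(cls == 2L)
    per_green <- vapply(seq_along(spec$leaves), function(i) {
      px <- inst == i
      tot <- sum(px)
      if (tot == 0L) return(NA_real_)
      sum(cls[px] == 1L) / tot
    }, numeric(1))
    truth <- structure(list(
      instance_map = inst,
      class_map = new_pixel_class_map(cls),
      per_leaf_green_fraction = per_green,
      death_rate_pct = 100 * n_dead_px / n_leaf
    ), class = "ground_truth")
    list(image = img, truth = truth)
  })
}

# Sample one non-overlapping leaf layout for a plant. `occ` is a logical
# occupancy matrix including a 1-pixel halo so that instances stay
# 8-disconnected.
place_leaves <- function(n_leaves, dead_fracs, H, W, max_tries = 400L) {
  occ <- matrix(FALSE, H, W)
  leaves <- vector("list", n_leaves)
  halo <- expand.grid(dr = -1:1, dc = -1:1)
  for (i in seq_len(n_leaves)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      len <- stats::runif(1, 0.14, 0.28) * min(H, W)
      wid <- stats::runif(1, 0.02, 0.04) * min(H, W)
      wid <- max(3, min(wid, len))
      m <- len / 2 + 2
      leaf <- synthetic_leaf_spec(
        centroid = c(stats::runif(1, m, W - m), stats::runif(1, m, H - m)),
        orientation = stats::runif(1, 0, 180),
        length = len, width = wid,
        dead_fraction = dead_fracs[i])
      lp <- leaf_pixels(leaf, H, W)
      if (length(lp$idx) < 16L) next
      rr <- ((lp$idx - 1L) %% H) + 1L
      cc <- ((lp$idx - 1L) %/% H) + 1L
      hit <- FALSE
      for (h in seq_len(nrow(halo))) {
        r2 <- pmin(pmax(rr + halo$dr[h], 1L), H)
        c2 <- pmin(pmax(cc + halo$dc[h], 1L), W)
        if (any(occ[(c2 - 1L) * H + r2])) { hit <- TRUE; break }
      }
      if (hit) next
      occ[lp$idx] <- TRUE
      leaves[[i]] <- leaf
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place leaf ", i, " without overlap; canvas too full")
  }
  leaves
}

#' Generate a synthetic cohort of graded varieties
#'
#' Builds a dataset emulating a screening trial: `n_varieties` varieties
#' with `plants_per_variety` replicate plants each (8 in the emulated
#' trial). Each variety is given a target tolerance grade; its plants'
#' ground-truth death rates are drawn uniformly inside the target grade's
#' bin, at least `margin` percentage points away from the bin edges, so a
#' correct pipeline can recover the grade unambiguously.
#'
#' Every leaf of a plant gets the plant's target dead fraction, making the
#' pooled plant death rate equal the target up to per-leaf one-pixel
#' rounding.
#'
#' @param n_varieties number of varieties, >= 1.
#' @param plants_per_variety replicates per variety, >= 1.
#' @param grade_targets integer vector, one grade in \{1,3,5,7,9\} per
#'   variety.
#' @param seed integer master seed; the full dataset is reproducible.
#' @param image_size length-2 (H, W), default 640 x 640.
#' @param leaves_per_plant length-2 integer range to sample from.
#' @param margin distance in percentage points kept from bin edges.
#' @param noise_sigma forwarded to [synthetic_plant_spec()].
#' @param table the [grade_table()] defining the bins.
#' @return list of records, each with \code{image}, \code{truth},
#'   \code{variety_id}, \code{plant_id}, \code{grade_target}, \code{spec}.
#' @export
generate_cohort <- function(n_varieties, plants_per_variety = 8L,
                            grade_targets, seed = 1L,
                            image_size = c(640L, 640L),
                            leaves_per_plant = c(3L, 6L),
                            margin = 2, noise_sigma = 0.008,
                            table = grade_table()) {
  if (n_varieties < 1L || plants_per_variety < 1L)
    stop("cohort must contain at least one variety and one plant")
  if (length(grade_targets) != n_varieties)
    stop("`grade_targets` must have one grade per variety")
  if (!all(grade_targets %in% table$grade))
    stop("grades must be in {", paste(table$grade, collapse = ","), "}")
  H <- image_size[1]; W <- image_size[2]
  lo_all <- c(0, utils::head(table$upper, -1))
  hi_all <- pmin(table$upper, 100)
  with_seed(seed, {
    records <- vector("list", n_varieties * plants_per_variety)
    k <- 0L
    for (vi in seq_len(n_varieties)) {
      bin_i <- match(grade_targets[vi], table$grade)
      lo <- lo_all[bin_i] + margin
      hi <- hi_all[bin_i] - margin
      if (lo >= hi) stop("`margin` leaves an empty target bin")
      for (pi in seq_len(plants_per_variety)) {
        target_rate <- stats::runif(1, lo, hi)
        n_leaves <- sample(seq(leaves_per_plant[1], leaves_per_plant[2]), 1)
        dead_fracs <- rep(target_rate / 100, n_leaves)
        leaves <- place_leaves(n_leaves, dead_fracs, H, W)
        plant_seed <- sample.int(.Machine$integer.max, 1)
        spec <- synthetic_plant_spec(leaves, image_size = image_size,
                                     noise_sigma = noise_sigma,
                                     seed = plant_seed)
        rp <- render_plant(spec)
        k <- k + 1L
        records[[k]] <- list(image = rp$image, truth = rp$truth,
                             variety_id = sprintf("v%02d", vi),
                             plant_id = sprintf("p%02d", pi),
                             grade_target = as.integer(grade_targets[vi]),
                             spec = spec)
      }
    }
    records
  })
}

#' Write a synthetic record to disk
#'
#' Writes the rendered image as 8-bit RGB PNG, the instance map as an RGB
#' PNG with the 16-bit instance id split across the red (high byte) and
#' green (low byte) channels, the class map as an 8-bit grayscale PNG with
#' raw levels 0/1/2, and a JSON sidecar with per-leaf green fractions and
#' the ground-truth death rate.
#'
#' @param record one element of a [generate_cohort()] result, or a
#'   [render_plant()] result.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_synthetic_record <- function(record, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- record$truth
  p_img <- file.path(dir, paste0(stem, ".png"))
  p_inst <- file.path(dir, paste0(stem, "_instances.png"))
  p_cls <- file.path(dir, paste0(stem, "_classes.png"))
  p_json <- file.path(dir, paste0(stem, ".json"))
  png::writePNG(record$image, p_img)
  id <- truth$instance_map
  inst_rgb <- array(0, dim = c(nrow(id), ncol(id), 3))
  inst_rgb[, , 1] <- (id %/% 256L) / 255
  inst_rgb[, , 2] <- (id %% 256L) / 255
  png::writePNG(inst_rgb, p_inst)
  png::writePNG(unclass(truth$class_map) / 255, p_cls)
  jsonlite::write_json(list(
    per_leaf_green_fraction = truth$per_leaf_green_fraction,
    death_rate_pct = truth$death_rate_pct,
    variety_id = record$variety_id %||% NA,
    plant_id = record$plant_id %||% NA,
    grade_target = record$grade_target %||% NA
  ), p_json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(image = p_img, instances = p_inst, classes = p_cls,
              sidecar = p_json))
}

#' Read back an instance map written by [write_synthetic_record()]
#' @param path the `*_instances.png` path.
#' @return integer matrix of instance ids.
#' @export
read_instance_map <- function(path) {
  a <- png::readPNG(path)
  matrix(as.integer(round(a[, , 1] * 255)) * 256L +
         as.integer(round(a[, , 2] * 255)),
         nrow = dim(a)[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
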