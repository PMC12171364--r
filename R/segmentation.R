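#' Colour thresholds for leaf pixel classification
#'
#' HSV thresholds for the reference colour-based segmentation backend.
#' Green and yellow hue bands must not overlap; a pixel is foreground only
#' if both its saturation and value clear the minima, which removes the
#' near-black background. Hue is in degrees on a 0-360 scale.
#'
#' The defaults leave a guard gap between the yellow band (senescent
#' tissue) and the green band so that noisy pixels near the boundary fall
#' to background rather than flipping class.
#'
#' @param green_hue_range length-2 degrees, band classified as green leaf.
#' @param yellow_hue_range length-2 degrees, band classified as dead leaf.
#' @param min_saturation minimum HSV saturation for foreground, in [0,1].
#' @param min_value minimum HSV value for foreground, in [0,1].
#' @return A \code{color_thresholds} list.
#' @export
color_thresholds <- function(green_hue_range = c(82, 170),
                             yellow_hue_range = c(20, 78),
                             min_saturation = 0.25,
                             min_value = 0.15) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] >= r[2] || r[1] < 0 || r[2] > 360)
      stop(sprintf("`%s` must be an increasing pair within [0, 360]", nm))
  }
  chk(green_hue_range, "green_hue_range")
  chk(yellow_hue_range, "yellow_hue_range")
  if (max(yellow_hue_range[1], green_hue_range[1]) <=
      min(yellow_hue_range[2], green_hue_range[2]))
    stop("green and yellow hue ranges must not overlap")
  if (min_saturation < 0 || min_saturation > 1 ||
      min_value < 0 || min_value > 1)
    stop("saturation/value minima must lie in [0, 1]")
  structure(list(green_hue_range = as.numeric(green_hue_range),
                 yellow_hue_range = as.numeric(yellow_hue_range),
                 min_saturation = min_saturation,
                 min_value = min_value),
            class = "color_thresholds")
}

new_pixel_class_map <- function(labels) {
  stopifnot(is.matrix(labels), all(labels %in% 0:2))
  structure(labels, class = c("pixel_class_map", class(matrix())))
}

#' Classify pixels as background, green leaf or dead leaf
#'
#' Converts the image to HSV and labels every pixel: 0 background, 1 green
#' leaf, 2 dead (yellowed) leaf. Dark or desaturated pixels are background;
#' the rest are labelled by hue band, and hues outside both bands are
#' background.
#'
#' @param rgb_image numeric array \code{H x W x 3} with values in [0, 1].
#' @param thresholds a [color_thresholds()].
#' @return An integer \code{pixel_class_map} matrix \code{H x W}.
#' @examples
#' px <- array(c(0, 1, 0), dim = c(1, 1, 3))  # pure green
#' classify_pixels(px)[1, 1] == 1L
#' @export
classify_pixels <- function(rgb_image, thresholds = color_thresholds()) {
  if (length(dim(rgb_image)) != 3L || dim(rgb_image)[3] != 3L)
    stop("`rgb_image` must be an H x W x 3 array")
  stopifnot(inherits(thresholds, "color_thresholds"))
  H <- dim(rgb_image)[1]; W <- dim(rgb_image)[2]
  rgbm <- rbind(as.vector(rgb_image[, , 1]),
                as.vector(rgb_image[, , 2]),
                as.vector(rgb_image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  fg <- hsv[2, ] >= thresholds$min_saturation &
        hsv[3, ] >= thresholds$min_value
  lab <- integer(H * W)
  g <- thresholds$green_hue_range; y <- thresholds$yellow_hue_range
  lab[fg & hue >= g[1] & hue <= g[2]] <- 1L
  lab[fg & hue >= y[1] & hue <= y[2]] <- 2L
  new_pixel_class_map(matrix(lab, H, W))
}

#' Remove small foreground components
#'
#' Relabels 8-connected foreground components (labels 1 or 2) smaller than
#' \code{min_component_area} pixels as background, suppressing speckle
#' noise before instance extraction. Labels of surviving pixels are
#' untouched.
#'
#' @param map a \code{pixel_class_map}.
#' @param min_component_area minimum component size in pixels; 0 is a
#'   no-op.
#' @return The cleaned \code{pixel_class_map}.
#' @export
morphological_clean <- function(map, min_component_area = 25) {
  stopifnot(inherits(map, "pixel_class_map"))
  if (min_component_area < 0) stop("`min_component_area` must be >= 0")
  if (min_component_area == 0) return(map)
  comp <- label_components_8(unclass(map) > 0L)
  if (max(comp) == 0L) return(map)
  sizes <- tabulate(comp[comp > 0L])
  drop <- which(sizes < min_component_area)
  if (length(drop)) {
    out <- unclass(map)
    out[comp %in% drop] <- 0L
    map <- new_pixel_class_map(out)
  }
  map
}

#' Extract leaf instances from a class map
#'
#' Each 8-connected component of the leaf pixels (labels 1 and 2 pooled) is
#' one leaf instance; green and dead pixels are counted per component.
#' Touching leaves merge into one instance — the reference instancer does
#' not attempt leaf disocclusion.
#'
#' @param map a \code{pixel_class_map}.
#' @return A \code{leaf_instances} data frame with columns
#'   \code{instance_id}, \code{pixel_count}, \code{green_count},
#'   \code{dead_count}; zero rows for an all-background map.
#' @export
extract_instances <- function(map) {
  stopifnot(inherits(map, "pixel_class_map"))
  m <- unclass(map)
  comp <- label_components_8(m > 0L)
  k <- max(comp)
  if (k == 0L) return(empty_leaf_instances())
  idx <- comp > 0L
  green <- tabulate(comp[idx & m == 1L], nbins = k)
  dead <- tabulate(comp[idx & m == 2L], nbins = k)
  as_leaf_instances(data.frame(
    instance_id = seq_len(k),
    pixel_count = green + dead,
    green_count = green,
    dead_count = dead))
}

empty_leaf_instances <- function() {
  as_leaf_instances(data.frame(instance_id = integer(0),
                               pixel_count = integer(0),
                               green_count = integer(0),
                               dead_count = integer(0)))
}

as_leaf_instances <- function(x) {
  need <- c("instance_id", "pixel_count", "green_count", "dead_count")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("leaf instances need columns ", paste(need, collapse = ", "))
  if (nrow(x) && any(x$pixel_count != x$green_count + x$dead_count))
    stop("pixel_count must equal green_count + dead_count")
  if (nrow(x) && any(x$pixel_count <= 0))
    stop("instances must be non-empty")
  class(x) <- unique(c("leaf_instances", class(x)))
  x
}

#' Segment a seedling image
#'
#' The full reference pipeline: pixel classification, small-component
#' cleanup, instance extraction. The colour-threshold classifier stands in
#' for a learned instance segmenter; any backend producing a
#' \code{pixel_class_map} (e.g. rasterized Labelme annotations, see
#' [labelme_to_classmap()]) can replace the first stage.
#'
#' @param rgb_image numeric array \code{H x W x 3} in [0, 1].
#' @param thresholds a [color_thresholds()].
#' @param min_component_area cleanup threshold in pixels.
#' @return list with \code{class_map} and \code{instances}.
#' @export
segment <- function(rgb_image, thresholds = color_thresholds(),
                    min_component_area = 25) {
  cm <- classify_pixels(rgb_image, thresholds)
  cm <- morphological_clean(cm, min_component_area)
  list(class_map = cm, instances = extract_instances(cm))
}

#' Render a class map back to colours
#'
#' Visualisation helper: background black, green leaf pure green, dead
#' leaf pure yellow. Classifying the rendered image reproduces the map.
#'
#' @param map a \code{pixel_class_map}.
#' @return numeric \code{H x W x 3} array.
#' @export
class_map_to_rgb <- function(map) {
  stopifnot(inherits(map, "pixel_class_map"))
  m <- unclass(map)
  img <- array(0, dim = c(nrow(m), ncol(m), 3))
  img[, , 1][m == 2L] <- 1
  img[, , 2][m %in% c(1L, 2L)] <- 1
  img
}

#' Write per-instance counts to CSV
#'
#' @param instances a \code{leaf_instances} data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_instances_csv <- function(instances, path) {
  instances <- as_leaf_instances(instances)
  utils::write.csv(as.data.frame(unclass(instances))[
    , c("instance_id", "pixel_count", "green_count", "dead_count")],
    path, row.names = FALSE)
  invisible(path)
}
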