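#' Rasterize Labelme polygon annotations to a pixel class map
#'
#' Converts a Labelme-style JSON annotation (as produced when leaves are
#' outlined by hand) into the same \code{pixel_class_map} the colour
#' classifier emits, so manual annotations can drive the grading pipeline
#' in place of the automatic segmentation.
#'
#' Polygons are filled with the even-odd rule against pixel centres
#' (0-based coordinates, pixel (r, c) has centre (c + 0.5, r + 0.5));
#' later shapes overwrite earlier ones. Shape labels are mapped to classes
#' through `label_map`; any label not present there is an error.
#'
#' @param annotation path to a Labelme JSON file, or an already-parsed
#'   list with elements \code{imageHeight}, \code{imageWidth} and
#'   \code{shapes} (each shape a list with \code{label} and \code{points},
#'   an n x 2 matrix of (x, y) vertices).
#' @param image_size optional (H, W) override; defaults to the JSON's
#'   \code{imageHeight}/\code{imageWidth}.
#' @param label_map named integer vector mapping shape labels to classes
#'   1 (green) or 2 (dead).
#' @return A \code{pixel_class_map}.
#' @export
labelme_to_classmap <- function(annotation, image_size = NULL,
                                label_map = c(green = 1L, dead = 2L)) {
  if (is.character(annotation))
    annotation <- jsonlite::read_json(annotation, simplifyVector = FALSE)
  if (is.null(image_size)) {
    if (is.null(annotation$imageHeight) || is.null(annotation$imageWidth))
      stop("annotation lacks imageHeight/imageWidth; pass `image_size`")
    image_size <- c(annotation$imageHeight, annotation$imageWidth)
  }
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  shapes <- annotation$shapes
  if (is.null(shapes)) shapes <- list()
  labs <- vapply(shapes, function(s) as.character(s$label), character(1))
  unknown <- setdiff(unique(labs), names(label_map))
  if (length(unknown))
    stop("unknown annotation labels: ", paste(unknown, collapse = ", "))
  cls <- matrix(0L, H, W)
  for (s in shapes) {
    pts <- s$points
    if (is.list(pts)) pts <- do.call(rbind, lapply(pts, unlist))
    pts <- matrix(as.numeric(pts), ncol = 2)
    inside <- polygon_pixels(pts, H, W)
    cls[inside] <- label_map[[as.character(s$label)]]
  }
  new_pixel_class_map(cls)
}

# Even-odd polygon fill against pixel centres; returns linear indices.
# `pts` is n x 2 (x, y) in 0-based image coordinates.
polygon_pixels <- function(pts, H, W) {
  n <- nrow(pts)
  if (n < 3L) return(integer(0))
  rmin <- max(1L, floor(min(pts[, 2]) + 0.5))
  rmax <- min(H, ceiling(max(pts[, 2]) + 0.5))
  cmin <- max(1L, floor(min(pts[, 1]) + 0.5))
  cmax <- min(W, ceiling(max(pts[, 1]) + 0.5))
  if (rmin > rmax || cmin > cmax) return(integer(0))
  rows <- rmin:rmax; cols <- cmin:cmax
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  crossings <- integer(length(px))
  for (e in seq_len(n)) {
    x1 <- pts[e, 1]; y1 <- pts[e, 2]
    e2 <- if (e == n) 1L else e + 1L
    x2 <- pts[e2, 1]; y2 <- pts[e2, 2]
    if (y1 == y2) next
    straddles <- (y1 > py) != (y2 > py)
    xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
    crossings <- crossings + as.integer(straddles & px < xi)
  }
  inside <- crossings %% 2L == 1L
  rr <- rep(rows, times = length(cols))[inside]
  cc <- rep(cols, each = length(rows))[inside]
  (cc - 1L) * H + rr
}
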