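#' Run configuration
#'
#' Bundles the tunables of the grading pipeline. `load_run_config()` reads
#' the same structure from a YAML file; unknown keys are rejected so typos
#' fail loudly.
#'
#' @param thresholds a [color_thresholds()].
#' @param table a [grade_table()].
#' @param min_component_area cleanup threshold in pixels.
#' @param seed integer seed for any randomized steps.
#' @param input_dir,output_dir optional I/O paths.
#' @return A \code{run_config} list.
#' @export
run_config <- function(thresholds = color_thresholds(),
                       table = grade_table(),
                       min_component_area = 25L, seed = 1L,
                       input_dir = NULL, output_dir = NULL) {
  stopifnot(inherits(thresholds, "color_thresholds"),
            inherits(table, "grade_table"))
  if (min_component_area < 0) stop("`min_component_area` must be >= 0")
  structure(list(thresholds = thresholds, table = table,
                 min_component_area = as.integer(min_component_area),
                 seed = as.integer(seed),
                 input_dir = input_dir, output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any of the keys \code{thresholds}
#'   (\code{green_hue_range}, \code{yellow_hue_range},
#'   \code{min_saturation}, \code{min_value}), \code{grade_table}
#'   (\code{upper}, \code{grade}, \code{label}),
#'   \code{min_component_area}, \code{seed}, \code{input_dir},
#'   \code{output_dir}.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("thresholds", "grade_table", "min_component_area", "seed",
             "input_dir", "output_dir")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  th <- if (is.null(y$thresholds)) color_thresholds() else {
    tk <- c("green_hue_range", "yellow_hue_range", "min_saturation",
            "min_value")
    badt <- setdiff(names(y$thresholds), tk)
    if (length(badt))
      stop("unknown threshold keys: ", paste(badt, collapse = ", "))
    do.call(color_thresholds, lapply(y$thresholds, unlist))
  }
  gt <- if (is.null(y$grade_table)) grade_table() else {
    g <- y$grade_table
    grade_table(upper = vapply(unlist(g$upper), function(u)
      if (identical(u, "inf") || identical(u, ".inf")) Inf else as.numeric(u),
      numeric(1)),
      grade = unlist(g$grade), label = unlist(g$label))
  }
  run_config(thresholds = th, table = gt,
             min_component_area = y$min_component_area %||% 25L,
             seed = y$seed %||% 1L,
             input_dir = y$input_dir, output_dir = y$output_dir)
}

#' Read a seedling image
#'
#' PNG is read natively; JPEG requires the EBImage package (Suggests).
#'
#' @param path image path.
#' @return numeric \code{H x W x 3} array in [0, 1].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG requires the EBImage package")
    e <- EBImage::readImage(path)
    img <- aperm(array(e, dim = dim(e)), c(2, 1, 3))
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L)
    img <- img[, , 1:3]  # drop alpha
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected a 3-channel image: ", path)
  img
}

#' Run the full grading pipeline over a set of images
#'
#' For every image: segment, extract leaf instances, phenotype the plant;
#' then aggregate phenotypes per variety. Unreadable or plant-free images
#' are recorded as per-file errors and the run continues; if every image
#' fails the call errors.
#'
#' @param config a [run_config()].
#' @param image_paths character vector of image files.
#' @param variety_ids optional vector parallel to `image_paths`; defaults
#'   to the part of each file name before the last underscore (e.g.
#'   \code{v03_p01.png} belongs to variety \code{v03}).
#' @param output_dir if non-NULL (default: the config's), writes
#'   \code{plants.csv}, \code{varieties.csv} and \code{report.json}.
#' @return list with data frames \code{plants}, \code{varieties} and
#'   \code{errors}, invisibly.
#' @export
run_pipeline <- function(config, image_paths, variety_ids = NULL,
                         output_dir = config$output_dir) {
  stopifnot(inherits(config, "run_config"))
  if (length(image_paths) == 0L) stop("no input images")
  if (is.null(variety_ids)) {
    stem <- tools::file_path_sans_ext(basename(image_paths))
    variety_ids <- sub("_[^_]*$", "", stem)
  }
  if (length(variety_ids) != length(image_paths))
    stop("`variety_ids` must be parallel to `image_paths`")
  plants <- list(); errors <- list(); phen_by_var <- list()
  for (i in seq_along(image_paths)) {
    path <- image_paths[i]
    res <- tryCatch({
      img <- read_image(path)
      seg <- segment(img, config$thresholds, config$min_component_area)
      phenotype_plant(seg$instances, config$table)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <-
        data.frame(path = path, message = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    vid <- as.character(variety_ids[i])
    phen_by_var[[vid]] <- c(phen_by_var[[vid]], list(res))
    plants[[length(plants) + 1L]] <- data.frame(
      path = path, variety_id = vid,
      death_rate_pct = res$death_rate_pct, grade = res$grade,
      alive = res$alive, green_leaf_count = res$green_leaf_count,
      stringsAsFactors = FALSE)
  }
  if (length(plants) == 0L)
    stop("all images failed: ", nrow(do.call(rbind, errors)), " errors")
  plants_df <- do.call(rbind, plants)
  varieties_df <- do.call(rbind, lapply(sort(names(phen_by_var)), function(v)
    as.data.frame(summarize_variety(v, phen_by_var[[v]], config$table))))
  errors_df <- if (length(errors)) do.call(rbind, errors)
    else data.frame(path = character(0), message = character(0))
  out <- list(plants = plants_df, varieties = varieties_df,
              errors = errors_df)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(plants_df, file.path(output_dir, "plants.csv"),
                     row.names = FALSE)
    utils::write.csv(varieties_df, file.path(output_dir, "varieties.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out, file.path(output_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(out)
}
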