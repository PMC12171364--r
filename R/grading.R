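#' Salt-tolerance grade table
#'
#' The ordinal grading standard for rice seedlings under salt stress. A
#' plant's leaf death rate (percent of leaf area that has yellowed) is
#' binned into grades 1, 3, 5, 7, 9 from "very strong" to "very weak"
#' tolerance. The default bins are \code{[0, 10]}, \code{(10, 25]},
#' \code{(25, 50]}, \code{(50, 80]} and \code{(80, Inf)}: each printed
#' boundary belongs to the lower (better) grade, consistent with the
#' standard's explicit "<= 10" for grade 1.
#'
#' @param upper numeric vector of strictly increasing bin upper bounds; the
#'   last must be \code{Inf}.
#' @param grade integer grades for each bin; must be exactly 1, 3, 5, 7, 9
#'   in that order.
#' @param label character tolerance labels per bin.
#' @return A \code{grade_table} data frame with columns \code{upper},
#'   \code{grade}, \code{label}.
#' @examples
#' grade_table()
#' assign_grade(c(6.52, 45.57))
#' @export
grade_table <- function(upper = c(10, 25, 50, 80, Inf),
                        grade = c(1L, 3L, 5L, 7L, 9L),
                        label = c("very strong", "strong", "medium",
                                  "weak", "very weak")) {
  upper <- as.numeric(upper)
  grade <- as.integer(grade)
  if (length(upper) != length(grade) || length(upper) != length(label))
    stop("`upper`, `grade` and `label` must have equal length")
  if (any(diff(upper) <= 0))
    stop("bin upper bounds must be strictly increasing")
  if (!identical(grade, c(1L, 3L, 5L, 7L, 9L)))
    stop("grades must be exactly 1, 3, 5, 7, 9 in order")
  if (!is.infinite(upper[length(upper)]))
    stop("the final bin must be unbounded (upper = Inf)")
  structure(
    data.frame(upper = upper, grade = grade, label = as.character(label),
               stringsAsFactors = FALSE),
    class = c("grade_table", "data.frame"))
}

#' @export
print.grade_table <- function(x, ...) {
  lo <- c(0, utils::head(x$upper, -1))
  cat("Salt-tolerance grade table\n")
  for (i in seq_len(nrow(x))) {
    iv <- if (i == 1L) sprintf("[%g, %g]", lo[i], x$upper[i])
          else if (is.infinite(x$upper[i])) sprintf("> %g", lo[i])
          else sprintf("(%g, %g]", lo[i], x$upper[i])
    cat(sprintf("  grade %d  %-10s  death rate %s\n", x$grade[i], x$label[i], iv))
  }
  invisible(x)
}

#' Leaf death rate
#'
#' Percent of a plant's leaf area that is dead:
#' \code{100 * dead_area / total_area}. Areas may be in any common unit
#' (pixels or cm^2); the ratio is unit-free.
#'
#' @param dead_area dead (yellowed) leaf area, >= 0.
#' @param total_area total leaf area, > 0, in the same units.
#' @return Death rate in percent, in \code{[0, 100]}.
#' @examples
#' leaf_death_rate(1.13, 17.4)
#' @export
leaf_death_rate <- function(dead_area, total_area) {
  if (any(total_area <= 0))
    stop("`total_area` must be positive (no leaf area measured)")
  if (any(dead_area < 0) || any(dead_area > total_area))
    stop("`dead_area` must lie in [0, total_area]")
  100 * dead_area / total_area
}

#' Assign a salt-tolerance grade from a leaf death rate
#'
#' Bins the death rate with the grade table: the first bin is closed
#' (\code{[0, b1]}), later bins half-open \code{(b_k, b_k+1]}, so boundary
#' values take the lower grade.
#'
#' @param death_rate_pct death rate(s) in percent, in \code{[0, 100]}.
#' @param table a [grade_table()].
#' @return Integer grade(s) in \{1, 3, 5, 7, 9\}.
#' @examples
#' assign_grade(10)   # boundary -> grade 1
#' assign_grade(82.43)
#' @export
assign_grade <- function(death_rate_pct, table = grade_table()) {
  stopifnot(inherits(table, "grade_table"))
  x <- as.numeric(death_rate_pct)
  if (any(is.na(x)) || any(x < 0) || any(x > 100))
    stop("`death_rate_pct` must lie in [0, 100]")
  inner <- utils::head(table$upper, -1)
  idx <- rowSums(outer(x, inner, ">")) + 1L
  table$grade[idx]
}

#' Is the plant alive?
#'
#' A plant with no green leaf tissue at all is recorded as dead; a single
#' green pixel anywhere keeps it alive.
#'
#' @param instances a \code{leaf_instances} data frame (see
#'   [extract_instances()]); may have zero rows.
#' @return \code{TRUE} iff total green pixel count is positive.
#' @export
is_alive <- function(instances) {
  instances <- as_leaf_instances(instances)
  nrow(instances) > 0L && sum(instances$green_count) > 0L
}

#' Count green leaves
#'
#' A leaf counts as green when strictly more than half of its area is green.
#'
#' @inheritParams is_alive
#' @return Integer count of green leaves.
#' @export
count_green_leaves <- function(instances) {
  instances <- as_leaf_instances(instances)
  if (nrow(instances) == 0L) return(0L)
  sum(instances$green_count / instances$pixel_count > 0.5)
}

#' Survival rate of a replicate cohort
#'
#' @param n_survivors number of plants retaining green tissue.
#' @param n_total total number of plants, > 0.
#' @return Percent survival.
#' @examples
#' survival_rate(6, 8)  # 75
#' @export
survival_rate <- function(n_survivors, n_total) {
  if (n_total <= 0) stop("`n_total` must be positive")
  if (n_survivors < 0 || n_survivors > n_total)
    stop("`n_survivors` must lie in [0, n_total]")
  100 * n_survivors / n_total
}

#' Green leaves per surviving plant
#'
#' @param total_green_leaves total green-leaf count over the cohort.
#' @param n_survivors number of surviving plants, > 0.
#' @return Mean green leaves per survivor.
#' @export
green_leaves_per_plant <- function(total_green_leaves, n_survivors) {
  if (n_survivors <= 0)
    stop("green leaves per plant is undefined with zero survivors")
  if (total_green_leaves < 0) stop("`total_green_leaves` must be >= 0")
  total_green_leaves / n_survivors
}

#' Phenotype one plant from its leaf instances
#'
#' Pools green and dead pixel counts over all leaves of the plant, computes
#' the leaf death rate, assigns the tolerance grade, and records survival
#' and the green-leaf count.
#'
#' @inheritParams is_alive
#' @param table a [grade_table()].
#' @return A \code{plant_phenotype} list: \code{death_rate_pct},
#'   \code{grade}, \code{alive}, \code{green_leaf_count}, plus the pooled
#'   \code{dead_pixels} and \code{total_pixels} used.
#' @export
phenotype_plant <- function(instances, table = grade_table()) {
  instances <- as_leaf_instances(instances)
  if (nrow(instances) == 0L)
    stop("no leaf instances: no plant detected")
  dead <- sum(instances$dead_count)
  total <- sum(instances$pixel_count)
  rate <- leaf_death_rate(dead, total)
  structure(list(
    death_rate_pct = rate,
    grade = assign_grade(rate, table),
    alive = is_alive(instances),
    green_leaf_count = count_green_leaves(instances),
    dead_pixels = dead,
    total_pixels = total
  ), class = "plant_phenotype")
}

#' @export
print.plant_phenotype <- function(x, ...) {
  cat(sprintf(
    "Plant phenotype: death rate %.2f%%, grade %d, %s, %d green leaves\n",
    x$death_rate_pct, x$grade, if (x$alive) "alive" else "dead",
    x$green_leaf_count))
  invisible(x)
}

#' Summarise a variety's replicate cohort
#'
#' Aggregates per-plant phenotypes into variety-level statistics: survival
#' rate, pooled death rate, green leaves per surviving plant, and the
#' variety grade. The variety grade is by default assigned from the
#' pixel-pooled death rate (total dead pixels over total leaf pixels across
#' replicates, i.e. the death-rate formula applied to the variety as a
#' whole); \code{method = "mean"} instead grades the mean of per-plant
#' rates.
#'
#' @param variety_id identifier for reporting.
#' @param phenotypes list of [phenotype_plant()] results, length >= 1.
#' @param table a [grade_table()].
#' @param method pooling rule for the variety death rate, \code{"pooled"}
#'   (default) or \code{"mean"}.
#' @return A \code{cohort_summary} list. \code{green_leaves_per_plant} is
#'   \code{NA} when no plant survived (the formula divides by survivors).
#' @export
summarize_variety <- function(variety_id, phenotypes, table = grade_table(),
                              method = c("pooled", "mean")) {
  method <- match.arg(method)
  if (length(phenotypes) == 0L) stop("need at least one phenotype")
  if (!all(vapply(phenotypes, inherits, logical(1), "plant_phenotype")))
    stop("`phenotypes` must be a list of plant_phenotype objects")
  n <- length(phenotypes)
  alive <- vapply(phenotypes, `[[`, logical(1), "alive")
  n_surv <- sum(alive)
  dead <- sum(vapply(phenotypes, `[[`, numeric(1), "dead_pixels"))
  total <- sum(vapply(phenotypes, `[[`, numeric(1), "total_pixels"))
  pooled <- if (method == "pooled") leaf_death_rate(dead, total)
            else mean(vapply(phenotypes, `[[`, numeric(1), "death_rate_pct"))
  greens <- sum(vapply(phenotypes, `[[`, integer(1), "green_leaf_count"))
  structure(list(
    variety_id = as.character(variety_id),
    n_plants = n,
    n_survivors = n_surv,
    survival_rate_pct = survival_rate(n_surv, n),
    pooled_death_rate_pct = pooled,
    green_leaves_per_plant = if (n_surv > 0)
      green_leaves_per_plant(greens, n_surv) else NA_real_,
    variety_grade = assign_grade(pooled, table)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Variety %s: %d/%d survived (%.1f%%), pooled death rate %.2f%%,",
           " grade %d, %.2f green leaves/plant\n"),
    x$variety_id, x$n_survivors, x$n_plants, x$survival_rate_pct,
    x$pooled_death_rate_pct, x$variety_grade, x$green_leaves_per_plant))
  invisible(x)
}

#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  data.frame(variety_id = x$variety_id, n_plants = x$n_plants,
             n_survivors = x$n_survivors,
             survival_rate_pct = x$survival_rate_pct,
             pooled_death_rate_pct = x$pooled_death_rate_pct,
             green_leaves_per_plant = x$green_leaves_per_plant,
             variety_grade = x$variety_grade,
             stringsAsFactors = FALSE)
}
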