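#' Stratified train/validation/test split
#'
#' Splits item ids into train, validation and test subsets at the given
#' ratios (default 7:2:1) with floor-then-remainder allocation: within each
#' stratum of n items, train takes \code{floor(n * r1)}, validation
#' \code{floor(n * r2)}, and test the remainder. With 2032 items unsplit at
#' 7:2:1 this yields 1422 / 406 / 204. Items are sorted before the seeded
#' shuffle, so the result is invariant to input ordering.
#'
#' @param items vector of item ids (coerced to character), non-empty,
#'   without duplicates.
#' @param ratios positive length-3 weights, normalized internally.
#' @param stratify_key optional vector parallel to `items` (e.g. variety);
#'   the allocation is applied within each stratum.
#' @param seed integer RNG seed for the shuffle.
#' @return A \code{split_result} list with character vectors \code{train},
#'   \code{val}, \code{test}.
#' @examples
#' lengths(split_dataset(sprintf("img%04d", 1:2032)))  # 1422 406 204
#' @export
split_dataset <- function(items, ratios = c(7, 2, 1), stratify_key = NULL,
                          seed = 1L) {
  items <- as.character(items)
  if (length(items) == 0L) stop("`items` must be non-empty")
  if (anyDuplicated(items)) stop("`items` must not contain duplicates")
  if (length(ratios) != 3L || any(ratios <= 0))
    stop("`ratios` must be three positive weights")
  r <- ratios / sum(ratios)
  if (is.null(stratify_key)) stratify_key <- rep("all", length(items))
  if (length(stratify_key) != length(items))
    stop("`stratify_key` must be parallel to `items`")
  ord <- order(items)
  items <- items[ord]
  stratify_key <- as.character(stratify_key)[ord]
  out <- list(train = character(0), val = character(0), test = character(0))
  with_seed(seed, {
    for (s in sort(unique(stratify_key))) {
      ids <- items[stratify_key == s]
      ids <- ids[sample.int(length(ids))]
      n <- length(ids)
      n_tr <- floor(n * r[1])
      n_va <- floor(n * r[2])
      out$train <- c(out$train, ids[seq_len(n_tr)])
      out$val <- c(out$val, ids[n_tr + seq_len(n_va)])
      out$test <- c(out$test, ids[setdiff(seq_len(n), seq_len(n_tr + n_va))])
    }
  })
  structure(out, class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Dataset split: train %d, val %d, test %d\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}
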