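#' Assign sites to spatially blocked cross-validation folds
#'
#' Sites are binned into square blocks of `cell_size` metres over their planar
#' coordinates; whole blocks are then dealt to `k` folds by a seeded random
#' draw that keeps fold site-counts near-equal (blocks are shuffled, then each
#' block goes to the currently smallest fold), repeated `repeats` times with
#' independent draws. Blocks are never split across folds, so no site ever
#' sits in both the training and test side of a split.
#'
#' @param x,y Site coordinates in metres.
#' @param cell_size Block edge length in metres (default 100 km).
#' @param k Number of folds.
#' @param repeats Number of independent fold plans.
#' @param seed RNG seed.
#' @return A `fold_plan`: list with `block` (site -> block id) and `folds`
#'   (n x repeats integer matrix of fold assignments).
#' @export
assign_spatial_folds <- function(x, y, cell_size = 100e3, k = 5, repeats = 10,
                                 seed = 1L) {
  stopifnot(length(x) == length(y), k >= 2)
  block <- paste(floor(x / cell_size), floor(y / cell_size), sep = ":")
  ub <- sort(unique(block))
  if (length(ub) < k) {
    stop("assign_spatial_folds: only ", length(ub), " non-empty blocks for ",
         k, " folds", call. = FALSE)
  }
  sizes <- table(block)[ub]
  set.seed(seed)
  folds <- matrix(NA_integer_, nrow = length(x), ncol = repeats)
  for (r in seq_len(repeats)) {
    ord <- sample.int(length(ub))
    fold_of_block <- integer(length(ub))
    load <- numeric(k)
    for (b in ord) {
      f <- which.min(load)           # smallest fold; ties resolved low-index
      fold_of_block[b] <- f
      load[f] <- load[f] + sizes[b]
    }
    folds[, r] <- fold_of_block[match(block, ub)]
  }
  structure(list(block = block, folds = folds, k = k, repeats = repeats,
                 cell_size = cell_size, seed = seed),
            class = "fold_plan")
}

within_plan_reorder <- function(plan, ord) {
  plan$block <- plan$block[ord]
  plan$folds <- plan$folds[ord, , drop = FALSE]
  plan
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Spatial fold plan: ", length(unique(x$block)), " blocks (",
      x$cell_size / 1000, " km cells), k = ", x$k, ", ", x$repeats,
      " repeat(s)\n", sep = "")
  invisible(x)
}
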