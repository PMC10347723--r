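#' Group positives into contiguous genomic blocks
#'
#' Positives are visited in a seeded random order; each still-unassigned
#' positive becomes a block seed and claims its `neighbors_per_seed`
#' nearest unassigned positives (genomic distance between tile starts, ties
#' towards the lower tile id). Every negative then joins the block of its
#' anchor positive, so genomic neighborhoods travel together through
#' cross-validation.
#'
#' @param dataset a [build_labeled_dataset()] result.
#' @param tiling the [tile_genome()] backing the dataset.
#' @param neighbors_per_seed positives claimed per block seed beyond the
#'   seed itself (default 49, i.e. blocks of about 50 positives).
#' @param seed RNG seed for the visiting order.
#' @return `data.table` with `tile_id`, `label` (1/0), `block_id`.
#' @export
make_blocks <- function(dataset, tiling, neighbors_per_seed = 49L, seed = 1L) {
  if (neighbors_per_seed < 0L) stop("neighbors_per_seed must be >= 0")
  pos <- dataset$positives
  tc <- tiling$tiles[match(pos, tiling$tiles$id)]
  start <- tc$start
  chrom <- tc$chrom
  block <- rep(NA_integer_, length(pos))
  with_seed(seed, {
    order_visit <- sample.int(length(pos))
    b <- 0L
    for (i in order_visit) {
      if (!is.na(block[i])) next
      b <- b + 1L
      block[i] <- b
      if (neighbors_per_seed > 0L) {
        free <- which(is.na(block) & chrom == chrom[i])
        if (length(free)) {
          d <- abs(start[free] - start[i])
          take <- free[order(d, pos[free])][seq_len(min(neighbors_per_seed, length(free)))]
          block[take] <- b
        }
      }
    }
  })
  pos_dt <- data.table::data.table(tile_id = pos, label = 1L, block_id = block)
  neg_dt <- data.table::data.table(tile_id = dataset$anchor$tile_id, label = 0L,
                                   block_id = block[match(dataset$anchor$anchor_id, pos)])
  rbind(pos_dt, neg_dt)
}

#' Assign cross-validation folds
#'
#' `mode = "block"`: whole blocks are dealt to folds greedily, largest
#' block (by positive count) first into the fold currently holding the
#' fewest positives, over a seeded shuffle for tie order; all members of a
#' block -- and therefore every negative and its anchor positive -- share a
#' fold. `mode = "random"`: tiles are shuffled into `K` near-equal folds
#' stratified by label.
#'
#' @param blocks for block mode, the [make_blocks()] table; for random
#'   mode, a `data.table` with `tile_id` and `label`.
#' @param K number of folds (default 5).
#' @param mode `"block"` or `"random"`.
#' @param seed RNG seed.
#' @return a `cv_partition`: `data.table` with `tile_id`, `label`, `fold`
#'   and (block mode) `block_id`.
#' @export
assign_folds <- function(blocks, K = 5L, mode = c("block", "random"), seed = 1L) {
  mode <- match.arg(mode)
  blocks <- data.table::as.data.table(blocks)
  out <- if (mode == "block") {
    if (!"block_id" %in% names(blocks)) stop("block mode needs block_id")
    bs <- blocks[, .(n_pos = sum(label == 1L)), by = block_id]
    if (K > nrow(bs)) stop("K exceeds the number of blocks")
    with_seed(seed, {
      bs <- bs[sample.int(nrow(bs))]
      bs <- bs[order(-n_pos)]
      load <- numeric(K)
      fold_of_block <- integer(nrow(bs))
      for (i in seq_len(nrow(bs))) {
        f <- which.min(load)
        fold_of_block[i] <- f
        load[f] <- load[f] + bs$n_pos[i]
      }
      res <- data.table::copy(blocks)
      res[, fold := fold_of_block[match(block_id, bs$block_id)]]
      res
    })
  } else {
    with_seed(seed, {
      res <- data.table::copy(blocks)
      res[, fold := 0L]
      for (lb in unique(res$label)) {
        idx <- which(res$label == lb)
        res$fold[idx] <- (sample.int(length(idx)) %% K) + 1L
      }
      res
    })
  }
  data.table::setattr(out, "class", c("cv_partition", class(out)))
  data.table::setattr(out, "K", as.integer(K))
  data.table::setattr(out, "mode", mode)
  out
}
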