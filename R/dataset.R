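#' Candidate negative tiles with nearest-positive anchors
#'
#' Every non-positive tile on the chromosomes where the lncRNA binds is
#' assigned to its nearest positive tile (genomic distance between tile
#' starts; ties broken towards the lower tile id). Anchors accumulating
#' more than `cap` candidates retain only the `cap` candidates nearest to
#' the anchor (ties again towards the lower id), which prevents negative
#' tiles from concentrating around any single positive.
#'
#' @param positives integer vector of positive tile ids.
#' @param tiling a [tile_genome()] object.
#' @param cap per-anchor candidate cap (default 100).
#' @return `data.table` with `tile_id`, `anchor_id`, `anchor_dist` (bp).
#' @export
build_candidate_negatives <- function(positives, tiling, cap = 100L) {
  if (!length(positives)) stop("at least one positive required")
  tiles <- tiling$tiles
  pos <- tiles[match(positives, tiles$id)]
  out <- list()
  for (ch in unique(pos$chrom)) {
    pch <- pos[pos$chrom == ch]
    cand <- tiles[tiles$chrom == ch & !(tiles$id %in% pch$id)]
    if (!nrow(cand)) next
    po <- pch[order(pch$start)]
    # nearest sorted positive via findInterval, tie -> lower tile id
    k <- findInterval(cand$start, po$start)
    lo <- pmax(k, 1L); hi <- pmin(k + 1L, nrow(po))
    d_lo <- abs(cand$start - po$start[lo])
    d_hi <- abs(cand$start - po$start[hi])
    take_lo <- d_lo < d_hi | (d_lo == d_hi & po$id[lo] <= po$id[hi])
    anchor <- ifelse(take_lo, po$id[lo], po$id[hi])
    dist <- pmin(d_lo, d_hi)
    out[[ch]] <- data.table::data.table(tile_id = cand$id, anchor_id = anchor,
                                        anchor_dist = dist)
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) stop("no candidate negatives available")
  # enforce the per-anchor cap, keeping candidates nearest to their anchor
  data.table::setorder(res, anchor_id, anchor_dist, tile_id)
  res <- res[, head(.SD, cap), by = anchor_id]
  data.table::setcolorder(res, c("tile_id", "anchor_id", "anchor_dist"))
  data.table::setorder(res, tile_id)
  res[]
}

# Distance (bp gap) from each tile id to the lncRNA gene interval.
tile_gene_distance <- function(tile_ids, tiling, gene) {
  tc <- tiling$tiles[match(tile_ids, tiling$tiles$id)]
  d <- interval_gap(tc$start, tc$end, gene$start, gene$end)
  d[tc$chrom != gene$chrom] <- NA_real_
  d
}

#' Distance-matched sampling of negative tiles
#'
#' Estimates the positives' tile-to-gene distance density over 50
#' log-spaced bins, weights each candidate negative by
#' (positive bin mass) / (candidate bin count), and samples
#' `ratio * n_positives` negatives without replacement proportionally to
#' these weights (exponential-key reservoir, reproducible under `seed`).
#' Candidates in bins holding no positive mass get weight zero; if no
#' candidate has positive weight, sampling falls back to uniform with a
#' warning.
#'
#' @param candidates output of [build_candidate_negatives()].
#' @param positives positive tile ids.
#' @param distance named (by tile id) or plain numeric vector of
#'   tile-to-gene distances covering positives and candidates, as from
#'   [tile_gene_distance()]; pass a function of tile ids alternatively.
#' @param ratio negatives per positive (default 5).
#' @param seed RNG seed.
#' @param tile_width,max_dist histogram range (defaults: `tile_width` 1000,
#'   `max_dist` the largest observed distance).
#' @return integer vector of sampled negative tile ids (sorted).
#' @export
sample_negatives <- function(candidates, positives, distance, ratio = 5,
                             seed = 1L, tile_width = 1000L, max_dist = NULL) {
  if (ratio <= 0) stop("ratio must be > 0")
  d_pos <- distance[as.character(positives)]
  d_cand <- distance[as.character(candidates$tile_id)]
  if (anyNA(d_pos) || anyNA(d_cand)) stop("distances missing for some tiles")
  if (is.null(max_dist)) max_dist <- max(c(d_pos, d_cand), 2 * tile_width)
  breaks <- c(-1, exp(seq(log(tile_width), log(max_dist), length.out = 50L)))
  breaks[length(breaks)] <- max(breaks[length(breaks)], max_dist) + 1
  bin_pos <- findInterval(d_pos, breaks)
  bin_cand <- findInterval(d_cand, breaks)
  pos_mass <- tabulate(bin_pos, nbins = length(breaks)) / length(d_pos)
  cand_count <- tabulate(bin_cand, nbins = length(breaks))
  w <- ifelse(cand_count[bin_cand] > 0, pos_mass[bin_cand] / cand_count[bin_cand], 0)
  m <- min(round(ratio * length(positives)), nrow(candidates))
  if (all(w == 0)) {
    warning("no distance overlap between candidates and positives; uniform sampling")
    w <- rep(1, nrow(candidates))
  }
  with_seed(seed, {
    key <- rep(Inf, length(w))
    ok <- w > 0
    key[ok] <- rexp(sum(ok)) / w[ok]
    if (sum(ok) < m) {
      # not enough weighted candidates: fill the remainder uniformly
      key[!ok] <- 1e9 + runif(sum(!ok))
    }
    take <- order(key)[seq_len(m)]
    sort(candidates$tile_id[take])
  })
}

#' Build the labeled dataset for one lncRNA
#'
#' Combines positives, capped nearest-anchor candidates and
#' distance-matched sampled negatives into the per-lncRNA classification
#' dataset.
#'
#' @param imap an [interaction_map()].
#' @param lnc lncRNA name.
#' @param ratio negatives per positive (default 5).
#' @param cap per-anchor candidate cap (default 100).
#' @param seed sampling seed.
#' @return a `labeled_dataset`: list with `lncRNA`, `positives`,
#'   `negatives`, `anchor` (data.table `tile_id`, `anchor_id`), `distance`
#'   (named vector over all dataset tiles), `ratio`, `candidates`.
#' @export
build_labeled_dataset <- function(imap, lnc, ratio = 5, cap = 100L, seed = 1L) {
  rec <- imap$lncRNAs[imap$lncRNAs$name == lnc]
  if (nrow(rec) != 1L) stop("unknown lncRNA ", lnc)
  positives <- imap$bound[[lnc]]
  gene <- list(chrom = rec$chrom, start = rec$gene_start, end = rec$gene_end)
  cand <- build_candidate_negatives(positives, imap$tiling, cap = cap)
  all_ids <- c(positives, cand$tile_id)
  distance <- setNames(tile_gene_distance(all_ids, imap$tiling, gene),
                       as.character(all_ids))
  negatives <- sample_negatives(cand, positives, distance, ratio = ratio,
                                seed = seed, tile_width = imap$tiling$tile_width)
  structure(list(lncRNA = lnc, positives = positives, negatives = negatives,
                 anchor = cand[cand$tile_id %in% negatives,
                               c("tile_id", "anchor_id")],
                 distance = distance, ratio = ratio,
                 candidates = cand),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset", x$lncRNA, "-", length(x$positives), "positives,",
      length(x$negatives), "negatives\n")
  invisible(x)
}

#' Quantile-quantile distance report for a labeled dataset
#'
#' Matched 1..99% quantiles of the positive tile-to-gene distance
#' distribution against the candidate negatives and against the sampled
#' negatives; points on the diagonal indicate a successful distance match.
#'
#' @param dataset a [build_labeled_dataset()] result.
#' @return `data.table` with `prob`, `positive`, `candidate`, `sampled`.
#' @export
qq_distance_report <- function(dataset) {
  if (!length(dataset$negatives)) stop("dataset has no negatives")
  p <- seq(0.01, 0.99, by = 0.01)
  d <- dataset$distance
  data.table::data.table(
    prob = p,
    positive = quantile(d[as.character(dataset$positives)], p, names = FALSE),
    candidate = quantile(d[as.character(dataset$candidates$tile_id)],
                         p, names = FALSE),
    sampled = quantile(d[as.character(dataset$negatives)], p, names = FALSE)
  )
}
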