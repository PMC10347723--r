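#' Construct an interaction map
#'
#' Container for per-lncRNA sets of bound tile ids over a tiled genome.
#'
#' @param lncRNAs `data.frame` with columns `name`, `chrom`, `gene_start`,
#'   `gene_end` (0-based half-open), optionally `mechanism`.
#' @param bound named list (by lncRNA name) of integer tile-id vectors.
#' @param tiling a [tile_genome()] object.
#' @param transcripts optional `DNAStringSet` of lncRNA transcripts.
#' @return an `interaction_map` object.
#' @export
interaction_map <- function(lncRNAs, bound, tiling, transcripts = NULL) {
  lncRNAs <- data.table::as.data.table(lncRNAs)
  stopifnot(all(c("name", "chrom", "gene_start", "gene_end") %in% names(lncRNAs)))
  if (!all(names(bound) %in% lncRNAs$name)) stop("bound entries without lncRNA record")
  all_ids <- tiling$tiles$id
  for (nm in names(bound)) {
    ids <- bound[[nm]]
    if (anyDuplicated(ids)) stop("duplicate bound tile ids for ", nm)
    if (!all(ids %in% all_ids)) stop("bound tile id outside the tiling for ", nm)
    bound[[nm]] <- sort(as.integer(ids))
  }
  structure(list(lncRNAs = lncRNAs, bound = bound, tiling = tiling,
                 transcripts = transcripts),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat("interaction_map:", length(x$bound), "lncRNA(s),",
      sum(lengths(x$bound)), "interactions\n")
  invisible(x)
}

#' Read lncRNA-tile interaction pairs from a TSV file
#'
#' Accepts two dialects: `lncRNA<TAB>chrom<TAB>position` (positions are
#' mapped to the containing tile; positions in a dropped trailing partial
#' tile are discarded with a warning) or `lncRNA<TAB>tile_id`.
#'
#' @param path TSV file (with or without a header line).
#' @param lncRNAs lncRNA annotation `data.frame` (see [interaction_map()]).
#' @param tiling a [tile_genome()] object.
#' @return an `interaction_map`.
#' @export
read_interaction_pairs <- function(path, lncRNAs, tiling) {
  dt <- data.table::fread(path, header = "auto")
  if (ncol(dt) == 3L) {
    data.table::setnames(dt, c("lncRNA", "chrom", "position"))
    dt[, tile_id := tile_id_at(tiling, chrom, position)]
    dt <- dt[!is.na(tile_id)]
  } else if (ncol(dt) == 2L) {
    data.table::setnames(dt, c("lncRNA", "tile_id"))
  } else stop("expected 2 or 3 tab-separated columns")
  bound <- lapply(split(dt$tile_id, dt$lncRNA), function(v) sort(unique(as.integer(v))))
  interaction_map(lncRNAs, bound, tiling)
}

#' Select analyzable lncRNAs and the cumulative interaction curve
#'
#' Keeps lncRNAs bound to at least `min_tiles` unique tiles (inclusive
#' threshold), sorted by decreasing coverage, and reports the cumulative
#' fraction of all unique (lncRNA, tile) pairs covered by the top-x lncRNAs.
#'
#' @param map an [interaction_map()].
#' @param min_tiles minimum number of unique bound tiles (default 1000).
#' @return list with `selected` (character), `coverage` (`data.table` of
#'   `name`, `n_tiles`, `selected`) and `cumulative` (`data.table` of
#'   `rank`, `name`, `cum_fraction`).
#' @export
select_lncrnas <- function(map, min_tiles = 1000L) {
  n <- lengths(map$bound)
  if (length(n) == 0L)
    return(list(selected = character(0),
                coverage = data.table::data.table(name = character(0),
                                                  n_tiles = integer(0),
                                                  selected = logical(0)),
                cumulative = data.table::data.table(rank = integer(0),
                                                    name = character(0),
                                                    cum_fraction = numeric(0))))
  ord <- order(-n, names(n))
  n <- n[ord]
  cov <- data.table::data.table(name = names(n), n_tiles = as.integer(n),
                                selected = n >= min_tiles)
  cum <- data.table::data.table(rank = seq_along(n), name = names(n),
                                cum_fraction = cumsum(as.numeric(n)) / sum(n))
  list(selected = cov$name[cov$selected], coverage = cov, cumulative = cum)
}

#' Nearest-gene baseline classifier
#'
#' Assigns each bound tile to the cis lncRNA whose gene lies closest to it
#' (gap distance, 0 when overlapping; ties broken by lexicographically
#' smaller lncRNA name) and reports the per-lncRNA sensitivity of this rule
#' together with the random-assignment baseline (uniform over the cis
#' lncRNAs of the tile's chromosome). Tiles on chromosomes without any
#' lncRNA gene are excluded from the denominator.
#'
#' @param map an [interaction_map()].
#' @param lncRNAs optional subset of lncRNA names to evaluate.
#' @return `data.table` with `name`, `n_tiles`, `n_scored`, `sensitivity`,
#'   `random_baseline`.
#' @export
nearest_gene_classifier <- function(map, lncRNAs = names(map$bound)) {
  genes <- map$lncRNAs
  tiles <- map$tiling$tiles
  out <- lapply(lncRNAs, function(nm) {
    ids <- map$bound[[nm]]
    tc <- tiles[match(ids, tiles$id)]
    res <- data.table::data.table(name = nm, n_tiles = length(ids),
                                  n_scored = 0L, sensitivity = NA_real_,
                                  random_baseline = NA_real_)
    correct <- 0L; scored <- 0L; base <- 0
    for (ch in unique(tc$chrom)) {
      g <- genes[genes$chrom == ch]
      if (nrow(g) == 0L) next
      sub <- tc[tc$chrom == ch]
      d <- vapply(seq_len(nrow(g)), function(i)
        as.numeric(interval_gap(sub$start, sub$end,
                                g$gene_start[i], g$gene_end[i])),
        numeric(nrow(sub)))
      d <- matrix(d, nrow = nrow(sub))
      pred <- apply(d, 1L, function(r) g$name[order(r, g$name)][1L])
      correct <- correct + sum(pred == nm)
      scored <- scored + nrow(sub)
      base <- base + nrow(sub) / nrow(g)
    }
    if (scored > 0L) {
      res$n_scored <- scored
      res$sensitivity <- correct / scored
      res$random_baseline <- base / scored
    }
    res
  })
  data.table::rbindlist(out)
}
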