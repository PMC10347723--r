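#' Feature family schema
#'
#' Assigns every feature to exactly one of the ten canonical families and
#' each family to a category: `primary` (sequence-derived) or `secondary`
#' (cell-context).
#'
#' @param features character vector of feature names.
#' @param family family name per feature.
#' @param category `"primary"` or `"secondary"` per feature.
#' @return a `family_schema` `data.table` (`feature`, `family`, `category`).
#' @export
family_schema <- function(features, family, category) {
  if (anyDuplicated(features)) stop("duplicate feature names")
  if (!all(category %in% c("primary", "secondary"))) stop("bad category")
  fc <- unique(data.table::data.table(family = family, category = category))
  if (anyDuplicated(fc$family)) stop("a family cannot span both categories")
  structure(data.table::data.table(feature = features, family = family,
                                   category = category),
            class = c("family_schema", "data.table", "data.frame"))
}

#' Families of a schema
#' @param schema a [family_schema()].
#' @param category optionally restrict to `"primary"` or `"secondary"`.
#' @return character vector of family names (schema order).
#' @export
schema_families <- function(schema, category = NULL) {
  if (is.null(category)) return(unique(schema[["family"]]))
  keep <- schema[["category"]] == category
  unique(schema[["family"]][keep])
}

#' The canonical ten-family schema at published resource counts
#'
#' Instantiates the full feature catalogue used with real interaction maps:
#' five sequence (primary) families -- 512 canonical 5-mer counts, one
#' merged-hit count per motif protein (623 TFs + 78 RBPs), 59 repeat-family
#' overlap counts plus the repeat-pair feature, the 4-value triplex quartet,
#' and the 3 shared-motif features (TF pair, RBP pair, PPI pair) -- and five
#' context (secondary) families: DNase + ATAC accessibility, methylation,
#' 48 chromatin marks plus the chromatin-pair feature, 275 TF ChIP antigens
#' plus the ChIP-pair feature, and 5 transcription assays. Totals: 1280
#' primary + 333 secondary = 1613 features.
#'
#' @param n_tf,n_rbp,n_repeat,n_marks,n_chip resource counts (defaults are
#'   the published ones).
#' @return a [family_schema()].
#' @export
canonical_family_schema <- function(n_tf = 623L, n_rbp = 78L, n_repeat = 59L,
                                    n_marks = 48L, n_chip = 275L) {
  uni <- kmer_universe(5L)
  feats <- list(
    list(uni$levels, "kmer", "primary"),
    list(c(sprintf("motif_TF%03d", seq_len(n_tf)),
           sprintf("motif_RBP%02d", seq_len(n_rbp))), "motif", "primary"),
    list(c(sprintf("repeat_%02d", seq_len(n_repeat)), "repeat_pair"),
         "repeat", "primary"),
    list(c("triplex_pairs", "triplex_total_len", "triplex_max_score",
           "triplex_tts_cov"), "triplex", "primary"),
    list(c("tf_pair", "rbp_pair", "ppi_pair"), "shared_motif", "primary"),
    list(c("dnase", "atac"), "accessibility", "secondary"),
    list("methylation", "methylation", "secondary"),
    list(c(sprintf("mark_%02d", seq_len(n_marks)), "chromatin_pair"),
         "chromatin_marks", "secondary"),
    list(c(sprintf("chip_%03d", seq_len(n_chip)), "chip_pair"),
         "tf_chip", "secondary"),
    list(c("groseq", "proseq", "rnaseq", "cage", "polii"),
         "transcription", "secondary")
  )
  family_schema(
    features = unlist(lapply(feats, `[[`, 1L)),
    family = rep(vapply(feats, `[[`, "", 2L), lengths(lapply(feats, `[[`, 1L))),
    category = rep(vapply(feats, `[[`, "", 3L), lengths(lapply(feats, `[[`, 1L)))
  )
}

#' Repeat-element overlap features for tiles
#'
#' Per repeat family, the number of instance intervals overlapping each
#' tile; `repeat_pair` is the number of repeat families overlapping both
#' the tile and the lncRNA gene.
#'
#' @param tiles `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open) and `id`.
#' @param repeat_instances `data.frame` with `chrom`, `start`, `end`,
#'   `family`.
#' @param lnc_gene optional list/row with `chrom`, `start`, `end`; when
#'   given, the `repeat_pair` column is appended.
#' @param families fixed column order (default: sorted families observed).
#' @return integer matrix tiles x features.
#' @export
repeat_features <- function(tiles, repeat_instances, lnc_gene = NULL,
                            families = NULL) {
  ri <- data.table::as.data.table(repeat_instances)
  if (any(ri$end < ri$start)) stop("negative-length repeat interval")
  if (is.null(families)) families <- sort(unique(ri$family))
  unknown <- setdiff(unique(ri$family), families)
  if (length(unknown)) {
    message("adding unknown repeat families: ", paste(unknown, collapse = ", "))
    families <- c(families, unknown)
  }
  out <- matrix(0L, nrow = nrow(tiles), ncol = length(families),
                dimnames = list(tiles$id, families))
  lnc_fams <- character(0)
  for (ch in unique(tiles$chrom)) {
    ti <- which(tiles$chrom == ch)
    sub <- ri[ri$chrom == ch]
    if (!nrow(sub)) next
    ir_t <- IRanges::IRanges(start = tiles$start[ti] + 1L, end = tiles$end[ti])
    ir_r <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    hits <- IRanges::findOverlaps(ir_t, ir_r)
    if (length(hits)) {
      dt <- data.table::data.table(row = ti[S4Vectors::queryHits(hits)],
                                   fam = sub$family[S4Vectors::subjectHits(hits)])
      cnt <- dt[, .N, by = .(row, fam)]
      out[cbind(cnt$row, match(cnt$fam, families))] <- cnt$N
    }
    if (!is.null(lnc_gene) && lnc_gene$chrom == ch) {
      ir_g <- IRanges::IRanges(start = lnc_gene$start + 1L, end = lnc_gene$end)
      gh <- IRanges::findOverlaps(ir_g, ir_r)
      lnc_fams <- unique(sub$family[S4Vectors::subjectHits(gh)])
    }
  }
  if (!is.null(lnc_gene)) {
    pair <- vapply(seq_len(nrow(tiles)), function(i)
      sum(families[out[i, ] > 0L] %in% lnc_fams), integer(1))
    out <- cbind(out, repeat_pair = pair)
  }
  out
}

#' Shared-motif features for one (lncRNA, tile) pair
#'
#' `tf_pair` / `rbp_pair` count proteins with at least one motif hit on both
#' sides; `ppi_pair` counts unique unordered protein pairs `(p, q)` of the
#' interaction network with `p` hitting the lncRNA side and `q` the tile
#' side.
#'
#' @param tile_tf_hits,tile_rbp_hits character vectors of proteins hitting
#'   the tile (TFs on DNA, RBPs on the putative transcript).
#' @param lnc_tf_hits,lnc_rbp_hits proteins hitting the lncRNA gene /
#'   transcript.
#' @param ppi_edges two-column `data.frame` of undirected protein-protein
#'   interaction edges (may be empty).
#' @return named numeric vector `c(tf_pair, rbp_pair, ppi_pair)`.
#' @export
shared_motif_features <- function(tile_tf_hits, tile_rbp_hits,
                                  lnc_tf_hits, lnc_rbp_hits,
                                  ppi_edges = NULL) {
  tf_pair <- length(intersect(tile_tf_hits, lnc_tf_hits))
  rbp_pair <- length(intersect(tile_rbp_hits, lnc_rbp_hits))
  ppi_pair <- 0L
  if (!is.null(ppi_edges) && nrow(ppi_edges)) {
    lnc_side <- unique(c(lnc_tf_hits, lnc_rbp_hits))
    tile_side <- unique(c(tile_tf_hits, tile_rbp_hits))
    a <- as.character(ppi_edges[[1L]]); b <- as.character(ppi_edges[[2L]])
    hit <- (a %in% lnc_side & b %in% tile_side) | (b %in% lnc_side & a %in% tile_side)
    key <- unique(paste(pmin(a[hit], b[hit]), pmax(a[hit], b[hit])))
    ppi_pair <- length(key)
  }
  c(tf_pair = tf_pair, rbp_pair = rbp_pair, ppi_pair = ppi_pair)
}

#' Aggregate an interval-score track over tiles
#'
#' `mode = "max"`: maximum score over intervals overlapping each tile (0 if
#' none). `mode = "sum"`: per-base sum within the tile, i.e. interval score
#' times overlap length.
#'
#' @param tiles `data.frame` with `chrom`, `start`, `end`, `id`.
#' @param track `data.frame` with `chrom`, `start`, `end`, `score`.
#' @param mode `"max"` or `"sum"`.
#' @return numeric vector, one value per tile.
#' @export
aggregate_track <- function(tiles, track, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  tr <- data.table::as.data.table(track)
  if (any(tr$end < tr$start)) stop("negative-length interval in track")
  out <- numeric(nrow(tiles))
  for (ch in unique(tiles$chrom)) {
    ti <- which(tiles$chrom == ch)
    sub <- tr[tr$chrom == ch]
    if (!nrow(sub)) next
    ir_t <- IRanges::IRanges(start = tiles$start[ti] + 1L, end = tiles$end[ti])
    ir_s <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    hits <- IRanges::findOverlaps(ir_t, ir_s)
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (mode == "max") {
      dt <- data.table::data.table(row = qi, v = sub$score[si])
      agg <- dt[, .(v = max(v)), by = row]
    } else {
      ov <- IRanges::width(IRanges::pintersect(ir_t[qi], ir_s[si]))
      dt <- data.table::data.table(row = qi, v = ov * sub$score[si])
      agg <- dt[, .(v = sum(v)), by = row]
    }
    out[ti[agg$row]] <- agg$v
  }
  out
}

#' Paired context features
#'
#' `chip_pair`: number of antigens with at least one peak overlapping both
#' the tile and the lncRNA gene; `chromatin_pair`: the same over histone
#' mark tracks.
#'
#' @param tiles `data.frame` with `chrom`, `start`, `end`, `id`.
#' @param lnc_gene list/row with `chrom`, `start`, `end`.
#' @param chip_tracks,mark_tracks named lists of peak tracks
#'   (`chrom`, `start`, `end`, `score`).
#' @return two-column matrix (`chip_pair`, `chromatin_pair`), one row per
#'   tile.
#' @export
paired_context_features <- function(tiles, lnc_gene, chip_tracks = list(),
                                    mark_tracks = list()) {
  overlaps_tiles <- function(tr) {
    hit <- logical(nrow(tiles))
    for (ch in unique(tiles$chrom)) {
      ti <- which(tiles$chrom == ch)
      sub <- tr[tr$chrom == ch]
      if (!nrow(sub)) next
      ir_t <- IRanges::IRanges(start = tiles$start[ti] + 1L, end = tiles$end[ti])
      ir_s <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
      hit[ti] <- IRanges::overlapsAny(ir_t, ir_s)
    }
    hit
  }
  pair_count <- function(tracks) {
    acc <- matrix(FALSE, nrow = nrow(tiles), ncol = length(tracks))
    on_lnc <- logical(length(tracks))
    for (i in seq_along(tracks)) {
      tr <- data.table::as.data.table(tracks[[i]])
      acc[, i] <- overlaps_tiles(tr)
      sub <- tr[tr$chrom == lnc_gene$chrom]
      on_lnc[i] <- nrow(sub) > 0 &&
        any(sub$start < lnc_gene$end & sub$end > lnc_gene$start)
    }
    as.integer(acc %*% as.numeric(on_lnc))
  }
  cbind(chip_pair = if (length(chip_tracks)) pair_count(chip_tracks) else
          integer(nrow(tiles)),
        chromatin_pair = if (length(mark_tracks)) pair_count(mark_tracks) else
          integer(nrow(tiles)))
}

#' Assemble the synthetic feature table for one lncRNA
#'
#' Materializes, for every tile of the lncRNA's chromosome, the feature
#' families requested from the synthetic bundle: canonical 5-mer counts
#' (`kmer`), the builtin triplex quartet against the lncRNA transcript
#' (`triplex`), repeat overlap counts plus repeat pair (`repeat`), and one
#' max-aggregated column per context track (families `transcription`,
#' `ctx_a`, `ctx_b`).
#'
#' @param genome [generate_genome()] output.
#' @param tracks [generate_context_tracks()] output.
#' @param imap [generate_interactions()] output.
#' @param lnc lncRNA name.
#' @param families families to materialize.
#' @param tile_ids optionally restrict to these tile ids (e.g. the tiles of
#'   a labeled dataset); default is every tile of the lncRNA's chromosome.
#' @return list with `X` (numeric matrix, tiles x features, rownames = tile
#'   ids), `schema` ([family_schema()]) and `tile_ids`.
#' @export
build_feature_table <- function(genome, tracks, imap, lnc,
                                families = c("triplex", "repeat",
                                             "transcription", "ctx_a", "ctx_b"),
                                tile_ids = NULL) {
  rec <- imap$lncRNAs[imap$lncRNAs$name == lnc]
  if (nrow(rec) != 1L) stop("unknown lncRNA ", lnc)
  tiles <- imap$tiling$tiles[imap$tiling$tiles$chrom == rec$chrom]
  if (!is.null(tile_ids)) {
    tiles <- tiles[tiles$id %in% tile_ids]
    if (nrow(tiles) != length(unique(tile_ids)))
      stop("some requested tiles are not on the lncRNA's chromosome")
  }
  w <- imap$tiling$tile_width
  chrom_seq <- genome$sequences[[rec$chrom]]
  tile_seqs <- Biostrings::DNAStringSet(
    lapply(seq_len(nrow(tiles)), function(i)
      Biostrings::subseq(chrom_seq, tiles$start[i] + 1L, tiles$end[i])))
  names(tile_seqs) <- tiles$id
  blocks <- list(); fam <- character(0); cat <- character(0)
  for (f in families) {
    if (f == "kmer") {
      m <- count_canonical_kmers(tile_seqs)
      blocks[[f]] <- m; fam <- c(fam, rep("kmer", ncol(m)))
      cat <- c(cat, rep("primary", ncol(m)))
    } else if (f == "triplex") {
      m <- triplex_features(as.character(genome$transcripts[[lnc]]), tile_seqs,
                            tile_ids = tiles$id)
      blocks[[f]] <- m; fam <- c(fam, rep("triplex", 4L))
      cat <- c(cat, rep("primary", 4L))
    } else if (f == "repeat") {
      m <- repeat_features(tiles, genome$repeat_instances,
                           lnc_gene = list(chrom = rec$chrom,
                                           start = rec$gene_start,
                                           end = rec$gene_end))
      blocks[[f]] <- m; fam <- c(fam, rep("repeat", ncol(m)))
      cat <- c(cat, rep("primary", ncol(m)))
    } else if (f %in% names(tracks)) {
      v <- aggregate_track(tiles, tracks[[f]], mode = "max")
      m <- matrix(v, ncol = 1L, dimnames = list(tiles$id, f))
      blocks[[f]] <- m; fam <- c(fam, f); cat <- c(cat, "secondary")
    } else stop("unknown feature family ", f)
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- tiles$id
  list(X = X, schema = family_schema(colnames(X), fam, cat), tile_ids = tiles$id)
}
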