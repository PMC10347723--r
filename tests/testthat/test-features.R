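test_that("the published-resource schema reproduces the catalogue counts", {
  sch <- canonical_family_schema()
  expect_equal(sum(sch$family == "kmer"), 512L)
  expect_equal(sum(sch$category == "primary"), 1280L)
  expect_equal(sum(sch$category == "secondary"), 333L)
  expect_equal(nrow(sch), 1613L)
  expect_equal(schema_families(sch, "primary"),
               c("kmer", "motif", "repeat", "triplex", "shared_motif"))
  expect_length(schema_families(sch, "secondary"), 5L)
})

test_that("repeat overlap counts and the repeat-pair intersection are exact", {
  tiles <- data.frame(id = 0:1, chrom = "c", start = c(0, 1000), end = c(1000, 2000))
  inst <- data.frame(chrom = "c",
                     start = c(100, 500, 700, 1500, 3000),
                     end = c(200, 600, 800, 1600, 3100),
                     family = c("Alu", "Alu", "L1", "ERVK", "L1"))
  m <- repeat_features(tiles, inst,
                       lnc_gene = list(chrom = "c", start = 2900, end = 3200))
  expect_equal(unname(m[1, c("Alu", "L1", "ERVK")]), c(2L, 1L, 0L))
  expect_equal(unname(m[2, c("Alu", "L1", "ERVK")]), c(0L, 0L, 1L))
  # lncRNA gene overlaps only L1 -> tile 0 shares {L1}, tile 1 shares {}
  expect_equal(unname(m[, "repeat_pair"]), c(1L, 0L))
  m0 <- repeat_features(tiles, inst[0, ], families = c("Alu"))
  expect_true(all(m0 == 0))
})

test_that("shared-motif features count intersections and PPI bridges", {
  expect_equal(unname(shared_motif_features(character(0), character(0),
                                            character(0), character(0))),
               c(0L, 0L, 0L))
  r <- shared_motif_features(c("Sp1", "Sp2", "Klf4"), "R2",
                             c("Sp1", "Sp2"), c("R1", "R2"),
                             ppi_edges = data.frame(a = "R1", b = "Klf4"))
  expect_equal(unname(r), c(2, 1, 1))
  # oracle: exhaustive edge enumeration on a random instance
  set.seed(3)
  prot <- paste0("P", 1:12)
  edges <- data.frame(a = sample(prot, 30, TRUE), b = sample(prot, 30, TRUE))
  tile_side <- sample(prot, 5); lnc_side <- sample(prot, 5)
  got <- shared_motif_features(tile_side, character(0), lnc_side, character(0),
                               ppi_edges = edges)[["ppi_pair"]]
  keys <- character(0)
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]
    if ((a %in% lnc_side && b %in% tile_side) ||
        (b %in% lnc_side && a %in% tile_side))
      keys <- c(keys, paste(min(a, b), max(a, b)))
  }
  expect_equal(got, length(unique(keys)))
})

test_that("track aggregation: max of overlapping peaks, per-base sums, additivity", {
  tiles <- data.frame(id = 0L, chrom = "c", start = 0, end = 1000)
  tr <- data.frame(chrom = "c", start = c(100, 800), end = c(300, 900),
                   score = c(5, 9))
  expect_equal(aggregate_track(tiles, tr, "max"), 9)
  tr2 <- data.frame(chrom = "c", start = 100, end = 300, score = 2)
  expect_equal(aggregate_track(tiles, tr2, "sum"), 400)
  expect_equal(aggregate_track(tiles, tr2[0, ], "max"), 0)
  expect_error(aggregate_track(tiles, data.frame(chrom = "c", start = 10,
                                                 end = 5, score = 1), "max"),
               "negative-length")
  # sum mode is additive over a partition of the interval
  parts <- data.frame(chrom = "c", start = c(100, 200), end = c(200, 300),
                      score = 2)
  expect_equal(aggregate_track(tiles, parts, "sum"),
               aggregate_track(tiles, tr2, "sum"))
})

test_that("paired context features count double-overlapping antigens", {
  tiles <- data.frame(id = 0:1, chrom = "c", start = c(0, 5000), end = c(1000, 6000))
  gene <- list(chrom = "c", start = 2000, end = 3000)
  mk <- function(...) data.frame(chrom = "c", ..., score = 1)
  chip <- list(tf1 = mk(start = c(100, 2100), end = c(200, 2200)),   # both sides
               tf2 = mk(start = 150, end = 250),                      # tile only
               tf3 = mk(start = c(900, 2500), end = c(950, 2600)))    # both sides
  pc <- paired_context_features(tiles, gene, chip_tracks = chip)
  expect_equal(unname(pc[, "chip_pair"]), c(2L, 0L))
  # oracle on random placements
  set.seed(9)
  tracks <- lapply(1:6, function(i)
    mk(start = (s <- sort(sample(0:5900, 4))), end = s + 80))
  names(tracks) <- paste0("ag", 1:6)
  got <- paired_context_features(tiles, gene, mark_tracks = tracks)[, "chromatin_pair"]
  naive <- sapply(seq_len(nrow(tiles)), function(j) {
    sum(vapply(tracks, function(tr) {
      on_tile <- any(tr$start < tiles$end[j] & tr$end > tiles$start[j])
      on_gene <- any(tr$start < gene$end & tr$end > gene$start)
      on_tile && on_gene
    }, TRUE))
  })
  expect_equal(unname(got), unname(naive))
})

test_that("the synthetic feature table matches its schema and has no gaps", {
  b <- tiny_bundle(seed = 21, n_pos = 40)
  ft <- build_feature_table(b$genome, b$tracks, b$imap, "lnc1",
                            families = c("kmer", "triplex", "repeat",
                                         "transcription", "ctx_a", "ctx_b"))
  expect_equal(ncol(ft$X), nrow(ft$schema))
  expect_false(anyNA(ft$X))
  expect_true(all(ft$X[, ft$schema$feature[ft$schema$family == "kmer"]] >= 0))
  # restriction to a tile subset preserves columns and rows
  ids <- b$imap$bound$lnc1[1:10]
  ft2 <- build_feature_table(b$genome, b$tracks, b$imap, "lnc1",
                             families = c("repeat", "ctx_a"), tile_ids = ids)
  expect_equal(rownames(ft2$X), as.character(sort(ids)))
})
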