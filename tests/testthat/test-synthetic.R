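test_that("config validation rejects inconsistent geometry and weights", {
  expect_error(synthetic_config(1, 1e5 + 500, 1000), "divisible")
  expect_error(synthetic_config(1, 1e5, 1000, decay_scale = 0), "decay_scale")
  expect_error(synthetic_config(1, 1e5, 1000, kmer_bias = c(1, 2)), "named")
  bad <- list(lnc_spec("l", "chrS1", 9e4, 1.2e5, "noise", 0, 10))
  expect_error(synthetic_config(1, 1e5, 1000, lncRNAs = bad), "exceeds")
  over <- list(lnc_spec("a", "chrS1", 0, 5000, "noise", 0, 10),
               lnc_spec("b", "chrS1", 4000, 9000, "noise", 0, 10))
  expect_error(generate_genome(synthetic_config(1, 1e5, 1000, lncRNAs = over)),
               "overlapping")
})

test_that("generation is byte-identical under a fixed seed", {
  mk <- function(seed) {
    cfg <- synthetic_config(1, 2e5, 1000,
                            list(lnc_spec("l", "chrS1", 1e5, 1.02e5,
                                          "triplex", 2, 30)),
                            decay_scale = 5e4, seed = seed)
    g <- generate_genome(cfg)
    tr <- generate_context_tracks(cfg, g)
    im <- generate_interactions(cfg, g, tr)
    list(s = as.character(g$sequences), t = as.character(g$transcripts),
         seeds = g$mirna_seeds, tracks = tr, bound = im$bound)
  }
  a <- mk(7); b <- mk(7); c <- mk(8)
  expect_identical(a, b)
  expect_false(identical(a$s, c$s))
  expect_false(identical(a$bound, c$bound))
})

test_that("an empty k-mer bias yields near-uniform 5-mer frequencies", {
  cfg <- synthetic_config(1, 5e5, 1000, seed = 3)
  g <- generate_genome(cfg)
  m <- count_canonical_kmers(Biostrings::subseq(g$sequences[[1]], 1, 100000))
  # each canonical 5-mer expects ~2 * L / 1024 occurrences
  expect_lt(abs(mean(m) - 2 * 99996 / 1024), 5)
  expect_gt(min(m), 0)
})

test_that("a planted k-mer bias shows up as positive density correlation", {
  uni <- kmer_universe(5)
  fav <- c("CTGCC", "CTTCC", "AAGGA")  # canonical forms
  bias <- setNames(rep(5, 3), fav)
  cfg <- synthetic_config(1, 1e5, 1000, seed = 9, kmer_bias = bias,
                          n_mirnas = 100L,
                          lncRNAs = list(lnc_spec("l", "chrS1", 5e4, 5.2e4,
                                                  "noise", 0, 10)),
                          transcript_length = 5000L)
  g <- generate_genome(cfg)
  w <- setNames(numeric(512), uni$levels); w[fav] <- 5
  d <- kmer_density(g$transcripts)
  expect_gt(suppressWarnings(cor(w, d[uni$levels], method = "spearman")), 0)
  # the same bias reaches seeds and repeat consensus sequences
  expect_gt(mean(seed_membership_density(g$mirna_seeds)[fav]),
            mean(seed_membership_density(g$mirna_seeds)))
})

test_that("context tracks have the configured autocorrelation structure", {
  cfg <- synthetic_config(1, 1e6, 1000, seed = 5, track_block_length = 1e4)
  g <- generate_genome(cfg)
  tr <- generate_context_tracks(cfg, g)
  v <- lncloc:::tile_track_mean(tr$transcription, "chrS1", 1000, 1000)
  lag1 <- cor(v[-1], v[-length(v)])
  expect_gt(lag1, 0.5)

  cfg2 <- synthetic_config(1, 2e5, 1000, seed = 5, track_block_length = 1)
  tr2 <- generate_context_tracks(cfg2, generate_genome(cfg2))
  v2 <- lncloc:::tile_track_mean(tr2$transcription, "chrS1", 200, 1000)
  expect_lt(abs(cor(v2[-1], v2[-length(v2)])), 0.2)

  # xor indicator from median-thresholded tracks is roughly balanced
  a <- lncloc:::tile_track_mean(tr$ctx_a, "chrS1", 1000, 1000)
  b <- lncloc:::tile_track_mean(tr$ctx_b, "chrS1", 1000, 1000)
  x <- xor(a > median(a), b > median(b))
  # discrete track levels make the median split slightly lumpy
  expect_lt(abs(mean(x) - 0.5), 0.15)
})

test_that("with zero effect the positive distances follow the decay law", {
  cfg <- synthetic_config(1, 4e6, 1000,
                          list(lnc_spec("l", "chrS1", 2e6, 2.002e6,
                                        "transcription", 0, 400)),
                          decay_scale = 3e5, seed = 13)
  g <- generate_genome(cfg)
  tr <- generate_context_tracks(cfg, g)
  im <- generate_interactions(cfg, g, tr)
  tiles <- im$tiling$tiles
  d_all <- interval_gap(tiles$start, tiles$end, 2e6, 2.002e6)
  d_pos <- d_all[match(im$bound$l, tiles$id)]
  # oracle: an independent draw from the stated sampling law
  d_ref <- withr::with_seed(99, {
    w <- exp(-d_all / 3e5)
    d_all[sample.int(length(d_all), 400, prob = w)]
  })
  p <- suppressWarnings(stats::ks.test(d_pos, d_ref)$p.value)
  expect_gt(p, 0.001)
})

test_that("planted transcription signal separates positives from matched negatives", {
  b <- tiny_bundle(seed = 17, mechanism = "transcription", n_pos = 150,
                   chrom_length = 4e6)
  ds <- build_labeled_dataset(b$imap, "lnc1", seed = 2)
  v <- lncloc:::tile_track_mean(b$tracks$transcription, "chrS1", 4000, 1000)
  wp <- v[ds$positives + 1L]; wn <- v[ds$negatives + 1L]
  p <- stats::wilcox.test(wp, wn, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("positives never exceed the chromosome and excess targets error", {
  cfg <- synthetic_config(1, 5e4, 1000,
                          list(lnc_spec("l", "chrS1", 2e4, 2.2e4,
                                        "noise", 0, 100)),
                          seed = 1)
  g <- generate_genome(cfg)
  tr <- generate_context_tracks(cfg, g)
  expect_error(generate_interactions(cfg, g, tr), "exceeds tiles")
})

test_that("the bundle writer emits the declared plain-text files", {
  b <- tiny_bundle(seed = 23, n_pos = 20)
  dir <- tempfile()
  write_synthetic_bundle(b$genome, b$tracks, b$imap, dir)
  expect_true(all(file.exists(file.path(dir,
    c("genome.fa", "transcripts.fa", "genes.bed", "repeats.bed",
      "track_transcription.bedgraph", "mirna_seeds.tsv", "interactions.tsv")))))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(fa), as.character(b$genome$sequences))
})
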