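# Small fixture builders shared across test files.

tiny_tiling <- function(sizes = c(chrA = 10000, chrB = 6000), w = 1000) {
  tile_genome(sizes, w)
}

# Random DNA string of length n under a local seed.
rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Naive double-strand canonical k-mer counter used as an oracle.
naive_canonical_counts <- function(seq, k = 5) {
  uni <- kmer_universe(k)
  out <- setNames(integer(length(uni$levels)), uni$levels)
  chars <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nchar(seq) - k + 1)) {
    w <- paste(chars[i:(i + k - 1)], collapse = "")
    if (!grepl("^[ACGT]+$", w)) next
    rc <- paste(rev(unname(comp[strsplit(w, "")[[1]]])), collapse = "")
    out[min(w, rc)] <- out[min(w, rc)] + 1L
  }
  out
}

# Exhaustive pair-counting AUROC oracle (ties get half credit).
pair_count_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Brute-force signed-KS oracle: evaluate the ECDF difference at every
# pooled point and take the first maximizer of the absolute value.
naive_signed_ks <- function(bound, unbound) {
  xs <- sort(unique(c(bound, unbound)))
  delta <- sapply(xs, function(x) mean(unbound <= x) - mean(bound <= x))
  delta[which.max(abs(delta))]
}

# A tiny synthetic bundle shared by several tests.
tiny_bundle <- function(seed = 5, mechanism = "transcription", n_pos = 80,
                        chrom_length = 6e5) {
  cfg <- synthetic_config(
    n_chroms = 1L, chrom_length = chrom_length, tile_width = 1000L,
    lncRNAs = list(lnc_spec("lnc1", "chrS1", chrom_length / 2,
                            chrom_length / 2 + 2000, mechanism, 3, n_pos)),
    decay_scale = 1e5, seed = seed)
  genome <- generate_genome(cfg)
  tracks <- generate_context_tracks(cfg, genome)
  imap <- generate_interactions(cfg, genome, tracks)
  list(cfg = cfg, genome = genome, tracks = tracks, imap = imap)
}
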