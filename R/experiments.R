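#' Configuration of the mechanism-recovery simulation study
#'
#' A four-lncRNA synthetic cohort, one planted mechanism each:
#' transcription (chrS1), exclusive-or pair (chrS2), triplex (chrS3) and
#' distance-only noise (chrS4). The non-noise lncRNAs carry 250 bound
#' tiles each at planted effect size 3; the noise lncRNA carries 700 bound
#' tiles so that, with the 5:1 negative ratio, its dataset exceeds 4000
#' examples -- the regime in which family MPVs of uninformative features
#' concentrate within a few hundredths of zero. Decay scales are set so
#' that near-gene positive occupancy stays below 1/6, leaving the
#' candidate negatives enough support to match the positive distance
#' distribution. See the methods vignette for how these sizes were chosen.
#'
#' @param seed generator seed.
#' @param n_positives bound tiles per non-noise lncRNA (default 250).
#' @param n_noise_positives bound tiles for the noise lncRNA (default 700).
#' @param effect_size planted log-odds effect (default 3).
#' @return a [synthetic_config()].
#' @export
recovery_cohort_config <- function(seed, n_positives = 250L,
                                   n_noise_positives = 700L,
                                   effect_size = 3) {
  synthetic_config(
    n_chroms = 4L, chrom_length = c(7e6, 7e6, 7e6, 14e6), tile_width = 1000L,
    lncRNAs = list(
      lnc_spec("lncT", "chrS1", 3.5e6, 3.5e6 + 2000, "transcription",
               effect_size, n_positives, decay_scale = 1e6),
      lnc_spec("lncX", "chrS2", 3.5e6, 3.5e6 + 2000, "xor_pair",
               effect_size, n_positives, decay_scale = 1e6),
      lnc_spec("lncQ", "chrS3", 3.5e6, 3.5e6 + 2000, "triplex",
               effect_size, n_positives, decay_scale = 1e6),
      lnc_spec("lncN", "chrS4", 7e6, 7e6 + 2000, "noise",
               0, n_noise_positives, decay_scale = 3e6)),
    decay_scale = 1e6, seed = seed, track_block_length = 1e4,
    tts_fraction = 0.15)
}

# Fit the full two-set model ensemble for one lncRNA of a synthetic bundle
# and return its MPV/MxPV table (and the ensemble itself).
analyze_lncrna <- function(genome, tracks, imap, lnc, families, seed,
                           ratio = 5, cap = 100L, K = 5L,
                           neighbors_per_seed = 14L, trees = 200L, n_pc = 8L) {
  ds <- build_labeled_dataset(imap, lnc, ratio = ratio, cap = cap,
                              seed = child_seed(seed, paste0("ds", lnc)))
  ids <- c(ds$positives, ds$negatives)
  ft <- build_feature_table(genome, tracks, imap, lnc, families = families,
                            tile_ids = ids)
  bl <- make_blocks(ds, imap$tiling, neighbors_per_seed = neighbors_per_seed,
                    seed = child_seed(seed, paste0("bl", lnc)))
  pt <- assign_folds(bl, K = K, mode = "block",
                     seed = child_seed(seed, paste0("cv", lnc)))
  specs <- enumerate_model_specs(ft$schema, lnc)
  res <- run_model_ensemble(ft$X, ft$schema, pt, specs, trees = trees,
                            n_pc = n_pc,
                            seed = child_seed(seed, paste0("rf", lnc)))
  list(dataset = ds, features = ft, partition = pt, results = res,
       mpv = mpv_table(res, ft$schema, lnc))
}

#' Run one replicate of the mechanism-recovery study
#'
#' Generates a [recovery_cohort_config()] bundle, fits the full
#' sequence-only and sequence+context model ensembles per lncRNA (block
#' cross-validation, 200 trees), computes MPV/MxPV per family, TA calls at
#' the MPV >= 0.01 threshold, and the exclusive-or pair complementarity.
#'
#' @param seed replicate seed (drives generation, sampling and fitting).
#' @param trees forest size (default 200).
#' @param n_positives,n_noise_positives,effect_size cohort sizes, passed to
#'   [recovery_cohort_config()].
#' @return list with `mpv` (combined table), `top_family` (named character:
#'   highest-MPV family per lncRNA), `ta` (TA calls), `xor` (complementarity
#'   result for the ctx_a/ctx_b pair on the xor lncRNA), `noise_max_abs_mpv`.
#' @export
run_recovery_cohort <- function(seed, trees = 200L, n_positives = 250L,
                                n_noise_positives = 700L, effect_size = 3) {
  cfg <- recovery_cohort_config(seed, n_positives, n_noise_positives,
                                effect_size)
  genome <- generate_genome(cfg)
  tracks <- generate_context_tracks(cfg, genome)
  imap <- generate_interactions(cfg, genome, tracks)
  families <- c("triplex", "repeat", "transcription", "ctx_a", "ctx_b")
  res <- lapply(c("lncT", "lncX", "lncQ", "lncN"), function(nm)
    analyze_lncrna(genome, tracks, imap, nm, families, seed, trees = trees))
  names(res) <- c("lncT", "lncX", "lncQ", "lncN")
  mpvs <- data.table::rbindlist(lapply(res, `[[`, "mpv"))
  top <- vapply(res, function(r) r$mpv$family[which.max(r$mpv$mpv)], "")
  ta <- classify_ta(mpvs, family = "transcription", threshold = 0.01)
  xr <- res$lncX
  xor <- complementarity(xr$features$X, xr$features$schema, xr$partition,
                         "ctx_a", "ctx_b", trees = trees,
                         seed = child_seed(seed, "xorcomp"))
  list(mpv = mpvs, top_family = top, ta = ta$labels, xor = xor,
       noise_max_abs_mpv = max(abs(res$lncN$mpv$mpv)))
}

#' Random- versus block-CV leakage experiment
#'
#' For each seed: one transcription-mechanism lncRNA with spatially
#' autocorrelated tracks; the full sequence+context model is evaluated
#' under a random five-fold partition and under the block partition of the
#' same dataset. Because neighboring tiles share both label propensity and
#' track blocks, random CV lets the forest exploit neighborhood identity
#' and generally reports the more optimistic AUROC.
#'
#' @param seeds vector of replicate seeds (default 1:10).
#' @param n_positives bound tiles (default 250).
#' @param trees forest size (default 100).
#' @return `data.table` with `seed`, `auroc_random`, `auroc_block`.
#' @export
leakage_experiment <- function(seeds = 1:10, n_positives = 250L, trees = 100L) {
  out <- lapply(seeds, function(sd) {
    cfg <- synthetic_config(
      n_chroms = 1L, chrom_length = 2e6, tile_width = 1000L,
      lncRNAs = list(lnc_spec("lncT", "chrS1", 1e6, 1e6 + 2000,
                              "transcription", 3, n_positives)),
      decay_scale = 2e5, seed = sd, track_block_length = 1e4)
    genome <- generate_genome(cfg)
    tracks <- generate_context_tracks(cfg, genome)
    imap <- generate_interactions(cfg, genome, tracks)
    ds <- build_labeled_dataset(imap, "lncT", seed = child_seed(sd, "ds"))
    ids <- c(ds$positives, ds$negatives)
    ft <- build_feature_table(genome, tracks, imap, "lncT",
                              families = c("triplex", "repeat", "transcription",
                                           "ctx_a", "ctx_b"), tile_ids = ids)
    bl <- make_blocks(ds, imap$tiling, neighbors_per_seed = 14L,
                      seed = child_seed(sd, "bl"))
    spec <- list(lncRNA = "lncT", set = "seq_context",
                 families = c("transcription", "ctx_a", "ctx_b"),
                 representation = "sequence_PC",
                 key = subset_key(c("transcription", "ctx_a", "ctx_b")),
                 id = "ctx:full")
    eval_part <- function(mode) {
      pt <- assign_folds(bl, K = 5L, mode = mode, seed = child_seed(sd, mode))
      r <- run_model_ensemble(ft$X, ft$schema, pt, list(spec), trees = trees,
                              n_pc = 8L, seed = child_seed(sd, paste0("rf", mode)))
      mean(r$table$auroc, na.rm = TRUE)
    }
    data.table::data.table(seed = sd, auroc_random = eval_part("random"),
                           auroc_block = eval_part("block"))
  })
  data.table::rbindlist(out)
}

#' 5-mer importance-rank versus sequence-density experiment
#'
#' One triplex-mechanism lncRNA whose triplex-forming oligo is fixed, with
#' the oligo's constituent 5-mers also enriched (shared `kmer_bias`) in the
#' lncRNA transcript, miRNA seeds and repeat consensus sequences. The
#' sequence-only ensemble over the k-mer and repeat families is fitted;
#' 5-mer importance ranks are aggregated over the top-20-percentile models
#' and correlated (Spearman) with 5-mer densities in the lncRNA transcript,
#' in miRNA seed membership and in repeat consensus sequences. The planted
#' sharing makes rank-vs-density correlations negative (important 5-mers
#' are dense).
#'
#' @param seed replicate seed.
#' @param n_positives bound tiles (default 250).
#' @param trees forest size (default 150).
#' @return list with `rho_lnc`, `p_lnc`, `rho_seed`, `rho_repeat`, and the
#'   underlying `ranks` table.
#' @export
kmer_rank_experiment <- function(seed, n_positives = 250L, trees = 150L) {
  # a de Bruijn purine sequence: its 32 windows cover every A/G 5-mer, so
  # the planted sites touch as many distinct canonical 5-mers as a purine
  # TFO can (the attainable rank-density correlation grows with that count)
  tfo <- "AAAAAGGGGGAGGGAAGGAGAGGAAAGAGAAGAAAA"
  bias <- setNames(rep(5, length(seed_kmers(tfo, 5L))), seed_kmers(tfo, 5L))
  cfg <- synthetic_config(
    n_chroms = 1L, chrom_length = 7e6, tile_width = 1000L,
    lncRNAs = list(lnc_spec("lncK", "chrS1", 3.5e6, 3.5e6 + 2000,
                            "triplex", 3, n_positives)),
    decay_scale = 8e5, seed = seed, kmer_bias = bias,
    tfo_sequence = tfo, tts_fraction = 0.15, tts_copies = 3L)
  genome <- generate_genome(cfg)
  tracks <- generate_context_tracks(cfg, genome)
  imap <- generate_interactions(cfg, genome, tracks)
  ds <- build_labeled_dataset(imap, "lncK", seed = child_seed(seed, "ds"))
  ids <- c(ds$positives, ds$negatives)
  ft <- build_feature_table(genome, tracks, imap, "lncK",
                            families = c("kmer", "repeat"), tile_ids = ids)
  bl <- make_blocks(ds, imap$tiling, neighbors_per_seed = 14L,
                    seed = child_seed(seed, "bl"))
  pt <- assign_folds(bl, K = 5L, mode = "block", seed = child_seed(seed, "cv"))
  specs <- Filter(function(s) s$set == "sequence_only",
                  enumerate_model_specs(ft$schema, "lncK"))
  res <- run_model_ensemble(ft$X, ft$schema, pt, specs, trees = trees,
                            seed = child_seed(seed, "rf"))
  ranks <- aggregate_feature_ranks(res, percentile = 20, set = "sequence_only")
  d_lnc <- kmer_density(genome$transcripts["lncK"])
  d_seed <- seed_membership_density(genome$mirna_seeds)
  d_rep <- kmer_density(genome$repeat_consensus, average = TRUE)
  c_lnc <- kmer_density_correlation(ranks, d_lnc)
  c_seed <- kmer_density_correlation(ranks, d_seed)
  c_rep <- kmer_density_correlation(ranks, d_rep)
  list(rho_lnc = c_lnc$rho, p_lnc = c_lnc$p_value,
       rho_seed = c_seed$rho, rho_repeat = c_rep$rho, ranks = ranks)
}

#' Distance-matching quality of the negative sampler
#'
#' One noise-mechanism lncRNA with 2000 bound tiles on a chromosome long
#' and flat enough (20 Mb, decay scale 3 Mb) that the candidate negatives
#' cover the positives' distance support; samples negatives at 1:1 and
#' returns the two-sample KS distance between the positive and sampled
#' negative tile-to-gene distance distributions.
#'
#' @param seed replicate seed.
#' @return list with `ks_d`, `n_pos`, `n_neg`.
#' @export
negative_match_experiment <- function(seed) {
  cfg <- synthetic_config(
    n_chroms = 1L, chrom_length = 20e6, tile_width = 1000L,
    lncRNAs = list(lnc_spec("lncN", "chrS1", 10e6, 10e6 + 2000, "noise",
                            0, 2000L)),
    decay_scale = 3e6, seed = seed)
  genome <- generate_genome(cfg)
  tracks <- generate_context_tracks(cfg, genome)
  imap <- generate_interactions(cfg, genome, tracks)
  ds <- build_labeled_dataset(imap, "lncN", ratio = 1, seed = child_seed(seed, "ds"))
  d <- ds$distance
  ks <- signed_ks(d[as.character(ds$positives)], d[as.character(ds$negatives)])
  list(ks_d = abs(ks$d_signed), n_pos = length(ds$positives),
       n_neg = length(ds$negatives))
}

#' False-positive control of the enrichment battery under a permuted null
#'
#' Builds a noise-mechanism dataset, permutes the bound/unbound labels
#' (severing any residual association), runs the signed-KS enrichment
#' battery over the 512 canonical 5-mers plus the three context tracks and
#' returns the fraction of Benjamini-Hochberg adjusted p-values below 0.05.
#'
#' @param seed replicate seed.
#' @param n_positives bound tiles (default 300).
#' @return list with `fp_rate`, `n_tests`.
#' @export
permutation_fdr_experiment <- function(seed, n_positives = 300L) {
  cfg <- synthetic_config(
    n_chroms = 1L, chrom_length = 3e6, tile_width = 1000L,
    lncRNAs = list(lnc_spec("lncN", "chrS1", 1.5e6, 1.5e6 + 2000, "noise",
                            0, n_positives)),
    decay_scale = 2e5, seed = seed)
  genome <- generate_genome(cfg)
  tracks <- generate_context_tracks(cfg, genome)
  imap <- generate_interactions(cfg, genome, tracks)
  ds <- build_labeled_dataset(imap, "lncN", seed = child_seed(seed, "ds"))
  ids <- c(ds$positives, ds$negatives)
  ft <- build_feature_table(genome, tracks, imap, "lncN",
                            families = c("kmer", "transcription", "ctx_a", "ctx_b"),
                            tile_ids = ids)
  perm <- with_seed(child_seed(seed, "perm"), sample(ids))
  ds_perm <- ds
  ds_perm$positives <- perm[seq_along(ds$positives)]
  ds_perm$negatives <- perm[-seq_along(ds$positives)]
  bat <- enrichment_battery(ft$X, list(lncN = ds_perm), colnames(ft$X))
  list(fp_rate = mean(bat$p_adj < 0.05), n_tests = nrow(bat))
}
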