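#' Specification of one synthetic lncRNA
#'
#' Describes a lncRNA gene planted in the synthetic genome together with the
#' mechanism that drives its chromatin binding:
#' * `"transcription"` — binding follows a spatially autocorrelated
#'   transcription-like context track (a secondary-family signal);
#' * `"triplex"` — binding follows planted triplex target sites whose
#'   purine run matches a triplex-forming oligo embedded in the lncRNA
#'   transcript (a primary, lncRNA-x-tile signal);
#' * `"xor_pair"` — binding follows the exclusive-or of two context tracks
#'   thresholded at their medians, so each track alone is uninformative;
#' * `"noise"` — binding depends on genomic distance only.
#'
#' @param name lncRNA identifier.
#' @param chrom chromosome name.
#' @param gene_start,gene_end 0-based half-open gene interval in bp.
#' @param mechanism one of `"transcription"`, `"triplex"`, `"xor_pair"`,
#'   `"noise"`.
#' @param effect_size log-odds contribution of the planted signal to the
#'   binding probability (ignored for `"noise"`).
#' @param n_target_positives number of bound tiles to sample.
#' @param decay_scale optional per-lncRNA distance-decay length (bp),
#'   overriding the configuration default. Choose it so that the expected
#'   positive occupancy near the gene, `n_target_positives * tile_width /
#'   (2 * decay_scale)`, stays below `1 / (1 + ratio)`: beyond that the
#'   near-gene tiles saturate with positives, no candidate set can match
#'   the positive distance distribution, and distance itself becomes a
#'   confounder.
#' @return a `lnc_spec` list.
#' @export
lnc_spec <- function(name, chrom, gene_start, gene_end,
                     mechanism = c("transcription", "triplex", "xor_pair", "noise"),
                     effect_size = 2, n_target_positives = 1000,
                     decay_scale = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(gene_end > gene_start, gene_start >= 0, is.finite(effect_size))
  structure(list(name = name, chrom = chrom,
                 gene_start = as.integer(gene_start), gene_end = as.integer(gene_end),
                 mechanism = mechanism, effect_size = effect_size,
                 n_target_positives = as.integer(n_target_positives),
                 decay_scale = decay_scale),
            class = "lnc_spec")
}

#' Configuration of the synthetic interactome generator
#'
#' The generator emulates the statistical structure of a lncRNA-chromatin
#' interaction study: per-lncRNA binding probability decaying exponentially
#' with distance from the lncRNA gene, modulated by a planted
#' mechanism-specific signal; spatially autocorrelated context tracks; and a
#' shared 5-mer enrichment (`kmer_bias`) applied when drawing lncRNA
#' transcripts, miRNA seeds and repeat consensus sequences, so that k-mer
#' density correlations between these entities exist by construction.
#'
#' @param n_chroms number of chromosomes (`chrS1`, `chrS2`, ...).
#' @param chrom_length chromosome length(s) in bp, recycled over
#'   chromosomes; every length must be divisible by `tile_width`.
#' @param tile_width tile width in bp (default 1000).
#' @param lncRNAs list of [lnc_spec()] objects.
#' @param decay_scale distance-decay length (bp) of the interaction
#'   probability.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param kmer_bias named numeric vector, canonical 5-mer -> enrichment
#'   weight (>= 0), shared across lncRNA transcripts, miRNA seeds and repeat
#'   consensus sequences.
#' @param track_block_length mean change-point spacing (bp) of the context
#'   tracks, i.e. their autocorrelation scale.
#' @param n_repeat_families,n_mirnas number of repeat families / miRNA seeds.
#' @param tts_fraction fraction of tiles on a triplex lncRNA's chromosome
#'   that receive a planted triplex target site.
#' @param tts_copies number of TTS copies inserted per planted tile
#'   (default 1; higher values strengthen the 5-mer footprint of the
#'   planted sites).
#' @param tts_length length (nt) of the planted purine run.
#' @param tfo_sequence optional fixed purine (A/G) string used as the TFO of
#'   every triplex lncRNA; by default a random purine run is drawn per
#'   lncRNA. Fixing it lets a k-mer bias target the TFO's constituent
#'   5-mers.
#' @param transcript_length length (nt) of generated lncRNA transcripts.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_chroms, chrom_length, tile_width = 1000L,
                             lncRNAs = list(), decay_scale = 2e5, seed = 1L,
                             kmer_bias = numeric(), track_block_length = 1e4,
                             n_repeat_families = 6L, n_mirnas = 30L,
                             tts_fraction = 0.15, tts_length = 25L,
                             tts_copies = 1L, tfo_sequence = NULL,
                             transcript_length = 2000L) {
  if (any(chrom_length %% tile_width != 0))
    stop("chrom_length must be divisible by tile_width")
  if (decay_scale <= 0) stop("decay_scale must be > 0")
  if (length(kmer_bias) && (is.null(names(kmer_bias)) || any(kmer_bias < 0)))
    stop("kmer_bias must be a named vector of non-negative weights")
  if (!is.null(tfo_sequence)) {
    if (!grepl("^[AG]+$", tfo_sequence)) stop("tfo_sequence must be a purine (A/G) string")
    tts_length <- nchar(tfo_sequence)
  }
  chroms <- paste0("chrS", seq_len(n_chroms))
  chrom_length <- setNames(rep(as.integer(chrom_length), length.out = n_chroms),
                           chroms)
  for (l in lncRNAs) {
    if (!inherits(l, "lnc_spec")) stop("lncRNAs must be lnc_spec objects")
    if (!l$chrom %in% chroms) stop("lncRNA ", l$name, " on unknown chromosome")
    if (l$gene_end > chrom_length[[l$chrom]])
      stop("gene interval of ", l$name, " exceeds chromosome")
  }
  structure(list(n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
                 tile_width = as.integer(tile_width), lncRNAs = lncRNAs,
                 decay_scale = decay_scale, seed = as.integer(seed),
                 kmer_bias = kmer_bias, track_block_length = track_block_length,
                 n_repeat_families = as.integer(n_repeat_families),
                 n_mirnas = as.integer(n_mirnas), tts_fraction = tts_fraction,
                 tts_length = as.integer(tts_length),
                 tts_copies = as.integer(tts_copies),
                 tfo_sequence = tfo_sequence,
                 transcript_length = as.integer(transcript_length),
                 chroms = chroms),
            class = "synthetic_config")
}

# Emit a random DNA string of length `len` by concatenating 5-mers sampled
# with probability proportional to 1 + bias(canonical 5-mer).  An empty bias
# yields i.i.d. uniform bases.
emit_biased_seq <- function(len, kmer_bias = numeric()) {
  if (length(kmer_bias) == 0L) {
    return(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  }
  uni <- kmer_universe(5L)
  w <- rep(1, length(uni$kmers))
  hit <- match(uni$canonical, names(kmer_bias))
  w[!is.na(hit)] <- w[!is.na(hit)] + kmer_bias[hit[!is.na(hit)]]
  n5 <- ceiling(len / 5)
  picks <- sample.int(length(uni$kmers), n5, replace = TRUE, prob = w)
  substr(paste(uni$kmers[picks], collapse = ""), 1L, len)
}

#' Generate the synthetic genome, annotations and sequence resources
#'
#' Draws uniform-background chromosome sequences, places the configured
#' lncRNA genes, emits lncRNA transcripts, miRNA seed 7-mers and repeat
#' consensus sequences under the shared `kmer_bias`, plants repeat instances
#' as intervals, and -- for triplex-mechanism lncRNAs -- embeds a
#' lncRNA-specific purine triplex-forming oligo (TFO) in the transcript and
#' matching triplex target sites (TTS) in a random subset of tiles on the
#' lncRNA's chromosome.
#'
#' @param cfg a [synthetic_config()].
#' @return a `synthetic_genome` list with elements `sequences`
#'   (`DNAStringSet`), `genes` (`data.table`), `transcripts`
#'   (`DNAStringSet`), `mirna_seeds` (character 7-mers), `repeat_consensus`
#'   (`DNAStringSet`), `repeat_instances` (`data.table`), `tfo` (named
#'   character), and `tts_tiles` (named list of 0-based per-chromosome tile
#'   indices carrying a planted TTS).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- data.table::rbindlist(lapply(cfg$lncRNAs, function(l)
    data.table::data.table(name = l$name, chrom = l$chrom,
                           start = l$gene_start, end = l$gene_end,
                           mechanism = l$mechanism)))
  if (nrow(genes)) {
    ov <- genes[, {
      o <- order(start)
      s <- start[o]; e <- end[o]
      .(bad = any(s[-1] < e[-length(e)]) && .N > 1)
    }, by = chrom]
    if (any(ov$bad)) stop("overlapping gene intervals on the same chromosome")
  }
  with_seed(child_seed(cfg$seed, "genome"), {
    # chromosomes are held as character vectors until all planting is done:
    # in-place slice assignment avoids copying megabase strings per insert
    seq_chars <- lapply(cfg$chroms, function(ch)
      sample(c("A", "C", "G", "T"), cfg$chrom_length[[ch]], replace = TRUE))
    names(seq_chars) <- cfg$chroms

    # lncRNA transcripts under the shared k-mer bias
    transcripts <- vapply(cfg$lncRNAs, function(l)
      emit_biased_seq(cfg$transcript_length, cfg$kmer_bias), character(1))
    names(transcripts) <- vapply(cfg$lncRNAs, `[[`, "", "name")

    # triplex planting: lncRNA-specific purine TFO in transcript, matching
    # TTS in a random subset of tiles on the lncRNA's chromosome
    tfo <- character(0)
    tts_tiles <- lapply(cfg$chroms, function(ch) integer(0))
    names(tts_tiles) <- cfg$chroms
    for (l in cfg$lncRNAs) {
      if (l$mechanism != "triplex") next
      t_seq <- cfg$tfo_sequence %||%
        paste(sample(c("A", "G"), cfg$tts_length, replace = TRUE), collapse = "")
      tfo[l$name] <- t_seq
      pos <- sample.int(cfg$transcript_length - cfg$tts_length, 1L)
      substr(transcripts[l$name], pos, pos + cfg$tts_length - 1L) <- t_seq
      n_tiles_chrom <- cfg$chrom_length[[l$chrom]] %/% cfg$tile_width
      planted <- which(runif(n_tiles_chrom) < cfg$tts_fraction) - 1L
      tts_tiles[[l$chrom]] <- sort(unique(c(tts_tiles[[l$chrom]], planted)))
      t_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(t_seq)))
      t_chars <- strsplit(t_seq, "")[[1]]
      t_rc_chars <- strsplit(t_rc, "")[[1]]
      slot <- cfg$tile_width %/% cfg$tts_copies
      for (ti in planted) {
        for (cp in seq_len(cfg$tts_copies)) {
          off <- (cp - 1L) * slot + sample.int(slot - cfg$tts_length, 1L)
          ins <- if (runif(1) < 0.5) t_chars else t_rc_chars
          at <- ti * cfg$tile_width + off
          seq_chars[[l$chrom]][(at + 1L):(at + cfg$tts_length)] <- ins
        }
      }
    }
    seqs <- vapply(seq_chars, paste, character(1), collapse = "")

    # miRNA seeds: a biased 5-mer core extended by two uniform bases
    mirna_seeds <- vapply(seq_len(cfg$n_mirnas), function(i) {
      core <- emit_biased_seq(5L, cfg$kmer_bias)
      paste0(paste(sample(c("A", "C", "G", "T"), 1), collapse = ""), core,
             paste(sample(c("A", "C", "G", "T"), 1), collapse = ""))
    }, character(1))
    names(mirna_seeds) <- sprintf("miR%02d", seq_len(cfg$n_mirnas))

    # repeat consensus sequences and planted instance intervals
    rep_names <- sprintf("Rep%02d", seq_len(cfg$n_repeat_families))
    repeat_consensus <- vapply(rep_names, function(r)
      emit_biased_seq(300L, cfg$kmer_bias), character(1))
    inst <- data.table::rbindlist(lapply(cfg$chroms, function(ch) {
      n <- max(1L, round(cfg$chrom_length[[ch]] / 1e5))
      data.table::rbindlist(lapply(rep_names, function(r) {
        st <- sort(sample.int(cfg$chrom_length[[ch]] - 300L, n))
        data.table::data.table(chrom = ch, start = st, end = st + 300L, family = r)
      }))
    }))

    structure(list(
      sequences = Biostrings::DNAStringSet(seqs),
      genes = genes,
      transcripts = Biostrings::DNAStringSet(transcripts),
      mirna_seeds = mirna_seeds,
      repeat_consensus = Biostrings::DNAStringSet(repeat_consensus),
      repeat_instances = inst,
      tfo = tfo,
      tts_tiles = tts_tiles
    ), class = "synthetic_genome")
  })
}

#' Generate spatially autocorrelated context tracks
#'
#' Emits three piecewise-constant interval-score tracks per chromosome with
#' change-points at exponential spacing of mean `track_block_length` and
#' i.i.d. standard-normal block values: `transcription` (the label-driving
#' signal for transcription-mechanism lncRNAs) and the pair `ctx_a`/`ctx_b`
#' whose median-thresholded exclusive-or drives `xor_pair` lncRNAs.
#'
#' @param cfg a [synthetic_config()].
#' @param genome output of [generate_genome()] (used for chromosome names).
#' @return named list of `data.table`s with columns
#'   `chrom`, `start`, `end`, `score`.
#' @export
generate_context_tracks <- function(cfg, genome) {
  # block values are drawn from a small set of discrete standard-normal
  # quantile levels rather than a continuum: a continuous per-block value
  # would act as a unique positional fingerprint that a forest can memorize
  # across fold boundaries, making any track spuriously predictive
  levels8 <- stats::qnorm((1:8 - 0.5) / 8)
  with_seed(child_seed(cfg$seed, "tracks"), {
    one_track <- function() {
      data.table::rbindlist(lapply(cfg$chroms, function(ch) {
        len <- cfg$chrom_length[[ch]]
        bl <- integer(0); total <- 0
        while (total < len) {
          b <- max(1L, round(rexp(1, 1 / cfg$track_block_length)))
          bl <- c(bl, b); total <- total + b
        }
        st <- cumsum(c(0L, bl[-length(bl)]))
        en <- pmin(st + bl, len)
        data.table::data.table(chrom = ch, start = st, end = en,
                               score = sample(levels8, length(bl), replace = TRUE))
      }))
    }
    list(transcription = one_track(), ctx_a = one_track(), ctx_b = one_track())
  })
}

# Length-weighted mean track value per tile on one chromosome (0-based tile
# index), used as the generator's per-tile signal.
tile_track_mean <- function(track, chrom, n_tiles, tile_width) {
  keep <- track[["chrom"]] == chrom
  tr <- track[keep]
  out <- numeric(n_tiles)
  ir_t <- IRanges::IRanges(start = (seq_len(n_tiles) - 1L) * tile_width + 1L,
                           width = tile_width)
  ir_s <- IRanges::IRanges(start = tr$start + 1L, end = tr$end)
  hits <- IRanges::findOverlaps(ir_t, ir_s)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(ir_t[qi], ir_s[si]))
    dt <- data.table::data.table(tile = qi, v = ov * tr$score[si])
    agg <- dt[, .(s = sum(v)), by = tile]
    out[agg$tile] <- agg$s / tile_width
  }
  out
}

# Per-tile planted signal for one lncRNA, standardized over the tiles of its
# chromosome (zero vector for the noise mechanism).
planted_signal <- function(cfg, genome, tracks, l) {
  n_tiles <- cfg$chrom_length[[l$chrom]] %/% cfg$tile_width
  z <- switch(l$mechanism,
    transcription = tile_track_mean(tracks$transcription, l$chrom, n_tiles, cfg$tile_width),
    triplex = {
      ind <- numeric(n_tiles)
      ind[genome$tts_tiles[[l$chrom]] + 1L] <- 1
      ind
    },
    xor_pair = {
      a <- tile_track_mean(tracks$ctx_a, l$chrom, n_tiles, cfg$tile_width)
      b <- tile_track_mean(tracks$ctx_b, l$chrom, n_tiles, cfg$tile_width)
      as.numeric(xor(a > median(a), b > median(b)))
    },
    noise = return(numeric(n_tiles))
  )
  s <- sd(z)
  if (s == 0) return(numeric(n_tiles))
  (z - mean(z)) / s
}

#' Sample the synthetic lncRNA-chromatin interaction map
#'
#' For each lncRNA the binding probability of a cis tile is proportional to
#' `exp(-distance / decay_scale) * plogis(effect_size * signal)`, where
#' `signal` is the standardized planted mechanism signal of the tile and
#' `distance` the gap between tile and gene (0 when overlapping). Positives
#' are drawn without replacement until `n_target_positives` are obtained.
#'
#' @param cfg a [synthetic_config()].
#' @param genome output of [generate_genome()].
#' @param tracks output of [generate_context_tracks()].
#' @return an `interaction_map` (see [interaction_map()]).
#' @export
generate_interactions <- function(cfg, genome, tracks) {
  tg <- tile_genome(cfg$chrom_length, cfg$tile_width)
  bound <- list()
  with_seed(child_seed(cfg$seed, "interactions"), {
    for (l in cfg$lncRNAs) {
      ct <- tg$tiles[tg$tiles$chrom == l$chrom]
      if (l$n_target_positives > nrow(ct))
        stop("n_target_positives for ", l$name, " exceeds tiles on its chromosome")
      d <- interval_gap(ct$start, ct$end, l$gene_start, l$gene_end)
      s <- planted_signal(cfg, genome, tracks, l)
      lambda <- l$decay_scale %||% cfg$decay_scale
      w <- exp(-d / lambda) * plogis(l$effect_size * s)
      pick <- sample(ct$id, l$n_target_positives, prob = w)
      bound[[l$name]] <- sort(pick)
    }
  })
  lnc_dt <- data.table::rbindlist(lapply(cfg$lncRNAs, function(l)
    data.table::data.table(name = l$name, chrom = l$chrom,
                           gene_start = l$gene_start, gene_end = l$gene_end,
                           mechanism = l$mechanism)))
  interaction_map(lnc_dt, bound, tg, transcripts = genome$transcripts)
}

#' Write a synthetic bundle to plain-text files
#'
#' Writes genome and transcript FASTA, gene and repeat BED, bedGraph-style
#' track TSVs, the miRNA seed list and the lncRNA-tile interaction pairs.
#'
#' @param genome,tracks,imap generator outputs.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(genome, tracks, imap, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(genome$sequences, file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(genome$transcripts, file.path(dir, "transcripts.fa"))
  Biostrings::writeXStringSet(genome$repeat_consensus, file.path(dir, "repeat_consensus.fa"))
  gw <- function(dt, f) data.table::fwrite(dt, file.path(dir, f), sep = "\t", col.names = FALSE)
  gw(genome$genes[, c("chrom", "start", "end", "name")], "genes.bed")
  gw(genome$repeat_instances[, c("chrom", "start", "end", "family")], "repeats.bed")
  for (nm in names(tracks)) gw(tracks[[nm]], paste0("track_", nm, ".bedgraph"))
  writeLines(paste(names(genome$mirna_seeds), genome$mirna_seeds, sep = "\t"),
             file.path(dir, "mirna_seeds.tsv"))
  pairs <- data.table::rbindlist(lapply(names(imap$bound), function(nm)
    data.table::data.table(lncRNA = nm, tile_id = imap$bound[[nm]])))
  data.table::fwrite(pairs, file.path(dir, "interactions.tsv"), sep = "\t")
  invisible(dir)
}
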