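# Maximal candidate windows (0-based half-open) where the density of the
# target letters in every sliding `win`-window is at least `min_hits`.
# Returns the merged positions of qualifying sliding windows.
purine_windows <- function(chars, letters = c("A", "G"), win = 15L, min_hits = 14L) {
  n <- length(chars)
  if (n < win) return(data.table::data.table(start = integer(0), end = integer(0)))
  x <- as.integer(chars %in% letters)
  cs <- cumsum(x)
  cnt <- cs[win:n] - c(0L, cs)[1:(n - win + 1L)]
  pos <- which(cnt >= min_hits)  # window start, 1-based
  if (!length(pos)) return(data.table::data.table(start = integer(0), end = integer(0)))
  ir <- IRanges::reduce(IRanges::IRanges(start = pos, width = win))
  data.table::data.table(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Best approximate alignment between two candidate window strings under the
# purine Hoogsteen code (A.AT, G.GC, i.e. identity on the purine strand):
# slides one along the other and returns the longest overlap of length >= 15
# with at most one mismatch per started 15 nt, or 0.
best_match_length <- function(a, b) {
  la <- length(a); lb <- length(b)
  best <- 0L
  for (off in (-(la - 15L)):(lb - 15L)) {
    i1 <- max(1L, 1L - off); i2 <- min(la, lb - off)
    ov <- i2 - i1 + 1L
    if (ov < 15L || ov <= best) next
    mis <- a[i1:i2] != b[(i1 + off):(i2 + off)]
    cs <- cumsum(c(0L, mis))
    # longest sub-window of the overlap with <= 1 mismatch per started 15 nt
    for (s in seq_len(ov - 14L)) {
      if (ov - s + 1L <= best) break
      for (e in seq.int(ov, s + 14L)) {
        len <- e - s + 1L
        if (len <= best) break
        if (cs[e + 1L] - cs[s] <= len %/% 15L) {
          best <- len
          break
        }
      }
    }
  }
  best
}

#' Triplex formation potential between a lncRNA and a DNA tile
#'
#' A purine-motif triplex screen: triplex-forming oligo (TFO) candidates are
#' maximal windows of the lncRNA at least 15 nt long whose every 15-nt
#' sliding window is >= 90% A/G; triplex target site (TTS) candidates are
#' the analogous purine windows on either strand of the tile. A (TFO, TTS)
#' pair counts as a triplex if the two purine strings align over >= 15 nt
#' with at most one mismatch per 15 nt (Hoogsteen code A.AT / G.GC, i.e.
#' identity on the purine strand). The summary quartet is: number of
#' matching pairs, total matched length, maximum per-pair match length, and
#' fraction of the tile covered by matching TTS windows.
#'
#' @param lnc_seq lncRNA (transcript) sequence, read as DNA.
#' @param tile_seq tile DNA sequence.
#' @return numeric vector
#'   `c(triplex_pairs, triplex_total_len, triplex_max_score, triplex_tts_cov)`.
#' @export
triplex_quartet <- function(lnc_seq, tile_seq) {
  zero <- c(triplex_pairs = 0, triplex_total_len = 0,
            triplex_max_score = 0, triplex_tts_cov = 0)
  rna <- strsplit(toupper(as.character(lnc_seq)), "")[[1]]
  tfo <- purine_windows(rna)
  if (nrow(tfo) == 0L) return(zero)
  dna <- strsplit(toupper(as.character(tile_seq)), "")[[1]]
  n <- length(dna)
  fw <- purine_windows(dna)
  # purine run on the minus strand = pyrimidine run on the plus strand;
  # compare against the reverse complement so both read the purine strand
  rv <- purine_windows(dna, letters = c("C", "T"))
  tts <- rbind(
    data.table::data.table(start = fw$start, end = fw$end,
                           strand = rep("+", nrow(fw))),
    data.table::data.table(start = rv$start, end = rv$end,
                           strand = rep("-", nrow(rv))))
  if (nrow(tts) == 0L) return(zero)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_pairs <- 0L; tot <- 0L; mx <- 0L
  cov <- logical(n)
  for (i in seq_len(nrow(tfo))) {
    a <- rna[(tfo$start[i] + 1L):tfo$end[i]]
    for (j in seq_len(nrow(tts))) {
      b <- dna[(tts$start[j] + 1L):tts$end[j]]
      if (tts$strand[j] == "-") b <- rev(unname(comp[b]))
      m <- best_match_length(a, b)
      if (m >= 15L) {
        n_pairs <- n_pairs + 1L
        tot <- tot + m
        mx <- max(mx, m)
        cov[(tts$start[j] + 1L):tts$end[j]] <- TRUE
      }
    }
  }
  c(triplex_pairs = n_pairs, triplex_total_len = tot,
    triplex_max_score = mx, triplex_tts_cov = sum(cov) / n)
}

#' Triplex features for a set of tiles
#'
#' Either computes the builtin purine-motif quartet per tile
#' ([triplex_quartet()]) or echoes a precomputed per-(lncRNA, tile) table
#' from an external triplex tool.
#'
#' @param lnc_seq lncRNA transcript sequence (builtin provider).
#' @param tile_seqs `DNAStringSet` or character vector of tile sequences,
#'   named or indexed by tile id.
#' @param provider `"builtin"` or `"external"`.
#' @param external_table for `provider = "external"`: `data.frame` with a
#'   `tile_id` column and the four quartet columns; missing tiles yield
#'   zeros with a warning.
#' @param tile_ids tile ids aligned with `tile_seqs` (used for the external
#'   lookup and as rownames).
#' @return numeric matrix, tiles x 4 quartet columns.
#' @export
triplex_features <- function(lnc_seq = NULL, tile_seqs = NULL,
                             provider = c("builtin", "external"),
                             external_table = NULL, tile_ids = NULL) {
  provider <- match.arg(provider)
  cols <- c("triplex_pairs", "triplex_total_len", "triplex_max_score", "triplex_tts_cov")
  if (provider == "external") {
    if (is.null(external_table) || is.null(tile_ids))
      stop("external provider needs external_table and tile_ids")
    out <- matrix(0, nrow = length(tile_ids), ncol = 4L,
                  dimnames = list(tile_ids, cols))
    m <- match(tile_ids, external_table$tile_id)
    if (anyNA(m)) warning(sum(is.na(m)), " tile(s) missing from external triplex table; zeros used")
    ok <- !is.na(m)
    out[ok, ] <- as.matrix(external_table[m[ok], cols])
    return(out)
  }
  if (is.character(tile_seqs)) tile_seqs <- Biostrings::DNAStringSet(tile_seqs)
  # precompute TFO windows once: triplex_quartet re-derives them cheaply,
  # but skip tiles without any candidate purine window for speed
  tile_chr <- as.character(tile_seqs)
  out <- t(vapply(tile_chr, function(s) triplex_quartet(lnc_seq, s), numeric(4)))
  rownames(out) <- if (!is.null(tile_ids)) tile_ids else names(tile_seqs)
  colnames(out) <- cols
  out
}
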