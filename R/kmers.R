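#' Canonical k-mer universe
#'
#' Enumerates all `4^k` k-mers and their canonical forms, where the
#' canonical form of a k-mer is the lexicographic minimum (A<C<G<T) of the
#' k-mer and its reverse complement. For odd `k` no k-mer is its own
#' reverse complement, so there are exactly `4^k / 2` canonical k-mers
#' (512 for k = 5).
#'
#' @param k word size; must be odd.
#' @return list with `kmers` (all `4^k` words, Biostrings order),
#'   `canonical` (canonical form of each word) and `levels` (sorted unique
#'   canonical k-mers).
#' @export
kmer_universe <- function(k = 5L) {
  if (k %% 2L == 0L) stop("k must be odd (palindromic k-mers are ambiguous)")
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canonical <- ifelse(kmers <= rc, kmers, rc)
  list(kmers = kmers, canonical = canonical, levels = sort(unique(canonical)))
}

#' Count canonical k-mers in DNA sequences
#'
#' Counts every length-`k` window of each sequence under its canonical form
#' (lexicographic min of the word and its reverse complement), so the count
#' vector is strand-invariant. Windows containing non-ACGT letters are
#' skipped. Sequences shorter than `k` yield a zero vector with a warning.
#'
#' @param seqs character vector or `DNAStringSet`.
#' @param k odd word size (default 5).
#' @return integer matrix, `length(seqs)` rows x `4^k/2` canonical-k-mer
#'   columns (sorted canonical order).
#' @examples
#' count_canonical_kmers("AAAAA")[ , "AAAAA"]  # 1
#' @export
count_canonical_kmers <- function(seqs, k = 5L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (inherits(seqs, "XString")) seqs <- Biostrings::DNAStringSet(list(seqs))
  uni <- kmer_universe(k)
  if (any(Biostrings::width(seqs) < k))
    warning("sequence(s) shorter than k: zero counts emitted")
  raw <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  grp <- factor(uni$canonical, levels = uni$levels)
  out <- t(rowsum(t(raw), grp))
  storage.mode(out) <- "integer"
  rownames(out) <- names(seqs)
  out[, uni$levels, drop = FALSE]
}

#' Extract canonical 5-mers constituting a miRNA seed
#'
#' All overlapping 5-mers of the seed, canonicalized and deduplicated.
#'
#' @param seed a seed sequence (typically a 7-mer).
#' @param k word size (default 5).
#' @return character vector of canonical k-mers (empty if the seed has no
#'   valid ACGT k-mer window).
#' @export
seed_kmers <- function(seed, k = 5L) {
  seed <- toupper(gsub("U", "T", seed))
  n <- nchar(seed) - k + 1L
  if (n < 1L) return(character(0))
  words <- substring(seed, seq_len(n), seq_len(n) + k - 1L)
  words <- words[grepl("^[ACGT]+$", words)]
  if (!length(words)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  unique(ifelse(words <= rc, words, rc))
}
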