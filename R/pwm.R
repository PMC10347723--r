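#' Construct a position weight matrix
#'
#' Stores per-position base probabilities with a pseudocount and background,
#' and precomputes an integer-quantized log-odds score matrix (bin width
#' `delta` log-odds units) used by the exact threshold computation and the
#' scanner, so that scan hit probabilities match the dynamic-programming
#' score distribution exactly.
#'
#' @param name protein/motif identifier.
#' @param prob matrix of base probabilities, positions x 4 (columns
#'   A, C, G, T); rows are renormalized after adding `pseudocount`.
#' @param background background base frequencies (default uniform).
#' @param pseudocount probability added to every entry before log-odds
#'   (default 0.001).
#' @param delta score quantization bin in log-odds units (default 0.005).
#' @return a `pwm` object.
#' @export
pwm <- function(name, prob, background = rep(0.25, 4), pseudocount = 0.001,
                delta = 0.005) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4L) stop("prob must have 4 columns (A, C, G, T)")
  if (any(prob < 0)) stop("negative probabilities")
  background <- background / sum(background)
  p <- prob + pseudocount
  p <- p / rowSums(p)
  lo <- log(sweep(p, 2L, background, "/"))
  s_int <- round(lo / delta)
  storage.mode(s_int) <- "integer"
  colnames(p) <- colnames(s_int) <- c("A", "C", "G", "T")
  structure(list(name = name, prob = p, background = background,
                 pseudocount = pseudocount, delta = delta, score_int = s_int),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$name, "- length", nrow(x$prob), "\n")
  invisible(x)
}

#' Exact score threshold for a PWM p-value
#'
#' Computes the full distribution of the quantized log-odds score of a
#' random i.i.d. background sequence by dynamic programming (convolution
#' position by position) and returns the smallest score `s*` with
#' `P(score >= s* | background) <= pval`.
#'
#' @param x a [pwm()].
#' @param pval motif-hit p-value (default 1e-4).
#' @return list with `threshold` (log-odds units), `threshold_int`
#'   (quantized), and `attained_pval` (= `P(score >= s*)`).
#' @export
pwm_threshold <- function(x, pval = 1e-4) {
  stopifnot(inherits(x, "pwm"))
  if (pval <= 0 || pval >= 1) stop("pval must lie in (0, 1)")
  s <- x$score_int
  row_min <- apply(s, 1L, min); row_max <- apply(s, 1L, max)
  amin <- min(0L, cumsum(row_min)); amax <- max(0L, cumsum(row_max))
  dist <- numeric(amax - amin + 1L)  # index = score - amin + 1
  cmin <- 0L; cmax <- 0L             # running support bounds
  dist[0L - amin + 1L] <- 1
  for (j in seq_len(nrow(s))) {
    new <- numeric(length(dist))
    for (b in 1:4) {
      sh <- s[j, b]
      idx <- (cmin:cmax) - amin + 1L
      new[idx + sh] <- new[idx + sh] + dist[idx] * x$background[b]
    }
    cmin <- cmin + row_min[j]; cmax <- cmax + row_max[j]
    dist <- new
  }
  lo_min <- sum(row_min); lo_max <- sum(row_max)
  keep <- (lo_min - amin + 1L):(lo_max - amin + 1L)
  dist <- dist[keep]
  tail_p <- rev(cumsum(rev(dist)))
  scores <- lo_min:lo_max
  ok <- which(tail_p <= pval)
  if (!length(ok)) {  # pval below the most extreme attainable tail
    t_int <- lo_max + 1L
    att <- 0
  } else {
    t_int <- scores[ok[1L]]
    att <- tail_p[ok[1L]]
  }
  list(threshold = t_int * x$delta, threshold_int = as.integer(t_int),
       attained_pval = att)
}

# Encode a DNA string as integer base codes 1..4 (A, C, G, T); other
# letters become NA and poison any window containing them.
encode_dna <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  match(v, c("A", "C", "G", "T"))
}

#' Scan a sequence with one PWM on both strands
#'
#' Scores every offset with the quantized log-odds matrix on the forward
#' strand and with its reverse complement on the reverse strand; windows
#' containing non-ACGT letters never hit.
#'
#' @param seq DNA string.
#' @param x a [pwm()].
#' @param threshold_int quantized score threshold (from [pwm_threshold()]).
#' @return `data.table` of hits: `start` (0-based), `end`, `strand`,
#'   `score` (log-odds units).
#' @export
scan_pwm <- function(seq, x, threshold_int) {
  code <- encode_dna(seq)
  L <- nrow(x$score_int)
  n <- length(code) - L + 1L
  if (n < 1L)
    return(data.table::data.table(start = integer(0), end = integer(0),
                                  strand = character(0), score = numeric(0)))
  score_with <- function(m) {
    tot <- numeric(n)
    for (j in seq_len(L)) {
      sj <- m[j, ][code[j:(j + n - 1L)]]
      tot <- tot + sj
    }
    tot
  }
  # reverse strand: complement bases and reverse positions, hits reported
  # on forward coordinates
  m_rc <- x$score_int[rev(seq_len(L)), c(4L, 3L, 2L, 1L), drop = FALSE]
  res <- list()
  for (str in c("+", "-")) {
    sc <- if (str == "+") score_with(x$score_int) else score_with(m_rc)
    hit <- which(!is.na(sc) & sc >= threshold_int)
    if (length(hit))
      res[[str]] <- data.table::data.table(start = hit - 1L, end = hit - 1L + L,
                                           strand = str,
                                           score = sc[hit] * x$delta)
  }
  if (!length(res))
    return(data.table::data.table(start = integer(0), end = integer(0),
                                  strand = character(0), score = numeric(0)))
  data.table::rbindlist(res)
}

#' Merged motif-hit count for one protein
#'
#' Scans the sequence with every PWM of the protein (both strands), keeps
#' hits passing each PWM's own threshold, pools hits across PWMs and merges
#' intervals that overlap or are separated by at most `merge_gap` bp; the
#' feature value is the number of merged intervals.
#'
#' @param seq DNA string (for RBPs, the putative transcript read as DNA).
#' @param pwms list of [pwm()] objects for one protein.
#' @param pval per-PWM hit p-value (default 1e-4).
#' @param merge_gap maximum gap merged (default 1 bp).
#' @param thresholds optional precomputed list of [pwm_threshold()] results
#'   aligned with `pwms`.
#' @return integer merged-interval count.
#' @export
scan_and_merge <- function(seq, pwms, pval = 1e-4, merge_gap = 1L,
                           thresholds = NULL) {
  if (!length(pwms)) return(0L)
  if (is.null(thresholds)) thresholds <- lapply(pwms, pwm_threshold, pval = pval)
  hits <- data.table::rbindlist(lapply(seq_along(pwms), function(i)
    scan_pwm(seq, pwms[[i]], thresholds[[i]]$threshold_int)))
  if (nrow(hits) == 0L) return(0L)
  ir <- IRanges::IRanges(start = hits$start + 1L, end = hits$end)
  length(IRanges::reduce(ir, min.gapwidth = merge_gap + 1L))
}

#' Read PWMs from a JASPAR-style PFM file
#'
#' Parses records of the form `>ID name` followed by four base rows
#' (`A [ 1 2 3 ]` or bare numbers in A, C, G, T order); counts are
#' normalized per position.
#'
#' @param path PFM text file.
#' @inheritParams pwm
#' @return named list of [pwm()] objects.
#' @export
read_jaspar_pfm <- function(path, background = rep(0.25, 4), pseudocount = 0.001) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  idx <- grep("^>", lines)
  if (!length(idx)) stop("no '>' records found in ", path)
  out <- list()
  for (i in seq_along(idx)) {
    hdr <- sub("^>\\s*", "", lines[idx[i]])
    nm <- strsplit(hdr, "\\s+")[[1]]
    nm <- if (length(nm) > 1L) nm[2L] else nm[1L]
    to <- if (i < length(idx)) idx[i + 1L] - 1L else length(lines)
    rows <- lines[(idx[i] + 1L):to][1:4]
    num <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", r)
      as.numeric(strsplit(trimws(gsub("[\\[\\]]", " ", r, perl = TRUE)), "\\s+")[[1]])
    })
    counts <- do.call(cbind, num)  # positions x 4
    prob <- counts / rowSums(counts)
    out[[nm]] <- pwm(nm, prob, background = background, pseudocount = pseudocount)
  }
  out
}

#' Read PWMs from a MEME minimal-format file
#'
#' @param path MEME minimal motif file.
#' @inheritParams pwm
#' @return named list of [pwm()] objects.
#' @export
read_meme <- function(path, pseudocount = 0.001) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) && bgl[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1L]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tok))
    if (sum(!is.na(v)) == 4L) bg <- v[!is.na(v)]
  }
  idx <- grep("^MOTIF", lines)
  out <- list()
  for (i in seq_along(idx)) {
    nm <- strsplit(trimws(lines[idx[i]]), "\\s+")[[1]][2L]
    mh <- grep("^letter-probability matrix", lines[idx[i]:length(lines)])[1L] + idx[i] - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mh]))
    rows <- lines[(mh + 1L):(mh + w)]
    prob <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])))
    out[[nm]] <- pwm(nm, prob, background = bg, pseudocount = pseudocount)
  }
  out
}
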