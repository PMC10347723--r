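#' Signed two-sample Kolmogorov-Smirnov statistic
#'
#' Computes `D_signed = F_unbound(x*) - F_bound(x*)` where `x*` maximizes
#' the absolute ECDF difference over the pooled support (ties resolved
#' towards the smallest `x`). `|D_signed|` equals the classical two-sample
#' KS statistic; a positive value means the bound sample is stochastically
#' larger, i.e. the feature is enriched in bound tiles (swap the sign
#' convention with `positive_is_bound = FALSE`). The p-value is the
#' two-sided asymptotic KS tail probability of `|D_signed|`.
#'
#' @param bound,unbound numeric samples (non-empty).
#' @param positive_is_bound if `TRUE` (default) positive values indicate
#'   enrichment in the bound sample.
#' @return list with `d_signed`, `p_value`, `x_star`.
#' @export
signed_ks <- function(bound, unbound, positive_is_bound = TRUE) {
  if (!length(bound) || !length(unbound)) stop("both samples must be non-empty")
  xs <- sort(unique(c(bound, unbound)))
  fb <- vapply(xs, function(x) mean(bound <= x), numeric(1))
  fu <- vapply(xs, function(x) mean(unbound <= x), numeric(1))
  delta <- fu - fb
  i <- which.max(abs(delta))  # first maximum = smallest x on the sorted grid
  d <- delta[i]
  if (!positive_is_bound) d <- -d
  n_eff <- length(bound) * length(unbound) / (length(bound) + length(unbound))
  lambda <- sqrt(n_eff) * abs(d)
  p <- if (lambda < 1e-12) 1 else {
    k <- 1:100
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  list(d_signed = d, p_value = p, x_star = xs[i])
}

#' Bound-versus-unbound enrichment battery
#'
#' For every requested feature and lncRNA, compares the feature values of
#' bound (positive) tiles against the sampled unbound (negative) tiles with
#' the signed KS statistic, then applies Benjamini-Hochberg adjustment
#' across the whole battery. Constant features yield `D = 0`, `p = 1` and
#' are flagged.
#'
#' @param X feature matrix (rownames = tile ids).
#' @param datasets named list of [build_labeled_dataset()] results (one
#'   per lncRNA); matrices may differ per lncRNA, in which case pass a
#'   named list of matrices as `X`.
#' @param features feature (column) names to test.
#' @return `data.table` with `lncRNA`, `feature`, `d_signed`, `p_value`,
#'   `p_adj`, `constant`.
#' @export
enrichment_battery <- function(X, datasets, features) {
  rows <- list()
  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    Xl <- if (is.list(X) && !is.matrix(X)) X[[nm]] else X
    bi <- match(as.character(ds$positives), rownames(Xl))
    ui <- match(as.character(ds$negatives), rownames(Xl))
    if (anyNA(bi) || anyNA(ui)) stop("dataset tiles missing from feature matrix")
    for (f in features) {
      vb <- Xl[bi, f]; vu <- Xl[ui, f]
      if (length(unique(c(vb, vu))) == 1L) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          lncRNA = nm, feature = f, d_signed = 0, p_value = 1, constant = TRUE)
      } else {
        ks <- signed_ks(vb, vu)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          lncRNA = nm, feature = f, d_signed = ks$d_signed,
          p_value = ks$p_value, constant = FALSE)
      }
    }
  }
  out <- data.table::rbindlist(rows)
  out[, p_adj := p.adjust(p_value, method = "BH")]
  out[]
}

#' Pooled group comparison of a feature between lncRNA groups
#'
#' Pools the bound tiles of each group of lncRNAs (e.g. TA vs non-TA) and
#' compares the feature values between the two pools with the signed KS
#' statistic (positive = enriched in group A).
#'
#' @param X feature matrix (or named list of matrices per lncRNA).
#' @param datasets named list of labeled datasets.
#' @param group_a,group_b lncRNA names of the two groups.
#' @param feature feature name.
#' @return a [signed_ks()] result.
#' @export
group_enrichment <- function(X, datasets, group_a, group_b, feature) {
  pool <- function(g) unlist(lapply(g, function(nm) {
    Xl <- if (is.list(X) && !is.matrix(X)) X[[nm]] else X
    Xl[match(as.character(datasets[[nm]]$positives), rownames(Xl)), feature]
  }))
  signed_ks(pool(group_a), pool(group_b))
}

#' Correlation between 5-mer importance ranks and sequence density
#'
#' Spearman correlation (midranks) between a 5-mer's importance rank
#' (1 = most important, from [aggregate_feature_ranks()]) and its density
#' in a sequence source: counts in the lncRNA transcript, the number of
#' miRNA seeds containing the 5-mer, or mean density over repeat consensus
#' sequences. Important and dense therefore shows as a negative
#' correlation.
#'
#' @param rank_table [aggregate_feature_ranks()] output restricted to the
#'   512 canonical 5-mers (other features are ignored).
#' @param density named numeric vector over canonical 5-mers.
#' @return list with `rho`, `p_value`, `n`.
#' @export
kmer_density_correlation <- function(rank_table, density) {
  uni <- kmer_universe(5L)
  rt <- rank_table[rank_table$feature %in% uni$levels]
  if (nrow(rt) == 0L) stop("no 5-mer features in the rank table")
  d <- density[rt$feature]
  if (anyNA(d)) stop("density missing for some 5-mers")
  if (sd(d) == 0) return(list(rho = NA_real_, p_value = NA_real_, n = nrow(rt)))
  ct <- suppressWarnings(stats::cor.test(rt$median_rank, d, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(rt))
}

#' Per-5-mer density of a set of sequences
#'
#' @param seqs character vector or `DNAStringSet`.
#' @param average divide summed counts by the number of sequences.
#' @return named numeric vector over the 512 canonical 5-mers.
#' @export
kmer_density <- function(seqs, average = FALSE) {
  m <- count_canonical_kmers(seqs)
  v <- colSums(m)
  if (average) v <- v / nrow(m)
  v
}

#' Number of miRNA seeds containing each canonical 5-mer
#'
#' @param seeds character vector of seed sequences (typically 7-mers).
#' @return named integer vector over the 512 canonical 5-mers.
#' @export
seed_membership_density <- function(seeds) {
  uni <- kmer_universe(5L)
  out <- setNames(integer(length(uni$levels)), uni$levels)
  for (s in seeds) {
    ks <- seed_kmers(s)
    out[ks] <- out[ks] + 1L
  }
  out
}

#' lncRNA x miRNA seed enrichment matrix
#'
#' For every (lncRNA, miRNA) pair: the signed KS statistic of the summed
#' per-tile count of the seed's constituent canonical 5-mers, bound versus
#' unbound tiles. Rows and columns are ordered by average-linkage
#' hierarchical clustering on Euclidean distance. Seeds without a valid
#' 5-mer are dropped with a warning.
#'
#' @param X feature matrix containing the 512 canonical 5-mer columns (or
#'   named list of such matrices per lncRNA).
#' @param datasets named list of labeled datasets.
#' @param seeds named character vector of miRNA seeds.
#' @return list with `matrix` (reordered), `row_order`, `col_order`.
#' @export
seed_enrichment_matrix <- function(X, datasets, seeds) {
  kmer_sets <- lapply(seeds, seed_kmers)
  bad <- lengths(kmer_sets) == 0L
  if (any(bad)) {
    warning("dropping seed(s) without valid 5-mers: ",
            paste(names(seeds)[bad], collapse = ", "))
    kmer_sets <- kmer_sets[!bad]
  }
  if (!length(kmer_sets)) stop("no usable seeds")
  lncs <- names(datasets)
  M <- matrix(0, nrow = length(lncs), ncol = length(kmer_sets),
              dimnames = list(lncs, names(kmer_sets)))
  for (nm in lncs) {
    ds <- datasets[[nm]]
    Xl <- if (is.list(X) && !is.matrix(X)) X[[nm]] else X
    bi <- match(as.character(ds$positives), rownames(Xl))
    ui <- match(as.character(ds$negatives), rownames(Xl))
    for (j in seq_along(kmer_sets)) {
      cols <- kmer_sets[[j]]
      vb <- rowSums(Xl[bi, cols, drop = FALSE])
      vu <- rowSums(Xl[ui, cols, drop = FALSE])
      if (length(unique(c(vb, vu))) > 1L)
        M[nm, j] <- signed_ks(vb, vu)$d_signed
    }
  }
  ro <- if (nrow(M) > 2L) hclust(dist(M), method = "average")$order else seq_len(nrow(M))
  co <- if (ncol(M) > 2L) hclust(dist(t(M)), method = "average")$order else seq_len(ncol(M))
  list(matrix = M[ro, co, drop = FALSE], row_order = rownames(M)[ro],
       col_order = colnames(M)[co])
}
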