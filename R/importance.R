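# Fold-level AUROC lookup table for one model set, keyed by family subset.
model_fold_table <- function(results, set) {
  keep <- results$table[["set"]] == set
  tab <- results$table[keep]
  if (nrow(tab) == 0L) stop("no models of set ", set, " in results")
  tab
}

# Fold-averaged AUROC difference between model U and model U \ {A}; the
# empty primary subset is the featureless chance model with AUROC 0.5.
pair_difference <- function(tab, key_u, key_base, K) {
  mu <- tab[tab$subset == key_u]
  if (nrow(mu) == 0L) stop("model ", key_u, " missing (ensemble incomplete)")
  if (identical(key_base, "__chance__")) {
    return(mean(mu$auroc - 0.5, na.rm = TRUE))
  }
  mb <- tab[tab$subset == key_base]
  if (nrow(mb) == 0L) stop("model ", key_base, " missing (ensemble incomplete)")
  m <- merge(mu[, c("fold", "auroc")], mb[, c("fold", "auroc")], by = "fold",
             suffixes = c("_u", "_b"))
  ok <- !is.na(m$auroc_u) & !is.na(m$auroc_b)
  if (!any(ok)) return(NA_real_)
  mean(m$auroc_u[ok] - m$auroc_b[ok])
}

# Enumerate the (U, U - A) pairs of family `fam` within its category's
# model set.  For `sequence_only`, U - A = empty set maps to the chance
# baseline; for `seq_context`, the empty secondary subset is the PC-only
# model (which is part of the 2^m set).
family_pairs <- function(families, fam, set) {
  others <- setdiff(families, fam)
  bs <- do.call(c, lapply(0:length(others), function(k)
    combn(others, k, simplify = FALSE)))
  lapply(bs, function(b) {
    key_u <- subset_key(c(fam, b))
    key_base <- if (length(b)) subset_key(b)
                else if (set == "sequence_only") "__chance__"
                else subset_key(character(0))
    list(key_u = key_u, key_base = key_base)
  })
}

#' Marginal Predictive Value of a feature family
#'
#' `V_i = (1 / 2^(n-1)) * sum over U in E_i of (1/K) * sum over folds of
#' M_k(U) - M_k(U - A_i)`: the mean, over every model `U` of the family's
#' category set that contains family `A_i`, of the fold-averaged block-CV
#' AUROC drop caused by removing the family. For a primary family the
#' baseline of the single-family model is the featureless chance model
#' (AUROC 0.5); for a secondary family the empty-context baseline is the
#' trained PC-only model.
#'
#' @param results a [run_model_ensemble()] result containing the complete
#'   model set of the family's category.
#' @param fam family name.
#' @param category `"primary"` or `"secondary"`.
#' @param schema the [family_schema()] used to train the ensemble.
#' @return the MPV (numeric scalar).
#' @export
mpv <- function(results, fam, category, schema) {
  set <- if (category == "primary") "sequence_only" else "seq_context"
  fams <- schema_families(schema, category)
  if (!fam %in% fams) stop("family ", fam, " not in category ", category)
  tab <- model_fold_table(results, set)
  prs <- family_pairs(fams, fam, set)
  mean(vapply(prs, function(p)
    pair_difference(tab, p$key_u, p$key_base, results$K), numeric(1)))
}

#' Maximal Predictive Value of a feature family
#'
#' The maximum (rather than mean) fold-averaged AUROC gain over all models
#' containing the family; by construction `MxPV >= MPV`.
#'
#' @inheritParams mpv
#' @return the MxPV (numeric scalar).
#' @export
mxpv <- function(results, fam, category, schema) {
  set <- if (category == "primary") "sequence_only" else "seq_context"
  fams <- schema_families(schema, category)
  if (!fam %in% fams) stop("family ", fam, " not in category ", category)
  tab <- model_fold_table(results, set)
  prs <- family_pairs(fams, fam, set)
  max(vapply(prs, function(p)
    pair_difference(tab, p$key_u, p$key_base, results$K), numeric(1)))
}

#' MPV/MxPV table for all families of a schema
#'
#' @param results a [run_model_ensemble()] result with both model sets.
#' @param schema the [family_schema()].
#' @param lnc lncRNA name recorded in the output.
#' @return `data.table` with `lncRNA`, `family`, `category`, `mpv`, `mxpv`.
#' @export
mpv_table <- function(results, schema, lnc = "lncRNA") {
  fc <- unique(data.table::data.table(family = schema$family,
                                      category = schema$category))
  data.table::rbindlist(lapply(seq_len(nrow(fc)), function(i)
    data.table::data.table(
      lncRNA = lnc, family = fc$family[i], category = fc$category[i],
      mpv = mpv(results, fc$family[i], fc$category[i], schema),
      mxpv = mxpv(results, fc$family[i], fc$category[i], schema))))
}

#' Complementarity score of a family pair
#'
#' Trains three dedicated raw-feature models -- each family alone and the
#' pair -- and returns the mean block-CV AUROC of the pair model minus the
#' better single-family mean AUROC. Pairs may cross the primary/secondary
#' boundary. A clearly positive score indicates information neither family
#' carries alone (e.g. an exclusive-or relationship).
#'
#' @param X,schema,partition as in [run_model_ensemble()].
#' @param fam_a,fam_b the two family names.
#' @param trees,seed forest parameters.
#' @param lnc lncRNA label.
#' @return list with `score`, `auroc_a`, `auroc_b`, `auroc_pair`.
#' @export
complementarity <- function(X, schema, partition, fam_a, fam_b,
                            trees = 1000L, seed = 1L, lnc = "lncRNA") {
  mk <- function(fams) list(lncRNA = lnc, set = "pair", families = fams,
                            representation = "raw", key = subset_key(fams),
                            id = paste0("pair:", subset_key(fams)))
  specs <- list(mk(fam_a), mk(fam_b), mk(c(fam_a, fam_b)))
  r <- run_model_ensemble(X, schema, partition, specs, trees = trees, seed = seed)
  m <- r$table[, .(mean_auroc = mean(auroc, na.rm = TRUE)), by = subset]
  a <- m$mean_auroc[m$subset == subset_key(fam_a)]
  b <- m$mean_auroc[m$subset == subset_key(fam_b)]
  ab <- m$mean_auroc[m$subset == subset_key(c(fam_a, fam_b))]
  list(score = ab - max(a, b), auroc_a = a, auroc_b = b, auroc_pair = ab)
}

#' Aggregate per-feature importance ranks over the best models
#'
#' Restricts to the models of one set whose mean cross-validation AUROC
#' lies in the top `percentile` percent, ranks the features of each such
#' model by decreasing Gini importance (fold-averaged; ties get the
#' average rank), and reports each feature's median rank across the
#' selected models. Features absent from every selected model get no rank.
#'
#' @param results a [run_model_ensemble()] result.
#' @param percentile the top percentile of models retained (default 20).
#' @param set `"sequence_only"` (sequence-feature ranks) or `"seq_context"`
#'   (context-feature ranks).
#' @return `data.table` with `feature`, `median_rank`, `n_models`.
#' @export
aggregate_feature_ranks <- function(results, percentile = 20, set = "sequence_only") {
  tab <- model_fold_table(results, set)
  means <- tab[, .(mean_auroc = mean(auroc, na.rm = TRUE)), by = spec_id]
  cut <- quantile(means$mean_auroc, 1 - percentile / 100, names = FALSE)
  sel <- means$spec_id[means$mean_auroc >= cut]
  if (!length(sel)) stop("percentile selects zero models")
  ranks <- list()
  for (sid in sel) {
    folds <- results$importance[[sid]]
    folds <- folds[!vapply(folds, is.null, TRUE)]
    im <- Reduce(`+`, folds) / length(folds)
    rk <- rank(-im, ties.method = "average")
    ranks[[sid]] <- data.table::data.table(feature = names(rk), rank = rk)
  }
  all <- data.table::rbindlist(ranks)
  out <- all[, .(median_rank = median(rank), n_models = .N), by = feature]
  data.table::setorder(out, median_rank)
  out[]
}

#' Transcription-associated (TA) lncRNA calls
#'
#' A lncRNA is called TA when its Transcription-family MPV is at least
#' `threshold` (inclusive). Optionally compares the MPVs of another family
#' between the TA and non-TA groups with a one-sided Mann-Whitney test
#' (exact for small groups, normal approximation with tie correction
#' otherwise, as implemented by [stats::wilcox.test()]).
#'
#' @param mpvs a [mpv_table()]-style `data.table` for several lncRNAs.
#' @param family the family defining the call (default `"transcription"`).
#' @param threshold MPV threshold (default 0.01).
#' @param test_family optional family whose MPVs are compared between
#'   groups (alternative: greater in the non-TA group by default).
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `labels` (`data.table` `lncRNA`, `mpv`, `ta`) and
#'   `test` (`htest` or `NULL` when a group is empty).
#' @export
classify_ta <- function(mpvs, family = "transcription", threshold = 0.01,
                        test_family = NULL, alternative = "greater") {
  keep <- mpvs[["family"]] == family
  sub <- mpvs[keep]
  labels <- data.table::data.table(lncRNA = sub$lncRNA, mpv = sub$mpv,
                                   ta = sub$mpv >= threshold)
  test <- NULL
  if (!is.null(test_family) && length(unique(labels$ta)) == 2L) {
    keep_tf <- mpvs[["family"]] == test_family
    tf <- mpvs[keep_tf]
    g <- labels$ta[match(tf$lncRNA, labels$lncRNA)]
    test <- suppressWarnings(
      wilcox.test(tf$mpv[!g], tf$mpv[g], alternative = alternative))
  }
  list(labels = labels, test = test)
}
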