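#' Canonical key of a family subset
#' @param families character vector (possibly empty).
#' @return single string, families sorted and joined by `+` (empty subset:
#'   `"(none)"`).
#' @export
subset_key <- function(families) {
  if (!length(families)) "(none)" else paste(sort(families), collapse = "+")
}

#' Enumerate the model specifications for one lncRNA
#'
#' With `n` primary and `m` secondary families this yields the
#' `2^n - 1` "sequence-only" models (every non-empty primary subset, raw
#' representation) and the `2^m` "sequence + context" models (every
#' secondary subset including the empty one, each on top of the primary
#' principal-component block). For the canonical 5 + 5 schema that is 31
#' and 32 models.
#'
#' @param schema a [family_schema()].
#' @param lnc lncRNA name carried on each spec.
#' @return list of `model_spec` lists with fields `lncRNA`, `set`
#'   (`"sequence_only"` / `"seq_context"`), `families`, `representation`,
#'   `key`, `id`.
#' @export
enumerate_model_specs <- function(schema, lnc = "lncRNA") {
  prim <- schema_families(schema, "primary")
  sec <- schema_families(schema, "secondary")
  subsets <- function(x) {
    do.call(c, lapply(0:length(x), function(k)
      combn(x, k, simplify = FALSE)))
  }
  specs <- list()
  for (s in subsets(prim)) {
    if (!length(s)) next
    specs[[length(specs) + 1L]] <- list(
      lncRNA = lnc, set = "sequence_only", families = s,
      representation = "raw", key = subset_key(s),
      id = paste0("seq:", subset_key(s)))
  }
  for (s in subsets(sec)) {
    specs[[length(specs) + 1L]] <- list(
      lncRNA = lnc, set = "seq_context", families = s,
      representation = "sequence_PC", key = subset_key(s),
      id = paste0("ctx:", subset_key(s)))
  }
  specs
}

#' Principal-component representation of the sequence features
#'
#' Centers and unit-scales the primary feature columns (constant columns
#' dropped), fits the rotation on `fit_rows` (by default the training fold,
#' avoiding test leakage; pass all rows for the fit-on-everything variant)
#' and applies it to all rows. If `n_pc` exceeds the rank of the fitted
#' data it is reduced with a warning.
#'
#' @param X numeric matrix of primary features (all rows).
#' @param n_pc number of components (default 100).
#' @param fit_rows integer row indices used to fit the rotation (default
#'   all rows).
#' @return numeric score matrix, `nrow(X)` x `<= n_pc`, columns `PC1`, ...
#' @export
sequence_pca <- function(X, n_pc = 100L, fit_rows = seq_len(nrow(X))) {
  Xf <- X[fit_rows, , drop = FALSE]
  keep <- which(apply(Xf, 2L, sd) > 0)
  if (!length(keep)) stop("all primary columns constant on the fitted rows")
  pc <- prcomp(Xf[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  rank <- sum(pc$sdev > 1e-9)
  if (n_pc > rank) {
    warning("n_pc reduced to the rank of the fitted data (", rank, ")")
    n_pc <- rank
  }
  ctr <- pc$center; scl <- pc$scale
  S <- sweep(sweep(X[, keep, drop = FALSE], 2L, ctr), 2L, scl, "/") %*%
    pc$rotation[, seq_len(n_pc), drop = FALSE]
  colnames(S) <- paste0("PC", seq_len(n_pc))
  S
}

#' Area under the ROC curve (midrank Mann-Whitney)
#'
#' Tied scores receive half credit, so the value equals exhaustive
#' pair-counting over all positive x negative pairs.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 (or logical) class labels.
#' @return AUROC in `[0, 1]` (`NA` if a class is absent).
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (step interpolation)
#'
#' @inheritParams auroc
#' @return AUPR (`NA` if no positives).
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  if (np == 0L) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied score
  tp <- tp[last]; fp <- fp[last]
  rec <- tp / np
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

# Upsample the minority class of a 0/1 label vector to 1:1 by sampling row
# indices with replacement; returns the augmented index vector.
upsample_idx <- function(labels) {
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  if (length(i1) == length(i0)) return(seq_along(labels))
  if (length(i1) < length(i0)) {
    extra <- sample(i1, length(i0) - length(i1), replace = TRUE)
  } else {
    extra <- sample(i0, length(i1) - length(i0), replace = TRUE)
  }
  c(seq_along(labels), extra)
}

#' Train and evaluate the model ensemble over cross-validation folds
#'
#' For every fold: the primary-feature principal components are fitted
#' (once per fold, on the training split by default), the minority class of
#' the training split is upsampled to 1:1, and one probability random
#' forest per model specification is fitted (1000 trees, maximum depth 10,
#' minimum terminal-node size 10, `mtry = floor(sqrt(p))`) and scored on
#' the held-out fold by AUROC (midrank) and AUPR, recording Gini (impurity)
#' importances. Folds whose test split contains a single class yield `NA`
#' performance with a warning and are excluded from fold averages
#' downstream.
#'
#' @param X feature matrix (rownames = tile ids) covering the partition.
#' @param schema the matching [family_schema()].
#' @param partition an [assign_folds()] result.
#' @param specs list of model specs from [enumerate_model_specs()] (or a
#'   subset).
#' @param trees number of trees (default 1000).
#' @param n_pc principal components for the `sequence_PC` block
#'   (default 100).
#' @param pca_scope `"train_fold"` (default, leakage-safe) or `"all_data"`.
#' @param seed base seed; every (spec, fold) fit gets a derived seed.
#' @param min_leaf,max_depth forest hyperparameters (defaults 10, 10).
#' @return a `model_results` list: `table` (`data.table` spec_id / set /
#'   key / fold / auroc / aupr), `importance` (nested list
#'   `[[spec_id]][[fold]]`), `specs`, `K`.
#' @export
run_model_ensemble <- function(X, schema, partition, specs, trees = 1000L,
                               n_pc = 100L, pca_scope = c("train_fold", "all_data"),
                               seed = 1L, min_leaf = 10L, max_depth = 10L) {
  pca_scope <- match.arg(pca_scope)
  part <- data.table::as.data.table(partition)
  K <- attr(partition, "K") %||% max(part$fold)
  rows <- match(as.character(part$tile_id), rownames(X))
  if (anyNA(rows)) stop("partition tiles missing from the feature matrix")
  Xp <- X[rows, , drop = FALSE]
  y <- part$label
  prim_cols <- schema$feature[schema$category == "primary"]
  need_pc <- any(vapply(specs, function(s) s$representation == "sequence_PC", TRUE))
  fam_cols <- split(schema$feature, schema$family)
  res <- list(); imp <- list()
  for (k in seq_len(K)) {
    test <- which(part$fold == k); train <- which(part$fold != k)
    pc_block <- NULL
    if (need_pc) {
      fit_rows <- if (pca_scope == "train_fold") train else seq_len(nrow(Xp))
      pc_block <- suppressWarnings(
        sequence_pca(Xp[, prim_cols, drop = FALSE], n_pc = n_pc, fit_rows = fit_rows))
    }
    up <- with_seed(child_seed(seed, paste0("up", k)), upsample_idx(y[train]))
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      if (sp$representation == "raw") {
        cols <- unlist(fam_cols[sp$families], use.names = FALSE)
        D <- Xp[, cols, drop = FALSE]
      } else {
        cols <- unlist(fam_cols[sp$families], use.names = FALSE)
        D <- cbind(pc_block,
                   if (length(cols)) Xp[, cols, drop = FALSE])
      }
      Dtr <- as.data.frame(D[train, , drop = FALSE])[up, , drop = FALSE]
      ytr <- factor(y[train][up], levels = c(0L, 1L))
      fit <- ranger::ranger(
        x = Dtr, y = ytr, num.trees = trees,
        mtry = max(1L, floor(sqrt(ncol(D)))),
        min.node.size = min_leaf, max.depth = max_depth,
        probability = TRUE, importance = "impurity",
        num.threads = 1L,
        seed = child_seed(seed, paste0(sp$id, ":", k)))
      pr <- predict(fit, data = as.data.frame(D[test, , drop = FALSE]),
                    num.threads = 1L)$predictions[, "1"]
      yte <- y[test]
      a <- auroc(pr, yte)
      if (is.na(a)) warning("fold ", k, " has a single-class test split")
      res[[length(res) + 1L]] <- data.table::data.table(
        spec_id = sp$id, set = sp$set, subset = sp$key, fold = k,
        auroc = a, aupr = aupr(pr, yte))
      imp[[sp$id]][[k]] <- ranger::importance(fit)
    }
  }
  structure(list(table = data.table::rbindlist(res), importance = imp,
                 specs = specs, K = K),
            class = "model_results")
}

#' Train and evaluate a single model specification
#'
#' Convenience wrapper around [run_model_ensemble()] for one spec.
#'
#' @inheritParams run_model_ensemble
#' @param spec a single model spec.
#' @return the per-fold results `data.table` with an `importance`
#'   attribute.
#' @export
train_and_eval <- function(X, schema, partition, spec, ...) {
  r <- run_model_ensemble(X, schema, partition, list(spec), ...)
  out <- r$table
  data.table::setattr(out, "importance", r$importance[[spec$id]])
  out
}
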