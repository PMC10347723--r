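# Build a fake model_results object from a table of per-model fold AUROCs.
fake_results <- function(perf, K = 5L, set = "seq_context") {
  tab <- data.table::rbindlist(lapply(names(perf), function(key)
    data.table::data.table(spec_id = paste0("m:", key), set = set,
                           subset = key, fold = seq_len(K),
                           auroc = perf[[key]], aupr = NA_real_)))
  structure(list(table = tab, importance = list(), specs = list(), K = K),
            class = "model_results")
}

# All subsets of a set of family names, as subset keys.
all_keys <- function(fams, include_empty = TRUE) {
  ks <- unlist(lapply((if (include_empty) 0 else 1):length(fams), function(k)
    utils::combn(fams, k, FUN = subset_key, simplify = FALSE)), use.names = FALSE)
  if (include_empty && !"(none)" %in% ks) ks <- c("(none)", ks)
  unique(ks)
}

test_that("MPV and MxPV are zero under constant performance", {
  fams <- c("u", "v", "w")
  sch <- family_schema(paste0(rep(c("p", fams), each = 1), 1),
                       c("pf", fams),
                       c("primary", rep("secondary", 3)))
  perf <- setNames(rep(list(rep(0.7, 5)), 8), all_keys(fams))
  r <- fake_results(perf)
  for (f in fams) {
    expect_equal(mpv(r, f, "secondary", sch), 0)
    expect_equal(mxpv(r, f, "secondary", sch), 0)
  }
})

test_that("MPV/MxPV match a naive power-set oracle to 1e-12 and MxPV >= MPV", {
  fams <- c("u", "v", "w")
  sch <- family_schema(c("p1", "u1", "v1", "w1"),
                       c("pf", fams), c("primary", rep("secondary", 3)))
  for (seed in 1:10) {
    perf <- withr::with_seed(seed, {
      ks <- all_keys(fams)
      setNames(lapply(ks, function(k) runif(5, 0.4, 0.9)), ks)
    })
    r <- fake_results(perf)
    mean_of <- function(key) mean(perf[[key]])
    for (f in fams) {
      others <- setdiff(fams, f)
      diffs <- c()
      for (k in 0:length(others)) {
        for (b in utils::combn(others, k, simplify = FALSE)) {
          diffs <- c(diffs, mean_of(subset_key(c(f, b))) - mean_of(subset_key(b)))
        }
      }
      expect_length(diffs, 2^(length(fams) - 1))
      expect_equal(mpv(r, f, "secondary", sch), mean(diffs), tolerance = 1e-12)
      expect_equal(mxpv(r, f, "secondary", sch), max(diffs), tolerance = 1e-12)
      expect_gte(mxpv(r, f, "secondary", sch), mpv(r, f, "secondary", sch))
    }
  }
})

test_that("primary-family MPV uses the chance baseline for the empty subset", {
  fams <- c("a", "b")
  sch <- family_schema(c("a1", "b1"), fams, c("primary", "primary"))
  perf <- list("a" = rep(0.8, 5), "b" = rep(0.5, 5), "a+b" = rep(0.8, 5))
  tab <- fake_results(perf, set = "sequence_only")
  # pairs for a: (a+b) - (b) = 0.3 and (a) - chance 0.5 = 0.3
  expect_equal(mpv(tab, "a", "primary", sch), 0.3, tolerance = 1e-12)
  expect_equal(mpv(tab, "b", "primary", sch), 0.0, tolerance = 1e-12)
})

test_that("an incomplete ensemble raises an error", {
  fams <- c("u", "v")
  sch <- family_schema(c("p1", "u1", "v1"), c("pf", fams),
                       c("primary", "secondary", "secondary"))
  perf <- list("(none)" = rep(0.5, 5), "u" = rep(0.6, 5), "v" = rep(0.6, 5))
  r <- fake_results(perf)  # pair model u+v missing
  expect_error(mpv(r, "u", "secondary", sch), "missing")
})

test_that("MPV is invariant to power-set enumeration order", {
  fams <- c("u", "v", "w")
  sch <- family_schema(c("p1", "u1", "v1", "w1"),
                       c("pf", fams), c("primary", rep("secondary", 3)))
  perf <- withr::with_seed(3, {
    ks <- all_keys(fams)
    setNames(lapply(ks, function(k) runif(5, 0.4, 0.9)), ks)
  })
  r1 <- fake_results(perf)
  r2 <- fake_results(perf[sample(names(perf))])
  expect_equal(mpv(r1, "v", "secondary", sch), mpv(r2, "v", "secondary", sch),
               tolerance = 1e-15)
})

test_that("rank aggregation matches a naive re-aggregation oracle", {
  set.seed(6)
  feats <- paste0("f", 1:8)
  imp <- list()
  perf <- list()
  for (m in 1:5) {
    key <- paste0("model", m)
    perf[[key]] <- runif(3, 0.5, 0.9)
    imp[[paste0("m:", key)]] <- lapply(1:3, function(k)
      setNames(rgamma(8, 1), feats))
  }
  r <- fake_results(perf, K = 3, set = "sequence_only")
  r$importance <- imp
  out <- aggregate_feature_ranks(r, percentile = 40, set = "sequence_only")
  means <- sapply(perf, mean)
  sel <- names(means)[means >= quantile(means, 0.6)]
  for (f in feats) {
    rk <- sapply(sel, function(key) {
      avg <- Reduce(`+`, imp[[paste0("m:", key)]]) / 3
      rank(-avg, ties.method = "average")[[f]]
    })
    expect_equal(out$median_rank[out$feature == f], median(rk))
  }
  expect_error(aggregate_feature_ranks(r, percentile = 40, set = "nope"), "no models")
})

test_that("the top-importance feature of a single selected model gets rank 1", {
  perf <- list(best = rep(0.9, 2), worst = rep(0.5, 2))
  r <- fake_results(perf, K = 2, set = "sequence_only")
  r$importance <- list("m:best" = list(setNames(c(5, 1), c("big", "small")),
                                       setNames(c(4, 2), c("big", "small"))),
                       "m:worst" = list(setNames(c(1, 1), c("big", "small")),
                                        setNames(c(1, 1), c("big", "small"))))
  out <- aggregate_feature_ranks(r, percentile = 20, set = "sequence_only")
  expect_equal(out$median_rank[out$feature == "big"], 1)
  expect_equal(out$n_models, c(1L, 1L))  # only the best model selected
})

test_that("TA calls use an inclusive threshold and tolerate empty groups", {
  mt <- data.table::data.table(
    lncRNA = c("l1", "l2", "l3"), family = "transcription",
    category = "secondary", mpv = c(0.01, 0.0099, -0.2), mxpv = 0)
  ta <- classify_ta(mt)
  expect_equal(ta$labels$ta, c(TRUE, FALSE, FALSE))
  all_low <- data.table::copy(mt)[, mpv := -0.1]
  ta2 <- classify_ta(all_low)
  expect_false(any(ta2$labels$ta))
  expect_null(ta2$test)
})

test_that("complementarity: duplicate families add nothing, ceilings stay flat", {
  set.seed(21)
  n <- 600
  base <- rnorm(n)
  noisy <- base + rnorm(n, 0, 0.2)
  # fb is an exact duplicate of fa (a second noisy copy would genuinely
  # denoise the latent signal and count as real complementarity)
  X <- cbind(a1 = noisy, b1 = noisy, c1 = rnorm(n))
  rownames(X) <- 1:n
  sch <- family_schema(colnames(X), c("fa", "fb", "fc"), rep("primary", 3))
  part <- data.table::data.table(tile_id = 1:n,
                                 label = rbinom(n, 1, plogis(1.5 * base)),
                                 fold = rep(1:5, length.out = n))
  data.table::setattr(part, "K", 5L)
  # fb is (noisy) duplicate information of fa: no complementarity on
  # average (a single fit carries forest noise of the same order)
  dup <- mean(vapply(3:5, function(sd)
    complementarity(X, sch, part, "fa", "fb", trees = 100, seed = sd)$score,
    numeric(1)))
  expect_lte(dup, 0.02)
  # a perfectly separating family leaves no headroom for the pair
  X2 <- X; X2[, "a1"] <- ifelse(part$label == 1, 1, -1)
  sep <- complementarity(X2, sch, part, "fa", "fc", trees = 60, seed = 4)
  expect_equal(sep$auroc_a, 1.0)
  expect_lt(abs(sep$score), 1e-8)
})

test_that("the TA group test compares another family's MPVs between groups", {
  mt <- data.table::rbindlist(list(
    data.table::data.table(lncRNA = paste0("t", 1:4), family = "transcription",
                           category = "secondary", mpv = 0.05, mxpv = 0.05),
    data.table::data.table(lncRNA = paste0("n", 1:4), family = "transcription",
                           category = "secondary", mpv = -0.01, mxpv = 0),
    data.table::data.table(lncRNA = paste0("t", 1:4), family = "triplex",
                           category = "primary", mpv = c(0.001, 0.002, 0.0, 0.003),
                           mxpv = 0),
    data.table::data.table(lncRNA = paste0("n", 1:4), family = "triplex",
                           category = "primary", mpv = c(0.09, 0.11, 0.10, 0.12),
                           mxpv = 0)))
  ta <- classify_ta(mt, test_family = "triplex", alternative = "greater")
  expect_equal(sum(ta$labels$ta), 4L)
  # triplex MPVs are higher in the non-TA group
  expect_lt(ta$test$p.value, 0.05)
})
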