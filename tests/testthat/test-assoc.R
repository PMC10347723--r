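test_that("signed KS is zero on identical samples and antisymmetric under swap", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(signed_ks(x, x)$d_signed, 0)
  b <- c(2, 3, 4, 6, 8); u <- c(1, 2, 3, 4, 5)
  f <- signed_ks(b, u); g <- signed_ks(u, b)
  expect_gt(f$d_signed, 0)            # bound shifted up = enriched
  expect_equal(f$d_signed, -g$d_signed, tolerance = 1e-12)
  expect_error(signed_ks(numeric(0), x), "non-empty")
})

test_that("|signed KS| equals the classical statistic and the brute-force sweep", {
  for (seed in 1:100) {
    ab <- withr::with_seed(seed, {
      n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
      list(a = sample(0:12, n1, TRUE) + rnorm(n1, 0, 0.01),
           b = sample(0:12, n2, TRUE) + rnorm(n2, 0, 0.01))
    })
    r <- signed_ks(ab$a, ab$b)
    expect_equal(abs(r$d_signed),
                 unname(suppressWarnings(
                   stats::ks.test(ab$a, ab$b)$statistic)),
                 tolerance = 1e-12)
    expect_equal(r$d_signed, naive_signed_ks(ab$a, ab$b), tolerance = 1e-12)
  }
})

test_that("asymptotic p-values track ks.test for untied samples", {
  for (seed in 1:10) {
    ab <- withr::with_seed(seed, list(a = rnorm(60), b = rnorm(80, 0.3)))
    r <- signed_ks(ab$a, ab$b)
    p_ref <- stats::ks.test(ab$a, ab$b, exact = FALSE)$p.value
    expect_equal(r$p_value, p_ref, tolerance = 1e-6)
  }
})

test_that("the enrichment battery flags constants and BH behaves monotonically", {
  set.seed(2)
  X <- cbind(up = c(rnorm(50, 1), rnorm(50)), flat = rep(1, 100),
             null = rnorm(100))
  rownames(X) <- 1:100
  ds <- structure(list(positives = 1:50, negatives = 51:100),
                  class = "labeled_dataset")
  bat <- enrichment_battery(X, list(l1 = ds), c("up", "flat", "null"))
  expect_true(bat$constant[bat$feature == "flat"])
  expect_equal(bat$p_value[bat$feature == "flat"], 1)
  expect_gt(bat$d_signed[bat$feature == "up"], 0)
  expect_true(all(bat$p_adj >= bat$p_value - 1e-15))
  ord <- order(bat$p_value)
  expect_true(all(diff(bat$p_adj[ord]) >= -1e-15))
  # single-feature battery: adjusted equals raw
  one <- enrichment_battery(X, list(l1 = ds), "up")
  expect_equal(one$p_adj, one$p_value)
})

test_that("Spearman rank-density correlation hits the analytic extremes", {
  uni <- kmer_universe(5)
  rt <- data.table::data.table(feature = uni$levels,
                               median_rank = seq_len(512),
                               n_models = 1L)
  dens_inv <- setNames(rev(seq_len(512)), uni$levels)  # dense = important
  r <- kmer_density_correlation(rt, dens_inv)
  expect_equal(r$rho, -1, tolerance = 1e-12)
  dens_null <- withr::with_seed(4, setNames(rnorm(512), uni$levels))
  r0 <- kmer_density_correlation(rt, dens_null)
  expect_lt(abs(r0$rho), 0.12)
  flat <- setNames(rep(1, 512), uni$levels)
  expect_true(is.na(kmer_density_correlation(rt, flat)$rho))
  # midrank internal identity: rho equals Pearson correlation of midranks
  dens_ties <- withr::with_seed(5, setNames(sample(0:5, 512, TRUE), uni$levels))
  r2 <- kmer_density_correlation(rt, dens_ties)
  expect_equal(r2$rho,
               stats::cor(rank(rt$median_rank), rank(dens_ties[rt$feature])),
               tolerance = 1e-12)
})

test_that("seed enrichment matrix recovers a planted two-group block structure", {
  uni <- kmer_universe(5)
  gc_kmers <- head(grep("^(G|C)(G|C)(G|C)", uni$levels, value = TRUE), 20)
  at_kmers <- head(grep("^(A|T)(A|T)(A|T)", uni$levels, value = TRUE), 20)
  mk_seed <- function(k) paste0("A", k, "G")
  seeds <- c(setNames(sapply(gc_kmers[1:4], mk_seed), paste0("gc", 1:4)),
             setNames(sapply(at_kmers[1:4], mk_seed), paste0("at", 1:4)))
  n <- 200
  X <- withr::with_seed(7, matrix(rpois(n * 512, 1), n, 512,
                                  dimnames = list(1:n, uni$levels)))
  # lncRNA A: bound tiles enriched for GC k-mers; lncRNA B: for AT k-mers
  bound <- 1:100; unbound <- 101:200
  XA <- X; XA[bound, gc_kmers] <- XA[bound, gc_kmers] + 3
  XB <- X; XB[bound, at_kmers] <- XB[bound, at_kmers] + 3
  ds <- structure(list(positives = bound, negatives = unbound),
                  class = "labeled_dataset")
  m <- seed_enrichment_matrix(list(A = XA, B = XB),
                              list(A = ds, B = ds), seeds)
  M <- m$matrix[c("A", "B"), names(seeds)]
  sign_ok <- c(M["A", paste0("gc", 1:4)] > 0, M["B", paste0("at", 1:4)] > 0,
               M["A", paste0("at", 1:4)] <= 0.05, M["B", paste0("gc", 1:4)] <= 0.05)
  expect_gte(mean(sign_ok), 0.8)
  # identical bound/unbound distributions give the zero matrix
  ds0 <- structure(list(positives = 1:50, negatives = 51:100),
                   class = "labeled_dataset")
  X0 <- matrix(1, 100, 512, dimnames = list(1:100, uni$levels))
  m0 <- seed_enrichment_matrix(X0, list(A = ds0), seeds)
  expect_true(all(m0$matrix == 0))
  # row-order permutation invariance of the clustering
  m2 <- seed_enrichment_matrix(list(B = XB, A = XA),
                               list(B = ds, A = ds), seeds)
  expect_equal(m$matrix[m$row_order, m$col_order],
               m2$matrix[m$row_order, m$col_order])
})

test_that("seeds without valid 5-mers are dropped with a warning", {
  uni <- kmer_universe(5)
  X <- matrix(1:2, 100, 512, dimnames = list(1:100, uni$levels))
  ds <- structure(list(positives = 1:50, negatives = 51:100),
                  class = "labeled_dataset")
  expect_warning(
    m <- seed_enrichment_matrix(X, list(A = ds),
                                c(ok = "AAAAAGG", bad = "ANNG")),
    "dropping")
  expect_equal(colnames(m$matrix), "ok")
})

test_that("pooled group enrichment detects a shifted feature between lncRNA groups", {
  set.seed(31)
  X <- cbind(f = c(rnorm(60, 1), rnorm(140)))
  rownames(X) <- 1:200
  ds_a <- structure(list(positives = 1:60, negatives = 151:200),
                    class = "labeled_dataset")
  ds_b <- structure(list(positives = 61:150, negatives = 151:200),
                    class = "labeled_dataset")
  r <- group_enrichment(X, list(A = ds_a, B = ds_b), "A", "B", "f")
  expect_gt(r$d_signed, 0.3)
  expect_lt(r$p_value, 1e-3)
})
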