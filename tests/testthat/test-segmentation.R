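make_series <- function(activities, catalog, n_per_bin = 100, seed = 1,
                        chrom_len = 2e8) {
  # helper: a bin series with one bin per activity row, built through the
  # simulator so spans and counts are realistic
  set.seed(seed)
  B <- nrow(activities)
  counts <- t(sapply(seq_len(B), function(b)
    simulate_counts(activities[b, ], catalog, n_per_bin)))
  width <- chrom_len / B
  bins <- data.frame(bin = seq_len(B),
                     chrom_start = "1",
                     pos_start = as.integer((seq_len(B) - 1) * width + 1),
                     chrom_end = "1",
                     pos_end = as.integer(seq_len(B) * width - 1000),
                     n = rowSums(counts))
  structure(list(bins = bins, counts = counts, mode = "genome",
                 bin_size = n_per_bin, sample_id = "toy",
                 mutations = NULL, chrom_order = canonical_chromosomes()),
            class = "bin_series")
}

test_that("segment cost has the closed form for a single signature", {
  cat1 <- synthetic_catalog(1, overlap = 0.2)
  s <- make_series(matrix(1, 2, 1), cat1, n_per_bin = 150, seed = 2)
  sc <- segment_cost(s, 1, 1, cat1)
  mu <- unclass(cat1)[1, ]
  k <- s$counts[1, ] > 0
  expect_equal(sc$cost, -2 * sum(s$counts[1, k] * log(mu[k])))
  # pooling two identical bins returns the same activity as one
  s2 <- make_series(rbind(c(0.6, 0.4), c(0.6, 0.4)), synthetic_catalog(2),
                    seed = 3)
  s2$counts[2, ] <- s2$counts[1, ]
  cat2 <- synthetic_catalog(2)
  a1 <- segment_cost(s2, 1, 1, cat2)$activity
  a12 <- segment_cost(s2, 1, 2, cat2)$activity
  expect_equal(a12, a1, tolerance = 1e-6)
})

test_that("segment costs are superadditive under splitting", {
  cat3 <- synthetic_catalog(3, overlap = 0.3)
  set.seed(10)
  for (rep in 1:5) {
    act <- t(sapply(1:6, function(i) {
      a <- as.vector(rmultinom(1, 12, rep(1, 3))); a / sum(a)
    }))
    s <- make_series(act, cat3, n_per_bin = 80, seed = 10 + rep)
    for (m in 1:5) {
      whole <- segment_cost(s, 1, 6, cat3)$cost
      left <- segment_cost(s, 1, m, cat3)$cost
      right <- segment_cost(s, m + 1, 6, cat3)$cost
      expect_gte(whole, left + right - 1e-6)
    }
  }
})

test_that("the BIC default penalty follows (S-1) log N", {
  cat2 <- synthetic_catalog(2)
  s <- make_series(matrix(c(0.5, 0.5), 1, 2, byrow = TRUE), cat2,
                   n_per_bin = 10000, seed = 4)
  expect_equal(default_penalty(s, cat2), log(10000))
  cat4 <- synthetic_catalog(4)
  s4 <- make_series(matrix(0.25, 1, 4), cat4, n_per_bin = 5000, seed = 5)
  expect_equal(default_penalty(s4, cat4), 3 * log(5000))
  # doubling N adds (S-1) log 2
  s8 <- make_series(matrix(0.25, 2, 4), cat4, n_per_bin = 5000, seed = 6)
  expect_equal(default_penalty(s8, cat4) - default_penalty(s4, cat4),
               3 * log(2))
  cat1 <- synthetic_catalog(1)
  s1 <- make_series(matrix(1, 1, 1), cat1, seed = 7)
  expect_warning(p <- default_penalty(s1, cat1), "single-signature")
  expect_equal(p, Inf)
})

test_that("infinite penalty yields a single segment", {
  cat2 <- synthetic_catalog(2, overlap = 0)
  s <- make_series(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)), cat2, seed = 8)
  r <- pelt_segment(s, cat2, penalty = Inf)
  expect_equal(nrow(r$segments), 1)
  expect_equal(nrow(r$changepoints), 0)
})

test_that("PELT equals exhaustive dynamic programming on random series", {
  cat3 <- synthetic_catalog(3, overlap = 0.3)
  for (trial in 1:25) {
    set.seed(2000 + trial)
    B <- sample(2:12, 1)
    act <- t(sapply(seq_len(B), function(i) {
      a <- as.vector(rmultinom(1, 10, rep(1, 3))); a / sum(a)
    }))
    s <- make_series(act, cat3, n_per_bin = 60, seed = 3000 + trial)
    pen <- runif(1, 2, 30)
    r <- pelt_segment(s, cat3, penalty = pen)
    e <- exhaustive_segmentation(s$counts, cat3, pen)
    expect_equal(r$changepoints$boundary, as.integer(e$boundaries))
    expect_equal(r$total_penalized_cost, e$cost, tolerance = 1e-8)
  }
})

test_that("no two changepoints sit at adjacent bins", {
  cat2 <- synthetic_catalog(2, overlap = 0)
  act <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  s <- make_series(act, cat2, n_per_bin = 200, seed = 12)
  r <- pelt_segment(s, cat2, penalty = 1)
  if (nrow(r$changepoints) > 1)
    expect_true(all(diff(r$changepoints$boundary) >= 2))
  expect_true(all(r$segments$end_bin >= r$segments$start_bin))
})

test_that("the penalty never increases the number of changepoints", {
  cat3 <- synthetic_catalog(3, overlap = 0.2)
  for (trial in 1:5) {
    set.seed(4000 + trial)
    act <- t(sapply(1:8, function(i) {
      a <- as.vector(rmultinom(1, 10, rep(1, 3))); a / sum(a)
    }))
    s <- make_series(act, cat3, n_per_bin = 80, seed = 5000 + trial)
    n0 <- nrow(pelt_segment(s, cat3, penalty = 0)$changepoints)
    n1 <- nrow(pelt_segment(s, cat3)$changepoints)
    expect_lte(n1, n0)
  }
})

test_that("penalized cost is invariant to consistent channel relabeling", {
  cat3 <- synthetic_catalog(3, overlap = 0.2)
  act <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.1, 0.8), c(0.1, 0.1, 0.8))
  s <- make_series(act, cat3, n_per_bin = 100, seed = 13)
  set.seed(14)
  perm <- sample(96)
  m <- unclass(cat3)[, perm]
  colnames(m) <- sbs96_labels()
  catp <- signature_catalog(m)
  sp <- s
  sp$counts <- s$counts[, perm]
  colnames(sp$counts) <- sbs96_labels()
  r <- pelt_segment(s, cat3, penalty = 10)
  rp <- pelt_segment(sp, catp, penalty = 10)
  expect_equal(rp$total_penalized_cost, r$total_penalized_cost,
               tolerance = 1e-8)
  expect_equal(rp$changepoints$boundary, r$changepoints$boundary)
})

test_that("a planted activity switch is recovered at the right boundary", {
  cat2 <- synthetic_catalog(2, overlap = 0)
  hits <- 0
  for (seed in 1:10) {
    act <- rbind(matrix(rep(c(0.9, 0.1), 10), 10, byrow = TRUE),
                 matrix(rep(c(0.1, 0.9), 10), 10, byrow = TRUE))
    s <- make_series(act, cat2, n_per_bin = 200, seed = 6000 + seed)
    r <- pelt_segment(s, cat2)
    if (nrow(r$changepoints) == 1 &&
        abs(r$changepoints$boundary - 10) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("chromosome-wise profiles are independent across chromosomes", {
  cat2 <- synthetic_catalog(2, overlap = 0)
  lay <- tiny_layout()
  # constant activity within each chromosome, different between them:
  # chromosome-wise segmentation must flag nothing
  segs <- data.frame(chrom = c("1", "2"), start = 0, end = lay$length)
  cfg <- simulation_config(lay, cat2, segs,
                           rbind(c(0.9, 0.1), c(0.1, 0.9)), 3000, seed = 31)
  mut <- simulate_sample(cfg)$mutations
  prof <- run_profile(mut, cat2, bin_size = 100, mode = "chromosome")
  expect_equal(nrow(prof$changepoints), 0)
  # per-chromosome results do not depend on the other chromosome
  prof1 <- run_profile(mut[mut$chrom == "1", ], cat2, bin_size = 100,
                       mode = "chromosome")
  sub <- prof$segments[prof$segments$chrom_start == "1",
                       c("start_bin", "end_bin", "log_likelihood")]
  rownames(sub) <- NULL
  expect_equal(sub,
               prof1$segments[, c("start_bin", "end_bin", "log_likelihood")])
})

test_that("genome-wise and chromosome-wise modes localize the same switch", {
  cat2 <- synthetic_catalog(2, overlap = 0)
  lay <- tiny_layout()
  segs <- data.frame(chrom = c("1", "1", "2"),
                     start = c(0, 1e8, 0), end = c(1e8, 2e8, 1.5e8))
  act <- rbind(c(0.9, 0.1), c(0.1, 0.9), c(0.1, 0.9))
  cfg <- simulation_config(lay, cat2, segs, act, 4000, seed = 77)
  sim <- simulate_sample(cfg)
  pg <- run_profile(sim$mutations, cat2, bin_size = 100, mode = "genome")
  pc <- run_profile(sim$mutations, cat2, bin_size = 100, mode = "chromosome")
  rg <- recovery_at_bin_tolerance(pg, sim$truth$changepoints)
  rc <- recovery_at_bin_tolerance(pc, sim$truth$changepoints)
  expect_equal(rg$recall, 1)
  expect_equal(rc$recall, 1)
  # both modes place the changepoint on chromosome 1 near 100 Mb
  expect_equal(pg$changepoints$chrom[1], "1")
  expect_equal(pc$changepoints$chrom[1], "1")
})
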