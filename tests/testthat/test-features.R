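kat_mut <- function(pos, chrom = "1", sample = "s") {
  data.frame(sample = sample, chrom = chrom, pos = pos,
             stringsAsFactors = FALSE)
}

test_that("the rainfall criterion fires on six tight mutations and not five", {
  ev <- detect_kataegis(kat_mut(seq(1000, 3500, by = 500)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_mutations, 6)
  expect_equal(ev$mean_gap, 500)
  expect_equal(c(ev$start, ev$end), c(1000, 3500))
  # five mutations, however tight, are not an event
  ev5 <- detect_kataegis(kat_mut(seq(100, 140, by = 10)))
  expect_equal(nrow(ev5), 0)
})

test_that("kataegis detection equals the brute-force window scan", {
  for (trial in 1:60) {
    set.seed(trial)
    n <- sample(10:60, 1)
    # mix of background and clustered positions so events are plausible
    pos <- sort(c(sample.int(3e6, n),
                  if (trial %% 2 == 0)
                    cumsum(c(sample.int(1e6, 1), sample.int(800, 12)))))
    got <- detect_kataegis(kat_mut(pos))
    want <- brute_kataegis(pos)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_mutations, want$n_mutations)
    }
  }
})

test_that("kataegis events are maximal and non-overlapping", {
  for (trial in 1:20) {
    set.seed(300 + trial)
    pos <- sort(cumsum(sample(c(50, 200, 900, 5000), 80, replace = TRUE)))
    ev <- detect_kataegis(kat_mut(pos))
    if (nrow(ev) > 1)
      expect_true(all(ev$start[-1] > ev$end[-nrow(ev)]))
    for (k in seq_len(nrow(ev))) {
      i <- which(pos == ev$start[k]); j <- which(pos == ev$end[k])
      # extending one mutation in either direction violates the criterion
      if (i > 1)
        expect_gt((pos[j] - pos[i - 1]) / (j - i + 1), 1000)
      if (j < length(pos))
        expect_gt((pos[j + 1] - pos[i]) / (j + 1 - i), 1000)
    }
  }
})

test_that("kataegis respects per-sample and per-chromosome boundaries", {
  m <- rbind(kat_mut(seq(1000, 3000, by = 500), sample = "a"),
             kat_mut(seq(1000, 3000, by = 500), chrom = "2", sample = "a"),
             kat_mut(seq(1000, 3000, by = 500), sample = "b"))
  # 5 mutations per (sample, chromosome): nothing merges across either
  expect_equal(nrow(detect_kataegis(m)), 0)
})

test_that("gene density counts window overlaps", {
  lay <- genome_layout("1", 10000)
  none <- gene_density(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0)), lay, window = 1000)
  expect_equal(sum(none$value), 0)
  expect_equal(nrow(none), 10)
  one <- gene_density(data.frame(chrom = "1", start = 1500, end = 3500),
                      lay, window = 1000)
  expect_equal(one$value, c(0, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  # brute-force oracle on random gene sets
  for (trial in 1:5) {
    set.seed(500 + trial)
    g <- data.frame(chrom = "1", start = sample(0:9000, 20, replace = TRUE))
    g$end <- g$start + sample(100:2500, 20, replace = TRUE)
    g$end <- pmin(g$end, 10000)
    got <- gene_density(g, lay, window = 1000)
    want <- vapply(seq(0, 9000, by = 1000), function(s)
      sum(g$start < s + 1000 & g$end > s), numeric(1))
    expect_equal(got$value, want)
  }
})

test_that("density normalization scales the extremes to zero and one", {
  lay <- genome_layout("1", 5000)
  g <- data.frame(chrom = "1", start = c(0, 0, 1000), end = c(1000, 900, 2000))
  d <- gene_density(g, lay, window = 1000, normalize = TRUE)
  expect_equal(max(d$value), 1)
  expect_equal(min(d$value), 0)
})

test_that("tiled event density conserves totals for point-like events", {
  lay <- genome_layout("1", 1e7)
  set.seed(77)
  ev <- data.frame(chrom = "1", start = sample(0:(1e7 - 2), 30))
  ev$end <- ev$start + 1
  d <- event_density(ev, lay, window = 1e6)
  expect_equal(sum(d$value), 30)
})

test_that("CNA intervals keep non-diploid autosomal segments only", {
  segs <- data.frame(chrom = c("1", "5", "X", "2"),
                     start = c(0, 1e6, 0, 5e6),
                     end = c(1e6, 2e6, 1e6, 6e6),
                     value = c(2, 3, 1, 2))
  out <- cna_intervals(segs)
  expect_equal(nrow(out), 1)
  expect_equal(out$chrom, "5")
  expect_equal(out$value, 3)
  # an all-diploid genome yields nothing
  expect_equal(nrow(cna_intervals(transform(segs, value = 2))), 0)
})

test_that("replication-timing consensus is the per-segment median", {
  base <- data.frame(chrom = "1", start = c(0, 1e6), end = c(1e6, 2e6))
  t1 <- transform(base, value = c(1, 5))
  t2 <- transform(base, value = c(2, 6))
  t3 <- transform(base, value = c(9, 7))
  cons <- replication_timing_consensus(list(t1, t2, t3))
  expect_equal(cons$value, c(2, 6))
  expect_equal(replication_timing_consensus(list(t1))$value, t1$value)
  bad <- transform(base, start = c(0, 2e6), end = c(1e6, 3e6), value = 1)
  expect_error(replication_timing_consensus(list(t1, bad)), "mismatched")
  # random tracks against an independent median
  set.seed(9)
  tracks <- lapply(1:5, function(i) transform(base, value = runif(2)))
  vals <- sapply(tracks, `[[`, "value")
  expect_equal(replication_timing_consensus(tracks)$value,
               apply(vals, 1, median))
})

test_that("compartment labels recode to indicator values", {
  tr <- data.frame(chrom = "1", start = c(0, 1e6, 2e6),
                   end = c(1e6, 2e6, 3e6), value = c("A", "B", "A"))
  out <- recode_compartments(tr)
  expect_equal(out$value, c(1, 0, 1))
  expect_error(recode_compartments(transform(tr, value = "C")), "A or B")
})

test_that("nearest-event distances use edges, overlap, and concatenation", {
  lay <- tiny_layout()
  cps <- data.frame(chrom = c("1", "1"), start = c(5000, 0),
                    end = c(10000, 1000))
  ev <- data.frame(chrom = "1", start = c(12500, 7000), end = c(13000, 7100))
  d <- nearest_event_distance(cps, ev, lay)
  expect_equal(d[1], 0)        # overlap
  expect_equal(d[2], 6000)     # closest edge gap
  # same-edge example from a single event
  d2 <- nearest_event_distance(data.frame(chrom = "1", start = 0, end = 10000),
                               data.frame(chrom = "1", start = 12500,
                                          end = 13000), lay)
  expect_equal(d2, 2500)
  # cross-chromosome distances follow the end-to-end concatenation
  d3 <- nearest_event_distance(data.frame(chrom = "1", start = 2e8 - 1000,
                                          end = 2e8),
                               data.frame(chrom = "2", start = 5000,
                                          end = 6000), lay)
  expect_equal(d3, 5000)
  expect_error(nearest_event_distance(cps, ev[0, ], lay), "no events")
})

test_that("nearest-event distances equal the exhaustive pairwise minimum", {
  lay <- tiny_layout()
  set.seed(12)
  off <- chrom_offsets(lay)
  for (trial in 1:5) {
    ci <- sample(1:2, 8, replace = TRUE)
    cps <- data.frame(chrom = lay$chrom[ci],
                      start = floor(runif(8) * (lay$length[ci] - 1e6)))
    cps$end <- cps$start + 1e5
    ei <- sample(1:2, 10, replace = TRUE)
    ev <- data.frame(chrom = lay$chrom[ei],
                     start = floor(runif(10) * (lay$length[ei] - 1e6)))
    ev$end <- ev$start + 1e4
    got <- nearest_event_distance(cps, ev, lay)
    for (i in 1:8) {
      ds <- sapply(1:10, function(j) {
        a1 <- off[cps$chrom[i]] + cps$start[i]; a2 <- off[cps$chrom[i]] + cps$end[i]
        b1 <- off[ev$chrom[j]] + ev$start[j]; b2 <- off[ev$chrom[j]] + ev$end[j]
        max(c(b1 - a2, a1 - b2, 0))
      })
      expect_equal(got[i], min(ds))
    }
  }
})
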