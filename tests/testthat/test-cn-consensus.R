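test_that("expansion pads, clamps, and splits same-caller overlap midpoints", {
  seg <- data.frame(chrom = "chr1", start = 10001L, end = 20000L, cn = 3,
                    caller = "a")
  e <- expand_and_divide(seg, pad = 5000)
  expect_equal(c(e$start, e$end), c(5001L, 25000L))
  # two segments whose expansions overlap on [7000, 15000]: split at 11000
  seg2 <- data.frame(chrom = "chr1", start = c(1L, 12000L),
                     end = c(10000L, 20000L), cn = c(3, 1), caller = "a")
  e2 <- expand_and_divide(seg2, pad = 5000)
  expect_equal(e2$start, c(1L, 11001L))
  expect_equal(e2$end, c(11000L, 25000L))
  expect_equal(e2$cn, c(3, 1))  # values unchanged
  # clamp at both ends
  seg3 <- data.frame(chrom = "chr1", start = 3000L, end = 99000L, cn = 2,
                     caller = "a")
  e3 <- expand_and_divide(seg3, pad = 5000,
                          chrom_lengths = c(chr1 = 100000))
  expect_equal(c(e3$start, e3$end), c(1L, 100000L))
  expect_error(
    expand_and_divide(data.frame(chrom = "chr1", start = c(1L, 4000L),
                                 end = c(5000L, 8000L), cn = 2,
                                 caller = "a"), 0),
    "overlapping raw segments")
})

test_that("per-base oracle agrees with expansion/division on random input", {
  set.seed(21)
  lens <- c(chr1 = 50000)
  for (i in 1:20) {
    segs <- random_segments(1, 50000L)
    pad <- sample(c(0L, 500L, 5000L), 1)
    e <- expand_and_divide(segs, pad, lens)
    got <- rep(NA_real_, 50000)
    for (j in seq_len(nrow(e))) got[e$start[j]:e$end[j]] <- e$cn[j]
    want <- oracle_cn_per_base(segs, pad, lens, NA_real_)$chr1
    expect_equal(got, want)
    # coverage conservation: division never changes the covered union
    covered <- rep(FALSE, 50000)
    for (j in seq_len(nrow(segs))) {
      covered[max(1, segs$start[j] - pad):min(50000, segs$end[j] + pad)] <- TRUE
    }
    got_cov <- rep(FALSE, 50000)
    for (j in seq_len(nrow(e))) got_cov[e$start[j]:e$end[j]] <- TRUE
    expect_equal(got_cov, covered)
  }
})

test_that("partition splits at every caller boundary with correct contributions", {
  segs <- data.frame(
    chrom = "chr1", start = c(1L, 5001L), end = c(10000L, 10000L),
    cn = c(4, 2), caller = c("A", "B"), stringsAsFactors = FALSE)
  p <- partition_segments(segs)
  expect_equal(p$intervals$start, c(1L, 5001L))
  expect_equal(p$intervals$end, c(5000L, 10000L))
  expect_equal(p$contrib[, "A"], c(4, 4))
  expect_equal(p$contrib[, "B"], c(NA_real_, 2))
  # single caller: intervals identical to its segments
  solo <- data.frame(chrom = "chr1", start = c(100L, 900L),
                     end = c(500L, 2000L), cn = c(1, 3), caller = "A")
  ps <- partition_segments(solo)
  covered <- ps$intervals[!is.na(ps$contrib[, "A"]), ]
  expect_equal(covered$start, solo$start)
  expect_equal(covered$end, solo$end)
  # identical segments from two callers share intervals
  two <- rbind(solo, transform(solo, caller = "B"))
  pt <- partition_segments(two)
  expect_equal(sum(!is.na(pt$contrib[, "A"]) & !is.na(pt$contrib[, "B"])), 2)
})

test_that("weighted consensus averages contributors and fills the default", {
  segs <- data.frame(
    chrom = "chr1", start = c(1L, 1L), end = c(10000L, 10000L),
    cn = c(4, 2), caller = c("A", "B"), stringsAsFactors = FALSE)
  p <- partition_segments(segs, chrom_lengths = c(chr1 = 20000))
  w <- weighted_consensus(p, cn_params(default_cn = 2))
  expect_equal(w$cn, c(3, 2))          # mean of {4,2}; default beyond
  expect_equal(w$n_callers, c(2L, 0L))
  solo <- partition_segments(segs[1, ], chrom_lengths = c(chr1 = 20000))
  expect_equal(weighted_consensus(solo, cn_params())$cn[1], 4)
})

test_that("pre-smoothing consensus equals the per-base oracle everywhere", {
  set.seed(33)
  for (i in 1:15) {
    lens <- c(chr1 = 60000)
    segs <- random_segments(sample(2:5, 1), 60000L)
    prm <- cn_params(pad = sample(c(0L, 1000L, 5000L), 1),
                     default_cn = 2, chrom_lengths = lens)
    res <- consensus_cn(segs, prm)
    got <- intervals_per_base(res$presmooth, lens)$chr1
    want <- oracle_cn_per_base(segs, prm$pad, lens, 2)$chr1
    expect_equal(got, want)
  }
})

test_that("smoothing merges within tolerance and conserves CN mass", {
  iv <- structure(data.frame(
    chrom = "chr1", start = c(1L, 101L), end = c(100L, 200L),
    cn = c(3, 3.05), n_callers = c(2L, 3L)),
    class = c("cn_intervals", "data.frame"))
  sm <- smooth_intervals(iv, 0.1)
  expect_equal(nrow(sm), 1)
  expect_equal(sm$cn, 3.025)
  expect_equal(sm$n_callers, 2L)  # floor of length-weighted mean 2.5
  # beyond tolerance: untouched
  iv$cn <- c(2, 4)
  expect_equal(smooth_intervals(iv, 0.1)$cn, c(2, 4))
  # zero tolerance still merges exact ties
  iv$cn <- c(2, 2)
  expect_equal(nrow(smooth_intervals(iv, 0)), 1)
  # mass conservation on a random profile
  set.seed(4)
  segs <- random_segments(4, 80000L)
  res <- consensus_cn(segs, cn_params(chrom_lengths = c(chr1 = 80000)))
  mass <- function(d) sum((d$end - d$start + 1) * d$cn)
  expect_equal(mass(res$intervals), mass(res$presmooth), tolerance = 1e-12)
  # smoothed profile reaches a fixed point
  again <- smooth_intervals(res$intervals, 0.1)
  expect_equal(as.data.frame(again), as.data.frame(res$intervals))
})

test_that("bias and volatility follow the weighted formulas and scaling", {
  segs <- data.frame(
    chrom = "chr1", start = 1L, end = 10000L, cn = c(4, 2),
    caller = c("A", "B"), stringsAsFactors = FALSE)
  pre <- weighted_consensus(partition_segments(segs), cn_params())
  conc <- caller_concordance(pre)
  expect_equal(conc$bias[conc$caller == "A"], 1)
  expect_equal(conc$bias[conc$caller == "B"], -1)
  expect_equal(conc$volatility, c(0, 0))
  expect_equal(conc$volatility_scaled, c(0, 0))  # all tie -> 0
  # a caller alone is its own consensus
  solo <- weighted_consensus(partition_segments(segs[1, ]), cn_params())
  sc <- caller_concordance(solo)
  expect_equal(sc$bias, 0)
  expect_equal(sc$volatility, 0)
  # three callers with distinct |bias| scale to {0, mid, 1}
  tri <- data.frame(chrom = "chr1", start = 1L, end = 10000L,
                    cn = c(2, 3, 7), caller = c("A", "B", "C"))
  tc <- caller_concordance(
    weighted_consensus(partition_segments(tri), cn_params()))
  expect_equal(sort(tc$bias_scaled), c(0, 0.5, 1))
  expect_true(all(tc$bias_scaled >= 0 & tc$bias_scaled <= 1))
})

test_that("the full pipeline handles empty and perfectly agreeing input", {
  lens <- c(chr1 = 50000, chr2 = 30000)
  none <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), cn = numeric(0),
                     caller = character(0))
  res <- consensus_cn(none, cn_params(chrom_lengths = lens))
  expect_equal(nrow(res$intervals), 2)         # one default interval per chrom
  expect_equal(unique(res$intervals$cn), 2)
  expect_equal(nrow(res$concordance), 0)
  expect_error(consensus_cn(none, cn_params()), "chrom_lengths")
  # five identical callers: consensus equals input, all biases zero
  base <- data.frame(chrom = "chr1", start = c(1L, 20001L),
                     end = c(20000L, 50000L), cn = c(3, 1), caller = "x")
  segs <- do.call(rbind, lapply(paste0("c", 1:5), function(ca)
    transform(base, caller = ca)))
  res5 <- consensus_cn(segs, cn_params(pad = 0,
                                       chrom_lengths = c(chr1 = 50000)))
  expect_equal(res5$concordance$bias, rep(0, 5))
  expect_equal(res5$concordance$volatility, rep(0, 5))
  pb <- intervals_per_base(res5$presmooth, c(chr1 = 50000))$chr1
  expect_equal(pb, rep(c(3, 1), c(20000, 30000)))
})

test_that("increasing pad never shrinks the covered genome", {
  set.seed(55)
  segs <- random_segments(3, 40000L)
  lens <- c(chr1 = 40000)
  covered_len <- function(pad) {
    res <- consensus_cn(segs, cn_params(pad = pad, chrom_lengths = lens))
    sum((res$presmooth$end - res$presmooth$start + 1)[
      res$presmooth$n_callers > 0])
  }
  lens_by_pad <- vapply(c(0, 100, 1000, 5000), covered_len, numeric(1))
  expect_true(all(diff(lens_by_pad) >= 0))
})
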