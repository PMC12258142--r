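test_that("truth generation is reproducible and respects spacing", {
  cfg <- sim_config(seed = 101, n_sv = 50)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$sv), 50)
  # all breakends on one chromosome sit > 2 * window apart
  pos <- sort(c(t1$sv$pos1, t1$sv$pos2))
  expect_true(all(diff(pos) > 2 * cfg$window))
  # truth CN covers the chromosome contiguously
  cn <- t1$cn[order(t1$cn$start), ]
  expect_equal(cn$start[1], 1L)
  expect_equal(cn$end[nrow(cn)], as.integer(cfg$chrom_lengths[[1]]))
  expect_true(all(cn$start[-1] == cn$end[-nrow(cn)] + 1))
  expect_equal(nrow(generate_truth(sim_config(seed = 1, n_sv = 0))$sv), 0)
})

test_that("infeasible breakend packing is an explicit error", {
  cfg <- sim_config(seed = 1, n_sv = 40, chrom_lengths = c(chr1 = 1e4))
  expect_error(generate_truth(cfg), "cannot place")
})

test_that("translocations require a second chromosome", {
  expect_error(sim_config(sv_type_mix = c(DEL = 0.5, TRA = 0.5)),
               "two chromosomes")
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                    sv_type_mix = c(DEL = 0.5, TRA = 0.5), n_sv = 40,
                    seed = 3)
  truth <- generate_truth(cfg)
  expect_true(any(truth$sv$svtype == "TRA"))
})

test_that("a noise-free caller reproduces the truth exactly", {
  cfg <- sim_config(seed = 5, n_sv = 30,
                    callers = list(caller_profile(
                      "perfect", jitter_sd = 0, fn_rate = 0, fp_rate = 0,
                      cn_boundary_jitter_sd = 0, cn_value_noise_sd = 0)))
  sim <- simulate_callers(cfg)
  out <- sim$callers$perfect
  cols <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
            "svtype")
  expect_equal(as.data.frame(out$sv)[cols],
               as.data.frame(sim$truth$sv)[cols])
  expect_equal(out$cn[c("chrom", "start", "end", "cn")],
               sim$truth$cn[c("chrom", "start", "end", "cn")])
})

test_that("fn_rate 1 silences a caller's SV output", {
  cfg <- sim_config(seed = 5, n_sv = 30,
                    callers = list(caller_profile("mute", fn_rate = 1,
                                                  fp_rate = 0)))
  expect_equal(nrow(simulate_callers(cfg)$callers$mute$sv), 0)
})

test_that("caller substreams are independent of the panel composition", {
  profs <- lapply(paste0("caller", 1:3), caller_profile)
  a <- simulate_callers(sim_config(seed = 9, callers = profs))
  b <- simulate_callers(sim_config(seed = 9, callers = profs[1:2]))
  expect_identical(a$callers$caller1, b$callers$caller1)
  expect_identical(a$callers$caller2, b$callers$caller2)
})

test_that("simulated caller CN stays a disjoint cover of the chromosome", {
  cfg <- sim_config(seed = 17)
  sim <- simulate_callers(cfg)
  for (cal in sim$callers) {
    cn <- cal$cn[order(cal$cn$start), ]
    expect_equal(cn$start[1], 1L)
    expect_equal(cn$end[nrow(cn)], as.integer(cfg$chrom_lengths[[1]]))
    expect_true(all(cn$start[-1] == cn$end[-nrow(cn)] + 1))
    expect_true(all(cn$cn >= 0))
  }
})

test_that("evaluation metrics match hand counts on a planted instance", {
  truth <- canonicalize_pairs(sv_pairs(
    rep("chr1", 3), c(1000L, 5000L, 9000L), "+",
    rep("chr1", 3), c(2000L, 6000L, 10000L), "-"))
  # two recovered (one jittered 10 bp), one missed, one planted FP
  cons <- canonicalize_pairs(sv_pairs(
    rep("chr1", 3), c(1010L, 5000L, 40000L), "+",
    rep("chr1", 3), c(2000L, 6000L, 50000L), "-"))
  ev <- evaluate_consensus(cons, truth, match_window = 150)
  expect_equal(ev$tp, 2L)
  expect_equal(ev$fp, 1L)
  expect_equal(ev$fn, 1L)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 2 / 3)
  expect_equal(ev$mean_offset, mean(c(5, 0)))  # (10+0)/2 and (0+0)/2
  # conventions on empty sets
  empty <- truth[0, ]
  expect_equal(evaluate_consensus(empty, truth)$precision, 1)
  expect_equal(evaluate_consensus(empty, truth)$recall, 0)
})

test_that("simulation files round-trip through the real readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 23, n_sv = 25)
  sim <- simulate_callers(cfg)
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_sv_bedpe(paths[["caller1_sv"]], "caller1",
                        rank = names(cfg$chrom_lengths))
  cols <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
            "svtype")
  expect_equal(as.data.frame(back)[cols],
               as.data.frame(sim$callers$caller1$sv)[cols])
  seg <- read_segments(paths[["caller1_cn"]], "caller1")
  expect_equal(as.data.frame(seg)[c("chrom", "start", "end")],
               sim$callers$caller1$cn[c("chrom", "start", "end")])
  expect_equal(seg$cn, sim$callers$caller1$cn$cn, tolerance = 1e-5)
})

test_that("consensus position error never exceeds the worst member error", {
  cfg <- sim_config(seed = 31)
  sim <- simulate_callers(cfg)
  cons <- merge_svs(lapply(sim$callers, `[[`, "sv"),
                    merge_params(), rank = names(cfg$chrom_lengths))
  members <- attr(cons, "members")
  truth <- sim$truth$sv
  for (i in seq_len(nrow(cons))) {
    hit <- which(truth$strand1 == cons$strand1[i] &
                   truth$strand2 == cons$strand2[i] &
                   abs(truth$pos1 - cons$pos1[i]) <= 150 &
                   abs(truth$pos2 - cons$pos2[i]) <= 150)
    if (!length(hit)) next
    mem <- members[members$cluster == cons$cluster[i], ]
    worst <- max(abs(mem$pos1 - truth$pos1[hit]),
                 abs(mem$pos2 - truth$pos2[hit]))
    err <- max(abs(cons$pos1[i] - truth$pos1[hit]),
               abs(cons$pos2[i] - truth$pos2[hit]))
    expect_lte(err, worst)
  }
})

test_that("noise-free CN panels recover truth away from boundaries", {
  profs <- lapply(paste0("c", 1:4), caller_profile,
                  cn_value_noise_sd = 0, cn_boundary_jitter_sd = 500)
  cfg <- sim_config(seed = 41, callers = profs,
                    chrom_lengths = c(chr1 = 2e5), n_cn_segments = 4)
  sim <- simulate_callers(cfg)
  segs <- do.call(rbind, lapply(sim$callers, `[[`, "cn"))
  prm <- cn_params(chrom_lengths = cfg$chrom_lengths)
  res <- consensus_cn(segs, prm)
  got <- intervals_per_base(res$presmooth, cfg$chrom_lengths)$chr1
  truth_pb <- intervals_per_base(sim$truth$cn, cfg$chrom_lengths)$chr1
  # interior bases: farther than pad + boundary jitter from a truth bound
  guard <- prm$pad + 4 * 500
  bounds <- c(1, sim$truth$cn$end, cfg$chrom_lengths[[1]])
  dist <- vapply(seq_along(got), function(b) min(abs(b - bounds)),
                 numeric(1))
  interior <- dist > guard
  expect_true(any(interior))
  expect_equal(got[interior], truth_pb[interior])
})
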