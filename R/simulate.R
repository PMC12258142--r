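# sample() treats a length-1 numeric as 1:x; these helpers never do.
sample1 <- function(x) x[sample.int(length(x), 1)]
shuffle <- function(x) x[sample.int(length(x))]

# Derived substream seed: one root seed plus a purpose label, so adding a
# caller never perturbs the randomness of another stream. Kept < 2^31 - 1.
substream_seed <- function(root, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(root) + h) %% 2147483647)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulated caller error profile
#'
#' Describes how one synthetic caller corrupts the shared truth: breakend
#' positional jitter, missed calls, caller-private false calls, and
#' copy-number boundary/value noise.
#'
#' @param name Caller id.
#' @param jitter_sd SD, in bp, of Gaussian breakend jitter (rounded to
#'   integer offsets; default 20).
#' @param fn_rate Probability of missing a truth SV (default 0.1).
#' @param fp_rate Expected private false calls per truth SV (default 0.2).
#' @param cn_boundary_jitter_sd SD, in bp, of CN segment boundary jitter
#'   (default 1000).
#' @param cn_value_noise_sd SD, in CN units, of CN value noise
#'   (default 0.1).
#' @return A list of class `caller_profile`.
#' @export
caller_profile <- function(name, jitter_sd = 20, fn_rate = 0.1,
                           fp_rate = 0.2, cn_boundary_jitter_sd = 1000,
                           cn_value_noise_sd = 0.1) {
  stopifnot(nzchar(name), jitter_sd >= 0, fn_rate >= 0, fn_rate <= 1,
            fp_rate >= 0, cn_boundary_jitter_sd >= 0,
            cn_value_noise_sd >= 0)
  structure(list(name = name, jitter_sd = jitter_sd, fn_rate = fn_rate,
                 fp_rate = fp_rate,
                 cn_boundary_jitter_sd = cn_boundary_jitter_sd,
                 cn_value_noise_sd = cn_value_noise_sd),
            class = "caller_profile")
}

#' Simulation configuration
#'
#' Defines the genome, the truth set and the panel of simulated callers.
#' Truth SV breakends are spaced more than `2 * window` apart so clusters
#' are unambiguous at the merge window.
#'
#' @param seed Root seed; all randomness flows from it via named
#'   substreams (truth, per-caller SV, per-caller CN).
#' @param chrom_lengths Named chromosome lengths (default one 10 Mb
#'   chromosome).
#' @param n_sv Number of truth SVs (default 100).
#' @param sv_type_mix Named proportions over DEL/DUP/INV/TRA summing to 1;
#'   TRA requires at least two chromosomes (default DEL .4 / DUP .3 /
#'   INV .3).
#' @param n_cn_segments Total truth CN segments across the genome
#'   (default 20).
#' @param cn_values Permitted truth CN states (default 0:4 and 6).
#' @param callers List of [caller_profile()]s (default six callers with
#'   profile defaults).
#' @param window Merge window the truth spacing guards (default 150).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1e7),
                       n_sv = 100L,
                       sv_type_mix = c(DEL = 0.4, DUP = 0.3, INV = 0.3,
                                       TRA = 0),
                       n_cn_segments = 20L,
                       cn_values = c(0, 1, 2, 3, 4, 6),
                       callers = lapply(paste0("caller", 1:6),
                                        caller_profile),
                       window = 150L) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0),
            n_sv >= 0, n_cn_segments >= 1,
            all(names(sv_type_mix) %in% c("DEL", "DUP", "INV", "TRA")),
            abs(sum(sv_type_mix) - 1) < 1e-9, all(sv_type_mix >= 0),
            length(callers) >= 1, all(cn_values >= 0))
  mix <- c(DEL = 0, DUP = 0, INV = 0, TRA = 0)
  mix[names(sv_type_mix)] <- sv_type_mix
  if (mix[["TRA"]] > 0 && length(chrom_lengths) < 2) {
    stop("translocations need at least two chromosomes", call. = FALSE)
  }
  stopifnot(all(vapply(callers, inherits, logical(1), "caller_profile")))
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_sv = as.integer(n_sv), sv_type_mix = mix,
                 n_cn_segments = as.integer(n_cn_segments),
                 cn_values = cn_values, callers = callers,
                 window = as.integer(window)),
            class = "sim_config")
}

# k positions in [1, len], pairwise gaps > min_gap, uniform given spacing.
spaced_positions <- function(k, len, min_gap) {
  if (k == 0) return(integer(0))
  slack <- len - (k - 1) * (min_gap + 1) - 1
  if (slack < k) {
    stop("cannot place ", k, " breakends with spacing > ", min_gap,
         " bp on a ", len, " bp chromosome", call. = FALSE)
  }
  base <- sort(sample.int(slack, k))
  as.integer(base + (0:(k - 1)) * (min_gap + 1))
}

#' Generate the shared truth set
#'
#' Draws `n_sv` truth SVs (types per the configured mix, breakends
#' uniform subject to pairwise separation greater than `2 * window`) and a
#' piecewise-constant truth copy-number profile covering every chromosome,
#' with no two adjacent truth segments sharing a CN state. Fully
#' reproducible from the configuration seed.
#'
#' @param config [sim_config()].
#' @return List with elements `sv` (canonical `sv_pairs`, caller
#'   `"truth"`) and `cn` (segment data frame, caller `"truth"`).
#' @export
generate_truth <- function(config) {
  chroms <- names(config$chrom_lengths)
  rank <- chroms
  with_seed(substream_seed(config$seed, "truth"), {
    types <- if (config$n_sv > 0) {
      sample(names(config$sv_type_mix), config$n_sv, replace = TRUE,
             prob = config$sv_type_mix)
    } else character(0)
    # how many breakends each chromosome must host
    need <- stats::setNames(integer(length(chroms)), chroms)
    placement <- vector("list", config$n_sv)
    for (i in seq_along(types)) {
      if (types[i] == "TRA") {
        cs <- sample(chroms, 2, prob = config$chrom_lengths)
        placement[[i]] <- cs
        need[cs] <- need[cs] + 1L
      } else {
        cs <- sample(chroms, 1, prob = config$chrom_lengths)
        placement[[i]] <- c(cs, cs)
        need[cs] <- need[cs] + 2L
      }
    }
    pool <- lapply(chroms, function(ch) {
      shuffle(spaced_positions(need[[ch]], config$chrom_lengths[[ch]],
                               2L * config$window))
    })
    names(pool) <- chroms
    take <- stats::setNames(integer(length(chroms)), chroms)
    draw <- function(ch) {
      take[ch] <<- take[ch] + 1L
      pool[[ch]][take[ch]]
    }
    rows <- lapply(seq_along(types), function(i) {
      cs <- placement[[i]]
      p <- c(draw(cs[1]), draw(cs[2]))
      strands <- switch(types[i],
        DEL = c("+", "-"), DUP = c("-", "+"),
        INV = rep(sample(c("+", "-"), 1), 2),
        TRA = sample(c("+", "-"), 2, replace = TRUE))
      sv_pairs(cs[1], p[1], strands[1], cs[2], p[2], strands[2],
               caller = "truth")
    })
    sv <- if (length(rows)) {
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    } else {
      empty_sv_pairs()
    }
    class(sv) <- c("sv_pairs", "data.frame")
    sv <- canonicalize_pairs(sv, rank)

    # truth CN: allocate segments to chromosomes by length (>= 1 each)
    total_len <- sum(config$chrom_lengths)
    alloc <- pmax(round(config$n_cn_segments *
                          config$chrom_lengths / total_len), 1L)
    cn_rows <- lapply(chroms, function(ch) {
      len <- config$chrom_lengths[[ch]]
      k <- alloc[[ch]]
      bounds <- if (k > 1) sort(sample.int(len - 1, k - 1)) else integer(0)
      start <- c(1L, bounds + 1L)
      end <- c(bounds, as.integer(len))
      cn <- numeric(k)
      cn[1] <- sample1(config$cn_values)
      for (j in seq_len(k - 1)) {
        cn[j + 1] <- sample1(setdiff(config$cn_values, cn[j]))
      }
      data.frame(chrom = ch, start = start, end = end, cn = cn,
                 caller = "truth", stringsAsFactors = FALSE)
    })
    cn <- do.call(rbind, c(cn_rows, list(make.row.names = FALSE)))
    list(sv = sv, cn = cn)
  })
}

#' Simulate one caller's output from the truth
#'
#' Each truth SV is missed with probability `fn_rate`; survivors receive
#' independent integer Gaussian jitter on each breakend. A
#' `Poisson(fp_rate * n_sv)` number of caller-private false SVs is placed
#' with every breakend more than `2 * window` away from any truth
#' breakend. CN segment boundaries are jittered and re-disjointified and
#' values perturbed (clamped at 0). Randomness comes from the caller's
#' named substreams of the root seed.
#'
#' @param truth Output of [generate_truth()].
#' @param profile [caller_profile()].
#' @param config [sim_config()].
#' @return List with `sv` (canonical `sv_pairs`) and `cn` (segments), both
#'   carrying the profile's caller id.
#' @export
simulate_caller <- function(truth, profile, config) {
  chroms <- names(config$chrom_lengths)
  rank <- chroms
  clamp <- function(p, ch) {
    pmin(pmax(p, 1L), as.integer(config$chrom_lengths[ch]))
  }
  sv <- with_seed(substream_seed(config$seed,
                                 paste0("caller:", profile$name, ":sv")), {
    tsv <- truth$sv
    keep <- stats::runif(nrow(tsv)) >= profile$fn_rate
    tsv <- tsv[keep, , drop = FALSE]
    if (nrow(tsv)) {
      tsv$pos1 <- clamp(tsv$pos1 +
        as.integer(round(stats::rnorm(nrow(tsv), 0, profile$jitter_sd))),
        tsv$chrom1)
      tsv$pos2 <- clamp(tsv$pos2 +
        as.integer(round(stats::rnorm(nrow(tsv), 0, profile$jitter_sd))),
        tsv$chrom2)
    }
    n_fp <- stats::rpois(1, profile$fp_rate * nrow(truth$sv))
    fp_rows <- list()
    if (n_fp > 0) {
      guard <- 2L * config$window
      truth_bnd <- split(c(truth$sv$pos1, truth$sv$pos2),
                         c(truth$sv$chrom1, truth$sv$chrom2))
      draw_pos <- function(ch) {
        # rejection sample a position clear of every truth breakend
        repeat {
          p <- sample.int(config$chrom_lengths[[ch]], 1)
          tb <- truth_bnd[[ch]]
          if (is.null(tb) || all(abs(p - tb) > guard)) return(p)
        }
      }
      mix <- config$sv_type_mix
      if (length(chroms) < 2) mix[["TRA"]] <- 0
      for (i in seq_len(n_fp)) {
        type <- sample(names(mix), 1, prob = mix)
        if (type == "TRA") {
          cs <- sample(chroms, 2, prob = config$chrom_lengths)
          p <- c(draw_pos(cs[1]), draw_pos(cs[2]))
        } else {
          cs <- rep(sample(chroms, 1, prob = config$chrom_lengths), 2)
          repeat {
            p <- c(draw_pos(cs[1]), draw_pos(cs[2]))
            if (abs(p[1] - p[2]) > 2L * config$window) break
          }
        }
        strands <- switch(type,
          DEL = c("+", "-"), DUP = c("-", "+"),
          INV = rep(sample(c("+", "-"), 1), 2),
          TRA = sample(c("+", "-"), 2, replace = TRUE))
        fp_rows[[i]] <- sv_pairs(cs[1], p[1], strands[1],
                                 cs[2], p[2], strands[2],
                                 caller = profile$name)
      }
    }
    out <- do.call(rbind, c(list(tsv), fp_rows,
                            list(make.row.names = FALSE)))
    if (nrow(out)) out$caller <- profile$name
    class(out) <- c("sv_pairs", "data.frame")
    canonicalize_pairs(out, rank)
  })
  cn <- with_seed(substream_seed(config$seed,
                                 paste0("caller:", profile$name, ":cn")), {
    rows <- lapply(chroms, function(ch) {
      d <- truth$cn[truth$cn$chrom == ch, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      len <- as.integer(config$chrom_lengths[[ch]])
      k <- nrow(d)
      if (k == 0) return(NULL)
      bounds <- d$end[-k]
      if (k > 1 && profile$cn_boundary_jitter_sd > 0) {
        bounds <- bounds + as.integer(
          round(stats::rnorm(k - 1, 0, profile$cn_boundary_jitter_sd)))
        bounds <- pmin(pmax(bounds, 1L), len - 1L)
        bounds <- sort(bounds)
        # re-disjointify: enforce strictly increasing boundaries
        for (j in seq_len(k - 1)[-1]) {
          if (bounds[j] <= bounds[j - 1]) bounds[j] <- bounds[j - 1] + 1L
        }
        bounds <- pmin(bounds, len - 1L)
        bounds <- unique(bounds)
      }
      kk <- length(bounds) + 1L
      cnv <- d$cn[seq_len(kk)]
      if (profile$cn_value_noise_sd > 0) {
        cnv <- pmax(0, cnv + stats::rnorm(kk, 0, profile$cn_value_noise_sd))
      }
      data.frame(chrom = ch, start = c(1L, bounds + 1L),
                 end = c(bounds, len), cn = cnv, caller = profile$name,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  list(sv = sv, cn = cn)
}

#' Simulate the full multi-caller panel
#'
#' @param config [sim_config()].
#' @return List with `truth` and `callers` (named list of per-caller
#'   `list(sv, cn)`).
#' @export
simulate_callers <- function(config) {
  truth <- generate_truth(config)
  callers <- lapply(config$callers, simulate_caller, truth = truth,
                    config = config)
  names(callers) <- vapply(config$callers, `[[`, character(1), "name")
  list(truth = truth, callers = callers)
}

#' Write a simulation to disk through the real writers
#'
#' Per caller, a BEDPE of SV calls and a TSV of CN segments; plus
#' `truth_sv.bedpe` and `truth_cn.tsv`. Exercises the same writers (and,
#' on re-import, readers) as real data.
#'
#' @param sim Output of [simulate_callers()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a named vector of written paths.
#' @export
write_simulation <- function(sim, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  seg_out <- function(seg, path) {
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(c("chrom\tstart\tend\tcn",
                 sprintf("%s\t%d\t%d\t%.6g", seg$chrom,
                         as.integer(seg$start), as.integer(seg$end),
                         seg$cn)), con)
  }
  p <- file.path(outdir, "truth_sv.bedpe")
  write_sv_bedpe(sim$truth$sv, p)
  written["truth_sv"] <- p
  p <- file.path(outdir, "truth_cn.tsv")
  seg_out(sim$truth$cn, p)
  written["truth_cn"] <- p
  for (nm in names(sim$callers)) {
    p <- file.path(outdir, paste0(nm, "_sv.bedpe"))
    write_sv_bedpe(sim$callers[[nm]]$sv, p)
    written[paste0(nm, "_sv")] <- p
    p <- file.path(outdir, paste0(nm, "_cn.tsv"))
    seg_out(sim$callers[[nm]]$cn, p)
    written[paste0(nm, "_cn")] <- p
  }
  invisible(written)
}

#' Score a consensus set against the truth
#'
#' Greedy one-to-one matching: consensus SVs, in sorted order, claim the
#' nearest unmatched truth SV with equal chromosomes and orientations and
#' both breakend offsets within `match_window`. Precision on an empty
#' consensus set is defined as 1 (no false calls were made); recall on an
#' empty truth set is 1.
#'
#' @param consensus `consensus_sv` (or `sv_pairs`) table.
#' @param truth Canonical `sv_pairs` truth table.
#' @param match_window Max per-breakend offset, in bp, for a match.
#' @return List: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `mean_offset` (mean absolute breakend offset over matches; `NaN` when
#'   there are none).
#' @export
evaluate_consensus <- function(consensus, truth, match_window = 150) {
  n_c <- nrow(consensus)
  n_t <- nrow(truth)
  matched_t <- rep(FALSE, n_t)
  offsets <- numeric(0)
  tp <- 0L
  for (i in seq_len(n_c)) {
    cand <- which(!matched_t &
                    truth$chrom1 == consensus$chrom1[i] &
                    truth$chrom2 == consensus$chrom2[i] &
                    truth$strand1 == consensus$strand1[i] &
                    truth$strand2 == consensus$strand2[i] &
                    abs(truth$pos1 - consensus$pos1[i]) <= match_window &
                    abs(truth$pos2 - consensus$pos2[i]) <= match_window)
    if (!length(cand)) next
    d <- (abs(truth$pos1[cand] - consensus$pos1[i]) +
            abs(truth$pos2[cand] - consensus$pos2[i]))
    j <- cand[which.min(d)]
    matched_t[j] <- TRUE
    tp <- tp + 1L
    offsets <- c(offsets,
                 (abs(truth$pos1[j] - consensus$pos1[i]) +
                    abs(truth$pos2[j] - consensus$pos2[i])) / 2)
  }
  precision <- if (n_c == 0) 1 else tp / n_c
  recall <- if (n_t == 0) 1 else tp / n_t
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(tp = tp, fp = n_c - tp, fn = n_t - tp, precision = precision,
       recall = recall, f1 = f1, mean_offset = mean(offsets))
}
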