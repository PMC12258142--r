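#' Parameters for the consensus copy-number pipeline
#'
#' @param pad Expansion, in bp, applied upstream and downstream of every
#'   caller segment before intersection (default 5000).
#' @param smooth_tol Maximum copy-number difference, in CN units, between
#'   adjacent consensus intervals for them to be merged during smoothing
#'   (default 0.1).
#' @param default_cn Copy number assigned to genome not covered by any
#'   caller (default 2, the diploid state).
#' @param chrom_lengths Named numeric vector of chromosome lengths used to
#'   clamp expansion and to emit uncovered intervals; when `NULL`, each
#'   chromosome's extent is taken as `[1, max(end)]` over its segments.
#' @return A list of class `cn_params`.
#' @export
cn_params <- function(pad = 5000, smooth_tol = 0.1, default_cn = 2,
                      chrom_lengths = NULL) {
  stopifnot(pad >= 0, smooth_tol >= 0, default_cn >= 0)
  structure(list(pad = as.integer(pad), smooth_tol = smooth_tol,
                 default_cn = default_cn, chrom_lengths = chrom_lengths),
            class = "cn_params")
}

#' Expand caller segments and divide same-caller overlaps equally
#'
#' Every segment of one caller grows by `pad` bp on each side (clamped to
#' `[1, chrom_length]`). Where the expansions of two neighbouring segments
#' of the same caller overlap, the overlap is divided equally at its
#' integer midpoint: the left segment keeps bases up to
#' `floor((ov_start + ov_end) / 2)`, the right segment starts one base
#' later. Copy-number values are unchanged; the output is disjoint and
#' sorted, and its union equals the union of the unclamped expansions
#' intersected with the chromosome.
#'
#' @param segments Data frame with columns `chrom, start, end, cn, caller`
#'   (1-based inclusive); per caller and chromosome the raw segments must
#'   be disjoint.
#' @param pad Expansion in bp.
#' @param chrom_lengths Optional named lengths for clamping.
#' @return Data frame of the same shape, expanded and divided.
#' @export
#' @examples
#' seg <- data.frame(chrom = "chr1", start = c(1, 12000), end = c(10000, 20000),
#'                   cn = c(3, 1), caller = "cnvkit")
#' expand_and_divide(seg, pad = 5000)  # splits at 11000/11001
expand_and_divide <- function(segments, pad = 5000, chrom_lengths = NULL) {
  if (nrow(segments) == 0) return(segments)
  pieces <- split(segments,
                  list(segments$caller, segments$chrom), drop = TRUE)
  out <- lapply(pieces, function(s) {
    s <- s[order(s$start), , drop = FALSE]
    if (any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("overlapping raw segments for caller ", s$caller[1],
           " on ", s$chrom[1], call. = FALSE)
    }
    len <- chrom_lengths[[s$chrom[1]]]
    # divide on the unclamped expansions (pads cancel, so every base ends
    # up on the side of its nearer raw segment), then clamp to the
    # chromosome; a segment pushed wholly past the end vanishes
    start <- as.integer(s$start) - as.integer(pad)
    end <- as.integer(s$end) + as.integer(pad)
    n <- nrow(s)
    if (n > 1) {
      for (i in 2:n) {
        if (start[i] <= end[i - 1]) {
          mid <- (start[i] + end[i - 1]) %/% 2L
          end[i - 1] <- mid
          start[i] <- mid + 1L
        }
      }
    }
    start <- pmax(start, 1L)
    if (!is.null(len)) end <- pmin(end, as.integer(len))
    keep <- start <= end
    data.frame(chrom = s$chrom[keep], start = start[keep], end = end[keep],
               cn = s$cn[keep], caller = s$caller[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Partition expanded segments at every caller boundary
#'
#' Per chromosome, the union of all callers' segment starts and `end + 1`
#' positions defines interval boundaries; consecutive boundaries delimit
#' consensus alteration sites over which every covering caller's copy
#' number is constant. Genome not covered by any caller is emitted as
#' intervals with no contributions (over `[1, chrom_length]` when lengths
#' are supplied, else up to the last covered base).
#'
#' @param segments Expanded, per-caller-disjoint segment table.
#' @param chrom_lengths Optional named chromosome lengths.
#' @return List of class `cn_partition`: `intervals` (chrom, start, end)
#'   and `contrib`, a numeric matrix (interval x caller) with `NA` where a
#'   caller has no segment.
#' @export
partition_segments <- function(segments, chrom_lengths = NULL) {
  callers <- sort(unique(segments$caller))
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    unique(segments$chrom)
  res_int <- list()
  res_mat <- list()
  for (chrom in chroms) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    len <- chrom_lengths[[chrom]]
    if (nrow(s) == 0) {
      if (is.null(len)) next
      iv <- data.frame(chrom = chrom, start = 1L, end = as.integer(len))
      res_int[[chrom]] <- iv
      res_mat[[chrom]] <- matrix(NA_real_, 1, length(callers),
                                 dimnames = list(NULL, callers))
      next
    }
    ir <- IRanges::IRanges(s$start, s$end)
    dj <- IRanges::disjoin(ir)
    span_end <- if (is.null(len)) max(s$end) else as.integer(len)
    gaps <- IRanges::gaps(IRanges::reduce(ir), start = 1L, end = span_end)
    allr <- c(dj, gaps)
    allr <- allr[order(IRanges::start(allr))]
    mat <- matrix(NA_real_, length(allr), length(callers),
                  dimnames = list(NULL, callers))
    for (k in seq_along(callers)) {
      sk <- which(s$caller == callers[k])
      if (!length(sk)) next
      hits <- IRanges::findOverlaps(allr, ir[sk])
      q <- S4Vectors::queryHits(hits)
      if (anyDuplicated(q)) {
        stop("caller ", callers[k], " is not disjoint on ", chrom,
             call. = FALSE)
      }
      mat[q, k] <- s$cn[sk][S4Vectors::subjectHits(hits)]
    }
    res_int[[chrom]] <- data.frame(chrom = chrom,
                                   start = IRanges::start(allr),
                                   end = IRanges::end(allr),
                                   stringsAsFactors = FALSE)
    res_mat[[chrom]] <- mat
  }
  intervals <- do.call(rbind, c(res_int, list(make.row.names = FALSE)))
  if (is.null(intervals)) {
    intervals <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0))
  }
  rownames(intervals) <- NULL
  contrib <- do.call(rbind, res_mat)
  if (is.null(contrib)) {
    contrib <- matrix(NA_real_, 0, length(callers),
                      dimnames = list(NULL, callers))
  }
  structure(list(intervals = intervals, contrib = contrib),
            class = "cn_partition")
}

#' Proportion-weighted consensus copy number per interval
#'
#' On each partition interval every contributing caller is constant, so the
#' proportion-weighted genome-wide average reduces to the arithmetic mean
#' of the contributing callers' values per interval; this equals the
#' per-base mean over covering callers at every base, which is the
#' normative contract tested against a per-base oracle. Intervals covered
#' by no caller receive `default_cn` with `n_callers = 0`.
#'
#' @param part A `cn_partition`.
#' @param params [cn_params()].
#' @return Data frame of class `cn_intervals` with columns `chrom, start,
#'   end, cn, n_callers` and the contribution matrix kept in attribute
#'   `"contrib"` (used by [caller_concordance()]).
#' @export
weighted_consensus <- function(part, params = cn_params()) {
  iv <- part$intervals
  m <- part$contrib
  n_callers <- if (ncol(m)) as.integer(rowSums(!is.na(m))) else
    rep(0L, nrow(iv))
  cn <- rep(params$default_cn, nrow(iv))
  has <- n_callers > 0L
  if (any(has)) cn[has] <- rowMeans(m[has, , drop = FALSE], na.rm = TRUE)
  out <- cbind(iv, data.frame(cn = cn, n_callers = n_callers))
  rownames(out) <- NULL
  class(out) <- c("cn_intervals", "data.frame")
  attr(out, "contrib") <- m
  out
}

#' Smooth a consensus copy-number profile
#'
#' Adjacent intervals on one chromosome (`end + 1 == next start`) whose
#' consensus copy numbers differ by at most `smooth_tol` are merged into
#' one interval carrying their length-weighted mean CN; merging repeats
#' left-to-right until no further pair qualifies. Each merge conserves
#' the total of length x CN exactly (up to floating arithmetic). Per-caller
#' contributions are dropped; `n_callers` is summarized as the
#' length-weighted mean rounded down.
#'
#' @param x A `cn_intervals` table.
#' @param smooth_tol Tolerance in CN units.
#' @return Smoothed `cn_intervals` (no `"contrib"` attribute).
#' @export
smooth_intervals <- function(x, smooth_tol = 0.1) {
  if (nrow(x) == 0) return(x)
  res <- lapply(split(seq_len(nrow(x)), x$chrom)[unique(x$chrom)],
                function(rows) {
    d <- x[rows, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    len <- as.numeric(d$end - d$start + 1)
    repeat {
      merged <- FALSE
      out <- list()
      cur <- list(start = d$start[1], end = d$end[1],
                  mass = len[1] * d$cn[1], nmass = len[1] * d$n_callers[1],
                  len = len[1], cn = d$cn[1])
      i <- 2L
      while (i <= nrow(d)) {
        adjacent <- d$start[i] == cur$end + 1
        if (adjacent && abs(d$cn[i] - cur$cn) <= smooth_tol) {
          cur$end <- d$end[i]
          cur$mass <- cur$mass + len[i] * d$cn[i]
          cur$nmass <- cur$nmass + len[i] * d$n_callers[i]
          cur$len <- cur$len + len[i]
          cur$cn <- cur$mass / cur$len
          merged <- TRUE
        } else {
          out[[length(out) + 1L]] <- cur
          cur <- list(start = d$start[i], end = d$end[i],
                      mass = len[i] * d$cn[i],
                      nmass = len[i] * d$n_callers[i],
                      len = len[i], cn = d$cn[i])
        }
        i <- i + 1L
      }
      out[[length(out) + 1L]] <- cur
      d <- data.frame(
        chrom = d$chrom[1],
        start = vapply(out, `[[`, numeric(1), "start"),
        end = vapply(out, `[[`, numeric(1), "end"),
        cn = vapply(out, function(o) o$mass / o$len, numeric(1)),
        n_callers = floor(vapply(out, function(o) o$nmass / o$len,
                                 numeric(1))),
        stringsAsFactors = FALSE)
      len <- as.numeric(d$end - d$start + 1)
      if (!merged) break
    }
    d
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out$n_callers <- as.integer(out$n_callers)
  class(out) <- c("cn_intervals", "data.frame")
  out
}

#' Per-caller concordance with the consensus copy number
#'
#' For caller *t*, over the intervals it covers, with deviation
#' `d_i = cn_t,i - consensus_i` and weight `w_i` = interval length:
#' bias is the weighted mean of `d_i` (signed) and volatility the weighted
#' standard deviation of `d_i` around the bias. Scaled versions min-max
#' scale `|bias|` and volatility to `[0, 1]` across callers (0 for all
#' callers when they tie). Computed on the pre-smoothing consensus, which
#' still carries per-caller contributions.
#'
#' @param x A `cn_intervals` table with its `"contrib"` attribute (i.e.
#'   the output of [weighted_consensus()], before smoothing).
#' @return Data frame with columns `caller, bias, volatility, bias_scaled,
#'   volatility_scaled`. Callers covering zero intervals are excluded with
#'   a message.
#' @export
caller_concordance <- function(x) {
  m <- attr(x, "contrib")
  if (is.null(m)) {
    stop("no per-caller contributions; concordance must be computed ",
         "before smoothing", call. = FALSE)
  }
  w_all <- as.numeric(x$end - x$start + 1)
  rows <- lapply(colnames(m), function(caller) {
    cov <- !is.na(m[, caller])
    if (!any(cov)) {
      message("caller ", caller, " covers no interval; excluded from ",
              "concordance")
      return(NULL)
    }
    d <- m[cov, caller] - x$cn[cov]
    w <- w_all[cov]
    bias <- sum(w * d) / sum(w)
    vol <- sqrt(sum(w * (d - bias)^2) / sum(w))
    data.frame(caller = caller, bias = bias, volatility = vol,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(caller = character(0), bias = numeric(0),
               volatility = numeric(0))
  }
  minmax <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }
  if (nrow(out)) {
    out$bias_scaled <- minmax(abs(out$bias))
    out$volatility_scaled <- minmax(out$volatility)
  } else {
    out$bias_scaled <- numeric(0)
    out$volatility_scaled <- numeric(0)
  }
  rownames(out) <- NULL
  out
}

#' Full consensus copy-number pipeline
#'
#' Runs, in order: per-caller expansion and equal division of overlaps,
#' partitioning at all caller boundaries, proportion-weighted consensus,
#' per-caller concordance (on the pre-smoothing profile), and smoothing.
#' Deterministic.
#'
#' @param segments Raw caller segment table (`chrom, start, end, cn,
#'   caller`, 1-based inclusive, per-caller disjoint), e.g. from
#'   [read_segments()]; may have zero rows.
#' @param params [cn_params()]; `chrom_lengths` is required when
#'   `segments` is empty (there is otherwise no genome to fill with the
#'   default copy number).
#' @return List of class `cn_consensus`: `intervals` (smoothed),
#'   `concordance`, and `presmooth` (the pre-smoothing intervals with
#'   contributions).
#' @export
consensus_cn <- function(segments, params = cn_params()) {
  if (nrow(segments) == 0 && is.null(params$chrom_lengths)) {
    stop("empty segment input needs chrom_lengths in cn_params()",
         call. = FALSE)
  }
  exp <- expand_and_divide(segments, params$pad, params$chrom_lengths)
  part <- partition_segments(exp, params$chrom_lengths)
  pre <- weighted_consensus(part, params)
  conc <- caller_concordance(pre)
  smoothed <- smooth_intervals(pre, params$smooth_tol)
  structure(list(intervals = smoothed, concordance = conc, presmooth = pre),
            class = "cn_consensus")
}

#' @export
print.cn_consensus <- function(x, ...) {
  cat(sprintf("<cn_consensus> %d smoothed interval(s), %d caller(s)\n",
              nrow(x$intervals), nrow(x$concordance)))
  invisible(x)
}
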