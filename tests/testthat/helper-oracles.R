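# Independent oracles and small fixture builders used across the suite.

# Brute-force single-linkage clustering: build the full O(n^2) relatedness
# graph and take its connected components (igraph). Shares no code with
# cluster_calls().
oracle_clusters <- function(calls, window) {
  n <- nrow(calls)
  if (n == 0) return(integer(0))
  key <- paste(calls$chrom1, calls$chrom2, calls$strand1, calls$strand2,
               calls$svtype == "INS")
  A <- outer(key, key, `==`) &
    abs(outer(calls$pos1, calls$pos1, `-`)) <= window &
    abs(outer(calls$pos2, calls$pos2, `-`)) <= window
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

# Two cluster labellings describe the same partition?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(outer(a, a, `==`), outer(b, b, `==`))
}

# Per-base consensus CN oracle. Each base goes to the raw segment of its
# caller whose interval is nearest (d = max(0, start - b, b - end)), among
# segments with d <= pad (i.e. whose expansion covers the base), ties to
# the leftmost segment; the consensus at a base is the mean over covering
# callers, or default_cn when none covers it. Returns one numeric vector
# per chromosome, length = chromosome length.
oracle_cn_per_base <- function(segments, pad, chrom_lengths, default_cn) {
  callers <- unique(segments$caller)
  out <- list()
  for (chrom in names(chrom_lengths)) {
    L <- as.integer(chrom_lengths[[chrom]])
    b <- seq_len(L)
    per_caller <- sapply(callers, function(ca) {
      s <- segments[segments$chrom == chrom & segments$caller == ca, ,
                    drop = FALSE]
      if (nrow(s) == 0) return(rep(NA_real_, L))
      s <- s[order(s$start), , drop = FALSE]
      d <- sapply(seq_len(nrow(s)), function(i) {
        pmax(0, s$start[i] - b, b - s$end[i])
      })
      d <- matrix(d, nrow = L)
      d[d > pad] <- Inf
      pick <- max.col(-d, ties.method = "first")
      cn <- s$cn[pick]
      cn[!is.finite(d[cbind(b, pick)])] <- NA_real_
      cn
    })
    per_caller <- matrix(per_caller, nrow = L)
    m <- rowMeans(per_caller, na.rm = TRUE)
    m[!is.finite(m)] <- default_cn
    out[[chrom]] <- m
  }
  out
}

# Expand a cn_intervals table to one value per base (per chromosome).
intervals_per_base <- function(iv, chrom_lengths) {
  out <- list()
  for (chrom in names(chrom_lengths)) {
    d <- iv[iv$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    out[[chrom]] <- rep(d$cn, d$end - d$start + 1)
  }
  out
}

# Random SV call set on a small genome; mixed types and orientations.
random_calls <- function(n, span = 20000L, n_callers = 4L,
                         rank = c("chr1", "chr2")) {
  chrom1 <- sample(rank, n, replace = TRUE)
  chrom2 <- ifelse(runif(n) < 0.2, sample(rank, n, replace = TRUE), chrom1)
  x <- sv_pairs(chrom1, sample.int(span, n, replace = TRUE),
                sample(c("+", "-"), n, replace = TRUE),
                chrom2, sample.int(span, n, replace = TRUE),
                sample(c("+", "-"), n, replace = TRUE),
                caller = paste0("c", sample.int(n_callers, n,
                                                replace = TRUE)))
  canonicalize_pairs(x, rank)
}

# Random per-caller disjoint raw segments on one small chromosome.
random_segments <- function(n_callers, chrom_len, max_segs = 6,
                            cn_values = c(0, 1, 2, 3, 4)) {
  rows <- lapply(seq_len(n_callers), function(k) {
    n_seg <- sample.int(max_segs, 1)
    bounds <- sort(sample.int(chrom_len, 2 * n_seg))
    start <- bounds[seq(1, 2 * n_seg, 2)]
    end <- bounds[seq(2, 2 * n_seg, 2)]
    keep <- c(TRUE, start[-1] > end[-n_seg] + 1)  # enforce raw disjointness
    data.frame(chrom = "chr1", start = start[keep], end = end[keep],
               cn = sample(cn_values, sum(keep), replace = TRUE),
               caller = paste0("c", k), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Minimal SV VCF writer for fixtures.
write_test_vcf <- function(path, body_lines) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"end\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"mate\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"mate chrom\">",
    "##INFO=<ID=CT,Number=1,Type=String,Description=\"connection\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO"), collapse = "\t"),
    body_lines), path)
  path
}
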