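#' Parameters for consensus SV merging
#'
#' @param window Maximum per-breakend position difference, in bp, for two
#'   calls to be related (default 150; the comparison is inclusive).
#' @param min_support Minimum number of distinct supporting callers a
#'   consensus SV must reach to be kept (default 3).
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(window = 150L, min_support = 3L) {
  window <- as.integer(window)
  min_support <- as.integer(min_support)
  stopifnot(window >= 0L, min_support >= 1L)
  structure(list(window = window, min_support = min_support),
            class = "merge_params")
}

#' Are two SV calls related?
#'
#' Two canonical calls are related when they agree in both chromosomes and
#' both orientations and each breakend's position difference is at most
#' `window` bp (inclusive). Insertions only relate to insertions. The
#' relation is symmetric.
#'
#' @param x,y Single-row `sv_pairs` tables (or rows of one).
#' @param window Window in bp.
#' @return Logical.
#' @export
are_related <- function(x, y, window = 150) {
  stopifnot(nrow(x) == 1, nrow(y) == 1)
  x$chrom1 == y$chrom1 && x$chrom2 == y$chrom2 &&
    x$strand1 == y$strand1 && x$strand2 == y$strand2 &&
    (x$svtype == "INS") == (y$svtype == "INS") &&
    abs(x$pos1 - y$pos1) <= window &&
    abs(x$pos2 - y$pos2) <= window
}

#' Cluster SV calls by single linkage
#'
#' Builds the connected components of the "related" relation
#' (see [are_related()]): calls sharing chromosomes and orientations whose
#' breakends lie within `window` bp are linked, and linkage is transitive,
#' so a chain of related calls forms one cluster even when its extremes are
#' farther apart than the window. The result partitions the input and does
#' not depend on input order.
#'
#' @param calls Canonical `sv_pairs` table.
#' @param window Window in bp.
#' @return Integer vector of cluster ids (1..k), one per input row; ids are
#'   assigned in order of each cluster's first sorted member.
#' @export
cluster_calls <- function(calls, window = 150) {
  n <- nrow(calls)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    # path halving
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  key <- paste(calls$chrom1, calls$chrom2, calls$strand1, calls$strand2,
               calls$svtype == "INS", sep = "\r")
  for (rows in split(seq_len(n), key)) {
    rows <- rows[order(calls$pos1[rows], calls$pos2[rows])]
    p1 <- calls$pos1[rows]
    p2 <- calls$pos2[rows]
    m <- length(rows)
    for (i in seq_len(m)) {
      j <- i + 1L
      while (j <= m && p1[j] - p1[i] <= window) {
        if (abs(p2[j] - p2[i]) <= window) union2(rows[i], rows[j])
        j <- j + 1L
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Consensus position of one breakend across cluster members: the
# statistical mode, ties broken toward the smallest tied position. A
# sample in which no position repeats has no mode; the lower median is
# used then (for two members this is again the smaller position), keeping
# the consensus central instead of collapsing to the minimum.
mode_pos <- function(p) {
  ux <- sort(unique(p))
  counts <- tabulate(match(p, ux))
  if (max(counts) > 1L) return(ux[which.max(counts)])
  sorted <- sort(p)
  sorted[floor((length(sorted) + 1) / 2)]
}

#' Collapse one cluster of related calls into a consensus SV
#'
#' The consensus breakend positions are the per-breakend statistical modes
#' of the member positions (ties broken toward the smallest position); the
#' supporting callers are the distinct member caller ids (duplicate calls
#' from one caller count once toward confidence but remain members); the
#' type is re-derived from the shared chromosomes and orientations.
#'
#' @param cluster Non-empty `sv_pairs` table whose rows share chromosomes
#'   and orientations.
#' @return One-row data frame with columns `chrom1, pos1, strand1, chrom2,
#'   pos2, strand2, svtype, supp, callers` (`callers` comma-joined, sorted).
#' @export
collapse_cluster <- function(cluster) {
  if (nrow(cluster) == 0) stop("cannot collapse an empty cluster", call. = FALSE)
  stopifnot(length(unique(cluster$chrom1)) == 1,
            length(unique(cluster$chrom2)) == 1,
            length(unique(cluster$strand1)) == 1,
            length(unique(cluster$strand2)) == 1)
  callers <- sort(unique(cluster$caller))
  svtype <- if (all(cluster$svtype == "INS")) "INS" else
    classify_svtype(cluster$chrom1[1], cluster$strand1[1],
                    cluster$chrom2[1], cluster$strand2[1])
  data.frame(
    chrom1 = cluster$chrom1[1], pos1 = mode_pos(cluster$pos1),
    strand1 = cluster$strand1[1],
    chrom2 = cluster$chrom2[1], pos2 = mode_pos(cluster$pos2),
    strand2 = cluster$strand2[1],
    svtype = svtype, supp = length(callers),
    callers = paste(callers, collapse = ","),
    stringsAsFactors = FALSE)
}

#' Merge multi-caller SV calls into consensus SVs
#'
#' Pools calls from all callers, canonicalizes them, clusters related calls
#' by single linkage within `window` bp, collapses each cluster to its mode
#' positions, drops consensus SVs supported by fewer than `min_support`
#' distinct callers, and sorts by (chromosome rank, position). The result
#' is deterministic and invariant to caller and call ordering.
#'
#' @param calls Either one pooled `sv_pairs` table (with its `caller`
#'   column filled) or a named list of per-caller `sv_pairs` tables (names
#'   overwrite the `caller` column).
#' @param params [merge_params()].
#' @param rank Chromosome ranking.
#' @return Data frame of class `consensus_sv`, one row per consensus SV,
#'   with attribute `"members"`: the pooled canonical calls plus a
#'   `cluster` id column (ids of surviving clusters appear in the `cluster`
#'   column of the consensus table).
#' @export
merge_svs <- function(calls, params = merge_params(), rank = default_chroms()) {
  if (is.data.frame(calls)) {
    pooled <- calls
  } else {
    stopifnot(is.list(calls))
    if (!is.null(names(calls))) {
      calls <- lapply(names(calls), function(nm) {
        x <- calls[[nm]]
        if (nrow(x)) x$caller <- nm
        x
      })
    }
    pooled <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
    if (is.null(pooled)) pooled <- empty_sv_pairs()
  }
  pooled <- canonicalize_pairs(pooled, rank)
  # pool in a reproducible order so cluster ids are stable
  ord <- order(chrom_index(pooled$chrom1, rank), pooled$pos1,
               chrom_index(pooled$chrom2, rank), pooled$pos2,
               pooled$strand1, pooled$strand2, pooled$svtype, pooled$caller)
  pooled <- pooled[ord, , drop = FALSE]
  rownames(pooled) <- NULL
  cl <- cluster_calls(pooled, params$window)
  pooled$cluster <- cl
  ids <- sort(unique(cl))
  cons <- do.call(rbind, lapply(split(seq_along(cl), cl)[as.character(ids)],
                                function(rows) {
    collapse_cluster(pooled[rows, , drop = FALSE])
  }))
  if (is.null(cons)) {
    cons <- data.frame(chrom1 = character(0), pos1 = integer(0),
                       strand1 = character(0), chrom2 = character(0),
                       pos2 = integer(0), strand2 = character(0),
                       svtype = character(0), supp = integer(0),
                       callers = character(0), cluster = integer(0),
                       stringsAsFactors = FALSE)
  } else {
    rownames(cons) <- NULL
    cons$cluster <- ids
    cons <- cons[cons$supp >= params$min_support, , drop = FALSE]
    cons <- cons[order(chrom_index(cons$chrom1, rank), cons$pos1,
                       chrom_index(cons$chrom2, rank), cons$pos2,
                       cons$strand1, cons$strand2, cons$svtype,
                       cons$callers), , drop = FALSE]
    rownames(cons) <- NULL
  }
  class(cons) <- c("consensus_sv", "data.frame")
  attr(cons, "members") <- pooled
  cons
}

#' @export
print.consensus_sv <- function(x, ...) {
  cat(sprintf("<consensus_sv> %d consensus SV(s)\n", nrow(x)))
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 10), ...)
    if (nrow(x) > 10) cat("...", nrow(x) - 10, "more row(s)\n")
  }
  invisible(x)
}
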