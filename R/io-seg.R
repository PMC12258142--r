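#' Read a caller's copy-number segments
#'
#' Tab-separated table with at least four columns: chromosome, start, end,
#' copy number. A header row is auto-detected (non-numeric start/end
#' fields) and skipped. Coordinates are normalized to 1-based inclusive.
#' Segments of one caller must be disjoint; overlaps, negative copy
#' numbers and inverted intervals are errors.
#'
#' @param path Segment file (SEG/BED-like TSV).
#' @param caller_id Caller identifier stored on every segment.
#' @param convention `"1-based-inclusive"` or `"0-based-half-open"`; in
#'   the latter, `start + 1` becomes the 1-based start and `end` is
#'   already the last included base + 0 offset (half-open end == 1-based
#'   inclusive end).
#' @param chrom_style Optional chromosome renaming.
#' @return Data frame of class `cn_segments` with columns
#'   `chrom, start, end, cn, caller`, sorted by chromosome and start.
#' @export
read_segments <- function(path, caller_id,
                          convention = c("1-based-inclusive",
                                         "0-based-half-open"),
                          chrom_style = NULL) {
  convention <- match.arg(convention)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t")
  if (length(fields) && any(lengths(fields) < 4)) {
    stop("segment file ", path, " has a row with fewer than 4 columns",
         call. = FALSE)
  }
  if (length(fields)) {
    first <- fields[[1]]
    if (is.na(suppressWarnings(as.numeric(first[2]))) ||
        is.na(suppressWarnings(as.numeric(first[3])))) {
      fields <- fields[-1]  # header row
    }
  }
  n <- length(fields)
  get <- function(k) vapply(fields, `[[`, character(1), k)
  if (n == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), cn = numeric(0),
                      caller = character(0), stringsAsFactors = FALSE)
  } else {
    chrom <- get(1)
    if (!is.null(chrom_style)) chrom <- normalize_chroms(chrom, chrom_style)
    start <- as.integer(get(2))
    end <- as.integer(get(3))
    cn <- as.numeric(get(4))
    if (convention == "0-based-half-open") start <- start + 1L
    if (anyNA(start) || anyNA(end) || anyNA(cn)) {
      stop("non-numeric start/end/cn in ", path, call. = FALSE)
    }
    if (any(cn < 0)) stop("negative copy number in ", path, call. = FALSE)
    if (any(start > end)) {
      stop("segment with start > end in ", path, call. = FALSE)
    }
    out <- data.frame(chrom = chrom, start = start, end = end, cn = cn,
                      caller = caller_id, stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    same <- out$chrom[-1] == out$chrom[-n]
    if (n > 1 && any(same & out$start[-1] <= out$end[-n])) {
      stop("overlapping segments for caller ", caller_id, " in ", path,
           " (raw caller segments must be disjoint)", call. = FALSE)
    }
  }
  class(out) <- c("cn_segments", "data.frame")
  out
}

#' Write a consensus copy-number profile
#'
#' Tab-separated columns `chrom, start, end, cn, n_callers` with a header.
#'
#' @param intervals `cn_intervals` table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_segments <- function(intervals, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  nc <- if ("n_callers" %in% colnames(intervals)) intervals$n_callers else
    rep(NA_integer_, nrow(intervals))
  writeLines(c("chrom\tstart\tend\tcn\tn_callers",
               sprintf("%s\t%d\t%d\t%.6g\t%s", intervals$chrom,
                       as.integer(intervals$start),
                       as.integer(intervals$end), intervals$cn,
                       ifelse(is.na(nc), ".", as.character(nc)))), con)
  invisible(path)
}

#' Write a per-caller concordance table
#'
#' @param concordance Output of [caller_concordance()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_concordance <- function(concordance, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(
    c("caller\tbias\tvolatility\tbias_scaled\tvolatility_scaled",
      sprintf("%s\t%.6g\t%.6g\t%.6g\t%.6g", concordance$caller,
              concordance$bias, concordance$volatility,
              concordance$bias_scaled, concordance$volatility_scaled)),
    con)
  invisible(path)
}
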