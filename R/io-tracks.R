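#' Export circos-style track files
#'
#' Writes one tab-separated file per track into `outdir`: a copy-number
#' track (`chrom, start, end, cn`), an SV track
#' (`chrom1, pos1, chrom2, pos2, svtype`, with the type labels DEL / DUP /
#' INV / TRA / INS), and one pass-through track per externally produced
#' event BED supplied (first three or more columns copied as-is). The
#' files are plain TSV loadable by standard circos-style plotters; no
#' rendering is performed.
#'
#' @param consensus_sv Optional `consensus_sv` table.
#' @param consensus_cn Optional `cn_intervals` table.
#' @param event_beds Named list of BED file paths to pass through.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a named character vector of written paths.
#' @export
export_tracks <- function(consensus_sv = NULL, consensus_cn = NULL,
                          event_beds = list(), outdir = ".") {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  put <- function(name, lines) {
    p <- file.path(outdir, name)
    con <- file(p, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(lines, con)
    written[[sub("_track\\.tsv$", "", name)]] <<- p
  }
  if (!is.null(consensus_cn)) {
    put("cn_track.tsv",
        c("chrom\tstart\tend\tcn",
          sprintf("%s\t%d\t%d\t%.6g", consensus_cn$chrom,
                  as.integer(consensus_cn$start),
                  as.integer(consensus_cn$end), consensus_cn$cn)))
  }
  if (!is.null(consensus_sv)) {
    put("sv_track.tsv",
        c("chrom1\tpos1\tchrom2\tpos2\tsvtype",
          sprintf("%s\t%d\t%s\t%d\t%s", consensus_sv$chrom1,
                  consensus_sv$pos1, consensus_sv$chrom2,
                  consensus_sv$pos2, consensus_sv$svtype)))
  }
  if (length(event_beds)) {
    stopifnot(!is.null(names(event_beds)), all(nzchar(names(event_beds))))
    for (nm in names(event_beds)) {
      lines <- readLines(event_beds[[nm]])
      lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
      if (length(lines) && any(lengths(strsplit(lines, "\t")) < 3)) {
        stop("event BED ", event_beds[[nm]], " has rows with fewer than ",
             "3 columns", call. = FALSE)
      }
      put(paste0(nm, "_track.tsv"), lines)
    }
  }
  invisible(written)
}
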