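#' Default chromosome ranking
#'
#' The autosomes 1..22 followed by X and Y, optionally with a "chr" prefix.
#' The position of a name in this vector defines its rank; every chromosome
#' appearing in an input must be present here (or in a user-supplied ranking)
#' or the offending name triggers an error. Mitochondrial and alternative
#' contigs are deliberately absent by default; pass a custom vector to admit
#' them.
#'
#' @param style `"chr"` for UCSC-style names (`chr1`), `"plain"` for bare
#'   names (`1`).
#' @return Character vector of chromosome names in rank order.
#' @export
#' @examples
#' default_chroms()[c(1, 23)]
default_chroms <- function(style = c("chr", "plain")) {
  style <- match.arg(style)
  base <- c(as.character(1:22), "X", "Y")
  if (style == "chr") paste0("chr", base) else base
}

#' Normalize chromosome naming style
#'
#' Strips or adds the `"chr"` prefix so heterogeneous caller outputs rank
#' under one scheme.
#'
#' @param chrom Character vector of chromosome names.
#' @param style Target style, `"chr"` or `"plain"`.
#' @return Renamed character vector.
#' @export
normalize_chroms <- function(chrom, style = c("chr", "plain")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", as.character(chrom))
  if (style == "chr") paste0("chr", bare) else bare
}

# Rank lookup; errors on any name outside the ranking.
chrom_index <- function(chrom, rank) {
  idx <- match(chrom, rank)
  if (anyNA(idx)) {
    bad <- unique(chrom[is.na(idx)])
    stop("chromosome(s) not rankable: ", paste(bad, collapse = ", "),
         " (known: ", paste(utils::head(rank, 3), collapse = ", "), ", ...)",
         call. = FALSE)
  }
  idx
}
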