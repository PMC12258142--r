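#' @keywords internal
SV_TYPES <- c("DEL", "DUP", "INV", "TRA", "INS")
ORIENTS <- c("+", "-")

#' Classify SV type from breakend geometry
#'
#' An SV joining two oriented breakends is typed purely by its geometry:
#' interchromosomal pairs are translocations (TRA); on one chromosome the
#' orientation pair decides between deletion-like (+,-), duplication-like
#' (-,+) and inversion (+,+ or -,-) junctions. `"+"` means the sequence
#' 5' of (to the left of) the breakpoint is retained in the derivative
#' chromosome; `"-"` means the 3' side is retained. Insertions carry no
#' two-breakend geometry and are never produced here; a caller-declared INS
#' label is preserved upstream instead.
#'
#' @param chrom1,chrom2 Chromosome of the first / second breakend.
#' @param strand1,strand2 Orientation flags, `"+"` or `"-"`.
#' @return Character vector over `DEL`, `DUP`, `INV`, `TRA`.
#' @export
#' @examples
#' classify_svtype("chr1", "+", "chr1", "-")  # DEL
#' classify_svtype("chr1", "+", "chr2", "+")  # TRA
classify_svtype <- function(chrom1, strand1, chrom2, strand2) {
  stopifnot(all(strand1 %in% ORIENTS), all(strand2 %in% ORIENTS))
  n <- max(length(chrom1), length(strand1), length(chrom2), length(strand2))
  if (n == 0) return(character(0))
  type <- unname(c("+-" = "DEL", "-+" = "DUP", "++" = "INV", "--" = "INV")[
    paste0(rep_len(strand1, n), rep_len(strand2, n))])
  type[rep_len(as.character(chrom1), n) !=
         rep_len(as.character(chrom2), n)] <- "TRA"
  type
}

#' Build a table of oriented breakend pairs
#'
#' The standardized SV record: two (chromosome, position, orientation)
#' breakends plus type, caller and optional quality metadata, stored one call
#' per row. Positions are 1-based inclusive (VCF-style). Unless a row is an
#' insertion, its `svtype` is recomputed from geometry so heterogeneous
#' caller labels cannot disagree with the breakend orientations.
#'
#' @param chrom1,pos1,strand1 First breakend.
#' @param chrom2,pos2,strand2 Second breakend.
#' @param svtype Optional caller-declared types; only `INS` survives — all
#'   other rows are typed from geometry.
#' @param caller Caller identifier(s).
#' @param qual Optional numeric quality.
#' @param filter Optional FILTER string.
#' @return A data frame of class `sv_pairs`.
#' @export
sv_pairs <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                     svtype = NULL, caller = "unknown",
                     qual = NA_real_, filter = NA_character_) {
  n <- length(chrom1)
  pos1 <- as.integer(pos1)
  pos2 <- as.integer(pos2)
  chrom1 <- as.character(chrom1)
  chrom2 <- as.character(chrom2)
  if (n > 0) {
    stopifnot(length(pos1) == n, length(chrom2) == n, length(pos2) == n,
              all(nzchar(chrom1)), all(nzchar(chrom2)),
              all(pos1 >= 1L), all(pos2 >= 1L),
              all(strand1 %in% ORIENTS), all(strand2 %in% ORIENTS))
  }
  geom <- if (n > 0) classify_svtype(chrom1, strand1, chrom2, strand2) else character(0)
  if (is.null(svtype)) {
    svtype <- geom
  } else {
    svtype <- as.character(svtype)
    ins <- !is.na(svtype) & svtype == "INS"
    svtype[!ins] <- geom[!ins]
  }
  out <- data.frame(
    chrom1 = chrom1, pos1 = pos1, strand1 = rep_len(as.character(strand1), n),
    chrom2 = chrom2, pos2 = pos2, strand2 = rep_len(as.character(strand2), n),
    svtype = svtype, caller = rep_len(as.character(caller), n),
    qual = rep_len(as.numeric(qual), n),
    filter = rep_len(as.character(filter), n),
    stringsAsFactors = FALSE)
  class(out) <- c("sv_pairs", "data.frame")
  out
}

empty_sv_pairs <- function() {
  sv_pairs(character(0), integer(0), character(0),
           character(0), integer(0), character(0))
}

#' Put breakend pairs into canonical order
#'
#' Canonical order sorts the two breakends of every pair by
#' (chromosome rank, position); orientations travel with their breakends and
#' non-insertion types are re-derived afterwards. Idempotent, and the
#' derived type is invariant under swapping the input breakends.
#'
#' @param x An `sv_pairs` table.
#' @param rank Chromosome ranking (see [default_chroms()]).
#' @return The reordered `sv_pairs` table.
#' @export
canonicalize_pairs <- function(x, rank = default_chroms()) {
  if (nrow(x) == 0) return(x)
  i1 <- chrom_index(x$chrom1, rank)
  i2 <- chrom_index(x$chrom2, rank)
  swap <- i1 > i2 | (i1 == i2 & x$pos1 > x$pos2)
  for (f in c("chrom", "pos", "strand")) {
    a <- paste0(f, "1"); b <- paste0(f, "2")
    tmp <- x[[a]][swap]
    x[[a]][swap] <- x[[b]][swap]
    x[[b]][swap] <- tmp
  }
  ins <- x$svtype == "INS"
  x$svtype[!ins] <- classify_svtype(x$chrom1, x$strand1,
                                    x$chrom2, x$strand2)[!ins]
  x
}

#' Parse a VCF breakend (BND) ALT allele
#'
#' The four bracket shapes encode the orientation of the local breakend and
#' of its mate: `t[p[` joins the retained left flank of this locus to the
#' right flank of the mate (+,-); `t]p]` gives (+,+); `]p]t` gives (-,+);
#' `[p[t` gives (-,-).
#'
#' @param alt Character vector of BND ALT strings.
#' @return Data frame with columns `orient_self`, `orient_mate`,
#'   `mate_chrom`, `mate_pos`.
#' @export
#' @examples
#' parse_bnd_alt("A[chr2:321682[")   # (+,-)
#' parse_bnd_alt("]chr13:123456]T")  # (-,+)
parse_bnd_alt <- function(alt) {
  re <- "^([^][]*)([][])([^:]+):([0-9]+)([][])([^][]*)$"
  ok <- grepl(re, alt)
  if (!all(ok)) {
    stop("malformed BND ALT allele(s): ",
         paste(alt[!ok], collapse = ", "), call. = FALSE)
  }
  t_first <- sub(re, "\\1", alt)
  t_last <- sub(re, "\\6", alt)
  br1 <- sub(re, "\\2", alt)
  br2 <- sub(re, "\\5", alt)
  bad <- br1 != br2 | (nzchar(t_first) == nzchar(t_last))
  if (any(bad)) {
    stop("malformed BND ALT allele(s): ",
         paste(alt[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    orient_self = ifelse(nzchar(t_first), "+", "-"),
    orient_mate = ifelse(br1 == "[", "-", "+"),
    mate_chrom = sub(re, "\\3", alt),
    mate_pos = as.integer(sub(re, "\\4", alt)),
    stringsAsFactors = FALSE)
}

#' Render a breakend as a BND ALT allele
#'
#' Inverse of [parse_bnd_alt()]: given the local orientation, the mate
#' locus and its orientation, produce the bracketed ALT string.
#'
#' @param ref Reference base printed in the allele (default `"N"`).
#' @param mate_chrom,mate_pos Mate breakend locus.
#' @param orient_self,orient_mate Orientations of the local and mate
#'   breakends.
#' @return Character vector of ALT strings.
#' @export
bnd_alt <- function(mate_chrom, mate_pos, orient_self, orient_mate,
                    ref = "N") {
  stopifnot(all(orient_self %in% ORIENTS), all(orient_mate %in% ORIENTS))
  br <- ifelse(orient_mate == "-", "[", "]")
  p <- paste0(br, mate_chrom, ":", mate_pos, br)
  ifelse(orient_self == "+", paste0(ref, p), paste0(p, ref))
}

#' @export
print.sv_pairs <- function(x, ...) {
  cat(sprintf("<sv_pairs> %d call(s) from %d caller(s)\n",
              nrow(x), length(unique(x$caller))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more row(s)\n")
  invisible(x)
}
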