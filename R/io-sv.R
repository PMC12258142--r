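#' VCF dialect configuration for SV callers
#'
#' Rather than hard-coding caller-specific parsing, readers take a small
#' dialect object naming the INFO keys used for the segment end, the mate
#' chromosome of interchromosomal symbolic records, and the
#' connection-type orientation string, plus whether non-PASS records are
#' excluded. Shipped preset names (`manta`, `delly`, `lumpy`, `svaba`,
#' `gridss`, `generic`) all resolve to the common dialect; any field can
#' be overridden.
#'
#' @param name Preset name.
#' @param end_key INFO key holding the second coordinate (default `END`).
#' @param svtype_key INFO key holding the declared type (default `SVTYPE`).
#' @param mate_chrom_key INFO key holding the mate chromosome of a
#'   symbolic translocation record (default `CHR2`).
#' @param ct_key INFO key holding a connection-type string such as
#'   `3to5` (default `CT`; `3` maps to `"+"`, `5` to `"-"`).
#' @param filter_pass Exclude records whose FILTER is not `PASS` or `.`
#'   (default `TRUE`).
#' @param inv_orient Orientation pair assumed for symbolic `<INV>` records,
#'   which carry no bracket geometry (default `c("+", "+")`).
#' @return A list of class `sv_dialect`.
#' @export
sv_dialect <- function(name = c("generic", "manta", "delly", "lumpy",
                                "svaba", "gridss"),
                       end_key = "END", svtype_key = "SVTYPE",
                       mate_chrom_key = "CHR2", ct_key = "CT",
                       filter_pass = TRUE, inv_orient = c("+", "+")) {
  name <- match.arg(name)
  stopifnot(all(inv_orient %in% ORIENTS), length(inv_orient) == 2)
  structure(list(name = name, end_key = end_key, svtype_key = svtype_key,
                 mate_chrom_key = mate_chrom_key, ct_key = ct_key,
                 filter_pass = filter_pass, inv_orient = inv_orient),
            class = "sv_dialect")
}

ct_to_orient <- function(ct) {
  parts <- strsplit(ct, "to", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% c("3", "5"))) return(NULL)
  ifelse(parts == "3", "+", "-")
}

#' Read SV calls from a VCF file
#'
#' Accepts breakend (BND, bracketed ALT) records and symbolic records
#' (`<DEL>`, `<DUP>`, `<INV>`, `<INS>`, `<TRA>`/`<BND>` with a mate-chrom
#' INFO key). Mated BND records are collapsed to one breakend pair by
#' reciprocal coordinate matching; unmated breakends are dropped and
#' counted. Non-PASS records are excluded when the dialect requests it.
#' A parse report (`total`, `parsed`, `filtered`, `dropped_unmated`,
#' `errored`; record counts, so a BND pair contributes 2 to `parsed`) is
#' attached as attribute `"report"`.
#'
#' @param path VCF 4.x file.
#' @param caller_id Caller identifier stored on every call.
#' @param rank Chromosome ranking.
#' @param dialect [sv_dialect()].
#' @param chrom_style Optional `"chr"` or `"plain"` to rename chromosomes
#'   before ranking.
#' @return Canonical `sv_pairs` table.
#' @export
read_sv_vcf <- function(path, caller_id, rank = default_chroms(),
                        dialect = sv_dialect(), chrom_style = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  empty <- function(report) {
    out <- canonicalize_pairs(empty_sv_pairs(), rank)
    attr(out, "report") <- report
    out
  }
  if (is.null(fix) || nrow(fix) == 0) {
    return(empty(list(total = 0L, parsed = 0L, filtered = 0L,
                      dropped_unmated = 0L, errored = 0L)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  total <- nrow(fix)
  if (!is.null(chrom_style)) {
    fix$CHROM <- normalize_chroms(fix$CHROM, chrom_style)
  }
  fix$POS <- as.integer(fix$POS)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  info_get <- function(key) {
    as.character(vcfR::extract.info(v, element = key))
  }
  end_v <- suppressWarnings(as.integer(info_get(dialect$end_key)))
  svtype_v <- info_get(dialect$svtype_key)
  chr2_v <- info_get(dialect$mate_chrom_key)
  ct_v <- info_get(dialect$ct_key)
  if (!is.null(chrom_style) && any(!is.na(chr2_v))) {
    chr2_v[!is.na(chr2_v)] <- normalize_chroms(chr2_v[!is.na(chr2_v)],
                                               chrom_style)
  }

  keep <- rep(TRUE, total)
  if (isTRUE(dialect$filter_pass)) {
    keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  }
  filtered <- sum(!keep)

  is_bnd <- keep & grepl("[][]", fix$ALT)
  is_sym <- keep & !is_bnd & grepl("^<.+>$", fix$ALT)
  errored <- sum(keep & !is_bnd & !is_sym)

  rows <- list()
  parsed <- 0L

  # --- mated breakend records -------------------------------------------
  bidx <- which(is_bnd)
  dropped_unmated <- 0L
  if (length(bidx)) {
    bp <- parse_bnd_alt(fix$ALT[bidx])
    if (!is.null(chrom_style)) {
      bp$mate_chrom <- normalize_chroms(bp$mate_chrom, chrom_style)
    }
    self_key <- paste0(fix$CHROM[bidx], ":", fix$POS[bidx])
    mate_key <- paste0(bp$mate_chrom, ":", bp$mate_pos)
    used <- rep(FALSE, length(bidx))
    for (i in seq_along(bidx)) {
      if (used[i]) next
      j <- which(!used & self_key == mate_key[i] & mate_key == self_key[i])
      j <- setdiff(j, i)
      if (!length(j)) {
        used[i] <- TRUE
        dropped_unmated <- dropped_unmated + 1L
        next
      }
      j <- j[1]
      used[c(i, j)] <- TRUE
      parsed <- parsed + 2L
      rows[[length(rows) + 1L]] <- sv_pairs(
        fix$CHROM[bidx[i]], fix$POS[bidx[i]], bp$orient_self[i],
        bp$mate_chrom[i], bp$mate_pos[i], bp$orient_mate[i],
        caller = caller_id, qual = qual[bidx[i]],
        filter = fix$FILTER[bidx[i]])
    }
  }

  # --- symbolic records -------------------------------------------------
  for (i in which(is_sym)) {
    sym <- sub("^<(.+)>$", "\\1", fix$ALT[i])
    type <- if (sym %in% SV_TYPES) sym else svtype_v[i]
    if (is.na(type) || !type %in% c(SV_TYPES, "BND")) {
      errored <- errored + 1L
      next
    }
    ct <- if (!is.na(ct_v[i])) ct_to_orient(ct_v[i]) else NULL
    if (type %in% c("TRA", "BND")) {
      if (is.na(chr2_v[i]) || is.na(end_v[i])) {
        errored <- errored + 1L
        next
      }
      strands <- if (!is.null(ct)) ct else c("+", "-")
      pr <- sv_pairs(fix$CHROM[i], fix$POS[i], strands[1],
                     chr2_v[i], end_v[i], strands[2],
                     caller = caller_id, qual = qual[i],
                     filter = fix$FILTER[i])
    } else {
      end_i <- end_v[i]
      if (is.na(end_i)) {
        if (type == "INS") end_i <- fix$POS[i] else {
          errored <- errored + 1L
          next
        }
      }
      strands <- switch(type,
                        DEL = c("+", "-"), DUP = c("-", "+"),
                        INV = dialect$inv_orient, INS = c("+", "-"))
      pr <- sv_pairs(fix$CHROM[i], fix$POS[i], strands[1],
                     fix$CHROM[i], end_i, strands[2],
                     svtype = type, caller = caller_id, qual = qual[i],
                     filter = fix$FILTER[i])
    }
    parsed <- parsed + 1L
    rows[[length(rows) + 1L]] <- pr
  }

  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    empty_sv_pairs()
  }
  class(out) <- c("sv_pairs", "data.frame")
  out <- canonicalize_pairs(out, rank)
  attr(out, "report") <- list(total = total, parsed = parsed,
                              filtered = filtered,
                              dropped_unmated = dropped_unmated,
                              errored = errored)
  out
}

#' Read SV calls from a BEDPE file
#'
#' Standard 10+ column BEDPE: the two 0-based half-open intervals are
#' converted to 1-based breakend positions (`start + 1` of each interval);
#' strand columns 9-10 map directly to breakend orientations. Column 11,
#' when present and a recognized type, supplies a declared SV type (only
#' `INS` survives reclassification).
#'
#' @param path BEDPE file; lines starting with `#` are skipped.
#' @param caller_id Caller identifier.
#' @param rank Chromosome ranking.
#' @param chrom_style Optional chromosome renaming.
#' @return Canonical `sv_pairs` table with a `"report"` attribute.
#' @export
read_sv_bedpe <- function(path, caller_id, rank = default_chroms(),
                          chrom_style = NULL) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  fields <- strsplit(lines[body], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 10)) {
    bad <- body[which(nf < 10)[1]]
    stop("BEDPE line ", bad, " has ", nf[which(nf < 10)[1]],
         " column(s); at least 10 required", call. = FALSE)
  }
  get <- function(k) vapply(fields, `[[`, character(1), k)
  n <- length(fields)
  if (n == 0) {
    out <- empty_sv_pairs()
  } else {
    svtype <- rep(NA_character_, n)
    if (all(nf >= 11)) {
      cand <- get(11)
      svtype[cand %in% SV_TYPES] <- cand[cand %in% SV_TYPES]
    }
    chrom1 <- get(1); chrom2 <- get(4)
    if (!is.null(chrom_style)) {
      chrom1 <- normalize_chroms(chrom1, chrom_style)
      chrom2 <- normalize_chroms(chrom2, chrom_style)
    }
    out <- sv_pairs(chrom1, as.integer(get(2)) + 1L, get(9),
                    chrom2, as.integer(get(5)) + 1L, get(10),
                    svtype = svtype, caller = caller_id,
                    qual = suppressWarnings(as.numeric(get(8))))
  }
  out <- canonicalize_pairs(out, rank)
  attr(out, "report") <- list(total = n, parsed = n, filtered = 0L,
                              dropped_unmated = 0L, errored = 0L)
  out
}

#' Write SV calls as BEDPE
#'
#' One line per call: two 1 bp intervals in 0-based half-open convention
#' (`pos - 1`, `pos`), name, score, strands, then the SV type and any
#' extra columns supplied. Byte-stable for a given input.
#'
#' @param pairs `sv_pairs` or `consensus_sv` rows.
#' @param path Output path.
#' @param names Record names (default `sv1..svN`).
#' @param score Score column (default `qual`, or `.`).
#' @param extra Optional data frame of additional columns.
#' @param header Logical; write a `#`-prefixed header line.
#' @return Invisibly, `path`.
#' @export
write_sv_bedpe <- function(pairs, path, names = NULL, score = NULL,
                           extra = NULL, header = TRUE) {
  n <- nrow(pairs)
  if (is.null(names)) names <- paste0("sv", seq_len(n))
  if (is.null(score)) {
    score <- if ("qual" %in% colnames(pairs)) pairs$qual else
      rep(NA_real_, n)
  }
  score <- ifelse(is.na(score), ".", as.character(score))
  cols <- data.frame(
    chrom1 = pairs$chrom1, start1 = pairs$pos1 - 1L, end1 = pairs$pos1,
    chrom2 = pairs$chrom2, start2 = pairs$pos2 - 1L, end2 = pairs$pos2,
    name = names, score = score,
    strand1 = pairs$strand1, strand2 = pairs$strand2,
    svtype = pairs$svtype, stringsAsFactors = FALSE)
  if (!is.null(extra)) cols <- cbind(cols, extra)
  con <- file(path, open = "wb")  # binary: byte-stable newlines
  on.exit(close(con))
  if (header) {
    writeLines(paste0("#", paste(colnames(cols), collapse = "\t")), con)
  }
  if (n) {
    writeLines(do.call(paste, c(lapply(cols, as.character), sep = "\t")),
               con)
  }
  invisible(path)
}

#' Write consensus SVs to BEDPE or VCF
#'
#' BEDPE output carries the support count and the comma-joined sorted
#' caller list as extra columns. VCF output writes each non-insertion
#' consensus as a mated BND record pair with INFO keys `SUPP` (integer
#' support) and `SUPP_CALLERS` (comma-joined sorted caller ids);
#' insertions are written as symbolic `<INS>` records. Output is sorted
#' by (chromosome rank, position) and byte-stable for a given input.
#'
#' @param consensus A `consensus_sv` table.
#' @param path Output path.
#' @param format `"bedpe"` or `"vcf"`.
#' @param rank Chromosome ranking used for sorting.
#' @return Invisibly, `path`.
#' @export
write_consensus_sv <- function(consensus, path,
                               format = c("bedpe", "vcf"),
                               rank = default_chroms()) {
  format <- match.arg(format)
  x <- as.data.frame(consensus)
  if (nrow(x)) {
    x <- x[order(chrom_index(x$chrom1, rank), x$pos1,
                 chrom_index(x$chrom2, rank), x$pos2,
                 x$strand1, x$strand2, x$svtype, x$callers), , drop = FALSE]
  }
  if (format == "bedpe") {
    return(write_sv_bedpe(
      x, path, names = sprintf("cons%d", seq_len(nrow(x))),
      score = x$supp,
      extra = data.frame(supp = x$supp, callers = x$callers,
                         stringsAsFactors = FALSE)))
  }
  hdr <- c(
    "##fileformat=VCFv4.3",
    "##source=svconsensus",
    paste0("##INFO=<ID=SVTYPE,Number=1,Type=String,",
           "Description=\"Type of structural variant\">"),
    paste0("##INFO=<ID=END,Number=1,Type=Integer,",
           "Description=\"End position of the variant\">"),
    paste0("##INFO=<ID=MATEID,Number=1,Type=String,",
           "Description=\"ID of mate breakend\">"),
    paste0("##INFO=<ID=SUPP,Number=1,Type=Integer,",
           "Description=\"Number of distinct supporting callers\">"),
    paste0("##INFO=<ID=SUPP_CALLERS,Number=1,Type=String,",
           "Description=\"Comma-separated supporting caller ids\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO"), collapse = "\t"))
  body <- character(0)
  for (i in seq_len(nrow(x))) {
    supp_info <- sprintf("SUPP=%d;SUPP_CALLERS=%s", x$supp[i], x$callers[i])
    if (x$svtype[i] == "INS") {
      body <- c(body, paste(
        x$chrom1[i], x$pos1[i], sprintf("cons%d", i), "N", "<INS>", ".",
        "PASS",
        sprintf("SVTYPE=INS;END=%d;%s", x$pos2[i], supp_info),
        sep = "\t"))
    } else {
      id1 <- sprintf("cons%d_1", i)
      id2 <- sprintf("cons%d_2", i)
      alt1 <- bnd_alt(x$chrom2[i], x$pos2[i], x$strand1[i], x$strand2[i])
      alt2 <- bnd_alt(x$chrom1[i], x$pos1[i], x$strand2[i], x$strand1[i])
      body <- c(body,
        paste(x$chrom1[i], x$pos1[i], id1, "N", alt1, ".", "PASS",
              sprintf("SVTYPE=BND;MATEID=%s;%s", id2, supp_info),
              sep = "\t"),
        paste(x$chrom2[i], x$pos2[i], id2, "N", alt2, ".", "PASS",
              sprintf("SVTYPE=BND;MATEID=%s;%s", id1, supp_info),
              sep = "\t"))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
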