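#' Construct a tumor purity/ploidy record
#'
#' @param purity Tumor cell fraction in `[0, 1]`.
#' @param ploidy Average genome copy count, positive.
#' @param source Estimating tool: `"sequenza"`, `"purple"`, or `"other"`.
#' @return A list of class `purity_ploidy`.
#' @export
purity_ploidy <- function(purity, ploidy,
                          source = c("sequenza", "purple", "other")) {
  source <- match.arg(source)
  stopifnot(is.numeric(purity), length(purity) == 1,
            purity >= 0, purity <= 1,
            is.numeric(ploidy), length(ploidy) == 1, ploidy > 0)
  structure(list(purity = purity, ploidy = ploidy, source = source),
            class = "purity_ploidy")
}

#' Select the preferred purity/ploidy estimate
#'
#' When several tools report a purity/ploidy solution, Sequenza's estimate
#' is preferred; failing that, PURPLE's; failing that, the first estimate
#' supplied. Deterministic.
#'
#' @param candidates List of [purity_ploidy()] records.
#' @return The selected record.
#' @export
#' @examples
#' select_purity_ploidy(list(purity_ploidy(0.6, 3.1, "purple"),
#'                           purity_ploidy(0.55, 2.9, "sequenza")))
select_purity_ploidy <- function(candidates) {
  if (length(candidates) == 0) {
    stop("no purity/ploidy estimate available", call. = FALSE)
  }
  stopifnot(all(vapply(candidates, inherits, logical(1), "purity_ploidy")))
  src <- vapply(candidates, `[[`, character(1), "source")
  for (pref in c("sequenza", "purple")) {
    hit <- which(src == pref)
    if (length(hit)) return(candidates[[hit[1]]])
  }
  candidates[[1]]
}

#' Read a purity/ploidy summary file
#'
#' Accepts a headered TSV and looks for a purity column (named `purity`
#' or `cellularity`) and a ploidy column (`ploidy`, `ploidy.estimate`,
#' `ploidy_estimate`); the first data row is used. This covers both
#' Sequenza's confints table and PURPLE's purity summary without
#' tool-specific parsers.
#'
#' @param path Summary file.
#' @param source Tool that produced it.
#' @return A [purity_ploidy()] record.
#' @export
read_purity_ploidy <- function(path,
                               source = c("sequenza", "purple", "other")) {
  source <- match.arg(source)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("no rows in ", path, call. = FALSE)
  nm <- tolower(names(tab))
  pu <- which(nm %in% c("purity", "cellularity"))[1]
  pl <- which(nm %in% c("ploidy", "ploidy.estimate", "ploidy_estimate"))[1]
  if (is.na(pu) || is.na(pl)) {
    stop("no purity/ploidy columns found in ", path, call. = FALSE)
  }
  purity_ploidy(as.numeric(tab[1, pu]), as.numeric(tab[1, pl]), source)
}

#' @export
print.purity_ploidy <- function(x, ...) {
  cat(sprintf("<purity_ploidy> purity %.3f, ploidy %.3f (%s)\n",
              x$purity, x$ploidy, x$source))
  invisible(x)
}
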