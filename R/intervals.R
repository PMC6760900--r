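#' Genomic intervals (0-based, half-open)
#'
#' All internal coordinates in this package are 0-based half-open, the
#' convention of the UCSC chain format: an interval covers positions
#' `start, start+1, ..., end-1` and has length `end - start`. Report
#' rendering ([render_interval()]) converts to the 1-based inclusive form
#' used in prose (e.g. a 7 bp deletion at "chr4:138,873,545-138,873,551").
#'
#' @param chrom Chromosome / sequence name.
#' @param start 0-based start (integer, >= 0).
#' @param end 0-based exclusive end (integer, > start).
#' @param strand "+" or "-".
#' @return An object of class `genomic_interval`.
#' @examples
#' iv <- genomic_interval("chr4", 138873544, 138873551)
#' render_interval(iv)
#' interval_length(iv)
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != 1 || !nzchar(chrom)) stop("chrom must be a single name")
  if (is.na(start) || start < 0) stop("start must be >= 0")
  if (is.na(end) || end <= start) stop("end must be > start")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param iv A `genomic_interval`.
#' @export
interval_length <- function(iv) iv$end - iv$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(render_interval(x), "(", x$strand, ")\n")
  invisible(x)
}

#' Render an interval as 1-based inclusive text
#'
#' Converts the internal 0-based half-open interval to the `chrom:start-end`
#' dialect with 1-based inclusive coordinates and thousands separators,
#' matching how loci are quoted in reports. [parse_interval()] is the exact
#' inverse.
#'
#' @param iv A [genomic_interval()].
#' @return A character scalar, e.g. `"chr4:138,873,545-138,873,551"`.
#' @export
render_interval <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  fmt <- function(x) formatC(x, format = "d", big.mark = ",")
  paste0(iv$chrom, ":", fmt(iv$start + 1), "-", fmt(iv$end))
}

#' Parse the 1-based inclusive interval dialect
#'
#' @param text Text like `"chr4:138,873,545-138,873,551"` (en dash also
#'   accepted).
#' @param strand Strand to attach ("+" by default; the rendering carries no
#'   strand).
#' @return A [genomic_interval()] in internal 0-based half-open coordinates.
#' @export
parse_interval <- function(text, strand = "+") {
  txt <- gsub(",", "", text, fixed = TRUE)
  txt <- gsub("–", "-", txt)  # en dash
  m <- regmatches(txt, regexec("^(.+):([0-9]+)-([0-9]+)$", txt))[[1]]
  if (length(m) != 4) stop("cannot parse interval: ", text)
  start1 <- as.numeric(m[3]); end1 <- as.numeric(m[4])
  if (end1 < start1) stop("end before start in: ", text)
  genomic_interval(m[2], start1 - 1, end1, strand)
}
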