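#' UCSC chain alignments
#'
#' A chain is a pairwise genome alignment made of gapless blocks. Each
#' block line carries `size dt dq`: `size` aligned bases, then `dt`
#' unaligned bases on the target and `dq` on the query before the next
#' block; the final line carries `size` only. All coordinates are 0-based
#' half-open. Minus-strand query coordinates are stored in the
#' reverse-complement frame, exactly as in the published format, and are
#' reflected to the forward frame on output by [map_through_chain()].
#'
#' @name chain
NULL

new_chain <- function(score, t_name, t_size, t_strand, t_start, t_end,
                      q_name, q_size, q_strand, q_start, q_end, id, blocks) {
  structure(list(
    score = score,
    t_name = t_name, t_size = t_size, t_strand = t_strand,
    t_start = t_start, t_end = t_end,
    q_name = q_name, q_size = q_size, q_strand = q_strand,
    q_start = q_start, q_end = q_end,
    id = id,
    blocks = blocks  # data.frame(size, dt, dq); last row dt = dq = NA
  ), class = "chain_alignment")
}

validate_chain <- function(ch, line = NA) {
  b <- ch$blocks
  if (nrow(b) < 1 || any(b$size <= 0)) {
    stop("chain ", ch$id, ": block sizes must be > 0")
  }
  gaps_t <- sum(b$dt[-nrow(b)])
  gaps_q <- sum(b$dq[-nrow(b)])
  t_span <- sum(b$size) + (if (nrow(b) > 1) gaps_t else 0)
  q_span <- sum(b$size) + (if (nrow(b) > 1) gaps_q else 0)
  if (t_span != ch$t_end - ch$t_start) {
    stop("chain ", ch$id, ": target span mismatch (blocks sum to ", t_span,
         ", header says ", ch$t_end - ch$t_start, ")")
  }
  if (q_span != ch$q_end - ch$q_start) {
    stop("chain ", ch$id, ": query span mismatch (blocks sum to ", q_span,
         ", header says ", ch$q_end - ch$q_start, ")")
  }
  ch
}

#' Read a UCSC chain file
#'
#' Parses every chain in the file and validates that the block sums span
#' the header's target and query intervals. Parsing is lossless:
#' [write_chain_file()] reproduces the input byte for byte on valid files.
#'
#' @param path Path to a chain file.
#' @return A list of `chain_alignment` objects.
#' @export
read_chain_file <- function(path) {
  if (!file.exists(path)) stop("chain file not found: ", path)
  lines <- readLines(path)
  chains <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1; next }
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) != 13) {
      stop("malformed chain header at line ", i, ": ", lines[i])
    }
    num <- suppressWarnings(as.numeric(f[c(2, 4, 6, 7, 9, 11, 12)]))
    if (anyNA(num)) stop("malformed chain header at line ", i, ": ", lines[i])
    blocks <- list(); j <- i + 1; done <- FALSE
    while (j <= length(lines) && !done) {
      bl <- trimws(lines[j])
      if (!nzchar(bl)) { j <- j + 1; break }
      bf <- suppressWarnings(as.numeric(strsplit(bl, "[ \t]+")[[1]]))
      if (anyNA(bf) || !length(bf) %in% c(1, 3)) {
        stop("malformed block line at line ", j, ": ", lines[j])
      }
      if (length(bf) == 1) {
        blocks[[length(blocks) + 1]] <- c(bf, NA, NA)
        done <- TRUE
      } else {
        blocks[[length(blocks) + 1]] <- bf
      }
      j <- j + 1
    }
    if (!done) stop("chain starting at line ", i, " lacks a terminal block")
    bm <- do.call(rbind, blocks)
    ch <- new_chain(
      score = num[1],
      t_name = f[3], t_size = num[2], t_strand = f[5],
      t_start = num[3], t_end = num[4],
      q_name = f[8], q_size = num[5], q_strand = f[10],
      q_start = num[6], q_end = num[7],
      id = f[13],
      blocks = data.frame(size = bm[, 1], dt = bm[, 2], dq = bm[, 3])
    )
    chains[[length(chains) + 1]] <- validate_chain(ch)
    i <- j
  }
  chains
}

#' Serialize chains back to the UCSC chain format
#'
#' @param chains A list of `chain_alignment` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chain_file <- function(chains, path) {
  out <- character(0)
  for (ch in chains) {
    hdr <- paste("chain", ch$score, ch$t_name, ch$t_size, ch$t_strand,
                 ch$t_start, ch$t_end, ch$q_name, ch$q_size, ch$q_strand,
                 ch$q_start, ch$q_end, ch$id)
    b <- ch$blocks
    body <- vapply(seq_len(nrow(b)), function(k) {
      if (k == nrow(b)) as.character(b$size[k])
      else paste(b$size[k], b$dt[k], b$dq[k])
    }, character(1))
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Project a target interval through a chain onto the query assembly
#'
#' Walks the chain blocks and returns the query-side projections of the
#' aligned portions of `iv`; positions falling into target gaps (`dt`) are
#' dropped. For minus-strand queries the stored reverse-complement-frame
#' coordinates are reflected back to the forward frame
#' (`forward = q_size - x`). Used by the synteny filter to find the
#' orthologous locus of a candidate ORF.
#'
#' @param iv A [genomic_interval()] on the chain's target sequence.
#' @param chain A `chain_alignment`.
#' @return A list of [genomic_interval()] on the query (possibly empty);
#'   adjacent projections are not merged across gaps.
#' @export
map_through_chain <- function(iv, chain) {
  stopifnot(inherits(iv, "genomic_interval"),
            inherits(chain, "chain_alignment"))
  if (iv$chrom != chain$t_name) return(list())
  out <- list()
  t_pos <- chain$t_start
  q_pos <- chain$q_start
  b <- chain$blocks
  for (k in seq_len(nrow(b))) {
    bs <- b$size[k]
    ov_start <- max(iv$start, t_pos)
    ov_end <- min(iv$end, t_pos + bs)
    if (ov_start < ov_end) {
      off <- ov_start - t_pos
      qs <- q_pos + off
      qe <- qs + (ov_end - ov_start)
      if (chain$q_strand == "-") {
        fwd <- c(chain$q_size - qe, chain$q_size - qs)
        out[[length(out) + 1]] <- genomic_interval(
          chain$q_name, fwd[1], fwd[2],
          strand = if (iv$strand == "+") "-" else "+")
      } else {
        out[[length(out) + 1]] <- genomic_interval(
          chain$q_name, qs, qe, strand = iv$strand)
      }
    }
    if (k < nrow(b)) {
      t_pos <- t_pos + bs + b$dt[k]
      q_pos <- q_pos + bs + b$dq[k]
    }
  }
  out
}
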