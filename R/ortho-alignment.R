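#' Orthologous-region multiple alignment with ORF annotation
#'
#' Holds aligned sequences (letters A, C, G, T, `-`, N) for the taxa of a
#' species tree, together with the ORF location in alignment columns and
#' the reading-frame anchor (the column of the first codon base).
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param orf Length-2 integer vector: first and last ORF column (1-based,
#'   inclusive, in alignment coordinates).
#' @param reference Taxon whose degapped ORF must be codon-complete
#'   (defaults to the first taxon).
#' @return An object of class `ortho_alignment` with the character matrix
#'   in `$mat` (taxa x columns).
#' @export
ortho_alignment <- function(seqs, orf, reference = names(seqs)[1]) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by taxon")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("aligned sequences differ in length")
  ncol <- lens[[1]]
  orf <- as.integer(orf)
  if (length(orf) != 2 || orf[1] < 1 || orf[2] > ncol || orf[1] > orf[2]) {
    stop("ORF interval must lie within the alignment")
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad)) stop("invalid alignment letters: ",
                        paste(bad, collapse = ", "))
  if (!reference %in% names(seqs)) stop("reference taxon not in alignment")
  ref_orf <- mat[reference, orf[1]:orf[2]]
  if (sum(ref_orf != "-") %% 3 != 0) {
    stop("reference ORF gap-free length not divisible by 3")
  }
  structure(list(taxa = names(seqs), mat = mat, orf = orf,
                 frame_anchor = orf[1], reference = reference),
            class = "ortho_alignment")
}

#' @export
print.ortho_alignment <- function(x, ...) {
  cat("ortho_alignment:", length(x$taxa), "taxa x", ncol(x$mat),
      "columns; ORF columns", x$orf[1], "-", x$orf[2], "\n")
  invisible(x)
}

# in-frame codon start columns of the ORF (alignment coordinates)
codon_starts <- function(aln) {
  seq(aln$orf[1], aln$orf[2] - 2, by = 3)
}

# codon of one taxon/ancestor row at a codon start column, or NA if gapped
codon_at <- function(row, start) {
  cd <- row[start:(start + 2)]
  if (any(cd == "-") || any(cd == "N")) NA_character_
  else paste(cd, collapse = "")
}

#' Degapped ORF translation of one taxon, stop as 21st symbol
#'
#' Removes alignment gaps from the taxon's ORF and translates it with `*`
#' standing in for stop codons, so disrupted frames remain comparable.
#'
#' @param aln An [ortho_alignment()].
#' @param taxon Taxon name.
#' @return Amino-acid string over the 20 letters plus `*`.
#' @export
orf_protein <- function(aln, taxon) {
  if (!taxon %in% aln$taxa) stop("taxon not in alignment: ", taxon)
  nt <- aln$mat[taxon, aln$orf[1]:aln$orf[2]]
  nt <- nt[nt != "-"]
  nt <- paste(nt, collapse = "")
  if (nchar(nt) %% 3 != 0) nt <- substr(nt, 1, 3 * (nchar(nt) %/% 3))
  if (!nzchar(nt)) return("")
  translate_cds(nt)
}
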