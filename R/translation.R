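#' Proteogenomic peptide uniqueness
#'
#' A mass-spectrometry peptide supports translation of a candidate protein
#' iff (a) its whole sequence is an exact substring of the candidate and
#' (b) it differs by at least two amino acids from every equal-length
#' window of every background protein. The reported distance is the
#' minimum Hamming distance over all background windows.
#'
#' Isoleucine and leucine are treated as distinct residues by default;
#' set `il_equivalent = TRUE` to collapse them (mass spectrometry cannot
#' distinguish the two).
#'
#' @param pep Peptide sequence.
#' @param target Candidate protein sequence.
#' @param background Character vector of background protein sequences
#'   (excluding the target).
#' @param il_equivalent Treat I and L as identical.
#' @return List with `unique` (verdict), `min_distance` (NA when the
#'   peptide is longer than every background protein or the verdict is
#'   vacuous), and `substring_match`.
#' @export
peptide_unique <- function(pep, target, background, il_equivalent = FALSE) {
  pep <- toupper(pep); target <- toupper(target)
  if (!nzchar(pep)) stop("empty peptide")
  if (nchar(pep) > nchar(target)) {
    return(list(unique = FALSE, min_distance = NA_real_,
                substring_match = FALSE))
  }
  canon <- function(x) if (il_equivalent) gsub("I", "L", x, fixed = TRUE)
                       else x
  match <- grepl(canon(pep), canon(target), fixed = TRUE)
  mind <- min_background_hamming(canon(pep),
                                 vapply(toupper(background), canon,
                                        character(1), USE.NAMES = FALSE))
  list(unique = match && (is.infinite(mind) || mind >= 2),
       min_distance = if (is.infinite(mind)) NA_real_ else mind,
       substring_match = match)
}

# minimum Hamming distance between pep and every length-|pep| window of
# every background sequence; Inf when no window exists
min_background_hamming <- function(pep, background) {
  k <- nchar(pep)
  pc <- chars(pep)
  best <- Inf
  for (bg in background) {
    n <- nchar(bg)
    if (n < k) next
    bc <- chars(bg)
    for (s in seq_len(n - k + 1)) {
      d <- sum(pc != bc[s:(s + k - 1)])
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

#' P-site offset configuration for ribosome profiling
#'
#' Maps each sample to the usable read lengths and the 5'-end offset that
#' places the ribosomal P-site, as determined from start/stop-codon
#' metaplots (e.g. brain: lengths 29 and 30, offset 12 each; testis:
#' length 28, offset 12).
#'
#' @param offsets Named list: sample -> named numeric vector
#'   (names = read lengths, values = offsets).
#' @return A list of class `psite_config`.
#' @examples
#' cfg <- psite_config(list(brain = c(`29` = 12, `30` = 12),
#'                          testis = c(`28` = 12)))
#' @export
psite_config <- function(offsets) {
  for (s in names(offsets)) {
    len <- as.numeric(names(offsets[[s]]))
    off <- as.numeric(offsets[[s]])
    if (any(is.na(len)) || any(off < 0) || any(off >= len)) {
      stop("offsets must satisfy 0 <= offset < read length (sample ", s, ")")
    }
  }
  structure(list(offsets = offsets), class = "psite_config")
}

#' Assign ribosome P-sites and reading-frame fractions
#'
#' Reads whose length is absent from the sample's offset table are
#' discarded. For a retained read the P-site is `5' end + offset` on the
#' forward strand and `5' end - offset` on the reverse strand. Frame is
#' computed relative to a CDS start position: `(psite - cds_start) mod 3`
#' forward, `(cds_start - psite) mod 3` reverse.
#'
#' @param reads Data.frame with columns `pos` (5' end), `length`, `strand`.
#' @param cfg A [psite_config()].
#' @param sample Sample name present in `cfg`.
#' @param cds_start CDS start coordinate (same system as `pos`; position of
#'   the first base of the start codon, strand-aware).
#' @return List with `psites` (data.frame pos/length/strand/psite/frame),
#'   `frame_fractions` (length-3 numeric over frames 0,1,2; zeros when no
#'   read is retained) and `n_discarded`.
#' @export
assign_p_sites <- function(reads, cfg, sample, cds_start = 0) {
  if (!sample %in% names(cfg$offsets)) {
    stop("sample not in P-site config: ", sample)
  }
  tab <- cfg$offsets[[sample]]
  keep <- as.character(reads$length) %in% names(tab)
  kept <- reads[keep, , drop = FALSE]
  if (!nrow(kept)) {
    return(list(psites = cbind(kept, psite = numeric(0), frame = integer(0)),
                frame_fractions = c(`0` = 0, `1` = 0, `2` = 0),
                n_discarded = sum(!keep)))
  }
  off <- as.numeric(tab[as.character(kept$length)])
  psite <- ifelse(kept$strand == "+", kept$pos + off, kept$pos - off)
  frame <- ifelse(kept$strand == "+",
                  (psite - cds_start) %% 3, (cds_start - psite) %% 3)
  fr <- table(factor(frame, levels = 0:2))
  list(psites = cbind(kept, psite = psite, frame = as.integer(frame)),
       frame_fractions = as.numeric(fr) / nrow(kept),
       n_discarded = sum(!keep))
}

#' Gene-level ribosome-profiling support
#'
#' A gene counts as ribosome-supported when at least one in-frame P-site
#' falls within its annotated ORF — a deliberate simplification of
#' spectral periodicity testing, which is out of scope here.
#'
#' @param psites Result of [assign_p_sites()].
#' @param orf_start,orf_end ORF interval (same coordinates as the reads;
#'   half-open).
#' @return Logical.
#' @export
ribo_supported <- function(psites, orf_start, orf_end) {
  p <- psites$psites
  any(p$frame == 0 & p$psite >= orf_start & p$psite < orf_end)
}

#' Combine ribosome and peptide evidence per gene
#'
#' A gene has direct evidence for translation when it is supported by
#' ribosome profiling OR by at least one unique peptide.
#'
#' @param genes Character vector of gene ids (no duplicates).
#' @param ribo_calls Named logical vector (gene -> ribo support).
#' @param peptide_calls Named logical vector (gene -> peptide support).
#' @return List with `table` (gene, ribo_supported, peptide_supported,
#'   supported) and `n_supported`.
#' @export
summarize_translation <- function(genes, ribo_calls, peptide_calls) {
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  rb <- stats::setNames(rep(FALSE, length(genes)), genes)
  pp <- rb
  rb[names(ribo_calls)[ribo_calls]] <- TRUE
  pp[names(peptide_calls)[peptide_calls]] <- TRUE
  rb <- rb[genes]; pp <- pp[genes]
  tab <- data.frame(gene = genes, ribo_supported = unname(rb),
                    peptide_supported = unname(pp),
                    supported = unname(rb | pp))
  list(table = tab, n_supported = sum(tab$supported))
}
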