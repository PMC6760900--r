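#' Screen configuration
#'
#' Bundles the thresholds and alignment parameters of the de novo
#' candidate screen. Defaults follow the screen's published rules: minimum
#' protein length 30 aa; a candidate is discarded if it hits the
#' close-relative proteome at E < 1e-7 or the broader database at
#' E < 1e-3; the synteny filter discards a candidate whose protein aligns
#' to an overlapping ortholog-region ORF with local score >= 40. Alignment
#' defaults mirror the EMBOSS water defaults (BLOSUM62, gap open 10,
#' gap extend 0.5).
#'
#' @param min_protein_len Minimum protein length in amino acids.
#' @param e_thresh_close E-value threshold against the close proteome.
#' @param e_thresh_far E-value threshold against the far (database) set.
#' @param synteny_score_thresh Local alignment score threshold for the
#'   synteny filter.
#' @param matrix Scoring matrix name (a matrix shipped with Biostrings).
#' @param gap_open,gap_extend Affine gap penalties for the synteny
#'   alignment (positive costs; water defaults). A gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param db_gap_open,db_gap_extend Gap penalties for the database-search
#'   (phylostratigraphy) alignments. Default 11/1 — the penalties to which
#'   the Karlin-Altschul constants below are calibrated; the E-value model
#'   is only valid with matching penalties.
#' @param lambda,K Karlin-Altschul statistics used by [estimate_evalue()]
#'   (published gapped-BLOSUM62 values for gap penalties 11/1).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(min_protein_len = 30,
                          e_thresh_close = 1e-7,
                          e_thresh_far = 1e-3,
                          synteny_score_thresh = 40,
                          matrix = "BLOSUM62",
                          gap_open = 10, gap_extend = 0.5,
                          db_gap_open = 11, db_gap_extend = 1,
                          lambda = 0.267, K = 0.041) {
  stopifnot(min_protein_len >= 1, e_thresh_close > 0, e_thresh_far > 0,
            synteny_score_thresh > 0, gap_open >= 0, gap_extend >= 0,
            db_gap_open >= 0, db_gap_extend >= 0, lambda > 0, K > 0)
  structure(list(min_protein_len = min_protein_len,
                 e_thresh_close = e_thresh_close,
                 e_thresh_far = e_thresh_far,
                 synteny_score_thresh = synteny_score_thresh,
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend,
                 db_gap_open = db_gap_open, db_gap_extend = db_gap_extend,
                 lambda = lambda, K = K),
            class = "screen_config")
}

get_score_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "X")

check_protein <- function(seq, what = "sequence") {
  if (!nzchar(seq)) stop(what, " is empty")
  bad <- setdiff(unique(chars(toupper(seq))), AA_LETTERS)
  if (length(bad)) {
    stop(what, " contains unknown residue letter(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment of two protein sequences under the configured
#' substitution matrix and affine gap penalties. Masked residues (`X`, or
#' lowercase input which is uppercased to `X`-free letters by the caller)
#' never score positively under BLOSUM62, so low-complexity-masked regions
#' cannot seed hits. The score of a sequence against itself equals the sum
#' of the matrix diagonal entries, and a pair with no positive-scoring
#' residue match scores 0 (the empty local alignment).
#'
#' @param a,b Protein sequences (non-empty).
#' @param cfg A [screen_config()].
#' @return A list (class `alignment_hit`) with `query`, `target`,
#'   `score`, `e_value` (NA until [estimate_evalue()] is applied) and the
#'   aligned intervals.
#' @export
local_align <- function(a, b, cfg = screen_config()) {
  a <- toupper(a); b <- toupper(b)
  check_protein(a, "query"); check_protein(b, "target")
  mat <- get_score_matrix(cfg$matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat,
    gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend,
    type = "local")
  sc <- max(0, Biostrings::score(pa))
  q_iv <- c(Biostrings::start(Biostrings::pattern(pa)) - 1,
            Biostrings::end(Biostrings::pattern(pa)))
  t_iv <- c(Biostrings::start(Biostrings::subject(pa)) - 1,
            Biostrings::end(Biostrings::subject(pa)))
  structure(list(query = a, target = b, score = sc,
                 query_interval = q_iv, target_interval = t_iv,
                 e_value = NA_real_),
            class = "alignment_hit")
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a query of length `m` and a
#' database of `n` residues. With the gapped BLOSUM62 constants
#' (lambda = 0.267, K = 0.041) this approximates the statistics of the
#' standard protein search tools. E is strictly decreasing in the score
#' and linear in both `m` and `n`.
#'
#' @param score Raw local alignment score (> 0), or an `alignment_hit`.
#' @param m Query length in residues.
#' @param n Database size in residues.
#' @param cfg A [screen_config()] supplying lambda and K.
#' @return The E-value (positive real).
#' @export
estimate_evalue <- function(score, m, n, cfg = screen_config()) {
  if (inherits(score, "alignment_hit")) score <- score$score
  if (m <= 0 || n <= 0) stop("m and n must be positive")
  if (score <= 0) stop("score must be positive")
  cfg$K * m * n * exp(-cfg$lambda * score)
}

#' Best E-value of one protein against a set of proteins
#'
#' Aligns `query` to every record in `targets` with the database-search
#' gap penalties (the ones matching the configured Karlin-Altschul
#' constants) and returns the smallest E-value (Inf when no alignment
#' scores positively). `n` is the total residue count of the target set,
#' entering every E-value as the database size.
#'
#' @param query Protein sequence.
#' @param targets Named character vector of protein sequences.
#' @param cfg A [screen_config()].
#' @return List with `e_value`, `score`, `target` (id of best hit or NA).
#' @export
best_hit <- function(query, targets, cfg = screen_config()) {
  if (!length(targets)) return(list(e_value = Inf, score = 0,
                                    target = NA_character_))
  db_cfg <- cfg
  db_cfg$gap_open <- cfg$db_gap_open
  db_cfg$gap_extend <- cfg$db_gap_extend
  n <- sum(nchar(targets))
  m <- nchar(query)
  best <- list(e_value = Inf, score = 0, target = NA_character_)
  for (id in names(targets)) {
    hit <- local_align(query, targets[[id]], db_cfg)
    if (hit$score > 0) {
      e <- estimate_evalue(hit$score, m, n, cfg)
      if (e < best$e_value) best <- list(e_value = e, score = hit$score,
                                         target = id)
    }
  }
  best
}
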