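#' ORF integrity filter
#'
#' A candidate ORF must (1) encode at least 30 amino acids, (2) start with
#' a start codon, (3) end with a stop codon, and (4) contain no internal
#' stop codon. The verdict reports the first failing condition in that
#' order. Protein length is `CDS length / 3 - 1` (the terminal stop is not
#' an amino acid).
#'
#' @param model A [gene_model()] with `cds_seq` set, or a CDS string.
#' @param cfg A [screen_config()] (supplies the minimum length).
#' @return List with `ok` (logical) and `reason` (`NA` when ok; otherwise
#'   one of "length", "start codon", "stop codon", "internal stop").
#' @export
filter_orf_integrity <- function(model, cfg = screen_config()) {
  cds <- if (inherits(model, "gene_model")) model$cds_seq else model
  if (is.null(cds)) stop("no CDS sequence available")
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  n_codons <- nchar(cds) / 3
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa_len <- n_codons - 1
  if (aa_len < cfg$min_protein_len) {
    return(list(ok = FALSE, reason = "length"))
  }
  if (codons[1] != "ATG") return(list(ok = FALSE, reason = "start codon"))
  if (!is_stop_codon(codons[n_codons])) {
    return(list(ok = FALSE, reason = "stop codon"))
  }
  if (n_codons > 2 && any(is_stop_codon(codons[2:(n_codons - 1)]))) {
    return(list(ok = FALSE, reason = "internal stop"))
  }
  list(ok = TRUE, reason = NA_character_)
}

#' Phylostratigraphy filter
#'
#' Implements the two-step homology screen: a candidate is removed if its
#' best hit against the close-relative proteome reaches E < `e_thresh_close`
#' (1e-7 by default), or if its best hit against the far set — excluding
#' records from the focal genus — reaches E < `e_thresh_far` (1e-3).
#' Survivors are the putative lineage-specific (orphan) proteins.
#'
#' @param candidates Named character vector of candidate protein sequences.
#' @param close_proteome Named character vector (close relative).
#' @param far_proteome Named character vector (broad database).
#' @param cfg A [screen_config()].
#' @param far_taxa Optional character vector, one taxon label per
#'   `far_proteome` record; records whose taxon is in `exclude_taxa` are
#'   dropped before searching (the screen ignores hits from the focal
#'   genus).
#' @param exclude_taxa Taxon labels to exclude from the far set.
#' @return A data.frame with one row per candidate: `gene`,
#'   `best_e_close`, `best_e_far`, `phylostrat_pass`.
#' @export
phylostrat_filter <- function(candidates, close_proteome, far_proteome,
                              cfg = screen_config(),
                              far_taxa = NULL, exclude_taxa = character(0)) {
  if (!length(candidates)) {
    return(data.frame(gene = character(0), best_e_close = numeric(0),
                      best_e_far = numeric(0),
                      phylostrat_pass = logical(0)))
  }
  if (!is.null(far_taxa)) {
    stopifnot(length(far_taxa) == length(far_proteome))
    far_proteome <- far_proteome[!far_taxa %in% exclude_taxa]
  }
  rows <- lapply(names(candidates), function(id) {
    ec <- best_hit(candidates[[id]], close_proteome, cfg)$e_value
    ef <- best_hit(candidates[[id]], far_proteome, cfg)$e_value
    data.frame(gene = id, best_e_close = ec, best_e_far = ef,
               phylostrat_pass = ec >= cfg$e_thresh_close &
                 ef >= cfg$e_thresh_far)
  })
  do.call(rbind, rows)
}

#' Synteny filter through chain alignments
#'
#' Projects the candidate's ORF through the supplied genome-alignment
#' chains, collects other-species ORFs overlapping the projected region,
#' and aligns the candidate protein to each of their proteins. The
#' candidate is filtered out if any local alignment score reaches the
#' threshold (40 by default). Candidates whose locus is not covered by any
#' chain, or whose projection overlaps no ORF, pass vacuously.
#'
#' @param protein Candidate protein sequence.
#' @param orf_iv [genomic_interval()] of the candidate ORF on the focal
#'   genome.
#' @param chains List of `chain_alignment` (focal genome as target).
#' @param other_models List of `gene_model` objects for the other species;
#'   each must carry `features` rows with CDS intervals (on the chain query
#'   assembly) and a `protein` sequence.
#' @param cfg A [screen_config()].
#' @return List with `pass` (TRUE = retained), `max_score`, and
#'   `overlapping_genes`.
#' @export
synteny_filter <- function(protein, orf_iv, chains, other_models,
                           cfg = screen_config()) {
  if (!length(chains)) {
    dn_log("no chains cover ", render_interval(orf_iv), "; candidate passes")
    return(list(pass = TRUE, max_score = NA_real_,
                overlapping_genes = character(0)))
  }
  proj <- list()
  for (ch in chains) proj <- c(proj, map_through_chain(orf_iv, ch))
  if (!length(proj)) {
    return(list(pass = TRUE, max_score = NA_real_,
                overlapping_genes = character(0)))
  }
  overlaps <- function(iv, chrom, s, e) {
    iv$chrom == chrom & iv$start < e & s < iv$end
  }
  hit_genes <- character(0)
  for (gm in other_models) {
    cds <- gm$features[gm$features$feature == "CDS", , drop = FALSE]
    if (!nrow(cds)) next
    hit <- any(vapply(proj, function(p) {
      any(overlaps(p, cds$chrom, cds$start, cds$end))
    }, logical(1)))
    if (hit) hit_genes <- c(hit_genes, gm$gene)
  }
  if (!length(hit_genes)) {
    return(list(pass = TRUE, max_score = NA_real_,
                overlapping_genes = character(0)))
  }
  scores <- vapply(other_models[vapply(other_models, function(g)
    g$gene %in% hit_genes, logical(1))], function(gm) {
      local_align(protein, gm$protein, cfg)$score
    }, numeric(1))
  mx <- max(scores)
  list(pass = mx < cfg$synteny_score_thresh, max_score = mx,
       overlapping_genes = hit_genes)
}

#' Run the full candidate screen
#'
#' Applies, in order, the ORF-integrity filter, the phylostratigraphy
#' filter and the synteny filter; a gene is a de novo candidate iff all
#' three verdicts are true.
#'
#' @param models Named list of [gene_model()] objects (CDS sequence set).
#' @param close_proteome,far_proteome Named protein vectors for
#'   [phylostrat_filter()].
#' @param chains List of chains for [synteny_filter()] (may be empty).
#' @param other_models List of other-species `gene_model`s.
#' @param cfg A [screen_config()].
#' @param far_taxa,exclude_taxa Passed to [phylostrat_filter()].
#' @return A data.frame with one row per gene: the three verdicts, the
#'   screen metrics and `candidate` (the conjunction).
#' @export
screen_candidates <- function(models, close_proteome, far_proteome,
                              chains = list(), other_models = list(),
                              cfg = screen_config(),
                              far_taxa = NULL, exclude_taxa = character(0)) {
  genes <- names(models)
  orf_ok <- vapply(models, function(m) filter_orf_integrity(m, cfg)$ok,
                   logical(1))
  prots <- vapply(models, function(m) m$protein %||% "", character(1))
  surv <- genes[orf_ok & nzchar(prots)]
  ps <- phylostrat_filter(stats::setNames(prots[surv], surv),
                          close_proteome, far_proteome, cfg,
                          far_taxa, exclude_taxa)
  res <- data.frame(gene = genes, orf_ok = orf_ok,
                    best_e_close = NA_real_, best_e_far = NA_real_,
                    phylostrat_pass = FALSE, synteny_pass = FALSE,
                    synteny_max_score = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(res) <- genes
  if (nrow(ps)) {
    res[ps$gene, c("best_e_close", "best_e_far")] <-
      ps[, c("best_e_close", "best_e_far")]
    res[ps$gene, "phylostrat_pass"] <- ps$phylostrat_pass
  }
  for (g in genes) {
    if (!res[g, "orf_ok"] || !res[g, "phylostrat_pass"]) next
    iv <- model_orf_interval(models[[g]])
    if (is.null(iv)) {
      res[g, "synteny_pass"] <- TRUE
      next
    }
    sf <- synteny_filter(models[[g]]$protein, iv, chains, other_models, cfg)
    res[g, "synteny_pass"] <- sf$pass
    res[g, "synteny_max_score"] <- sf$max_score
  }
  res$candidate <- res$orf_ok & res$phylostrat_pass & res$synteny_pass
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genomic span of a model's CDS, or NULL when no features are attached
model_orf_interval <- function(model) {
  f <- model$features
  if (is.null(f)) return(NULL)
  cds <- f[f$feature == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(NULL)
  genomic_interval(cds$chrom[1], min(cds$start), max(cds$end),
                   strand = cds$strand[1])
}
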