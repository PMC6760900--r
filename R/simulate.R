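#' Simulation configuration
#'
#' One seeded configuration object drives every generator, so a full
#' synthetic study is a pure function of its `sim_config`. The defaults
#' are the package's study conditions: 40 focal genes of which 20 are
#' planted orphans; a 6-taxon tree (2 outgroups) with one planted
#' enabler, one stop gain and one 17 nt frameshift deletion at branch
#' lengths of at most 0.02 substitutions/site; a 24-sample (12 KO / 12
#' WT) count matrix over 2,000 genes with three estrous-phase clusters,
#' marker shifts (Pgr/Esr1 up, Gper1 down in cluster 1) and 60 genes with
#' a 1.5-fold knockout effect confined to cluster 1 at NB dispersion
#' 0.05; 100 genes with a 0.9 translated fraction; and 16 knockout vs 20
#' wildtype/het litters with early-mixture weights 0.75 vs 0.1 and
#' infanticide probabilities 0.25 vs 0.
#'
#' @param seed Integer seed (mandatory; every generator derives its
#'   randomness from it).
#' @param ... Named blocks overriding defaults (merged recursively), e.g.
#'   `counts = list(dispersion = 0.1)`.
#' @return Nested list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    proteome = list(
      n_genes = 40, n_orphans = 20, len_range = c(80, 150),
      close_divergence = 0.10, far_divergence = 0.25,
      focal_taxon = "Mus"),
    orf = list(
      tree = paste0("((out1:0.01,out2:0.01)outgroups:0.008,",
                    "((ingA:0.005,ingB:0.005)cladeAB:0.005,",
                    "(ingC:0.005,ingD:0.005)cladeCD:0.005)ingroup:0.01)",
                    "root;"),
      outgroups = c("out1", "out2"),
      n_codons = 100, flank = 150,
      events = list(
        list(type = "stop_loss", branch = "ingroup", codon = 20),
        list(type = "stop_gain", branch = "ingA", codon = 50),
        list(type = "deletion", branch = "cladeCD", codon = 70,
             length = 17))),
    counts = list(
      n_genes = 2000, cluster_sizes = c(12, 6, 6),
      meanlog = 5.5, sdlog = 1.2, dispersion = 0.01,
      n_de = 60, fold_change = 1.5, de_cluster = 1, de_min_mean = 100,
      n_cluster_genes = 300, cluster_lfc = 2,
      markers = c("Pgr", "Esr1", "Gper1"), marker_fold = 4),
    translation = list(
      n_genes = 100, translated_fraction = 0.9, peptide_len = 9,
      protein_len = c(60, 120), reads_per_gene = 20),
    litters = list(
      n_ko = 16, n_wt = 20,
      early_weight = c(KO = 0.75, WT = 0.1),
      infanticide_prob = c(KO = 0.25, WT = 0),
      early_mean = 23, early_sd = 1.5, early_range = c(20, 25),
      late_mean = 37, late_sd = 2, late_range = c(35, 46),
      days1_mean = 22.5, days1_sd = 2,
      pups_mean = 7, pups_sd = 1.5))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      # one-level merge: a named entry replaces the default wholesale
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "sim_config")
}

AA20 <- setdiff(AA_LETTERS, "X")

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1, replace = TRUE), collapse = ""))
}

# i.i.d. uniform amino-acid replacement at the given per-site rate;
# the leading M is preserved so mutants stay valid ORF products
mutate_protein <- function(seq, rate) {
  aa <- chars(seq)
  hit <- which(stats::runif(length(aa)) < rate)
  hit <- hit[hit > 1]
  for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1)
  paste(aa, collapse = "")
}

# reverse-translate a protein into a CDS (random synonymous codons) and
# append a stop codon
CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

reverse_translate <- function(protein) {
  aa <- chars(protein)
  cods <- vapply(aa, function(a) sample(CODON_TABLE[[a]], 1), character(1))
  paste0(paste(cods, collapse = ""), sample(STOP_CODONS, 1))
}

#' Simulate proteomes with planted orphans
#'
#' Generates a focal proteome in which `n_orphans` genes are planted
#' orphans (random sequences with matched length and composition, absent
#' from every other proteome) and the rest have diverged homologs: a
#' close-relative homolog at `close_divergence` amino-acid replacement
#' rate and a far-database homolog at `far_divergence`. The far set also
#' contains the focal proteins themselves under the focal genus label, so
#' genus exclusion is exercised. Gene models (with CDS) and toy chain
#' alignments consistent with gene placement are emitted: homolog loci
#' are covered by a chain onto the other-species assembly where an
#' ortholog ORF lies, orphan loci are not.
#'
#' @param cfg A [sim_config()].
#' @return List: `models` (named focal [gene_model()]s), `proteins`,
#'   `close_proteome`, `far_proteome`, `far_taxa`, `exclude_taxa`,
#'   `chains`, `other_models`, and `truth` (data.frame gene/orphan).
#' @export
simulate_proteomes <- function(cfg = sim_config()) {
  p <- cfg$proteome
  stopifnot(p$n_orphans <= p$n_genes)
  with_seed(cfg$seed + 101L, {
    genes <- sprintf("gene%03d", seq_len(p$n_genes))
    orphan <- seq_len(p$n_genes) <= p$n_orphans
    lens <- sample(p$len_range[1]:p$len_range[2], p$n_genes, replace = TRUE)
    prots <- stats::setNames(vapply(lens, random_protein, character(1)),
                             genes)
    close <- list(); far <- list(); far_taxa <- character(0)
    other_models <- list(); chains <- list(); models <- list()
    for (i in seq_len(p$n_genes)) {
      g <- genes[i]
      cds <- reverse_translate(prots[[g]])
      start <- (i - 1) * 5000
      feats <- data.frame(gene = g, transcript = paste0(g, ".t1"),
                          chrom = "chrF", start = start,
                          end = start + nchar(cds), strand = "+",
                          feature = c("exon", "CDS"))
      models[[g]] <- gene_model(g, feats, cds_seq = cds)
      far[[paste0(g, "_self")]] <- prots[[g]]
      far_taxa <- c(far_taxa, p$focal_taxon)
      if (!orphan[i]) {
        close[[paste0(g, "_rat")]] <- mutate_protein(prots[[g]],
                                                     p$close_divergence)
        far[[paste0(g, "_far")]] <- mutate_protein(prots[[g]],
                                                   p$far_divergence)
        far_taxa <- c(far_taxa, "OtherGenus")
        # chain covering the homolog locus, mapping 1:1 to the other
        # species assembly where the ortholog ORF sits
        span <- nchar(cds)
        chains[[length(chains) + 1]] <- validate_chain(new_chain(
          score = 1000, t_name = "chrF", t_size = p$n_genes * 5000,
          t_strand = "+", t_start = start, t_end = start + span,
          q_name = "chrO", q_size = p$n_genes * 5000,
          q_strand = "+", q_start = start, q_end = start + span,
          id = as.character(length(chains) + 1),
          blocks = data.frame(size = span, dt = NA, dq = NA)))
        ofeats <- data.frame(gene = paste0(g, "_rat"),
                             transcript = paste0(g, "_rat.t1"),
                             chrom = "chrO", start = start,
                             end = start + span, strand = "+",
                             feature = c("exon", "CDS"))
        other_models[[paste0(g, "_rat")]] <-
          gene_model(paste0(g, "_rat"), ofeats,
                     protein = close[[paste0(g, "_rat")]])
      }
    }
    list(models = models, proteins = prots,
         close_proteome = unlist(close),
         far_proteome = unlist(far), far_taxa = far_taxa,
         exclude_taxa = p$focal_taxon,
         chains = chains, other_models = other_models,
         truth = data.frame(gene = genes, orphan = orphan))
  })
}

#' Simulate an ORF's history on a species tree with planted events
#'
#' Evolves a root sequence (flank + ORF + flank) along the configured
#' tree by Jukes-Cantor substitution and applies the planted events on
#' their branches: `stop_loss` (an ancestral TGA becoming TGC below the
#' branch — an enabler), `stop_gain` (TGC becoming TGA — a disabler) and
#' `deletion` (a gap run of the given length, a frameshift when its
#' length is not a multiple of 3). Columns carrying planted events are
#' excluded from background substitution and deletions, so the truth
#' ledger is exactly recoverable; conflicting planted events on one
#' column raise a configuration error.
#'
#' @param cfg A [sim_config()].
#' @return List: `aln` (an [ortho_alignment()]), `tree` (`ape::phylo`),
#'   `outgroups`, `truth` (data.frame type/branch/column/length).
#' @export
simulate_orf_history <- function(cfg = sim_config()) {
  oc <- cfg$orf
  tree <- label_tree(ape::read.tree(text = oc$tree))
  labels <- node_labels(tree)
  ntip <- length(tree$tip.label)
  orf_start <- oc$flank + 1
  orf_len <- 3 * oc$n_codons
  total <- orf_len + 2 * oc$flank
  codon_col <- function(codon) orf_start + 3 * (codon - 1)

  # planted columns (protected from background mutation)
  protected <- integer(0)
  for (ev in oc$events) {
    cols <- if (ev$type == "deletion") {
      codon_col(ev$codon) + 0:(ev$length - 1)
    } else codon_col(ev$codon) + 0:2
    if (any(cols %in% protected)) {
      stop("conflicting planted events at one column")
    }
    if (max(cols) > oc$flank + orf_len) stop("planted event outside ORF")
    protected <- c(protected, cols)
  }

  with_seed(cfg$seed + 202L, {
    # root: flank + (ATG + non-stop codons + TAA) + flank
    bases <- c("A", "C", "G", "T")
    non_stop <- setdiff(unlist(CODON_TABLE), STOP_CODONS)
    body <- sample(non_stop, oc$n_codons - 2, replace = TRUE)
    root_seq <- c(sample(bases, oc$flank, TRUE),
                  chars(paste0("ATG", paste(body, collapse = ""), "TAA")),
                  sample(bases, oc$flank, TRUE))
    set_codon <- function(seq, codon, value) {
      seq[codon_col(codon) + 0:2] <- chars(value)
      seq
    }
    for (ev in oc$events) {
      if (ev$type == "stop_loss") root_seq <- set_codon(root_seq, ev$codon,
                                                        "TGA")
      if (ev$type == "stop_gain") root_seq <- set_codon(root_seq, ev$codon,
                                                        "TGC")
    }

    # evolve along the tree, applying planted events on their branches
    pre <- ape::reorder.phylo(tree, "postorder")$edge
    pre <- pre[nrow(pre):1, , drop = FALSE]
    lens <- ape::reorder.phylo(tree, "postorder")$edge.length
    lens <- lens[length(lens):1]
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[ntip + 1]] <- root_seq
    for (e in seq_len(nrow(pre))) {
      u <- pre[e, 1]; v <- pre[e, 2]
      s <- seqs[[u]]
      bl <- lens[e]
      p_sub <- 0.75 * (1 - exp(-4 / 3 * bl))
      mut <- which(stats::runif(total) < p_sub & s != "-")
      mut <- setdiff(mut, protected)
      for (i in mut) s[i] <- sample(setdiff(bases, s[i]), 1)
      for (ev in oc$events) {
        if (ev$branch != labels[v]) next
        if (ev$type == "stop_loss") s <- set_codon(s, ev$codon, "TGC")
        if (ev$type == "stop_gain") s <- set_codon(s, ev$codon, "TGA")
        if (ev$type == "deletion") {
          s[codon_col(ev$codon) + 0:(ev$length - 1)] <- "-"
        }
      }
      seqs[[v]] <- s
    }
    tipseqs <- stats::setNames(vapply(seq_len(ntip), function(i)
      paste(seqs[[i]], collapse = ""), character(1)), tree$tip.label)
    aln <- ortho_alignment(tipseqs, orf = c(orf_start, oc$flank + orf_len),
                           reference = oc$outgroups[1])
    truth <- do.call(rbind, lapply(oc$events, function(ev) {
      data.frame(type = ev$type, branch = ev$branch,
                 column = codon_col(ev$codon),
                 length = if (ev$type == "deletion") ev$length else NA_real_)
    }))
    list(aln = aln, tree = tree, outgroups = oc$outgroups, truth = truth)
  })
}

#' Simulate a genotype-by-cluster count matrix
#'
#' Negative-binomial counts for `n_genes` genes in 24 samples (12 KO, 12
#' WT split evenly over three estrous-phase clusters). Gene-wise baseline
#' means come from a log-normal grid; a subset of genes gets
#' cluster-specific shifts (giving the clusters their transcriptome
#' identity); the three marker genes follow the proestrus pattern (Pgr
#' and Esr1 up, Gper1 down in cluster 1); and the planted knockout fold
#' change is applied to `n_de` genes in the KO samples of cluster
#' `de_cluster` only.
#'
#' @param cfg A [sim_config()].
#' @return List: `counts` (matrix), `meta` (sample/genotype/cluster),
#'   `truth` (list with `de_genes`, `cluster_genes`, `fold_change`,
#'   `cluster`, `genotype`).
#' @export
simulate_counts <- function(cfg = sim_config()) {
  cc <- cfg$counts
  n_samples <- sum(cc$cluster_sizes)
  with_seed(cfg$seed + 303L, {
    genes <- sprintf("g%04d", seq_len(cc$n_genes))
    genes[seq_along(cc$markers)] <- cc$markers
    samples <- sprintf("S%02d", seq_len(n_samples))
    cluster <- rep(seq_along(cc$cluster_sizes), cc$cluster_sizes)
    genotype <- unlist(lapply(cc$cluster_sizes, function(m)
      rep(c("KO", "WT"), length.out = m)))
    base_mu <- stats::rlnorm(cc$n_genes, cc$meanlog, cc$sdlog)
    names(base_mu) <- genes
    base_mu[cc$markers] <- pmax(base_mu[cc$markers], 100)
    pool <- setdiff(genes, cc$markers)
    cluster_genes <- split(sample(pool, cc$n_cluster_genes),
                           rep(seq_along(cc$cluster_sizes),
                               length.out = cc$n_cluster_genes))
    # knockout effects are planted in the detectable expression range,
    # as occupied by the observed differentially expressed genes
    de_pool <- setdiff(pool[base_mu[pool] >= cc$de_min_mean],
                       unlist(cluster_genes))
    de_genes <- sample(de_pool, cc$n_de)
    mu <- matrix(base_mu, nrow = cc$n_genes, ncol = n_samples,
                 dimnames = list(genes, samples))
    for (k in seq_along(cluster_genes)) {
      mu[cluster_genes[[k]], cluster == k] <-
        mu[cluster_genes[[k]], cluster == k] * 2^cc$cluster_lfc
    }
    mu[cc$markers[1], cluster == 1] <- mu[cc$markers[1], cluster == 1] *
      cc$marker_fold
    mu[cc$markers[2], cluster == 1] <- mu[cc$markers[2], cluster == 1] *
      cc$marker_fold
    mu[cc$markers[3], cluster == 1] <- mu[cc$markers[3], cluster == 1] /
      cc$marker_fold
    ko_in_de_cluster <- genotype == "KO" & cluster == cc$de_cluster
    mu[de_genes, ko_in_de_cluster] <- mu[de_genes, ko_in_de_cluster] *
      cc$fold_change
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cc$dispersion),
                     nrow = cc$n_genes, dimnames = dimnames(mu))
    list(counts = counts,
         meta = data.frame(sample = samples, genotype = genotype,
                           cluster = cluster),
         truth = list(de_genes = de_genes, cluster_genes = cluster_genes,
                      fold_change = cc$fold_change, cluster = cluster,
                      genotype = genotype))
  })
}

#' Simulate translation evidence (peptides and ribosome footprints)
#'
#' Generates random candidate proteins of which a configured fraction is
#' truly translated. Each translated gene receives, by coin flip, a
#' unique peptide (an exact substring of its protein, re-drawn until it
#' differs by at least two residues from every background window), a set
#' of in-frame ribosome footprints (length 29, offset 12), or both;
#' untranslated genes receive neither, so the planted translated set is
#' exactly recoverable.
#'
#' @param cfg A [sim_config()].
#' @return List: `proteins` (named vector), `orf_table` (gene,
#'   orf_start, orf_end in toy genome coordinates), `peptides`
#'   (data.frame gene/peptide), `reads` (data.frame
#'   gene/pos/length/strand), `psite_cfg`, `truth` (data.frame
#'   gene/translated/has_peptide/has_ribo).
#' @export
simulate_translation <- function(cfg = sim_config()) {
  tc <- cfg$translation
  with_seed(cfg$seed + 404L, {
    genes <- sprintf("tg%03d", seq_len(tc$n_genes))
    lens <- sample(tc$protein_len[1]:tc$protein_len[2], tc$n_genes, TRUE)
    prots <- stats::setNames(vapply(lens, random_protein, character(1)),
                             genes)
    translated <- stats::setNames(
      seq_len(tc$n_genes) <= round(tc$translated_fraction * tc$n_genes),
      genes)
    orf_start <- stats::setNames(1000 * seq_len(tc$n_genes), genes)
    orf_end <- orf_start + 3 * (lens + 1)
    peptides <- list(); reads <- list()
    has_pep <- stats::setNames(rep(FALSE, tc$n_genes), genes)
    has_ribo <- has_pep
    for (g in genes[translated]) {
      kind <- sample(c("peptide", "ribo", "both"), 1)
      if (kind %in% c("peptide", "both")) {
        bg <- prots[setdiff(genes, g)]
        for (try in 1:50) {
          s <- sample.int(nchar(prots[[g]]) - tc$peptide_len + 1, 1)
          pep <- substr(prots[[g]], s, s + tc$peptide_len - 1)
          if (peptide_unique(pep, prots[[g]], bg)$unique) break
        }
        peptides[[length(peptides) + 1]] <- data.frame(gene = g,
                                                       peptide = pep)
        has_pep[g] <- TRUE
      }
      if (kind %in% c("ribo", "both")) {
        k <- sample(0:(nchar(prots[[g]]) - 1), tc$reads_per_gene,
                    replace = TRUE)
        reads[[length(reads) + 1]] <- data.frame(
          gene = g, pos = orf_start[[g]] + 3 * k - 12,
          length = 29, strand = "+")
        has_ribo[g] <- TRUE
      }
    }
    list(proteins = prots,
         orf_table = data.frame(gene = genes, orf_start = orf_start,
                                orf_end = orf_end),
         peptides = if (length(peptides)) do.call(rbind, peptides)
                    else data.frame(gene = character(0),
                                    peptide = character(0)),
         reads = if (length(reads)) do.call(rbind, reads)
                 else data.frame(gene = character(0), pos = numeric(0),
                                 length = numeric(0), strand = character(0)),
         psite_cfg = psite_config(list(sim = c(`29` = 12, `30` = 12))),
         truth = data.frame(gene = genes, translated = unname(translated),
                            has_peptide = unname(has_pep),
                            has_ribo = unname(has_ribo)))
  })
}

#' Simulate litter records with a bimodal second-litter interval
#'
#' Days from the first to the second litter are drawn from a two-
#' component mixture: an early component (postpartum-estrus conception;
#' rounded Gaussian clamped to 20-25 days) and a late component
#' (post-lactational; clamped to 35-46 days), with genotype-specific
#' early weights. Infanticide is Bernoulli per litter with
#' genotype-specific probability. Days to the first litter and pup
#' counts are genotype-independent.
#'
#' @param cfg A [sim_config()].
#' @return List: `records` (litter-record data.frame) and `truth`
#'   (per-pair mixture component and infanticide draw).
#' @export
simulate_litters <- function(cfg = sim_config()) {
  lc <- cfg$litters
  with_seed(cfg$seed + 505L, {
    gen <- c(rep("KO", lc$n_ko), rep("WT", lc$n_wt))
    n <- length(gen)
    early <- stats::rbinom(n, 1, lc$early_weight[gen]) == 1
    d2 <- ifelse(early,
                 pmin(pmax(round(stats::rnorm(n, lc$early_mean,
                                              lc$early_sd)),
                           lc$early_range[1]), lc$early_range[2]),
                 pmin(pmax(round(stats::rnorm(n, lc$late_mean,
                                              lc$late_sd)),
                           lc$late_range[1]), lc$late_range[2]))
    d1 <- pmax(round(stats::rnorm(n, lc$days1_mean, lc$days1_sd)), 18)
    p1 <- pmin(pmax(round(stats::rnorm(n, lc$pups_mean, lc$pups_sd)), 1), 12)
    p2 <- pmin(pmax(round(stats::rnorm(n, lc$pups_mean, lc$pups_sd)), 1), 12)
    inf <- stats::rbinom(n, 1, lc$infanticide_prob[gen]) == 1
    records <- data.frame(
      pair_id = sprintf("%s%02d", gen, stats::ave(seq_len(n), gen,
                                                  FUN = seq_along)),
      genotype = gen, cohort = "dedicated",
      days_litter1 = d1, days_litter1_to_2 = d2,
      pups_litter1 = p1, pups_litter2 = p2,
      infanticide = inf)
    list(records = records,
         truth = data.frame(pair_id = records$pair_id,
                            component = ifelse(early, "early", "late"),
                            infanticide = inf))
  })
}

#' Generate a complete synthetic study bundle on disk
#'
#' Runs every simulator and writes all the input files the pipeline
#' consumes (FASTA proteomes, gene-model TSVs, a chain file, the ORF
#' alignment FASTA and newick tree, the count matrix and sample metadata,
#' peptide/read tables with the P-site offset YAML, litter records) plus
#' `truth/*.tsv` ground-truth ledgers. A partial write is cleaned up
#' before the error propagates.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created; must not exist).
#' @return Invisibly, a list with all simulator outputs and `dir`.
#' @export
simulate_study <- function(cfg = sim_config(), out_dir) {
  if (dir.exists(out_dir)) stop("out_dir already exists: ", out_dir)
  dir.create(out_dir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE), add = TRUE)

  pr <- simulate_proteomes(cfg)
  oh <- simulate_orf_history(cfg)
  cm <- simulate_counts(cfg)
  tr <- simulate_translation(cfg)
  lt <- simulate_litters(cfg)

  w <- function(...) file.path(out_dir, ...)
  write_fasta(pr$proteins, w("focal_proteome.fasta"))
  write_fasta(pr$close_proteome, w("close_proteome.fasta"))
  write_fasta(pr$far_proteome, w("far_proteome.fasta"))
  utils::write.table(data.frame(id = names(pr$far_proteome),
                                taxon = pr$far_taxa),
                     w("far_taxa.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gene_models(do.call(rbind, lapply(pr$models, `[[`, "features")),
                    w("focal_models.tsv"))
  write_fasta(vapply(pr$models, `[[`, character(1), "cds_seq"),
              w("focal_cds.fasta"))
  write_gene_models(do.call(rbind, lapply(pr$other_models, `[[`,
                                          "features")),
                    w("other_models.tsv"))
  write_fasta(vapply(pr$other_models, `[[`, character(1), "protein"),
              w("other_proteins.fasta"))
  write_chain_file(pr$chains, w("chains.chain"))

  write_fasta(stats::setNames(
    apply(oh$aln$mat, 1, paste, collapse = ""), oh$aln$taxa),
    w("orf_alignment.fasta"))
  ape::write.tree(oh$tree, w("tree.nwk"))

  write_count_matrix(cm$counts, w("counts.tsv"))
  utils::write.csv(cm$meta, w("sample_meta.csv"), row.names = FALSE,
                   quote = FALSE)

  write_fasta(tr$proteins, w("candidate_proteins.fasta"))
  utils::write.table(tr$peptides, w("peptides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tr$reads, w("ribo_reads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tr$orf_table, w("orf_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(sim = as.list(tr$psite_cfg$offsets$sim)),
                   w("psite_offsets.yaml"))

  write_litter_records(lt$records, w("litters.csv"))

  dir.create(w("truth"))
  utils::write.table(pr$truth, w("truth", "orphans.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(oh$truth, w("truth", "orf_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = cm$truth$de_genes,
                                fold_change = cm$truth$fold_change),
                     w("truth", "de_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cm$meta, w("truth", "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tr$truth, w("truth", "translation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(lt$truth, w("truth", "litters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ok <- TRUE
  invisible(list(dir = out_dir, proteomes = pr, orf_history = oh,
                 counts = cm, translation = tr, litters = lt))
}
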