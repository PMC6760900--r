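cds_for <- function(protein) {
  # one fixed codon per amino acid keeps these fixtures deterministic
  tab <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
           G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
           M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
           S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  paste0(paste(tab[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

test_that("ORF integrity applies the four conditions in order", {
  p29 <- paste0("M", strrep("A", 28))
  expect_equal(filter_orf_integrity(cds_for(p29))$reason, "length")
  # 30 aa with an internal stop
  p30 <- paste0("M", strrep("A", 29))
  cds <- cds_for(p30)
  substr(cds, 46, 48) <- "TAA"
  expect_equal(filter_orf_integrity(cds)$reason, "internal stop")
  # valid 30-aa ORF passes
  expect_true(filter_orf_integrity(cds_for(p30))$ok)
  # missing start codon
  bad_start <- cds_for(p30)
  substr(bad_start, 1, 3) <- "GCT"
  expect_equal(filter_orf_integrity(bad_start)$reason, "start codon")
  # missing terminal stop
  no_stop <- substr(cds_for(p30), 1, 90)
  expect_equal(filter_orf_integrity(paste0(no_stop, "AAA"))$reason,
               "stop codon")
  expect_error(filter_orf_integrity("ATGAA"), "divisible")
})

test_that("local alignment reproduces known scores and the DP oracle", {
  cfg <- screen_config()
  expect_equal(local_align("ACDE", "ACDE", cfg)$score, 24)  # 4+9+6+5
  expect_equal(local_align("WWWW", "PPPP", cfg)$score, 0)
  expect_error(local_align("ACB", "ACD", cfg), "unknown residue")
  # masked residues never contribute positive score
  expect_equal(local_align("XXXX", "XXXX", cfg)$score, 0)
  # exhaustive short pairs over a reduced alphabet vs the DP oracle
  ab <- c("A", "C", "D", "W")
  short <- unlist(lapply(1:2, function(l) {
    apply(expand.grid(rep(list(ab), l)), 1, paste, collapse = "")
  }))
  for (x in short) for (y in short) {
    expect_equal(local_align(x, y, cfg)$score,
                 sw_oracle(x, y, blosum62), info = paste(x, y))
  }
  # random longer pairs, reduced and full alphabet
  set.seed(11)
  for (i in 1:60) {
    x <- rand_prot(sample(3:8, 1), ab)
    y <- rand_prot(sample(3:8, 1), ab)
    expect_equal(local_align(x, y, cfg)$score, sw_oracle(x, y, blosum62),
                 info = paste(x, y))
  }
  for (i in 1:60) {
    x <- rand_prot(sample(5:20, 1))
    y <- rand_prot(sample(5:20, 1))
    expect_equal(local_align(x, y, cfg)$score, sw_oracle(x, y, blosum62),
                 info = paste(x, y))
  }
})

test_that("E-value model is Karlin-Altschul with the documented constants", {
  # closed form at a fixed point, frozen from independent log-space
  # arithmetic: ln E = ln(0.041 * 100 * 1e6) - 0.267 * 57
  #                  = 15.226498 - 15.219 = 0.007498 -> E = 1.007526
  expect_equal(estimate_evalue(57, 100, 1e6), 1.007526, tolerance = 1e-5)
  # linear in n, decreasing in score, vanishing in the limit
  expect_equal(estimate_evalue(40, 100, 2e6),
               2 * estimate_evalue(40, 100, 1e6))
  expect_lt(estimate_evalue(41, 100, 1e6), estimate_evalue(40, 100, 1e6))
  expect_equal(estimate_evalue(1e5, 100, 1e6), 0)
  expect_error(estimate_evalue(40, 0, 1e6), "positive")
  expect_error(estimate_evalue(0, 100, 1e6), "positive")
})

test_that("phylostratigraphy thresholds and monotonicity behave as screened", {
  set.seed(21)
  target <- rand_prot(100)
  # a decoy database of unrelated proteins
  far <- setNames(vapply(rep(80, 10), rand_prot, character(1)),
                  paste0("f", 1:10))
  close <- setNames(vapply(rep(80, 10), rand_prot, character(1)),
                    paste0("c", 1:10))
  cand <- c(orph = target, homol = target)
  # planting an identical homolog in the close set removes that candidate
  close2 <- c(close, hom = cand[["homol"]])
  ps <- phylostrat_filter(cand["homol"], close2, far)
  expect_false(ps$phylostrat_pass)
  expect_lt(ps$best_e_close, 1e-7)
  # an unrelated candidate survives both sets
  ps2 <- phylostrat_filter(cand["orph"], close, far)
  expect_true(ps2$phylostrat_pass)
  # genus exclusion: a far-set self hit under the focal taxon is ignored
  far3 <- c(far, self = target)
  taxa <- c(rep("Other", length(far)), "Mus")
  ps3 <- phylostrat_filter(cand["orph"], close, far3,
                           far_taxa = taxa, exclude_taxa = "Mus")
  expect_true(ps3$phylostrat_pass)
  ps4 <- phylostrat_filter(cand["orph"], close, far3)
  expect_false(ps4$phylostrat_pass)
  # monotonicity: raising the close threshold never shrinks the survivors
  cfg_loose <- screen_config(e_thresh_close = 1e-4)
  ps5 <- phylostrat_filter(cand, close2, far, cfg = cfg_loose)
  ps6 <- phylostrat_filter(cand, close2, far, cfg = screen_config())
  expect_true(all(ps6$gene[ps6$phylostrat_pass] %in%
                  ps5$gene[ps5$phylostrat_pass]))
  # empty candidate list is an empty result, not an error
  expect_equal(nrow(phylostrat_filter(character(0), close, far)), 0)
})

test_that("synteny filter applies the score-40 rule through chains", {
  set.seed(31)
  protein <- rand_prot(60)
  orf_iv <- genomic_interval("chrF", 100, 280)
  ch <- read_chain_file({
    f <- tempfile()
    writeLines(c("chain 10 chrF 1000 + 100 280 chrO 1000 + 100 280 1",
                 "180", ""), f)
    f
  })
  other_hit <- list(gene_model("rat1", data.frame(
    gene = "rat1", transcript = "t", chrom = "chrO", start = 150,
    end = 260, strand = "+", feature = "CDS"), protein = protein))
  # identical protein scores far above 40: filtered out
  sf <- synteny_filter(protein, orf_iv, ch, other_hit)
  expect_false(sf$pass)
  expect_gte(sf$max_score, 40)
  # unrelated overlapping protein scoring < 40: retained
  other_weak <- other_hit
  other_weak[[1]]$protein <- rand_prot(60)
  sf2 <- synteny_filter(protein, orf_iv, ch, other_weak)
  s <- local_align(protein, other_weak[[1]]$protein)$score
  expect_equal(sf2$pass, s < 40)
  # a vacuous pass carries no alignment score
  expect_true(is.na(synteny_filter("A", genomic_interval("chrF", 100, 101),
                                   list(), list())$max_score))
  # no chain covering the locus: vacuous pass
  sf3 <- synteny_filter(protein, orf_iv, list(), other_hit)
  expect_true(sf3$pass)
  # overlapping ORF on another chromosome does not count
  other_far <- other_hit
  other_far[[1]]$features$chrom <- "chrZ"
  expect_true(synteny_filter(protein, orf_iv, ch, other_far)$pass)
})

test_that("screen recovers the planted orphan ledger on a small simulation", {
  cfg <- sim_config(5, proteome = list(n_genes = 12, n_orphans = 6))
  pr <- simulate_proteomes(cfg)
  res <- screen_candidates(pr$models, pr$close_proteome, pr$far_proteome,
                           pr$chains, pr$other_models,
                           far_taxa = pr$far_taxa,
                           exclude_taxa = pr$exclude_taxa)
  expect_equal(res$candidate, pr$truth$orphan)
})

test_that("expression summarization averages replicates then sums transcripts", {
  tab <- data.frame(gene = c("g1", "g2"), transcript = c("t1", "t2"),
                    tissue = "ovary", replicate = 1, fpkm = c(1, 3))
  s <- expression_summarize(tab)
  expect_equal(s$aggregate$aggregate, log2(2) + log2(4))  # 3.0
  # all-zero table aggregates to 0
  tab0 <- transform(tab, fpkm = 0)
  expect_equal(expression_summarize(tab0)$aggregate$aggregate, 0)
  # replicate permutation invariance and additivity over transcripts
  tab2 <- data.frame(gene = "g", transcript = rep(c("t1", "t2"), each = 3),
                     tissue = "brain", replicate = rep(1:3, 2),
                     fpkm = c(2, 4, 6, 1, 1, 1))
  s2 <- expression_summarize(tab2)
  set.seed(1)
  s3 <- expression_summarize(tab2[sample(nrow(tab2)), ])
  expect_equal(s2$gene$fpkm, s3$gene$fpkm)
  expect_equal(s2$gene$fpkm, mean(c(2, 4, 6)) + 1)
  # overall level is the max across tissues; a parsed record carries the
  # measured ovary abundance through unchanged
  tab3 <- data.frame(gene = "Gm13030", transcript = "Gm13030.t1",
                     tissue = c("ovary", "adipose"), replicate = 1,
                     fpkm = c(0.135, 0.115))
  s4 <- expression_summarize(tab3)
  expect_equal(s4$gene$fpkm[s4$gene$tissue == "ovary"], 0.135)
  expect_equal(s4$gene_overall$overall, 0.135)
  expect_error(expression_summarize(transform(tab, fpkm = -1)), "negative")
})
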