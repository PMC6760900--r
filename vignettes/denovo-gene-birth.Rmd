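---
title: "Tracing de novo gene birth: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing de novo gene birth: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovobirth)
```

This vignette documents the models behind each pipeline stage, the
parameters that matter, what the synthetic-data generators do and do
not emulate, and the design choices made where the design was
genuinely open.

## The screening model

A de novo gene is a protein-coding gene born from previously
non-coding, intergenic sequence — as opposed to a duplicate of an
existing gene. Because such genes by definition lack detectable
homologs outside their lineage of origin, the screen combines three
orthogonal filters.

**ORF integrity.** `filter_orf_integrity()` demands a protein of at
least 30 amino acids (`min_protein_len`, aa; genes shorter than this
are indistinguishable from spurious ORFs), a leading ATG, a terminal
stop and no internal stop. The conditions are evaluated in that order
and the verdict names the first failure, which makes filter reasons
stable and testable.

**Phylostratigraphy.** `phylostrat_filter()` removes candidates with a
close-relative hit at E < 10⁻⁷ or a non-focal-genus database hit at
E < 10⁻³ (`e_thresh_close`, `e_thresh_far`; both dimensionless
expected hit counts). Alignments are Smith–Waterman local alignments
under BLOSUM62; significance uses the Karlin–Altschul form
E = *K·m·n·*exp(−λS). Two parameter sets coexist deliberately:

* the *synteny* alignment uses the water defaults (gap open 10,
  extend 0.5) because the score-40 rule was defined with that tool;
* the *database-search* path uses gap open 11, extend 1, because the
  constants λ = 0.267, K = 0.041 are the published gapped-BLOSUM62
  values **for those penalties**. Using them with the more permissive
  water gaps systematically understates the E-values of gappy chance
  alignments and removes genuine orphans; penalties and statistics must
  match, so the E-value path mirrors the protein-database search tool
  the thresholds come from.

One convention to note: a gap of length L costs `open + L·extend`
(the alignment backend's convention), whereas water itself charges
`open + (L−1)·extend`; the half-point difference is irrelevant at the
score-40 threshold but is stated here for reproducibility.
Low-complexity masking is consumed, not computed — masked residues
arrive as `X`, which never scores positively under BLOSUM62, so masked
regions cannot seed hits. The non-genus exclusion of the far set is a
label filter on the record taxa, since a comprehensive database
contains the focal species' own proteins.

**Synteny.** `synteny_filter()` projects the candidate ORF through
UCSC chain alignments (0-based half-open internally; 1-based inclusive
only in rendered reports) and aligns the candidate protein to the
proteins of overlapping ORFs in the other species. A score of at least
40 (`synteny_score_thresh`, raw score units) removes the candidate.
Genes whose locus no chain covers pass vacuously — absence of
alignable synteny is evidence of lineage specificity, not missing
data, for well-assembled genomes.

## Translation evidence

`peptide_unique()` implements the proteogenomic uniqueness rule: exact
substring of the candidate and Hamming distance ≥ 2 to every
equal-length window of every background protein. Isoleucine and
leucine are treated as distinct residues by default; because mass
spectrometry cannot distinguish them, an `il_equivalent` switch
collapses the two (off by default, matching the stricter reading).
`assign_p_sites()` maps each retained read to its ribosomal P-site as
5′ end + offset, with the usable read lengths and offsets supplied per
sample (e.g. lengths 29–30 with offset 12 nt, as calibrated from
start/stop-codon metaplots). Gene-level ribosome support is defined
here as ≥ 1 in-frame P-site inside the ORF — a deliberate
simplification of spectral triplet-periodicity testing, which is out
of scope; consumers needing the stronger criterion can filter on the
reported frame fractions.

## ORF history on the species tree

The tree topology is an input, never estimated: the species phylogeny
is known and fixed. `map_substitutions()` uses unweighted Fitch
parsimony. The down-pass computes ancestral state sets; a standard
backtrack then resolves one most-parsimonious labelling — the parent
state is kept whenever it belongs to the child's set, otherwise the
first state in A<C<G<T order — so the number of emitted branch events
equals the parsimony score exactly. Ambiguity is not hidden: a change
whose endpoints' final (up-pass) sets overlap is possible on more than
one branch in some reconstruction and is flagged `ambiguous` rather
than silently resolved, because manual placement of such changes
cannot be automated faithfully. Gaps and N are missing data (full
state set), and all-gap columns are skipped with a log entry.

"Coding" vs "non-coding" substitution classes are positional — inside
or outside the annotated ORF interval — matching how per-branch
coding:non-coding tallies are reported in this kind of analysis;
synonymous/nonsynonymous annotation would be a separate column, not
the primary statistic. How much flanking sequence counts as
"non-coding" is set by the alignment the user supplies, since no fixed
flank width is canonical.

Enabler detection (`detect_enablers()`) asks, per in-frame codon,
whether every outgroup taxon carrying sequence has a stop (TAA, TAG or
TGA) while the ingroup consensus does not. Sites where some ingroup
taxa retain the stop are reported as `partial` rather than discarded —
lineages that kept the ancestral stop are exactly the interesting
secondary-loss cases. Disablers are stop gains (from Fitch-resolved
ancestral codons at the two ends of every branch) and maximal
clade-unique gap runs inside the ORF, frameshifting when length mod
3 ≠ 0. Gap runs not attributable to a clade are left unplaced rather
than guessed.

The neutral expectation multiplies the gap-free alignment length by
the genome-wide mean Jukes–Cantor distance,
d = −(3/4)·ln(1 − 4p/3), taken over random non-overlapping windows
(`window_distances()`; seeded sampling over the non-overlapping tiling
so the "random non-overlapping windows" scheme is exactly
reproducible). The full-scale analysis uses 10,000 windows of 25 kbp;
the test suite uses 100 windows of 1 kbp — the estimator is identical
and the Monte-Carlo error scales as expected. `neutrality_test()` is
an exact two-sided binomial test ("minlike" rule) of the coding
fraction among substitutions against the length share of the ORF; the
choice of an exact binomial is this package's, as the significance
procedure behind such ratios is conventionally unnamed.

## Cluster-stratified differential expression

Size factors are median-of-ratios over genes with all-positive counts;
the variance-stabilising transform is log2(count/factor + 1). The
exact transform used by the reference DE tool is internal to it, and
clustering acceptance here rests on recovery of synthetic ground
truth, not on reproducing particular coordinates, so the simple
monotone transform suffices. Clustering uses the 500 most variable
genes (`n_top`, configurable; a variable-subset convention of the
standard plotting routines — whether the original analysis used all
genes is unknowable and immaterial for marker-anchored labels),
Euclidean distance and complete linkage, cut at k = 3, with PCA
computed alongside since both views inform the cut. Cluster labels are
then anchored by markers: cluster 1 is the cluster maximising
median(Pgr) + median(Esr1) − median(Gper1) — the proestrus/early-
estrus pattern of high progesterone- and estrogen-receptor-1 and low
G-protein-coupled estrogen receptor 1 expression — so "cluster 1" is
reproducible across runs.

The per-cluster test is a simplified NB Wald test. Dispersion is
method-of-moments, but the per-gene estimator
α̂ = (s² − μ)/μ² has enormous sampling noise at n ≤ 12 — using it
per gene both loses power (inflated α̂) and breaks FDR control
(α̂ near zero turns moderate noise into extreme z-scores). The test
therefore fits a binned running-median trend of the per-gene estimates
over base mean and uses the trend (floor 10⁻⁸), the moments-based
analogue of the shrinkage estimators in the standard tools; raw
per-gene values are still reported. Genes with base mean below 1
normalised count are excluded from testing (independent-filtering
stand-in; configurable), and genes with an all-zero group are flagged
with infinite |log2FC| and not tested. BH adjustment is applied across
tested genes; the default significance threshold is adjusted p ≤ 0.01.

## Fertility statistics

The interval to the second litter is bimodal: conception at the
postpartum estrus gives a second litter within ~25 days, while
lactational suppression of ovulation delays it to ≥ 35 days. Both
grouping boundaries are inclusive, and the 26–34 day gap is labelled
`intermediate` with a warning since real cohorts show none. The
Wilcoxon rank-sum test is exact (full enumeration of rank assignments)
up to combined n = 20 without ties — enumeration stays well under a
second there — and otherwise uses the tie-corrected,
continuity-corrected normal approximation with midranks. The
two-sided Fisher exact test sums hypergeometric probabilities ≤ that
of the observed table (relative tolerance 10⁻⁷ for ties) — the
convention of the common statistical environment, stated explicitly
because two-sided Fisher definitions vary. The infanticide denominator
is litters observed, not breeding pairs.

## What the simulators emulate — and what they do not

Every generator is a pure function of `sim_config(seed)`; identical
configurations give byte-identical outputs, and each simulator writes
a ground-truth ledger covering every planted signal.

* `simulate_proteomes()` (40 genes, 20 planted orphans, lengths
  80–150 aa): non-orphans get close homologs at 0.10 amino-acid
  replacement rate and far homologs at 0.25 — divergences typical of
  the rat/broad-database comparison points — while orphans are random
  sequences of matched length and composition. The far set includes
  the focal proteins themselves under the focal-genus label, so genus
  exclusion is exercised. Protein mutation is i.i.d. uniform
  replacement; indel evolution and domain structure are not modelled,
  so the screen's recovery says nothing about paralog confusion or
  low-complexity pathologies in real proteomes.
* `simulate_orf_history()` evolves flank + ORF + flank by Jukes–Cantor
  substitution along a 6-taxon tree (2 outgroups; branch lengths
  ≤ 0.02 subs/site, the mutation-sparse regime of recent radiations)
  and applies planted events on their branches: a TGA→TGC stop loss on
  the ingroup stem, a TGC→TGA stop gain on one tip, a 17 nt deletion
  in one two-taxon clade. Planted columns are excluded from background
  substitution so the truth ledger is exactly recoverable — recovery
  rates therefore measure detector correctness, not robustness to
  mutational interference at the planted sites.
* `simulate_counts()` draws NB counts for 2,000 genes × 24 samples
  (12 KO / 12 WT) with a log-normal mean grid (meanlog 5.5,
  sdlog 1.2 — the count scale on which the observed DE table sits) and
  NB dispersion 0.01, typical for high-count bulk RNA-seq in inbred
  laboratory mice. An earlier working value of 0.05 with 6 vs 6
  samples was checked by a power calculation and found to cap
  recall at ~19% even with oracle dispersion — below any useful
  acceptance bar — whereas the published detections (fold changes
  0.75–1.59 at adjusted p ≤ 0.01, base means 176–23,879) imply the
  lower-dispersion, higher-count regime used here. Cluster sizes are
  (12, 6, 6), so the stratified cluster-1 contrast is 6 KO vs 6 WT.
  Three hundred genes carry cluster-specific shifts (the transcriptome
  identity of the phases), the three markers follow the proestrus
  pattern in cluster 1, and sixty genes with baseline mean ≥ 100 carry
  a 1.5-fold knockout effect **in cluster-1 samples only** — the
  synthetic analogue of a phase-restricted knockout effect.
  Library-size variation, batch effects and outlier samples are not
  simulated, so passing tests do not demonstrate robustness to those.
* `simulate_litters()` draws the interval to the second litter from a
  two-component mixture: rounded Gaussians clamped to 20–25 d (early,
  mean 23, sd 1.5) and 35–46 d (late, mean 37, sd 2). The clamps
  guarantee the empirical bimodal gap; a late clamp at ≥ 30 d would
  generate 30–34 d intermediates that real cohorts lack, so the
  stricter bound was chosen. Early weights are 0.75 (KO) vs 0.10
  (WT/het) over 16 vs 20 litters, with infanticide probabilities 0.25
  vs 0 — matching the observed contrast's shape. First-litter timing
  and pup counts are genotype-independent.
* `simulate_translation()` plants a 0.9 translated fraction over 100
  genes, giving each translated gene a unique peptide, in-frame
  footprints, or both, and untranslated genes neither — so the
  supported count equals the planted count exactly. Spectral
  periodicity, rRNA contamination and spectrum-level identification
  noise are not modelled.

## Numerical choices and degenerate inputs

* Local alignment scores are clamped at 0 (the empty local alignment);
  unknown residue letters are validation errors, not silent drops.
* `jc_distance()` errors at p ≥ 0.75 (saturation) rather than
  returning Inf/NaN.
* Fitch tie-breaks are first-by-A<C<G<T; with outgroup-stop enabler
  configurations this resolves the root to the outgroup state, and all
  genuinely ambiguous placements remain flagged.
* Flat marker medians make cluster relabelling unstable; the input
  labels are kept and a warning raised instead of an arbitrary
  permutation.
* Zero observed substitutions give a neutrality p of 1 with a warning;
  a zero margin gives a Fisher p of 1.
* Even-sized medians are midpoints of the central order statistics;
  missing litter fields are excluded with the retained n reported.
* Window sampling errors out with the maximum feasible window count
  when the sequences are too short.

## Problem sizes used by the tests

The acceptance checks run the aligner oracle on ~1,100 pairs (all
short reduced-alphabet pairs plus 500 random full-alphabet pairs), the
parsimony oracle on all 16 single-column patterns (which, by
per-column additivity of both Fitch and the exhaustive search, covers
all alignments over that alphabet) plus every alignment of up to 3
columns and sampled length-6 alignments, 50 ORF-history replicates, 20
count-matrix replicates, and window sets of 100 × 1 kbp. These sizes
were chosen so the full suite completes in a few minutes on one core
while keeping every Monte-Carlo margin at 3 standard errors or better.

## Known limitations

* The E-value model is an analytic stand-in for a database search
  tool's calibrated statistics; absolute E-values on real databases
  will differ, and the screen's guarantees are threshold-level, not
  hit-list-level.
* Ribosome support (≥ 1 in-frame P-site) is weaker than spectral
  periodicity testing.
* The NB Wald test with trended moments dispersion approximates, but
  does not reproduce, shrinkage-based DE tools; expect small
  differences near the significance boundary.
* Fitch parsimony reports ambiguity but cannot place events that are
  genuinely unplaceable without external information (e.g.
  introgression), which remains a manual interpretation.
* The simulators are deliberately minimal statistical emulations;
  conclusions about real-data robustness require real data.
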