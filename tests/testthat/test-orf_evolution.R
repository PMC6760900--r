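aln4 <- function(a, b, c, d, orf = NULL) {
  n <- nchar(a)
  if (is.null(orf)) orf <- c(1, n - n %% 3)
  ortho_alignment(c(A = a, B = b, C = c, D = d), orf = orf)
}
tree4 <- ape::read.tree(text = "((A:1,B:1)nAB:1,(C:1,D:1)nCD:1)root;")

test_that("Fitch mapping matches parsimony on toys and exhaustive cases", {
  # identical sequences: no events
  expect_equal(nrow(map_substitutions(
    aln4("ACG", "ACG", "ACG", "ACG"), tree4)), 0)
  # 3-taxon toy ((A,B),C): A=T, B=C, C=C -> event on A's terminal branch
  t3 <- ape::read.tree(text = "((A:1,B:1)ab:1,C:1)r;")
  a3 <- ortho_alignment(c(A = "TTT", B = "CTT", C = "CTT"), orf = c(1, 3))
  ev <- map_substitutions(a3, t3)
  ev1 <- ev[ev$column == 1, ]
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$branch, "A")
  expect_equal(c(ev1$from, ev1$to), c("C", "T"))
  # all 16 single-column patterns over {A,C} on the 4-taxon tree: the
  # event count equals the exhaustive-labelling minimum (per-column
  # independence extends this to alignments of any length)
  pats <- expand.grid(rep(list(c("A", "C")), 4), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pats))) {
    s <- unname(unlist(pats[i, ]))
    al <- aln4(strrep(s[1], 3), strrep(s[2], 3), strrep(s[3], 3),
               strrep(s[4], 3))
    got <- nrow(map_substitutions(al, tree4)) / 3
    expect_equal(got, parsimony_oracle_4tax(s), info = paste(s, collapse = ""))
  }
  # exhaustive 2-column alignments and random length-6 alignments
  seqs2 <- apply(expand.grid(c("A", "C"), c("A", "C")), 1, paste,
                 collapse = "")
  for (i1 in seqs2) for (i2 in seqs2) for (i3 in seqs2) for (i4 in seqs2) {
    al <- ortho_alignment(c(A = paste0(i1, "A"), B = paste0(i2, "A"),
                            C = paste0(i3, "A"), D = paste0(i4, "A")),
                          orf = c(1, 3))
    want <- sum(vapply(1:2, function(cc)
      parsimony_oracle_4tax(substr(c(i1, i2, i3, i4), cc, cc)),
      numeric(1)))
    expect_equal(nrow(map_substitutions(al, tree4)), want)
  }
  set.seed(6)
  for (r in 1:40) {
    m <- matrix(sample(c("A", "C"), 24, TRUE), nrow = 4)
    al <- aln4(paste(m[1, ], collapse = ""), paste(m[2, ], collapse = ""),
               paste(m[3, ], collapse = ""), paste(m[4, ], collapse = ""))
    want <- sum(vapply(1:6, function(cc) parsimony_oracle_4tax(m[, cc]),
                       numeric(1)))
    expect_equal(nrow(map_substitutions(al, tree4)), want)
  }
  # events inside/outside the ORF are classed coding/non-coding
  al <- ortho_alignment(c(A = "TACGT", B = "CACGA", C = "CACGA",
                          D = "CACGA"), orf = c(2, 4))
  ev <- map_substitutions(al, tree4)
  expect_setequal(ev$klass[ev$column == 1], "non-coding")
  expect_setequal(ev$klass[ev$column == 5], "non-coding")
  tal <- branch_tallies(ev)
  expect_equal(sum(tal$coding) + sum(tal$non_coding), nrow(ev))
})

test_that("enabler sites require outgroup stops and an ingroup non-stop consensus", {
  # outgroups TGA, all ingroup TGC: a clear enabler
  al <- ortho_alignment(c(out1 = "TGAAAA", out2 = "TGAAAA",
                          in1 = "TGCAAA", in2 = "TGCAAA", in3 = "TGCAAA"),
                        orf = c(1, 6))
  en <- detect_enablers(al, c("out1", "out2"))
  expect_equal(nrow(en), 1)
  expect_equal(en$column, 1)
  expect_equal(en$status, "enabler")
  expect_equal(c(en$outgroup_codon, en$ingroup_codon), c("TGA", "TGC"))
  # some ingroup taxa retain the stop: partial
  al2 <- ortho_alignment(c(out1 = "TGAAAA", out2 = "TGAAAA",
                           in1 = "TGCAAA", in2 = "TGCAAA", in3 = "TGAAAA",
                           in4 = "TGCAAA", in5 = "TGAAAA"),
                         orf = c(1, 6))
  en2 <- detect_enablers(al2, c("out1", "out2"))
  expect_equal(en2$status, "partial")
  expect_equal(en2$n_ingroup_stop, 2)
  # no outgroup stop anywhere: empty result
  al3 <- ortho_alignment(c(out1 = "TGGAAA", in1 = "TGCAAA"), orf = c(1, 6))
  expect_equal(nrow(detect_enablers(al3, "out1")), 0)
  expect_error(detect_enablers(al, "absent"), "outgroups")
})

test_that("disabler scan reports stop gains and clade-unique frameshift indels", {
  tr <- ape::read.tree(
    text = "((out1:1,out2:1)og:1,((iA:1,iB:1)ab:1,(iC:1,iD:1)cd:1)ig:1)r;")
  base <- "ATGAAACCCGGGTTTACACAT"   # 7 codons, no stops
  gap17 <- paste0(substr(base, 1, 2), strrep("-", 17), substr(base, 20, 21))
  al <- ortho_alignment(c(out1 = base, out2 = base, iA = base, iB = base,
                          iC = gap17, iD = gap17),
                        orf = c(1, 21), reference = "out1")
  dis <- detect_disablers(al, tr)
  fs <- dis[dis$effect == "frameshift_indel", ]
  expect_equal(nrow(fs), 1)
  expect_equal(fs$branch, "cd")   # placed on the clade's stem
  expect_equal(fs$length, 17)     # 17 mod 3 = 2 disrupts the frame
  # a 3-column gap is an in-frame indel, not a frameshift
  gap3 <- paste0(substr(base, 1, 3), "---", substr(base, 7, 21))
  al3 <- ortho_alignment(c(out1 = base, out2 = base, iA = base, iB = base,
                           iC = gap3, iD = gap3),
                         orf = c(1, 21), reference = "out1")
  d3 <- detect_disablers(al3, tr)
  expect_equal(d3$effect[!is.na(d3$length)], "indel")
  # a substitution creating an in-frame stop is a stop gain on its branch
  stopg <- paste0(substr(base, 1, 12), "TAA", substr(base, 16, 21))
  al4 <- ortho_alignment(c(out1 = base, out2 = base, iA = stopg, iB = base,
                           iC = base, iD = base),
                         orf = c(1, 21), reference = "out1")
  d4 <- detect_disablers(al4, tr)
  sg <- d4[d4$effect == "stop_gain", ]
  expect_equal(sg$branch, "iA")
  expect_equal(sg$column, 13)
  expect_equal(c(sg$from, sg$to), c("TTT", "TAA"))
})

test_that("planted ORF events are recovered on their branches", {
  oh <- simulate_orf_history(sim_config(3))
  en <- detect_enablers(oh$aln, oh$outgroups)
  dis <- detect_disablers(oh$aln, oh$tree)
  truth <- oh$truth
  sl <- truth[truth$type == "stop_loss", ]
  expect_true(sl$column %in% en$column)
  expect_true(any(dis$effect == "stop_loss" & dis$branch == sl$branch &
                  dis$column == sl$column))
  sg <- truth[truth$type == "stop_gain", ]
  expect_true(any(dis$effect == "stop_gain" & dis$branch == sg$branch &
                  dis$column == sg$column))
  del <- truth[truth$type == "deletion", ]
  expect_true(any(dis$effect == "frameshift_indel" &
                  dis$branch == del$branch & dis$column == del$column &
                  dis$length == del$length))
})

test_that("Jukes-Cantor transform matches its closed form and domain", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.1), 0.1073256, tolerance = 1e-6)
  expect_true(is.finite(jc_distance(0.74)))
  expect_error(jc_distance(0.75), "saturation")
  expect_error(jc_distance(-0.01), ">= 0")
  # strictly increasing
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(jc_distance(p)) > 0))
  # agrees with the standard phylogenetics implementation on sequence pairs
  set.seed(9)
  s1 <- sample(c("a", "c", "g", "t"), 3000, TRUE)
  s2 <- ifelse(runif(3000) < 0.12, sample(c("a", "c", "g", "t"), 3000, TRUE),
               s1)
  d_ape <- ape::dist.dna(ape::as.DNAbin(rbind(x = s1, y = s2)),
                         model = "JC69")
  p_obs <- mean(s1 != s2)
  expect_equal(as.numeric(d_ape), jc_distance(p_obs), tolerance = 1e-10)
})

test_that("window distances are seeded, gap-aware and recover divergence", {
  s <- paste(rep("ACGT", 300), collapse = "")
  w0 <- window_distances(s, s, 5, 100, seed = 1)
  expect_equal(w0$distances, rep(0, 5))
  # determinism: same seed, same window set
  w1 <- window_distances(s, s, 5, 100, seed = 7)
  w2 <- window_distances(s, s, 5, 100, seed = 7)
  expect_identical(w1$starts, w2$starts)
  expect_false(identical(w1$starts,
                         window_distances(s, s, 5, 100, seed = 8)$starts))
  # windows are non-overlapping
  expect_true(all(diff(w1$starts) >= 100))
  # error states the maximum feasible number of windows
  expect_error(window_distances(s, s, 100, 100, 1), "at most 12")
  # sequences simulated at true distance 0.02 recover it within 3 MC SE
  set.seed(7)
  L <- 100 * 1000
  p_true <- 0.75 * (1 - exp(-4 / 3 * 0.02))
  a <- sample(c("A", "C", "G", "T"), L, TRUE)
  b <- ifelse(runif(L) < p_true,
              vapply(a, function(x) sample(setdiff(c("A", "C", "G", "T"), x),
                                           1), character(1)), a)
  wd <- window_distances(paste(a, collapse = ""), paste(b, collapse = ""),
                         100, 1000, seed = 7)
  se <- sd(wd$distances) / sqrt(100)
  expect_lt(abs(wd$mean - 0.02), 3 * se + 1e-4)
  # N and gap columns are excluded from the mismatch proportion
  x <- "AAAANAAAAA"; y <- "AAAACAAAAT"
  wn <- window_distances(x, y, 1, 10, seed = 1)
  expect_equal(wn$distances, jc_distance(1 / 9))
})

test_that("neutral expectation is the product of length and mean distance", {
  e <- expected_substitutions(500, 0.013)
  expect_equal(e$expected, 6.5)
  expect_equal(expected_substitutions(0, 0.1)$expected, 0)
  expect_equal(expected_substitutions(1000, 0.013)$expected,
               2 * e$expected)
})

test_that("pairwise counts exclude indel columns and split by ORF", {
  al <- ortho_alignment(c(X = "AACGTAAA", Y = "ATCGAAAT",
                          Z = "AACGTAAA"), orf = c(2, 7))
  pc <- pairwise_counts(al, "X", "Y")
  expect_equal(pc$coding, 2)      # columns 2 and 5
  expect_equal(pc$non_coding, 1)  # column 8
  expect_equal(pc$sites_compared, 8)
  # identical pair
  pc0 <- pairwise_counts(al, "X", "Z")
  expect_equal(c(pc0$coding, pc0$non_coding), c(0, 0))
  # gap columns are dropped from sites compared
  alg <- ortho_alignment(c(X = "AAC-TAAA", Y = "ATCGAAAT",
                           Z = "AACGTAAA"), orf = c(5, 7),
                         reference = "Y")
  pcg <- pairwise_counts(alg, "X", "Y")
  expect_equal(pcg$sites_compared, 7)
  expect_error(pairwise_counts(al, "X", "Q"), "alignment")
})

test_that("neutrality test matches exhaustive binomial enumeration", {
  # enumeration oracle: sum of outcome probabilities <= observed
  enum_p <- function(k, n, p0) {
    pr <- dbinom(0:n, n, p0)
    sum(pr[pr <= pr[k + 1] * (1 + 1e-7)])
  }
  for (n in c(1, 3, 7, 12)) {
    for (k in 0:n) {
      for (p0 in c(0.3, 0.5, 300 / 800)) {
        got <- neutrality_test(k, n - k, p0 * 1000, (1 - p0) * 1000)
        expect_equal(got$p_value, enum_p(k, n, p0), tolerance = 1e-9,
                     info = paste(k, n, p0))
      }
    }
  }
  # the focal-branch shape: 7 coding vs 6 non-coding is non-significant
  r <- neutrality_test(7, 6, 300, 300)
  expect_gt(r$p_value, 0.05)
  expect_warning(p0 <- neutrality_test(0, 0, 10, 10), "no substitutions")
  expect_equal(p0$p_value, 1)
})
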