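#' Detect enabler sites (ancestral stop codons lost in the ingroup)
#'
#' An enabler mutation removes a premature stop codon and thereby opens
#' the full reading frame in the descendant lineage (e.g. an ancestral
#' TGA changing to TGC in all ingroup species). A codon position is an
#' enabler site when the in-frame codon is a stop (TAA/TAG/TGA) in every
#' outgroup taxon carrying sequence there and the ingroup consensus codon
#' is not a stop. Sites where some ingroup taxa still retain the stop are
#' reported with status `"partial"` rather than discarded.
#'
#' @param aln An [ortho_alignment()] (the ORF columns anchor the frame).
#' @param outgroups Character vector of outgroup taxa; the remaining taxa
#'   form the ingroup.
#' @return Data.frame with one row per enabler site: `column` (alignment
#'   column of the codon's first base), `outgroup_codon`,
#'   `ingroup_codon` (consensus), `status` ("enabler"/"partial"),
#'   `n_ingroup_stop`.
#' @export
detect_enablers <- function(aln, outgroups) {
  stopifnot(inherits(aln, "ortho_alignment"))
  if (is.null(aln$frame_anchor)) stop("reading frame anchor missing")
  if (!length(outgroups) || !all(outgroups %in% aln$taxa)) {
    stop("outgroups must be a non-empty subset of the alignment taxa")
  }
  ingroup <- setdiff(aln$taxa, outgroups)
  out <- list()
  for (start in codon_starts(aln)) {
    oc <- stats::na.omit(vapply(outgroups, function(t)
      codon_at(aln$mat[t, ], start), character(1)))
    if (!length(oc) || !all(is_stop_codon(oc))) next
    ic <- stats::na.omit(vapply(ingroup, function(t)
      codon_at(aln$mat[t, ], start), character(1)))
    if (!length(ic)) next
    cons <- names(sort(table(ic), decreasing = TRUE))[1]
    if (is_stop_codon(cons)) next
    n_stop <- sum(is_stop_codon(ic))
    out[[length(out) + 1]] <- data.frame(
      column = start,
      outgroup_codon = names(sort(table(oc), decreasing = TRUE))[1],
      ingroup_codon = cons,
      status = if (n_stop > 0) "partial" else "enabler",
      n_ingroup_stop = n_stop)
  }
  if (!length(out)) {
    return(data.frame(column = integer(0), outgroup_codon = character(0),
                      ingroup_codon = character(0), status = character(0),
                      n_ingroup_stop = integer(0)))
  }
  do.call(rbind, out)
}

#' Detect disabler events (stop gains and frameshift indels)
#'
#' Disablers secondarily disrupt an established ORF. Two kinds are
#' scanned: (1) branch substitutions that create an in-frame stop codon
#' within the ORF (stop gains; the reverse change is reported as a stop
#' loss), located by comparing the Fitch-resolved ancestral codons at the
#' two ends of every branch; and (2) maximal gap runs inside the ORF that
#' are shared by exactly the tips of one clade, reported as
#' `frameshift_indel` when the run length is not a multiple of 3 (e.g. a
#' 17 nt deletion) and `indel` otherwise, placed on the clade's stem
#' branch.
#'
#' @param aln An [ortho_alignment()].
#' @param tree An `ape::phylo` over the alignment taxa.
#' @return Data.frame of events: `branch`, `column` (first alignment
#'   column of the codon or gap run), `length` (nt, NA for
#'   substitutions), `from`, `to`, `klass` ("coding"), `effect`
#'   ("stop_gain"/"stop_loss"/"indel"/"frameshift_indel"), `placement`.
#' @export
detect_disablers <- function(aln, tree) {
  fr <- fitch_resolve(aln, tree)
  tree <- fr$tree
  labels <- node_labels(tree)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  out <- list()
  # stop gains/losses from resolved ancestral codons
  for (start in codon_starts(aln)) {
    for (e in seq_len(nrow(post))) {
      u <- post[e, 1]; v <- post[e, 2]
      cu <- codon_at(fr$resolved[u, ], start)
      cv <- if (v <= length(tree$tip.label)) {
        codon_at(aln$mat[labels[v], ], start)
      } else codon_at(fr$resolved[v, ], start)
      if (is.na(cu) || is.na(cv) || cu == cv) next
      if (is_stop_codon(cv) && !is_stop_codon(cu)) {
        out[[length(out) + 1]] <- data.frame(
          branch = labels[v], column = start, length = NA_real_,
          from = cu, to = cv, klass = "coding", effect = "stop_gain",
          placement = "unambiguous")
      } else if (is_stop_codon(cu) && !is_stop_codon(cv)) {
        out[[length(out) + 1]] <- data.frame(
          branch = labels[v], column = start, length = NA_real_,
          from = cu, to = cv, klass = "coding", effect = "stop_loss",
          placement = "unambiguous")
      }
    }
  }
  # clade-unique gap runs inside the ORF
  orf_cols <- aln$orf[1]:aln$orf[2]
  gapmat <- aln$mat[, orf_cols, drop = FALSE] == "-"
  runs <- list()
  for (t in aln$taxa) {
    r <- rle(gapmat[t, ])
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      key <- paste(pos[k], r$lengths[k], sep = ":")
      runs[[key]] <- c(runs[[key]], t)
    }
  }
  for (key in names(runs)) {
    taxa <- runs[[key]]
    parts <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
    len <- parts[2]
    col <- orf_cols[parts[1]]
    branch <- clade_stem_label(tree, taxa)
    if (is.na(branch)) next  # not a clade: placement not attributable
    out[[length(out) + 1]] <- data.frame(
      branch = branch, column = col, length = len,
      from = "seq", to = "gap", klass = "coding",
      effect = if (len %% 3 != 0) "frameshift_indel" else "indel",
      placement = "unambiguous")
  }
  if (!length(out)) {
    return(data.frame(branch = character(0), column = integer(0),
                      length = numeric(0), from = character(0),
                      to = character(0), klass = character(0),
                      effect = character(0), placement = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# label of the node whose tip set equals `taxa` (the clade's stem branch
# child), or NA when the taxa are not monophyletic in the tree
clade_stem_label <- function(tree, taxa) {
  tree <- label_tree(tree)
  ntip <- length(tree$tip.label)
  if (length(taxa) == 1) return(taxa)
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    tips <- tree$tip.label[descendant_tips(tree, node)]
    if (setequal(tips, taxa)) return(node_labels(tree)[node])
  }
  NA_character_
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

#' Two-sided binomial test for coding vs non-coding substitution excess
#'
#' Tests whether the observed number of coding substitutions among all
#' substitutions departs from the neutral expectation
#' `coding_len / (coding_len + noncoding_len)` (the fraction of compared
#' sites inside the ORF). The two-sided p-value sums the probabilities of
#' all outcomes no more likely than the observed one (the exact binomial
#' "minlike" rule).
#'
#' @param coding,noncoding Observed substitution counts (or a list with
#'   those fields, as returned by [pairwise_counts()]).
#' @param coding_len,noncoding_len Numbers of compared sites inside and
#'   outside the ORF (> 0).
#' @return List (class `test_result`): `statistic` (observed coding
#'   count), `p_value`, `method`, `n`.
#' @export
neutrality_test <- function(coding, noncoding, coding_len, noncoding_len) {
  if (is.list(coding) && !is.null(coding$coding)) {
    noncoding <- coding$non_coding
    coding <- coding$coding
  }
  stopifnot(coding_len > 0, noncoding_len > 0)
  total <- coding + noncoding
  p0 <- coding_len / (coding_len + noncoding_len)
  if (total == 0) {
    warning("no substitutions observed; p = 1")
    p <- 1
  } else {
    p <- stats::binom.test(coding, total, p = p0)$p.value
  }
  structure(list(statistic = coding, p_value = p,
                 method = "binomial_exact", n = total, expected_prop = p0),
            class = "test_result")
}

#' Pairwise coding / non-coding substitution counts
#'
#' Compares two taxa of the alignment column by column. Columns where
#' either taxon carries a gap or N are excluded (indels are excluded from
#' the comparison). Differences at columns inside the ORF count as
#' coding, outside as non-coding. For reporting, translations treat the
#' stop codon as a 21st amino-acid symbol (see [orf_protein()]).
#'
#' @param aln An [ortho_alignment()].
#' @param taxon_a,taxon_b Taxa to compare.
#' @return List (class `pairwise_counts`): `taxa`, `coding`,
#'   `non_coding`, `sites_compared`.
#' @export
pairwise_counts <- function(aln, taxon_a, taxon_b) {
  stopifnot(inherits(aln, "ortho_alignment"))
  if (!all(c(taxon_a, taxon_b) %in% aln$taxa)) {
    stop("both taxa must be in the alignment")
  }
  a <- aln$mat[taxon_a, ]; b <- aln$mat[taxon_b, ]
  ok <- a %in% DNA_STATES & b %in% DNA_STATES
  in_orf <- seq_along(a) >= aln$orf[1] & seq_along(a) <= aln$orf[2]
  diffs <- ok & a != b
  structure(list(taxa = c(taxon_a, taxon_b),
                 coding = sum(diffs & in_orf),
                 non_coding = sum(diffs & !in_orf),
                 sites_compared = sum(ok)),
            class = "pairwise_counts")
}
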