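#' Fitch parsimony substitution mapping
#'
#' @description
#' Places substitutions on the branches of a fixed species tree by Fitch
#' parsimony. For every usable alignment column the down-pass assigns
#' ancestral state sets, a standard backtrack resolves one
#' most-parsimonious labelling (the parent's state is kept whenever it is
#' in the child's down-pass set, otherwise the first state in A<C<G<T
#' order), and an event is emitted on each branch whose resolved endpoint
#' states differ — so the total event count per column equals the
#' column's parsimony score. The up-pass (final) state sets determine
#' whether a placement is forced: an event is `unambiguous` when the
#' endpoint final sets are disjoint (the change occurs on that branch in
#' every most-parsimonious reconstruction) and `ambiguous` otherwise.
#'
#' Gaps and N are treated as missing data (full state set); columns with
#' fewer than two informative taxa are skipped (all-gap columns with a log
#' entry). Events are classed `coding` when the column lies inside the
#' annotated ORF and `non-coding` otherwise.
#'
#' @param aln An [ortho_alignment()].
#' @param tree An `ape::phylo` tree whose tip labels match the alignment
#'   taxa. Internal nodes are auto-labelled `node<k>` when unlabelled;
#'   a branch is identified by the label of its child node.
#' @return A data.frame of branch events: `branch`, `column`, `from`,
#'   `to`, `klass` ("coding"/"non-coding"), `effect` ("substitution"),
#'   `placement` ("unambiguous"/"ambiguous").
#' @export
map_substitutions <- function(aln, tree) {
  fr <- fitch_resolve(aln, tree)
  fr$events
}

#' Per-branch coding:non-coding substitution tallies
#'
#' @param events Event table from [map_substitutions()].
#' @return A data.frame `branch`, `coding`, `non_coding` (the Fig-style
#'   "coding:non-coding" counts per branch).
#' @export
branch_tallies <- function(events) {
  if (!nrow(events)) {
    return(data.frame(branch = character(0), coding = integer(0),
                      non_coding = integer(0)))
  }
  sp <- split(events, events$branch)
  out <- do.call(rbind, lapply(names(sp), function(b) {
    data.frame(branch = b,
               coding = sum(sp[[b]]$klass == "coding"),
               non_coding = sum(sp[[b]]$klass == "non-coding"))
  }))
  rownames(out) <- NULL
  out
}

# ensure unique node labels; returns tree with labels set
label_tree <- function(tree) {
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)) ||
      anyNA(tree$node.label)) {
    tree$node.label <- paste0("node", seq_len(tree$Nnode))
  }
  tree
}

node_labels <- function(tree) c(tree$tip.label, tree$node.label)

DNA_STATES <- c("A", "C", "G", "T")

# Full Fitch machinery for one alignment on one tree. Returns the event
# table plus resolved ancestral state matrices (nodes x columns) used by
# the disabler scan.
fitch_resolve <- function(aln, tree) {
  stopifnot(inherits(aln, "ortho_alignment"), inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, aln$taxa)) {
    stop("tree tips must match alignment taxa")
  }
  tree <- label_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  labels <- node_labels(tree)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- post[nrow(post):1, , drop = FALSE]
  root <- ntip + 1
  ncol_aln <- ncol(aln$mat)
  tipmat <- aln$mat[tree$tip.label, , drop = FALSE]

  resolved <- matrix(NA_character_, nrow = nnode, ncol = ncol_aln)
  events <- list()

  for (col in seq_len(ncol_aln)) {
    obs <- tipmat[, col]
    informative <- obs %in% DNA_STATES
    if (all(!informative)) {
      dn_log("column ", col, " is all-gap/missing; skipped")
      next
    }
    # down-pass state sets as 4-column logical matrix over nodes
    down <- matrix(FALSE, nrow = nnode, ncol = 4)
    down[seq_len(ntip), ] <- TRUE  # missing tips get the full set
    for (i in seq_len(ntip)) {
      if (informative[i]) {
        down[i, ] <- DNA_STATES == obs[i]
      }
    }
    kids <- split(post[, 2], post[, 1])
    for (e in seq_len(nrow(post))) {
      u <- post[e, 1]
      if (any(down[u, ])) next  # already computed
      ch <- kids[[as.character(u)]]
      acc <- down[ch[1], ]
      for (c2 in ch[-1]) {
        inter <- acc & down[c2, ]
        acc <- if (any(inter)) inter else acc | down[c2, ]
      }
      down[u, ] <- acc
    }
    if (sum(informative) < 2) {
      # nothing to map, but still record the observed state for ancestors
      st <- DNA_STATES[which(down[root, ])[1]]
      resolved[, col] <- st
      resolved[seq_len(ntip), col] <- ifelse(informative, obs, st)
      next
    }
    # up-pass final sets (Fitch 1971) for ambiguity flags
    final <- matrix(FALSE, nrow = nnode, ncol = 4)
    final[root, ] <- down[root, ]
    for (e in seq_len(nrow(pre))) {
      u <- pre[e, 1]; v <- pre[e, 2]
      if (all(final[u, ] == (final[u, ] & down[v, ]))) {
        final[v, ] <- final[u, ]
      } else if (v > ntip) {
        ch <- kids[[as.character(v)]]
        union_ch <- Reduce(`|`, lapply(ch, function(c2) down[c2, ]))
        final[v, ] <- down[v, ] | (final[u, ] & union_ch)
      } else {
        final[v, ] <- down[v, ]
      }
    }
    # backtrack one most-parsimonious labelling
    res <- integer(nnode)
    res[root] <- which(down[root, ])[1]
    for (e in seq_len(nrow(pre))) {
      u <- pre[e, 1]; v <- pre[e, 2]
      res[v] <- if (down[v, res[u]]) res[u] else which(down[v, ])[1]
    }
    resolved[, col] <- DNA_STATES[res]
    klass <- if (col >= aln$orf[1] && col <= aln$orf[2]) "coding"
             else "non-coding"
    for (e in seq_len(nrow(post))) {
      u <- post[e, 1]; v <- post[e, 2]
      if (res[u] != res[v]) {
        amb <- any(final[u, ] & final[v, ])
        events[[length(events) + 1]] <- data.frame(
          branch = labels[v], column = col,
          from = DNA_STATES[res[u]], to = DNA_STATES[res[v]],
          klass = klass, effect = "substitution",
          placement = if (amb) "ambiguous" else "unambiguous")
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(0), column = integer(0),
               from = character(0), to = character(0),
               klass = character(0), effect = character(0),
               placement = character(0))
  rownames(resolved) <- labels
  list(events = ev, resolved = resolved, tree = tree)
}
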