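#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes g (using
#' only genes with all-positive counts) of `count[g, j] / geomean(g)`,
#' where `geomean(g)` is the gene's geometric mean across samples. This
#' makes factors scale-equivariant: multiplying one sample's counts by c
#' multiplies its factor by c. When no gene has all-positive counts, the
#' geometric means fall back to the positive entries only (logged).
#'
#' @param counts Genes x samples matrix of non-negative counts.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    sub <- counts[all_pos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    f <- apply(sub / geo, 2, stats::median)
  } else {
    dn_log("no gene with all-positive counts; using positive subsets")
    geo <- apply(counts, 1, function(x) {
      x <- x[x > 0]
      if (!length(x)) NA_real_ else exp(mean(log(x)))
    })
    ratios <- counts / geo
    f <- apply(ratios, 2, function(x) stats::median(x[is.finite(x) & x > 0]))
  }
  stats::setNames(f, colnames(counts))
}

#' Log variance-stabilizing transform
#'
#' `t[g, j] = log2(count[g, j] / factor[j] + 1)`: a monotone
#' variance-stabilizing transform of the normalized counts used for
#' clustering and marker inspection.
#'
#' @param counts Genes x samples count matrix.
#' @param factors Positive size factors, one per sample (estimated with
#'   [size_factors()] when omitted).
#' @return Transformed matrix of the same shape.
#' @export
vst_counts <- function(counts, factors = size_factors(counts)) {
  stopifnot(all(factors > 0), length(factors) == ncol(counts))
  log2(sweep(counts, 2, factors, "/") + 1)
}

#' PCA and hierarchical clustering of samples
#'
#' Clusters samples on the `n_top` most variable genes of the transformed
#' matrix: principal components (centered, not scaled) and complete-
#' linkage hierarchical clustering of the Euclidean sample distances, cut
#' into `k` clusters. Used to assign oviduct transcriptomes to estrous-
#' cycle phases.
#'
#' @param transformed Transformed genes x samples matrix ([vst_counts()]).
#' @param k Number of clusters (3 for the estrous-phase design).
#' @param n_top Number of most-variable genes used (all genes if fewer).
#' @return List (class `cluster_assignment`): `cluster` (named integer
#'   vector), `pc` (sample scores, PC1..), `hclust` (the dendrogram merge
#'   record), `top_genes`.
#' @export
cluster_samples <- function(transformed, k = 3, n_top = 500) {
  n <- ncol(transformed)
  if (k > n) stop("k must not exceed the number of samples")
  v <- apply(transformed, 1, stats::var)
  top <- names(sort(v, decreasing = TRUE))[seq_len(min(n_top, nrow(transformed)))]
  m <- t(transformed[top, , drop = FALSE])
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  hc <- stats::hclust(stats::dist(m), method = "complete")
  cl <- stats::cutree(hc, k = k)
  structure(list(cluster = cl, pc = pc$x, hclust = hc, top_genes = top),
            class = "cluster_assignment")
}

#' Anchor cluster labels to estrous-phase marker direction
#'
#' Relabels clusters so that "cluster 1" is reproducible across runs: the
#' cluster maximizing `median(Pgr) + median(Esr1) - median(Gper1)` on the
#' transformed values becomes cluster 1 (the phase of high progesterone
#' receptor and estrogen receptor 1 expression and low G-protein-coupled
#' estrogen receptor 1 expression, i.e. proestrus / early estrus);
#' remaining clusters follow in decreasing marker-score order. When all
#' marker scores tie, the relabeling is declared unstable (warning) and
#' the input labels are kept.
#'
#' @param transformed Transformed matrix containing the marker genes.
#' @param assignment A `cluster_assignment` (or named cluster vector).
#' @param markers Character vector of three marker gene ids, in the order
#'   up, up, down. Default `c("Pgr", "Esr1", "Gper1")`.
#' @return List: `cluster` (relabelled named vector), `marker_report`
#'   (per-cluster marker medians and score), `stable`.
#' @export
marker_direction_check <- function(transformed, assignment,
                                   markers = c("Pgr", "Esr1", "Gper1")) {
  cl <- if (inherits(assignment, "cluster_assignment")) assignment$cluster
        else assignment
  missing <- setdiff(markers, rownames(transformed))
  if (length(missing)) {
    stop("marker gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  ks <- sort(unique(cl))
  rep <- do.call(rbind, lapply(ks, function(k) {
    s <- names(cl)[cl == k]
    med <- vapply(markers, function(g)
      stats::median(transformed[g, s]), numeric(1))
    data.frame(cluster = k, t(med),
               score = med[1] + med[2] - med[3])
  }))
  names(rep)[2:4] <- markers
  if (length(unique(rep$score)) == 1 && length(ks) > 1) {
    warning("marker medians are flat across clusters; relabeling unstable")
    return(list(cluster = cl, marker_report = rep, stable = FALSE))
  }
  ord <- order(rep$score, decreasing = TRUE)
  relabel <- stats::setNames(seq_along(ks), rep$cluster[ord])
  new_cl <- stats::setNames(as.integer(relabel[as.character(cl)]), names(cl))
  rep$new_label <- as.integer(relabel[as.character(rep$cluster)])
  list(cluster = new_cl, marker_report = rep, stable = TRUE)
}

#' Negative-binomial Wald test for differential expression
#'
#' Per-gene knockout vs wildtype comparison on a subset of samples (one
#' estrous-phase cluster). Counts are normalized by the size factors;
#' genes with base mean below `min_base_mean` are excluded (independent
#' filtering). NB dispersion is estimated by the method of moments:
#' per-gene estimates `(var - mu) / mu^2` from the within-group variances
#' are noisy at these group sizes, so the test uses a mean-dispersion
#' trend (the running median of the per-gene estimates over bins of base
#' mean, floored at 1e-8) — a moments-based analogue of the shrinkage
#' estimators used by the standard DE tools. The Wald statistic tests the
#' log2 fold change with delta-method standard error
#' `sqrt((1/mu_KO + disp)/n_KO + (1/mu_WT + disp)/n_WT) / ln 2`, and
#' p-values are Benjamini-Hochberg adjusted across the tested genes.
#' Genes with an all-zero group are flagged (infinite |log2FC|) and not
#' tested.
#'
#' @param counts Genes x samples count matrix.
#' @param genotype Character vector ("KO"/"WT"), one per sample column.
#' @param factors Size factors (estimated from `counts` when omitted).
#' @param samples Optional character vector of sample names to restrict
#'   to (a cluster subset); both genotypes must be present.
#' @param alpha Adjusted-p significance threshold (reported, not used to
#'   drop rows).
#' @param min_base_mean Minimum mean normalized count for testing.
#' @return Data.frame: `gene`, `base_mean`, `fold_change` (linear,
#'   KO/WT), `log2fc`, `pvalue`, `padj`, `significant`, `tested`.
#' @export
de_test <- function(counts, genotype, factors = size_factors(counts),
                    samples = NULL, alpha = 0.01, min_base_mean = 1) {
  stopifnot(length(genotype) == ncol(counts))
  genotype <- stats::setNames(genotype, colnames(counts))
  if (!is.null(samples)) {
    counts <- counts[, samples, drop = FALSE]
    factors <- factors[samples]
    genotype <- genotype[samples]
  }
  if (!all(c("KO", "WT") %in% genotype)) {
    stop("both genotypes must be present in the tested subset")
  }
  norm <- sweep(counts, 2, factors, "/")
  ko <- genotype == "KO"; wt <- genotype == "WT"
  n_ko <- sum(ko); n_wt <- sum(wt)
  mu_ko <- rowMeans(norm[, ko, drop = FALSE])
  mu_wt <- rowMeans(norm[, wt, drop = FALSE])
  v_ko <- apply(norm[, ko, drop = FALSE], 1, stats::var)
  v_wt <- apply(norm[, wt, drop = FALSE], 1, stats::var)
  base_mean <- rowMeans(norm)
  disp_raw <- ((v_ko - mu_ko) / mu_ko^2 + (v_wt - mu_wt) / mu_wt^2) / 2
  disp <- pmax(dispersion_trend(base_mean, disp_raw), 1e-8)
  lfc <- log2(mu_ko / mu_wt)
  testable <- base_mean >= min_base_mean & mu_ko > 0 & mu_wt > 0
  se <- sqrt((1 / mu_ko + disp) / n_ko + (1 / mu_wt + disp) / n_wt) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!testable] <- NA
  padj <- rep(NA_real_, length(p))
  padj[testable] <- stats::p.adjust(p[testable], method = "BH")
  res <- data.frame(gene = rownames(counts), base_mean = base_mean,
                    fold_change = mu_ko / mu_wt, log2fc = lfc,
                    dispersion = disp, dispersion_raw = disp_raw,
                    pvalue = p, padj = padj,
                    significant = !is.na(padj) & padj <= alpha,
                    tested = testable)
  rownames(res) <- NULL
  res
}

# running-median mean-dispersion trend: median of the per-gene
# method-of-moments estimates within ~20 equal-occupancy bins of base
# mean, interpolated back to every gene
dispersion_trend <- function(base_mean, disp_raw, n_bins = 20) {
  ok <- is.finite(disp_raw) & is.finite(base_mean) & base_mean > 0
  if (sum(ok) < 10) return(pmax(disp_raw, 0))
  lb <- log(base_mean[ok])
  bins <- cut(rank(lb, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  med_x <- tapply(lb, bins, stats::median)
  med_y <- tapply(pmax(disp_raw[ok], 0), bins, stats::median)
  fit <- stats::approx(med_x, med_y, xout = log(pmax(base_mean, 1e-8)),
                       rule = 2)$y
  pmax(fit, 0)
}

#' Format significant DE results in report-table style
#'
#' Renders the significant genes ordered by adjusted p-value with the
#' columns used in the published cluster-1 table: gene, base mean
#' (rounded), linear fold change (2 decimals) and adjusted p (4
#' decimals).
#'
#' @param res Result of [de_test()].
#' @param alpha Threshold on adjusted p.
#' @return Data.frame `gene`, `base_mean`, `fold_change`, `adjusted_p`.
#' @export
format_de_table <- function(res, alpha = 0.01) {
  sig <- res[!is.na(res$padj) & res$padj <= alpha, , drop = FALSE]
  sig <- sig[order(sig$padj, -abs(sig$log2fc)), , drop = FALSE]
  data.frame(gene = sig$gene,
             base_mean = round(sig$base_mean),
             fold_change = sprintf("%.2f", sig$fold_change),
             adjusted_p = sprintf("%.4f", sig$padj))
}
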