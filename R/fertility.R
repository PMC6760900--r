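#' Early / late grouping of litter intervals
#'
#' The interval from the first to the second litter is bimodal: dams
#' either conceive at the postpartum estrus (second litter within 25
#' days, "early") or only after lactational suppression of ovulation
#' (35 days or more, "late"). Both boundaries are inclusive. Values in
#' the 26-34 day gap are labelled "intermediate" with a warning, since
#' the observed data contain none.
#'
#' @param days Positive integer vector of days from litter 1 to litter 2.
#' @return Character vector of labels ("early"/"late"/"intermediate"),
#'   same length as `days` (NA in, NA out).
#' @export
interval_groups <- function(days) {
  if (any(!is.na(days) & days <= 0)) stop("days must be positive")
  lab <- ifelse(is.na(days), NA_character_,
                ifelse(days <= 25, "early",
                       ifelse(days >= 35, "late", "intermediate")))
  if (any(!is.na(lab) & lab == "intermediate")) {
    warning("interval(s) in the 26-34 day gap labelled 'intermediate'")
  }
  lab
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact when the combined sample size is at most 20 and the pooled data
#' contain no ties: the null distribution of the rank sum of `x` is built
#' by full enumeration of all C(m+n, m) rank assignments, and the
#' two-sided p doubles the smaller tail (capped at 1). Otherwise a normal
#' approximation with midranks, tie-corrected variance and continuity
#' correction is used. The p-value is invariant under any strictly
#' monotone transform of the pooled data.
#'
#' @param x,y Non-empty numeric samples.
#' @return List (class `test_result`): `statistic` (rank sum of `x`),
#'   `p_value`, `method` ("wilcoxon_exact"/"wilcoxon_normal"), `n`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(m)])
  ties <- any(duplicated(pooled))
  if (N <= 20 && !ties) {
    combos <- utils::combn(N, m)
    sums <- colSums(matrix(sort(r)[combos], nrow = m))
    lo <- mean(sums <= W); hi <- mean(sums >= W)
    p <- min(1, 2 * min(lo, hi))
    method <- "wilcoxon_exact"
  } else {
    E <- m * (N + 1) / 2
    tie_tab <- table(pooled)
    v <- m * n * (N + 1) / 12 -
      m * n * sum(tie_tab^3 - tie_tab) / (12 * N * (N - 1))
    z <- max(0, abs(W - E) - 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "wilcoxon_normal"
  }
  structure(list(statistic = W, p_value = p, method = method,
                 n = c(x = m, y = n)),
            class = "test_result")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins; the two-sided p-value sums the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within
#' relative tolerance 1e-7 for ties) — the convention of the common
#' statistical environment. A zero row or column margin yields p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome yes/no).
#' @return List (class `test_result`): `statistic` (count in cell
#'   \[1,1\]), `p_value`, `method`, `n` (row margins).
#' @examples
#' # infanticide in 4 of 16 KO litters vs 0 of 20 WT/het litters
#' fisher_exact_2x2(matrix(c(4, 0, 12, 20), nrow = 2))$p_value  # 0.0309
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  a <- table[1, 1]
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); c2 <- sum(table[, 2])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(structure(list(statistic = a, p_value = 1,
                          method = "fisher_exact", n = c(r1 = r1, r2 = r2)),
                     class = "test_result"))
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  structure(list(statistic = a, p_value = min(1, p),
                 method = "fisher_exact", n = c(r1 = r1, r2 = r2)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic =", x$statistic,
      ", two-sided p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Cohort summary of litter records
#'
#' Per-genotype medians of days to the first litter, days from the first
#' to the second litter and pup counts, with the infanticide contingency
#' table (denominator = litters observed, not pairs). The median of an
#' even-sized sample is the midpoint of the central order statistics;
#' missing fields are excluded from the relevant median with the retained
#' n reported.
#'
#' @param records Litter-record data.frame ([read_litter_records()]).
#' @param cohort Optional cohort filter ("stock"/"dedicated").
#' @return List: `medians` (per-genotype data.frame with n columns),
#'   `infanticide` (2x2 matrix genotype x yes/no), `early_late` (per-pair
#'   classification of the litter-1-to-2 interval).
#' @export
cohort_summary <- function(records, cohort = NULL) {
  if (!is.null(cohort)) records <- records[records$cohort %in% cohort, ]
  if (!nrow(records)) stop("no records in the requested cohort")
  med_n <- function(x) {
    x <- x[!is.na(x)]
    c(median = if (length(x)) stats::median(x) else NA_real_,
      n = length(x))
  }
  gts <- unique(records$genotype)
  medians <- do.call(rbind, lapply(gts, function(g) {
    r <- records[records$genotype == g, ]
    m1 <- med_n(r$days_litter1); m2 <- med_n(r$days_litter1_to_2)
    p1 <- med_n(r$pups_litter1); p2 <- med_n(r$pups_litter2)
    data.frame(genotype = g,
               days_litter1 = m1[1], n_litter1 = m1[2],
               days_litter1_to_2 = m2[1], n_litter2 = m2[2],
               pups_litter1 = p1[1], n_pups1 = p1[2],
               pups_litter2 = p2[1], n_pups2 = p2[2])
  }))
  rownames(medians) <- NULL
  # litters observed: each record contributes its litters with a recorded
  # infanticide outcome
  inf <- t(vapply(gts, function(g) {
    r <- records[records$genotype == g, ]
    yes <- sum(r$infanticide, na.rm = TRUE)
    tot <- sum(!is.na(r$infanticide))
    c(yes = yes, no = tot - yes)
  }, numeric(2)))
  rownames(inf) <- gts
  list(medians = medians,
       infanticide = inf,
       early_late = data.frame(
         pair_id = records$pair_id,
         genotype = records$genotype,
         days_litter1_to_2 = records$days_litter1_to_2,
         group = suppressWarnings(
           interval_groups(records$days_litter1_to_2))))
}
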