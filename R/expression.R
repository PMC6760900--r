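#' Summarize transcript-level FPKM into gene and tissue abundances
#'
#' Implements the expression summarization used for candidate profiling:
#' a transcript's value in a tissue is the mean of its FPKM over
#' biological/technical replicates; a gene's value is the sum over its
#' transcripts; the aggregate expression of a gene set in a tissue is
#' `sum(log2(FPKM + 1))` over its genes; and a gene's overall level is its
#' maximum across tissues.
#'
#' @param fpkm Long-format data.frame with columns `gene`, `transcript`,
#'   `tissue`, `replicate`, `fpkm` (FPKM >= 0).
#' @return A list with `transcript` (transcript x tissue means), `gene`
#'   (gene x tissue sums), `aggregate` (per-tissue sum of log2(FPKM+1)
#'   over genes), and `gene_overall` (per-gene max across tissues).
#' @examples
#' tab <- data.frame(gene = c("g1", "g2"), transcript = c("t1", "t2"),
#'                   tissue = "ovary", replicate = 1, fpkm = c(1, 3))
#' expression_summarize(tab)$aggregate  # log2(2) + log2(4) = 3
#' @export
expression_summarize <- function(fpkm) {
  need <- c("gene", "transcript", "tissue", "replicate", "fpkm")
  if (!all(need %in% names(fpkm))) {
    stop("fpkm table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(fpkm$fpkm < 0)) stop("negative FPKM value")
  tr <- stats::aggregate(fpkm ~ transcript + gene + tissue, data = fpkm,
                         FUN = mean)
  gn <- stats::aggregate(fpkm ~ gene + tissue, data = tr, FUN = sum)
  agg <- stats::aggregate(list(aggregate = log2(gn$fpkm + 1)),
                          by = list(tissue = gn$tissue), FUN = sum)
  overall <- stats::aggregate(fpkm ~ gene, data = gn, FUN = max)
  names(overall)[2] <- "overall"
  list(transcript = tr, gene = gn, aggregate = agg, gene_overall = overall)
}
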