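#' Read a protein or nucleotide FASTA as a named character vector
#'
#' Thin wrappers over Biostrings readers; sequences come back as plain
#' uppercase character vectors named by record id (first whitespace-
#' delimited token of the header).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_protein <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta_protein
#' @export
read_fasta_dna <- function(path) {
  x <- Biostrings::readBStringSet(path)  # tolerate gaps/N in alignments
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a gene-model feature table
#'
#' Tab-separated with mandatory header
#' `gene, transcript, chrom, start, end, strand, feature`; `feature` is
#' `exon` or `CDS`; coordinates are 0-based half-open (the package's
#' internal convention).
#'
#' @param path TSV path.
#' @return A data.frame of features.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "transcript", "chrom", "start", "end", "strand", "feature")
  if (!all(need %in% names(df))) {
    stop("gene model table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_gene_models
#' @param models Feature data.frame.
#' @export
write_gene_models <- function(models, path) {
  utils::write.table(models, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a gene model object
#'
#' @param gene Gene id.
#' @param features Feature data.frame (rows for this gene, columns as in
#'   [read_gene_models()]).
#' @param cds_seq CDS nucleotide sequence (spliced, 5'->3').
#' @param protein Protein sequence (optional; translated from `cds_seq`
#'   when absent).
#' @return An object of class `gene_model` with exon and CDS intervals.
#' @export
gene_model <- function(gene, features = NULL, cds_seq = NULL, protein = NULL) {
  if (is.null(protein) && !is.null(cds_seq) && nchar(cds_seq) %% 3 == 0) {
    protein <- translate_cds(cds_seq, drop_stop = TRUE)
  }
  structure(list(gene = gene, features = features,
                 cds_seq = if (is.null(cds_seq)) NULL else toupper(cds_seq),
                 protein = protein),
            class = "gene_model")
}

#' Translate a CDS, representing stops as `*`
#'
#' The stop symbol acts as a 21st amino-acid letter so that stop-containing
#' reading frames can be compared like any other sequence.
#'
#' @param cds_seq Nucleotide string, length divisible by 3.
#' @param drop_stop Drop a single terminal stop from the translation.
#' @return Amino-acid string (with `*` for stops).
#' @export
translate_cds <- function(cds_seq, drop_stop = FALSE) {
  cds_seq <- toupper(cds_seq)
  if (nchar(cds_seq) %% 3 != 0) stop("CDS length not divisible by 3")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_seq), if.fuzzy.codon = "X",
    no.init.codon = TRUE))
  if (drop_stop) aa <- sub("\\*$", "", aa)
  aa
}

#' Read / write a genes-by-samples count matrix (TSV)
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param path TSV path.
#' @return Integer matrix with gene rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  if (any(m < 0)) stop("count matrix has negative entries")
  m
}

#' @rdname read_count_matrix
#' @param counts Matrix with gene rownames.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write litter records (CSV)
#'
#' Comma-separated with header; columns `pair_id, genotype, cohort,
#' days_litter1, days_litter1_to_2, pups_litter1, pups_litter2,
#' infanticide`. Missing interval fields are empty/NA.
#'
#' @param path CSV path.
#' @return A data.frame of litter records.
#' @export
read_litter_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "genotype", "cohort", "days_litter1",
            "days_litter1_to_2", "pups_litter1", "pups_litter2",
            "infanticide")
  if (!all(need %in% names(df))) {
    stop("litter record CSV must have columns: ",
         paste(need, collapse = ", "))
  }
  df$infanticide <- as.logical(df$infanticide)
  bad <- c(df$days_litter1, df$days_litter1_to_2)
  if (any(!is.na(bad) & bad <= 0)) stop("days fields must be positive")
  df
}

#' @rdname read_litter_records
#' @param records Litter record data.frame.
#' @export
write_litter_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
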