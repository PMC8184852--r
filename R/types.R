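#' Expression matrix with sample sheet
#'
#' Container for a gene x sample table of non-negative integer read counts
#' together with its sample annotation (genotype, material, timepoint in
#' hours, replicate). Every column of the count matrix must be described by
#' exactly one sample-sheet row.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data frame with columns `sample_id`, `genotype`,
#'   `material`, `timepoint_h`, `replicate`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts))) stop("counts must be integral")
  req <- c("sample_id", "genotype", "material", "timepoint_h", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0)
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!setequal(colnames(counts), samples$sample_id))
    stop("sample sheet must cover every count column exactly once")
  samples <- samples[match(colnames(counts), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$genotype), collapse = ", ")))
  invisible(x)
}

#' Allele count table for F1 hybrids
#'
#' Long-format table of two-allele read counts per gene and sample:
#' `count_a` is the outgroup allele, `count_b` the derived-lineage allele.
#' Includes the genomic DNA control samples that provide the mapping-bias
#' baseline for the allele-specific expression test.
#'
#' @param tbl data frame with columns `gene_id`, `sample_id`, `hybrid`,
#'   `material`, `timepoint_h`, `count_a`, `count_b` (and optionally a
#'   `replicate` column).
#' @param snps optional per-SNP sub-table (columns `gene_id`, `snp_id`,
#'   `position`, `distance_to_intron_bp`, `dna_coverage`, ...).
#' @return an object of class `allele_count_table` (a data frame).
#' @export
allele_count_table <- function(tbl, snps = NULL) {
  req <- c("gene_id", "sample_id", "hybrid", "material", "timepoint_h",
           "count_a", "count_b")
  miss <- setdiff(req, names(tbl))
  if (length(miss) > 0)
    stop("allele table is missing columns: ", paste(miss, collapse = ", "))
  if (any(tbl$count_a < 0) || any(tbl$count_b < 0))
    stop("allele counts must be non-negative")
  if (anyDuplicated(tbl[, c("gene_id", "sample_id")]))
    stop("duplicate (gene_id, sample_id) rows in allele table")
  structure(as.data.frame(tbl), snps = snps,
            class = c("allele_count_table", "data.frame"))
}
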