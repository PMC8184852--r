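# Readers and writers for every table the pipeline touches. All tabular
# formats are TSV/CSV with headers; gene ids are opaque strings; timepoints
# are hours as decimals. VCF positions stay 1-based (the VCF convention);
# any internal interval logic is half-open 0-based, and this reader is the
# boundary where the conversion would happen.

#' Write / read an expression matrix
#'
#' The counts travel as a long TSV (`gene_id`, `sample_id`, `count`) and the
#' sample sheet as a CSV, so a write followed by a read restores an
#' identical object.
#'
#' @param em an [expression_matrix()].
#' @param counts_path path to the counts TSV.
#' @param samples_path path to the sample-sheet CSV.
#' @export
write_counts <- function(em, counts_path, samples_path) {
  long <- data.frame(gene_id = rep(rownames(em$counts), ncol(em$counts)),
                     sample_id = rep(colnames(em$counts),
                                     each = nrow(em$counts)),
                     count = as.integer(em$counts))
  utils::write.table(long, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(em$samples, samples_path, row.names = FALSE)
  invisible(em)
}

#' @rdname write_counts
#' @return `read_counts()` returns a validated [expression_matrix()];
#'   malformed rows are rejected with a message naming the offending line
#'   (1-based, counting the header as line 1).
#' @export
read_counts <- function(counts_path, samples_path) {
  long <- utils::read.delim(counts_path, stringsAsFactors = FALSE)
  req <- c("gene_id", "sample_id", "count")
  miss <- setdiff(req, names(long))
  if (length(miss) > 0)
    stop(sprintf("%s: missing columns: %s", counts_path,
                 paste(miss, collapse = ", ")))
  bad <- which(is.na(long$count) | long$count < 0 |
                 long$count != floor(long$count))
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: count '%s' is not a non-negative integer",
                 counts_path, bad[1] + 1L, long$count[bad[1]]))
  dup <- which(duplicated(long[, c("gene_id", "sample_id")]))
  if (length(dup) > 0)
    stop(sprintf("%s: line %d: duplicate (gene_id, sample_id) key",
                 counts_path, dup[1] + 1L))
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  genes <- unique(long$gene_id)
  ids <- unique(long$sample_id)
  unknown <- setdiff(ids, samples$sample_id)
  if (length(unknown) > 0)
    stop(sprintf("%s: sample ids absent from sample sheet: %s", counts_path,
                 paste(utils::head(unknown, 3), collapse = ", ")))
  counts <- matrix(0L, length(genes), length(ids),
                   dimnames = list(genes, ids))
  counts[cbind(match(long$gene_id, genes), match(long$sample_id, ids))] <-
    as.integer(long$count)
  expression_matrix(counts, samples[samples$sample_id %in% ids, ,
                                    drop = FALSE])
}

#' Write / read an allele count table
#'
#' Long TSV with one row per (gene, sample, allele), allele coded `A`
#' (outgroup allele) or `B` (derived allele).
#'
#' @param at an [allele_count_table()].
#' @param path path to the TSV.
#' @param samples_path path to the sample-sheet CSV describing the hybrid
#'   RNA and DNA samples.
#' @export
write_alleles <- function(at, path, samples_path = NULL) {
  long <- rbind(
    data.frame(gene_id = at$gene_id, sample_id = at$sample_id, allele = "A",
               count = at$count_a),
    data.frame(gene_id = at$gene_id, sample_id = at$sample_id, allele = "B",
               count = at$count_b))
  long <- long[order(long$gene_id, long$sample_id, long$allele), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(samples_path)) {
    sheet <- unique(at[, c("sample_id", "hybrid", "material", "timepoint_h")])
    utils::write.csv(sheet, samples_path, row.names = FALSE)
  }
  invisible(at)
}

#' @rdname write_alleles
#' @export
read_alleles <- function(path, samples_path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "sample_id", "allele", "count")
  miss <- setdiff(req, names(long))
  if (length(miss) > 0)
    stop(sprintf("%s: missing columns: %s", path,
                 paste(miss, collapse = ", ")))
  bad <- which(is.na(long$count) | long$count < 0 |
                 long$count != floor(long$count))
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: count '%s' is not a non-negative integer",
                 path, bad[1] + 1L, long$count[bad[1]]))
  badal <- which(!long$allele %in% c("A", "B"))
  if (length(badal) > 0)
    stop(sprintf("%s: line %d: allele must be 'A' or 'B'", path,
                 badal[1] + 1L))
  sheet <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  a <- long[long$allele == "A", c("gene_id", "sample_id", "count")]
  b <- long[long$allele == "B", c("gene_id", "sample_id", "count")]
  names(a)[3] <- "count_a"; names(b)[3] <- "count_b"
  tbl <- merge(a, b, by = c("gene_id", "sample_id"))
  tbl <- merge(tbl, sheet, by = "sample_id")
  tbl <- tbl[order(tbl$sample_id, tbl$gene_id),
             c("gene_id", "sample_id", "hybrid", "material", "timepoint_h",
               "count_a", "count_b")]
  rownames(tbl) <- NULL
  allele_count_table(tbl)
}

#' Write / read the planted-truth table
#' @param truth a `sim_truth` data frame from [simulate_experiment()].
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a haplotype matrix as a minimal diploid VCF
#'
#' Consecutive haplotypes are paired into diploid individuals. The writer
#' emits a small VCF 4.2 file with `GT:GQ:DP` fields so that the population
#' reader (and its filters) can be exercised on synthetic data.
#'
#' @param pop result of [simulate_population()].
#' @param path output `.vcf` path.
#' @param chrom chromosome label.
#' @param gq,dp genotype quality and depth written for every call.
#' @param qual site quality written for every record.
#' @export
write_population_vcf <- function(pop, path, chrom = "chr1", gq = 99,
                                 dp = 30, qual = 100) {
  hap <- pop$haplotypes
  n <- nrow(hap)
  if (n %% 2 != 0) stop("need an even number of haplotypes to pair diploids")
  ind <- paste0("ind", seq_len(n / 2))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ind), collapse = "\t")), con)
  if (ncol(hap) > 0) {
    for (j in seq_len(ncol(hap))) {
      gt <- paste0(hap[seq(1, n, 2), j], "|", hap[seq(2, n, 2), j],
                   ":", gq, ":", dp)
      writeLines(paste(c(chrom, pop$positions[j], ".", "A", "T", qual,
                         "PASS", ".", "GT:GQ:DP", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read population variation data from VCF plus site annotation
#'
#' Parses a VCF 4.x file (via the \pkg{vcfR} package) and joins a per-site
#' annotation TSV (`chrom`, `pos`, `class`, `gene`) labelling sites as
#' synonymous / nonsynonymous / other and assigning them to genes. Nothing
#' is filtered here beyond structural validation; quality and missing-data
#' filtering is the job of [filter_population()].
#'
#' @param vcf_path path to an uncompressed or bgzipped VCF.
#' @param annotation_path path to the annotation TSV.
#' @return a `population_data` list with elements `sites` (data frame:
#'   chrom, pos, ref, alt, qual, class, gene, is_indel, is_multiallelic),
#'   `gt` (sites x individuals matrix of allele-dosage 0/1/2, NA = missing),
#'   `gq` and `dp` (matching numeric matrices, NA when absent).
#' @export
read_population <- function(vcf_path, annotation_path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_population() requires the vcfR package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop(sprintf("%s: no variant records", vcf_path))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop(sprintf("%s: records without GT field", vcf_path))
  dose <- function(x) {
    x <- sub(":.*", "", x)
    x[x %in% c(".", "./.", ".|.")] <- NA
    a1 <- substr(x, 1, 1); a2 <- substr(x, 3, 3)
    suppressWarnings(as.integer(a1) + as.integer(a2))
  }
  gt <- apply(gt_raw, 2, dose)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  num_mat <- function(el) {
    m <- tryCatch(vcfR::extract.gt(v, element = el, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) matrix(NA_real_, nrow(fix), ncol(gt)) else m
  }
  gq <- num_mat("GQ")
  dp <- num_mat("DP")
  alt <- fix$ALT
  ref <- fix$REF
  sites <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = ref, alt = alt,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    is_indel = nchar(ref) > 1 |
      vapply(strsplit(alt, ","), function(x) any(nchar(x) > 1), logical(1)),
    is_multiallelic = grepl(",", alt),
    stringsAsFactors = FALSE)
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop(sprintf("%s: duplicate positions within a chromosome", vcf_path))
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "class", "gene")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0)
    stop(sprintf("%s: missing columns: %s", annotation_path,
                 paste(miss, collapse = ", ")))
  key <- paste(sites$chrom, sites$pos)
  akey <- paste(ann$chrom, ann$pos)
  m <- match(key, akey)
  sites$class <- ifelse(is.na(m), "other", ann$class[m])
  sites$gene <- ifelse(is.na(m), NA_character_, ann$gene[m])
  structure(list(sites = sites, gt = gt, gq = gq, dp = dp),
            class = "population_data")
}

#' Write a pair of aligned coding sequences as FASTA
#' @param pair result of [simulate_codon_pair()] (or any list with `seq1`,
#'   `seq2`).
#' @param path output FASTA path.
#' @param names sequence names.
#' @export
write_codon_pair_fasta <- function(pair, path, names = c("seq1", "seq2")) {
  seqinr::write.fasta(list(strsplit(pair$seq1, "")[[1]],
                           strsplit(pair$seq2, "")[[1]]),
                      names = names, file.out = path)
  invisible(path)
}

#' @rdname write_codon_pair_fasta
#' @export
read_codon_pair_fasta <- function(path) {
  s <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = TRUE)
  if (length(s) < 2) stop(sprintf("%s: expected two sequences", path))
  list(seq1 = as.character(s[[1]]), seq2 = as.character(s[[2]]))
}

#' Write an arbitrary results bundle as JSON
#' @param records a list (or data frame) of results.
#' @param path output `.json` path.
#' @export
write_results <- function(records, path) {
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
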