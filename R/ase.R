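# Allele-specific expression against the genomic DNA baseline.
#
# Per gene and hybrid, the two allele counts are modelled with a
# quasi-binomial GLM (logit link) over the 7 sample types (DNA, RNA 0 h,
# RNA 1.5 h, ..., RNA 24 h). The DNA control carries any residual mapping
# bias, so the basal contrast is RNA 0 h vs DNA and the plastic contrasts
# are RNA t vs RNA 0 h; both are t-tests on the residual degrees of freedom
# with the Pearson dispersion floored at 1 (never deflated below binomial).

#' Filter SNPs for allele-specific quantification
#'
#' Retains SNPs that are more than `intron_dist_bp` away from the nearest
#' intron, do not sit in a SNP-dense region (more than `max_snps_per_window`
#' SNPs within a 200-bp window, a signature of divergent or misannotated
#' segments that map poorly), and have DNA coverage of at least
#' `min_dna_coverage` reads. Nothing is dropped silently: the removed SNPs
#' are returned alongside a reason code.
#'
#' @param snps data frame with columns `gene_id`, `snp_id`, `position`,
#'   `distance_to_intron_bp`, `dna_coverage`.
#' @param intron_dist_bp minimum distance to the nearest intron (exclusive).
#' @param max_snps_per_window maximum number of SNPs tolerated in any 200-bp
#'   window; every SNP inside an overloaded window is removed.
#' @param window_bp width of the density window.
#' @param min_dna_coverage minimum total DNA read coverage (inclusive).
#' @return list with `retained` and `removed` data frames; `removed` has a
#'   `reason` column.
#' @export
filter_snps <- function(snps, intron_dist_bp = 50, max_snps_per_window = 10,
                        window_bp = 200, min_dna_coverage = 5) {
  req <- c("gene_id", "snp_id", "position", "distance_to_intron_bp",
           "dna_coverage")
  miss <- setdiff(req, names(snps))
  if (length(miss) > 0)
    stop("SNP table is missing columns: ", paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(snps))
  reason[snps$dna_coverage < min_dna_coverage] <- "low_dna_coverage"
  reason[snps$distance_to_intron_bp <= intron_dist_bp] <- "near_intron"
  half <- window_bp / 2
  for (g in unique(snps$gene_id)) {
    i <- which(snps$gene_id == g)
    pos <- snps$position[i]
    n_in_win <- vapply(pos, function(p) sum(abs(pos - p) <= half),
                       integer(1))
    centers <- pos[n_in_win > max_snps_per_window]
    if (length(centers) > 0) {
      dense <- vapply(pos, function(p) any(abs(centers - p) <= half),
                      logical(1))
      reason[i[dense]] <- "snp_dense_region"
    }
  }
  list(retained = snps[is.na(reason), , drop = FALSE],
       removed = cbind(snps[!is.na(reason), , drop = FALSE],
                       reason = reason[!is.na(reason)]))
}

#' Aggregate per-SNP allele counts to the gene level
#'
#' The gene total is the sum of SNP totals; the gene-level allele-B fraction
#' is the median across SNPs of the per-SNP B fraction, applied to the total
#' and rounded half-to-even with exact conservation of the total. Genes
#' whose mean total across samples falls below `min_mean_count` are dropped
#' (low-expression filter); genes with no covered SNP in a sample are marked
#' unquantifiable there.
#'
#' @param snp_counts data frame with columns `gene_id`, `snp_id`,
#'   `sample_id`, `count_a`, `count_b`.
#' @param min_mean_count low-expression cutoff on the per-gene mean total.
#' @return list with `counts` (gene x sample rows: `count_a`, `count_b`)
#'   and `dropped` (gene ids removed by the mean-count filter or
#'   unquantifiable everywhere, with reasons).
#' @export
aggregate_gene_alleles <- function(snp_counts, min_mean_count = 10) {
  req <- c("gene_id", "snp_id", "sample_id", "count_a", "count_b")
  miss <- setdiff(req, names(snp_counts))
  if (length(miss) > 0)
    stop("SNP count table is missing columns: ",
         paste(miss, collapse = ", "))
  key <- interaction(snp_counts$gene_id, snp_counts$sample_id, drop = TRUE)
  tot_snp <- snp_counts$count_a + snp_counts$count_b
  frac_b <- ifelse(tot_snp > 0, snp_counts$count_b / tot_snp, NA)
  agg <- data.frame(
    gene_id = tapply(as.character(snp_counts$gene_id), key, `[`, 1),
    sample_id = tapply(as.character(snp_counts$sample_id), key, `[`, 1),
    total = as.numeric(tapply(tot_snp, key, sum)),
    frac_b = as.numeric(tapply(frac_b, key, stats::median, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg$quantifiable <- agg$total > 0 & !is.na(agg$frac_b)
  agg$count_b <- ifelse(agg$quantifiable, round(agg$frac_b * agg$total), 0)
  agg$count_a <- ifelse(agg$quantifiable, agg$total - agg$count_b, 0)
  mean_tot <- tapply(agg$total, agg$gene_id, mean)
  low <- names(mean_tot)[mean_tot < min_mean_count]
  unq <- tapply(agg$quantifiable, agg$gene_id, function(x) !any(x))
  dead <- names(unq)[unq]
  dropped <- data.frame(
    gene_id = c(low, setdiff(dead, low)),
    reason = c(rep("mean_count_below_cutoff", length(low)),
               rep("unquantifiable", length(setdiff(dead, low)))),
    stringsAsFactors = FALSE)
  keep <- !(agg$gene_id %in% dropped$gene_id)
  list(counts = agg[keep, c("gene_id", "sample_id", "count_a", "count_b",
                            "quantifiable")],
       dropped = dropped)
}

#' Normalize gene-level allele counts by sample totals
#'
#' Each sample's counts are divided by a size factor equal to the sample's
#' total read count over retained genes divided by the median of those
#' totals across samples. Within-sample allele fractions are preserved
#' exactly.
#'
#' @param at an [allele_count_table()] (or data frame with `sample_id`,
#'   `count_a`, `count_b`).
#' @return the table with `count_a`/`count_b` rescaled (no longer integral)
#'   and the factors in `attr(, "size_factors")`.
#' @export
normalize_alleles <- function(at) {
  tot <- tapply(at$count_a + at$count_b, at$sample_id, sum)
  sf <- tot / stats::median(tot)
  f <- as.numeric(sf[as.character(at$sample_id)])
  out <- at
  out$count_a <- at$count_a / f
  out$count_b <- at$count_b / f
  attr(out, "size_factors") <- sf
  out
}

#' Test allele-specific expression for one hybrid
#'
#' Fits, per gene, a quasi-binomial GLM of the allele-B count out of the
#' total on the 7 sample types and tests the basal contrast (RNA 0 h vs
#' DNA) and each plastic contrast (RNA t vs RNA 0 h). P-values are
#' BH-corrected across genes separately per contrast; `basal_cis` uses
#' `alpha_basal`, the plastic flags use `alpha_plastic`.
#'
#' @param at an [allele_count_table()] (both hybrids may be present).
#' @param hybrid which hybrid to test.
#' @param alpha_basal FDR threshold for basal allele-specific expression.
#' @param alpha_plastic FDR threshold for plastic shifts of the allelic
#'   ratio.
#' @param min_mean_count genes with a lower mean total are excluded.
#' @param min_replicates minimum replicates per sample type.
#' @return data frame, one row per gene x contrast: `log2_ratio` (basal:
#'   RNA 0 h allelic log2 ratio minus the DNA log2 ratio; plastic: allelic
#'   log2 ratio at t minus at 0 h), `se`, `stat`, `df`, `p`, `q`,
#'   `significant`, plus an `excluded` attribute listing genes that could
#'   not be tested and why.
#' @export
test_ase <- function(at, hybrid, alpha_basal = 0.05, alpha_plastic = 0.1,
                     min_mean_count = 10, min_replicates = 2) {
  d <- at[at$hybrid == hybrid, , drop = FALSE]
  if (nrow(d) == 0) stop(sprintf("no samples for hybrid '%s'", hybrid))
  d$type <- ifelse(d$material == "DNA", "DNA",
                   sprintf("RNA_%g", d$timepoint_h))
  tps <- sort(unique(d$timepoint_h[d$material == "RNA"]))
  types <- c("DNA", sprintf("RNA_%g", tps))
  d$type <- factor(d$type, levels = types)
  if (!"DNA" %in% d$material) stop("DNA control samples are required")
  nrep <- table(unique(d[, c("sample_id", "type")])$type)
  if (any(nrep < min_replicates))
    stop("need >= ", min_replicates, " replicates per sample type")

  by_gene <- split(d, d$gene_id)
  genes <- names(by_gene)
  res <- vector("list", length(genes))
  excluded <- character(0); reasons <- character(0)
  ln2 <- log(2)
  contr_names <- c("basal", sprintf("plastic_%g", tps[tps > 0]))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    dg <- by_gene[[gi]]
    tot <- dg$count_a + dg$count_b
    type_tot <- tapply(tot, dg$type, sum)
    if (mean(tot) < min_mean_count) {
      excluded <- c(excluded, g); reasons <- c(reasons, "low_mean_count")
      next
    }
    if (any(is.na(type_tot)) || any(type_tot == 0)) {
      excluded <- c(excluded, g)
      reasons <- c(reasons, "zero_total_in_sample_type")
      next
    }
    fit <- suppressWarnings(
      stats::glm(cbind(count_b, count_a) ~ 0 + type,
                 family = stats::quasibinomial(), data = dg))
    beta <- stats::coef(fit)
    names(beta) <- sub("^type", "", names(beta))
    sm <- summary(fit)
    disp <- max(1, sm$dispersion)
    V <- sm$cov.unscaled * disp
    rownames(V) <- colnames(V) <- names(beta)
    rdf <- fit$df.residual
    one <- function(contrast, a, b) {
      est <- beta[a] - beta[b]
      se <- sqrt(V[a, a] + V[b, b] - 2 * V[a, b])
      stat <- est / se
      data.frame(gene_id = g, hybrid = hybrid, contrast = contrast,
                 timepoint_h = if (grepl("plastic", contrast))
                   as.numeric(sub("plastic_", "", contrast)) else 0,
                 log2_ratio = as.numeric(est) / ln2,
                 se = as.numeric(se) / ln2, stat = as.numeric(stat),
                 df = rdf, p = 2 * stats::pt(-abs(as.numeric(stat)), rdf),
                 stringsAsFactors = FALSE)
    }
    rows <- list(one("basal", "RNA_0", "DNA"))
    for (t in tps[tps > 0])
      rows <- c(rows, list(one(sprintf("plastic_%g", t),
                               sprintf("RNA_%g", t), "RNA_0")))
    res[[gi]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    stop("no testable genes for hybrid '", hybrid, "'")
  out$q <- NA_real_
  for (cn in contr_names) {
    i <- out$contrast == cn
    out$q[i] <- bh_adjust(out$p[i])
  }
  out$significant <- ifelse(out$contrast == "basal",
                            !is.na(out$q) & out$q <= alpha_basal,
                            !is.na(out$q) & out$q <= alpha_plastic)
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(gene_id = excluded, reason = reasons,
                                      stringsAsFactors = FALSE)
  out
}
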