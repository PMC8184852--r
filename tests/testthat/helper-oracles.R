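# Independent oracle implementations used to cross-check the package.
# Deliberately written from first principles, not by calling package code.

# Tajima's D computed straight from the 1989 definitions, with pi obtained
# by explicit pairwise haplotype comparison.
oracle_tajimas_d <- function(hap) {
  n <- nrow(hap)
  seg <- apply(hap, 2, function(col) {
    s <- sum(col)
    s > 0 && s < n
  })
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  diffs <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) diffs <- diffs + sum(hap[i, ] != hap[j, ])
  }
  pi <- diffs / (n * (n - 1) / 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_pairwise_pi <- function(hap) {
  n <- nrow(hap)
  diffs <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) diffs <- diffs + sum(hap[i, ] != hap[j, ])
  }
  diffs / (n * (n - 1) / 2)
}

# Textbook r x c chi-squared homogeneity statistic from margins.
oracle_chisq <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# Median-of-ratios size factors, brute force.
oracle_size_factors <- function(counts) {
  allpos <- apply(counts, 1, function(r) all(r > 0))
  ref <- apply(counts[allpos, , drop = FALSE], 1,
               function(r) exp(mean(log(r))))
  vapply(seq_len(ncol(counts)),
         function(j) median(counts[allpos, j] / ref), numeric(1))
}

# All-null simulation configuration shared by calibration tests.
null_sim_config <- function(n_genes, seed, plastic_none_fraction = 0, ...) {
  mp <- c(none = 1, `Only-Ortho` = 0, `Only-Para` = 0, `Only-Mag` = 0,
          `Only-Mit` = 0, `Ortho-Mag` = 0, `Ortho-Mit` = 0,
          `Para-Mag` = 0, `Para-Mit` = 0)
  sim_config(n_genes = n_genes, mode_proportions = mp,
             plastic_none_fraction = plastic_none_fraction, seed = seed, ...)
}

# Minimal allele-count table builder for ASE unit tests: one gene, given
# per-sample-type (a, b) count pairs replicated `reps` times.
toy_allele_table <- function(ab_by_type, reps = 4, hybrid = "hybrid1",
                             gene = "g1") {
  rows <- list()
  for (tp in names(ab_by_type)) {
    mat <- if (tp == "DNA") "DNA" else "RNA"
    th <- if (tp == "DNA") 0 else as.numeric(sub("RNA_", "", tp))
    for (r in seq_len(reps)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gene, sample_id = sprintf("%s_%s_r%d", hybrid, tp, r),
        hybrid = hybrid, material = mat, timepoint_h = th,
        count_a = ab_by_type[[tp]][1], count_b = ab_by_type[[tp]][2],
        stringsAsFactors = FALSE)
    }
  }
  allele_count_table(do.call(rbind, rows))
}
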