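test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(bb_overdispersion = 1), "bb_overdispersion")
  expect_error(sim_config(mode_proportions = c(none = 0.5)),
               "mode_proportions")
  expect_error(sim_config(timepoints_h = c(1.5, 0, 3)), "timepoints_h")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
})

test_that("same seed gives identical outputs, and substreams are stable", {
  s1 <- simulate_experiment(sim_config(n_genes = 40, seed = 9))
  s2 <- simulate_experiment(sim_config(n_genes = 40, seed = 9))
  expect_identical(s1, s2)
  # growing the gene set must not reshuffle earlier genes
  s3 <- simulate_experiment(sim_config(n_genes = 60, seed = 9))
  expect_identical(s1$truth, s3$truth[1:40, ])
  expect_identical(s1$expression$counts,
                   s3$expression$counts[1:40, colnames(s1$expression$counts)])
})

test_that("null configuration centres the allelic ratio on 0.5 and the
           parental contrast on zero", {
  cfg <- null_sim_config(400, seed = 21, mapping_bias_sd = 0,
                         plast_log2 = 0)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$planted_mode == "none"))
  at <- sim$alleles
  frac <- sum(at$count_b) / sum(at$count_a + at$count_b)
  expect_lt(abs(frac - 0.5), 0.01)
  em <- sim$expression
  d1 <- em$samples$genotype == "derived1"
  og <- em$samples$genotype == "outgroup"
  lfc <- log2(mean(em$counts[, em$samples$sample_id[d1]]) /
                mean(em$counts[, em$samples$sample_id[og]]))
  expect_lt(abs(lfc), 0.05)
})

test_that("planted cis basal effects surface in the allele fraction at the
           expected beta-binomial mean", {
  cfg <- sim_config(n_genes = 2000, effect_log2 = 1.5, mean_depth = 200,
                    mapping_bias_sd = 0, seed = 14)
  sim <- simulate_experiment(cfg)
  tr <- sim$truth
  at <- sim$alleles
  rna0 <- at$material == "RNA" & at$timepoint_h == 0
  expected <- 2^1.5 / (1 + 2^1.5)
  for (h in 1:2) {
    eff <- tr$gene_id[tr[[paste0("cis_basal_d", h)]] == 1.5]
    sel <- rna0 & at$hybrid == paste0("hybrid", h) & at$gene_id %in% eff
    frac <- sum(at$count_b[sel]) / sum(at$count_a[sel] + at$count_b[sel])
    expect_lt(abs(frac - expected), 0.02)
  }
})

test_that("allele totals are conserved into the hybrid expression counts", {
  sim <- simulate_experiment(sim_config(n_genes = 30, seed = 5))
  at <- sim$alleles
  rna <- at[at$material == "RNA", ]
  tot <- tapply(rna$count_a + rna$count_b,
                list(rna$gene_id, rna$sample_id), sum)
  expect_true(all(sim$expression$counts[rownames(tot), colnames(tot)] ==
                    tot))
})

test_that("population simulator respects theta and is deterministic", {
  expect_error(simulate_population(16, 100, 0), "theta")
  expect_error(simulate_population(3, 100, 0.01), "n_haplotypes")
  p0 <- simulate_population(16, 5000, 1e-12, seed = 1)
  expect_equal(ncol(p0$haplotypes), 0)
  p1 <- simulate_population(16, 5000, 0.005, seed = 2)
  p2 <- simulate_population(16, 5000, 0.005, seed = 2)
  expect_identical(p1, p2)
  # segregating-site count near theta * a1 * L
  a1 <- sum(1 / (1:15))
  expect_lt(abs(ncol(p1$haplotypes) - 0.005 * a1 * 5000),
            4 * sqrt(0.005 * a1 * 5000))
  expect_true(all(colSums(p1$haplotypes) >= 1 &
                    colSums(p1$haplotypes) <= 15))
})

test_that("codon-pair simulator plants divergence of the requested kind", {
  p0 <- simulate_codon_pair(100, 0, 0, seed = 3)
  expect_identical(p0$seq1, p0$seq2)
  ps <- simulate_codon_pair(2000, 0, 0.1, seed = 4)
  kk <- kaks_pair(ps$seq1, ps$seq2)
  expect_equal(kk$ka, 0)
  expect_gt(kk$ks, 0)
  expect_error(simulate_codon_pair(100, 0.6, 0.1, seed = 1), "ka")
  expect_error(simulate_codon_pair(10, 0.1, 0.1, seed = 1), "n_codons")
  # no stop codons introduced
  stops <- c("taa", "tag", "tga")
  p <- simulate_codon_pair(500, 0.2, 0.2, seed = 6)
  codons2 <- substring(p$seq2, seq(1, nchar(p$seq2), 3),
                       seq(3, nchar(p$seq2), 3))
  expect_false(any(codons2 %in% stops))
})

test_that("permuting replicate labels leaves the fitted model unchanged", {
  sim <- simulate_experiment(null_sim_config(60, seed = 31))
  em <- sim$expression
  # swap replicate labels within every cell: the fit only sees cell
  # membership, so every statistic must be identical
  perm <- em
  key <- interaction(perm$samples$genotype, perm$samples$timepoint_h)
  new_order <- unlist(lapply(split(seq_len(nrow(perm$samples)), key),
                             function(i) rev(i)), use.names = FALSE)
  perm$samples$replicate <- perm$samples$replicate[new_order]
  f1 <- fit_nested_model(em)
  f2 <- fit_nested_model(perm)
  expect_equal(f1$log_rate, f2$log_rate)
  expect_equal(f1$dispersion, f2$dispersion)
})
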