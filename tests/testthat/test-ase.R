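test_that("SNP filters implement the distance, density and coverage
           rules", {
  snps <- data.frame(
    gene_id = "g1",
    snp_id = paste0("s", 1:4),
    position = c(100, 500, 900, 1300),
    distance_to_intron_bp = c(30, 51, 200, 200),
    dna_coverage = c(20, 20, 4, 5))
  f <- filter_snps(snps)
  expect_equal(f$retained$snp_id, c("s2", "s4"))
  expect_equal(f$removed$reason[f$removed$snp_id == "s1"], "near_intron")
  expect_equal(f$removed$reason[f$removed$snp_id == "s3"],
               "low_dna_coverage")

  # 11 SNPs inside one 200-bp window: all 11 removed; a distant SNP stays
  dense <- data.frame(
    gene_id = "g2", snp_id = paste0("d", 1:12),
    position = c(seq(1000, 1100, by = 10), 5000),
    distance_to_intron_bp = 300, dna_coverage = 30)
  f2 <- filter_snps(dense)
  expect_equal(f2$retained$snp_id, "d12")
  expect_true(all(f2$removed$reason == "snp_dense_region"))

  # exactly 10 SNPs in the window are tolerated
  ok10 <- dense[c(1:10, 12), ]
  expect_equal(nrow(filter_snps(ok10)$retained), 11)

  expect_error(filter_snps(snps[, -3]), "missing columns")
})

test_that("gene aggregation uses the median SNP ratio and conserves
           totals", {
  one <- data.frame(gene_id = "g1", snp_id = "s1", sample_id = "a",
                    count_a = 30, count_b = 70)
  r1 <- aggregate_gene_alleles(one)
  expect_equal(r1$counts$count_a, 30)
  expect_equal(r1$counts$count_b, 70)

  three <- data.frame(gene_id = "g1", snp_id = paste0("s", 1:3),
                      sample_id = "a",
                      count_a = c(80, 50, 10), count_b = c(20, 50, 90))
  r3 <- aggregate_gene_alleles(three)
  expect_equal(r3$counts$count_b, 150)  # median fraction 0.5 of total 300
  expect_equal(r3$counts$count_a + r3$counts$count_b, 300)

  zero <- data.frame(gene_id = "g1", snp_id = "s1", sample_id = "a",
                     count_a = 0, count_b = 0)
  rz <- aggregate_gene_alleles(zero)
  expect_equal(rz$dropped$gene_id, "g1")

  low <- data.frame(gene_id = "g1", snp_id = "s1",
                    sample_id = c("a", "b"),
                    count_a = c(5, 5), count_b = c(4, 4))
  expect_equal(aggregate_gene_alleles(low)$dropped$reason,
               "mean_count_below_cutoff")
})

test_that("allele normalization matches brute force and preserves
           fractions", {
  sim <- simulate_experiment(sim_config(n_genes = 30, seed = 19))
  at <- sim$alleles
  nn <- normalize_alleles(at)
  tot <- tapply(at$count_a + at$count_b, at$sample_id, sum)
  sf <- tot / median(tot)
  expect_equal(attr(nn, "size_factors"), sf)
  # equal totals -> factors 1; tripled sample -> factor 3
  eq <- data.frame(sample_id = rep(c("x", "y"), each = 2),
                   count_a = c(10, 20, 15, 15), count_b = c(20, 10, 10, 20))
  expect_true(all(attr(normalize_alleles(eq), "size_factors") == 1))
  tri <- data.frame(sample_id = rep(c("x", "y"), each = 2),
                    count_a = c(10, 20, 30, 60), count_b = c(20, 10, 60, 30))
  expect_equal(unname(attr(normalize_alleles(tri), "size_factors")["y"]),
               1.5)
  # allele fractions untouched
  f0 <- at$count_b / (at$count_a + at$count_b)
  f1 <- nn$count_b / (nn$count_a + nn$count_b)
  expect_equal(f0, f1)
})

test_that("quasi-binomial ASE test matches a direct glm fit", {
  at <- toy_allele_table(list(DNA = c(100, 100), RNA_0 = c(60, 140),
                              RNA_1.5 = c(60, 140), RNA_3 = c(70, 130),
                              RNA_6 = c(80, 120), RNA_12 = c(65, 135),
                              RNA_24 = c(60, 140)))
  res <- test_ase(at, "hybrid1")
  basal <- res[res$contrast == "basal", ]
  # independent route: glm with quasibinomial family and explicit contrast
  d <- at
  d$type <- factor(ifelse(d$material == "DNA", "DNA",
                          sprintf("RNA_%g", d$timepoint_h)))
  fit <- glm(cbind(count_b, count_a) ~ 0 + type, quasibinomial(), data = d)
  sm <- summary(fit)
  est <- (coef(fit)["typeRNA_0"] - coef(fit)["typeDNA"]) / log(2)
  expect_equal(basal$log2_ratio, unname(est), tolerance = 1e-9)
  disp <- max(1, sm$dispersion)
  se <- sqrt(disp * (sm$cov.unscaled["typeRNA_0", "typeRNA_0"] +
                       sm$cov.unscaled["typeDNA", "typeDNA"])) / log(2)
  expect_equal(basal$se, unname(se), tolerance = 1e-9)
  expect_equal(basal$df, fit$df.residual)
})

test_that("ASE calls require departure from the DNA baseline", {
  # both RNA and DNA at 50:50 -> no ASE
  null <- toy_allele_table(list(DNA = c(100, 100), RNA_0 = c(100, 100),
                                RNA_1.5 = c(100, 100), RNA_3 = c(100, 100),
                                RNA_6 = c(100, 100), RNA_12 = c(100, 100),
                                RNA_24 = c(100, 100)))
  r <- test_ase(null, "hybrid1")
  expect_false(any(r$significant))

  # DNA 50:50 but RNA 0 h at 150:50: clear basal ASE
  ase <- toy_allele_table(list(DNA = c(100, 100), RNA_0 = c(50, 150),
                               RNA_1.5 = c(50, 150), RNA_3 = c(50, 150),
                               RNA_6 = c(50, 150), RNA_12 = c(50, 150),
                               RNA_24 = c(50, 150)))
  r2 <- test_ase(ase, "hybrid1")
  b2 <- r2[r2$contrast == "basal", ]
  expect_true(b2$significant)
  expect_lt(b2$q, 1e-4)

  # matched mapping bias in DNA and RNA (60:40 everywhere) is absorbed
  bias <- toy_allele_table(list(DNA = c(80, 120), RNA_0 = c(80, 120),
                                RNA_1.5 = c(80, 120), RNA_3 = c(80, 120),
                                RNA_6 = c(80, 120), RNA_12 = c(80, 120),
                                RNA_24 = c(80, 120)))
  r3 <- test_ase(bias, "hybrid1")
  expect_false(any(r3$significant))

  # delta_0 is zero by construction (no plastic_0 contrast emitted)
  expect_false("plastic_0" %in% r2$contrast)
})

test_that("genes that cannot be tested are excluded with a reason", {
  bad <- toy_allele_table(list(DNA = c(0, 0), RNA_0 = c(100, 100),
                               RNA_1.5 = c(100, 100), RNA_3 = c(100, 100),
                               RNA_6 = c(100, 100), RNA_12 = c(100, 100),
                               RNA_24 = c(100, 100)))
  good <- toy_allele_table(list(DNA = c(100, 100), RNA_0 = c(100, 100),
                                RNA_1.5 = c(100, 100), RNA_3 = c(100, 100),
                                RNA_6 = c(100, 100), RNA_12 = c(100, 100),
                                RNA_24 = c(100, 100)), gene = "g2")
  both <- allele_count_table(rbind(as.data.frame(bad), as.data.frame(good)))
  r <- test_ase(both, "hybrid1")
  exc <- attr(r, "excluded")
  expect_equal(exc$gene_id, "g1")
  expect_equal(exc$reason, "zero_total_in_sample_type")
  expect_true(all(r$gene_id == "g2"))
})
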