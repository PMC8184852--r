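test_that("folded SFS bins by minor-allele count", {
  expect_equal(fold_sfs(3, 4), c(1, 0))   # count 3 of 4 folds to class 1
  expect_equal(fold_sfs(2, 4), c(0, 1))
  expect_equal(fold_sfs(c(0, 4), 4), c(0, 0))  # monomorphic excluded
  set.seed(3)
  n <- 16
  ac <- sample(0:n, 500, replace = TRUE)
  brute <- tabulate(pmin(ac, n - ac)[ac > 0 & ac < n], nbins = n / 2)
  expect_equal(fold_sfs(ac, n), brute)
})

test_that("pi from allele counts equals pi from explicit pairwise
           comparison", {
  # two haplotypes differing at 3 sites: pi = 3
  hap2 <- rbind(c(1, 1, 1, 0), c(0, 0, 0, 0))
  expect_equal(pi_diversity(colSums(hap2), 2), 3)
  set.seed(5)
  for (i in 1:5) {
    p <- simulate_population(12, 3000, 0.004, seed = i)
    ac <- colSums(p$haplotypes)
    expect_equal(pi_diversity(ac, 12), oracle_pairwise_pi(p$haplotypes),
                 tolerance = 1e-9)
  }
})

test_that("Tajima's D matches an independent implementation to 1e-10", {
  # D = 0 exactly when pi equals Watterson's theta: n=4, S=11, pi=6
  expect_equal(tajimas_d(11, 6, 4), 0)
  expect_true(is.na(tajimas_d(0, 0, 10)))
  set.seed(9)
  for (i in 1:100) {
    n <- sample(c(8, 12, 16, 20), 1)
    hap <- matrix(rbinom(n * 200, 1, runif(1, 0.02, 0.3)), nrow = n)
    ac <- colSums(hap)
    seg <- ac > 0 & ac < n
    d_pkg <- tajimas_d(sum(seg), pi_diversity(ac, n), n)
    d_oracle <- oracle_tajimas_d(hap)
    expect_equal(d_pkg, d_oracle, tolerance = 1e-10)
  }
})

test_that("neutral simulations centre Tajima's D on zero", {
  ds <- vapply(1:50, function(i) {
    p <- simulate_population(16, 1e4, 0.005, seed = 1000 + i)
    ac <- colSums(p$haplotypes)
    tajimas_d(length(ac), pi_diversity(ac, 16), 16)
  }, numeric(1))
  expect_lt(abs(mean(ds)), 0.15)
})

test_that("Ka/Ks estimates are consistent with the generating rates", {
  p0 <- simulate_codon_pair(200, 0, 0, seed = 1)
  kk0 <- kaks_pair(p0$seq1, p0$seq2)
  expect_equal(kk0$ka, 0)
  expect_equal(kk0$ks, 0)
  # a single fourfold synonymous change on a diverse background:
  # Ka stays 0, Ks > 0
  s1 <- p0$seq1
  codons <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  i4 <- which(substr(codons, 1, 2) == "gg")[1]     # Gly: fourfold third pos
  s2 <- s1
  pos <- (i4 - 1) * 3 + 3
  old <- substr(s2, pos, pos)
  substr(s2, pos, pos) <- setdiff(c("a", "c", "g", "t"), old)[1]
  kk1 <- kaks_pair(s1, s2)
  expect_equal(kk1$ka, 0)
  expect_gt(kk1$ks, 0)
  # simulation consistency at (0.05, 0.10) over seeds
  kk <- vapply(1:8, function(i) {
    p <- simulate_codon_pair(3000, 0.05, 0.10, seed = i)
    r <- kaks_pair(p$seq1, p$seq2)
    c(r$ka, r$ks)
  }, numeric(2))
  expect_lt(abs(mean(kk[1, ]) / 0.05 - 1), 0.2)
  expect_lt(abs(mean(kk[2, ]) / 0.10 - 1), 0.2)
})

test_that("population filter applies the quality rules in order and
           equalizes allele numbers", {
  sites <- data.frame(
    chrom = "c1", pos = c(1, 2, 3, 4, 5, 6),
    ref = c("A", "AT", "C", "G", "T", "A"),
    alt = c("T", "A", "G,T", "A", "C", "G"),
    qual = c(90, 90, 90, 10, 90, 90),
    is_indel = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_multiallelic = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    class = "synonymous", gene = "g1", stringsAsFactors = FALSE)
  gt <- matrix(1L, 6, 10)
  gt[5, 1:9] <- NA  # 90% missing
  pd <- structure(list(sites = sites, gt = gt,
                       gq = matrix(99, 6, 10), dp = matrix(30, 6, 10)),
                  class = "population_data")
  f <- filter_population(pd, seed = 1)
  expect_equal(f$pos, c(1, 6))
  rem <- attr(f, "removed")
  expect_setequal(rem$reason[rem$pos %in% c(2, 3, 4, 5)],
                  c("indel", "multiallelic", "low_site_quality",
                    "excess_missing"))
  # complete data: down-sampling is the identity at target 2N
  expect_equal(f$an, c(20L, 20L))
  expect_equal(f$ac, f$ac_raw)
  # genotype-level masking can push a site over the missing threshold
  pd2 <- pd
  pd2$gq <- matrix(99, 6, 10)
  pd2$gq[1, 1:9] <- 5
  f2 <- filter_population(pd2, seed = 1)
  expect_false(1 %in% f2$pos)
})

test_that("allele down-sampling preserves expected frequencies", {
  set.seed(6)
  n_sites <- 5000
  ac <- rbinom(n_sites, 20, 0.3)
  sites <- data.frame(chrom = "c1", pos = seq_len(n_sites), ref = "A",
                      alt = "T", qual = 90, is_indel = FALSE,
                      is_multiallelic = FALSE, class = "synonymous",
                      gene = "g1", stringsAsFactors = FALSE)
  gt <- t(vapply(ac, function(k) {
    g <- c(rep(1L, k), rep(0L, 20 - k))[sample.int(20)]
    g[seq(1, 20, 2)] + g[seq(2, 20, 2)]
  }, integer(10)))
  gt[1, 1] <- NA  # one masked genotype sets the target to 18 alleles
  pd <- structure(list(sites = sites, gt = gt,
                       gq = matrix(99, n_sites, 10),
                       dp = matrix(30, n_sites, 10)),
                  class = "population_data")
  f <- filter_population(pd, seed = 4)
  expect_true(all(f$an == 18L))
  expect_lt(abs(mean(f$ac / f$an) - mean(ac / 20)), 0.01)
})

test_that("per-gene popgen statistics flag undefined quantities", {
  filt <- data.frame(
    chrom = "c1", pos = 1:6, class = c(rep("synonymous", 3),
                                       rep("nonsynonymous", 3)),
    gene = "g1", ac = c(2, 5, 0, 0, 0, 0), an = 10,
    stringsAsFactors = FALSE)
  st <- popgen_gene_stats(filt)
  expect_equal(st$S_syn, 2)
  expect_equal(st$S_non, 0)
  expect_true(is.na(st$D_non))   # no nonsynonymous segregating sites
  expect_false(is.na(st$D_syn))
  expect_true(is.na(st$pn_ps) || st$pn_ps == 0)
  expect_equal(st$pi_n, 0)
})

test_that("bootstrap comparison is calibrated, detects separation, and is
           reproducible", {
  set.seed(12)
  x <- rnorm(100)
  same <- bootstrap_compare(list(a = x, b = x + rnorm(100, 0, 1e-8)),
                            B = 500, seed = 3)
  expect_gt(same$p_matrix["a", "b"], 0.5)
  far <- bootstrap_compare(list(a = rnorm(100), b = rnorm(100, 5)),
                           B = 1000, seed = 3)
  expect_equal(far$p_matrix["a", "b"], 2 / 1000)
  # determinism given the same inputs and seed
  g <- list(a = rnorm(50), b = rnorm(50, 1))
  r1 <- bootstrap_compare(g, B = 400, seed = 9)
  r2 <- bootstrap_compare(g, B = 400, seed = 9)
  expect_identical(r1, r2)
  expect_warning(bootstrap_compare(list(a = rnorm(10), b = rnorm(50)),
                                   B = 100, seed = 1), "high bootstrap")
})

test_that("the interspecific D index follows its closed form", {
  expect_equal(d_index(0.5, 0.5), 1)
  expect_equal(d_index(0.5, -0.5), 2.5 / 1.5)
  expect_equal(suppressWarnings(d_index(-2, 0)), 0)
  expect_warning(d_index(-2.1, 0), "not interpretable")
})
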