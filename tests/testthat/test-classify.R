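mk_plast <- function(genes, slope, q) {
  data.frame(gene_id = genes, species = "outgroup", timepoint_h = 6,
             log2_slope = slope, se = 0.1, p = q, q = q,
             direction = ifelse(q <= 0.05, ifelse(slope > 0, "up", "down"),
                                "none"),
             stringsAsFactors = FALSE)
}
mk_basal <- function(genes, b, q) {
  data.frame(gene_id = genes, derived = "derived1", outgroup = "outgroup",
             log2_basal = b, se = 0.1, p = q, q = q,
             significant = q <= 0.05, stringsAsFactors = FALSE)
}
mk_delta <- function(genes, d, q) {
  data.frame(gene_id = genes, derived = "derived1", outgroup = "outgroup",
             timepoint_h = 6, log2_delta = d, se = 0.1, p = q, q = q,
             significant = q <= 0.1, stringsAsFactors = FALSE)
}

test_that("basal classification follows the outgroup's plastic
           direction", {
  g <- c("a", "b", "c", "d")
  pl <- mk_plast(g, c(2, -2, 2, 2), c(0.01, 0.01, 0.01, 0.01))
  ba <- mk_basal(g, c(1, 1, -1, 1), c(0.01, 0.01, 0.01, 0.2))
  expect_equal(classify_basal(ba, pl),
               c("ortho", "para", "para", "none"))
  # outgroup not significantly plastic -> none
  pl2 <- mk_plast(g, c(2, 2, 2, 2), c(0.5, 0.5, 0.5, 0.5))
  expect_equal(classify_basal(ba, pl2), rep("none", 4))
})

test_that("plastic classification covers magnification, mitigation and
           reversal for both directions", {
  g <- c("up_mag", "down_mag", "up_rev", "none")
  pl <- mk_plast(g, c(1, -2, 1, 1), rep(0.01, 4))
  # derived slopes: 2 (delta +1), -3 (delta -1), -0.5 (delta -1.5), ns
  de <- mk_delta(g, c(1, -1, -1.5, 0.3), c(0.05, 0.05, 0.05, 0.5))
  expect_equal(classify_plastic(de, pl),
               c("magnified", "magnified", "mitigated", "none"))
})

test_that("cis/trans assignment distinguishes the four evidence
           patterns", {
  out <- assign_cis_trans(par_est = c(1, 1, 0.2, 1, 0),
                          par_q = c(0.01, 0.01, 0.3, 0.01, 0.9),
                          ase_est = c(0.8, 0.1, 0.9, -0.8, 0),
                          ase_q = c(0.01, 0.5, 0.01, 0.01, 0.9),
                          alpha_par = 0.05, alpha_ase = 0.05)
  expect_equal(out, c("cis", "trans_only", "excluded_ase_only",
                      "excluded_discordant", "none"))
})

test_that("modes are the cross product of the two layers", {
  expect_equal(as.character(assign_mode("ortho", "mitigated")), "Ortho-Mit")
  expect_equal(as.character(assign_mode("para", "magnified")), "Para-Mag")
  expect_equal(as.character(assign_mode("none", "none")), "none")
  expect_equal(as.character(assign_mode("none", "magnified")), "Only-Mag")
  expect_equal(as.character(assign_mode("para", "none")), "Only-Para")
  # partition property: every combination yields exactly one defined label
  for (b in c("ortho", "para", "none")) {
    for (p in c("magnified", "mitigated", "none")) {
      md <- assign_mode(b, p)
      expect_false(is.na(md))
      expect_true(as.character(md) %in% MODE_LABELS)
    }
  }
})

test_that("relabelling the outgroup direction flips ortho and para
           consistently", {
  set.seed(41)
  g <- sprintf("g%02d", 1:50)
  pl <- mk_plast(g, rnorm(50), runif(50, 0, 0.04))
  ba <- mk_basal(g, rnorm(50), runif(50, 0, 0.04))
  cls <- classify_basal(ba, pl)
  flipped <- pl
  flipped$log2_slope <- -flipped$log2_slope
  cls2 <- classify_basal(ba, flipped)
  expect_equal(cls2[cls == "ortho"],
               rep("para", sum(cls == "ortho")))
  expect_equal(cls2[cls == "para"],
               rep("ortho", sum(cls == "para")))
})

test_that("quadrant test reproduces the closed form and a textbook
           oracle", {
  qt <- quadrant_test(2986, 4634)
  expect_equal(qt$statistic, (2 * 2986 - 4634)^2 / 4634, tolerance = 1e-10)
  expect_equal(qt$df, 1)
  qt2 <- quadrant_test(1975, 3263)
  expect_equal(qt2$statistic, (2 * 1975 - 3263)^2 / 3263, tolerance = 1e-10)
  # balanced counts give statistic 0, p 1
  qt0 <- quadrant_test(50, 100)
  expect_equal(qt0$statistic, 0)
  expect_equal(qt0$p, 1)
  # random draws against the closed form
  set.seed(7)
  for (i in 1:100) {
    n <- sample(10:5000, 1)
    k <- sample(0:n, 1)
    expect_equal(quadrant_test(k, n)$statistic, (2 * k - n)^2 / n,
                 tolerance = 1e-9)
  }
  # 2x2 independence variant
  tb <- matrix(c(30, 10, 20, 40), 2)
  qi <- quadrant_test(method = "independence", table = tb)
  expect_equal(qi$statistic, oracle_chisq(tb), tolerance = 1e-9)
})

test_that("odds ratios and percentages round as reported", {
  expect_equal(round(odds_ratio(730, 1112), 2), 1.91)
  expect_equal(round(odds_ratio(776, 1243), 2), 1.66)
  expect_equal(odds_ratio(50, 100), 1)
  expect_equal(pct(1975, 3263), 60.5)
  expect_equal(pct(2986, 4634), 64.4)
  expect_equal(pct(776, 1243), 62.4)
  expect_equal(pct(730, 1112), 65.6)
  expect_equal(pct(0, 10), 0)
})

test_that("every gene receives exactly one mode and one cis status per
           layer", {
  b <- run_pipeline(run_config(sim = sim_config(n_genes = 150, seed = 55),
                               seed = 55))
  for (cl in b$classification) {
    expect_false(any(is.na(cl$mode)))
    expect_true(all(as.character(cl$mode) %in% MODE_LABELS))
    expect_true(all(cl$cis_status_basal %in%
                      c("cis", "trans_only", "excluded_ase_only",
                        "excluded_discordant", "none")))
    # mode is none iff both layers are none
    expect_equal(as.character(cl$mode) == "none",
                 cl$basal_class == "none" & cl$plastic_class == "none")
  }
})
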