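#' Modes of expression-plasticity evolution
#'
#' The nine labels used throughout the package: no change, a basal change
#' alone (orthoplastic or paraplastic), a plastic-slope change alone
#' (magnified or mitigated), or one of the four combinations.
#' @export
MODE_LABELS <- c("none",
                 "Only-Ortho", "Only-Para", "Only-Mag", "Only-Mit",
                 "Ortho-Mag", "Ortho-Mit", "Para-Mag", "Para-Mit")

#' Simulation configuration
#'
#' Defines the synthetic study: three parental species (an outgroup and two
#' derived sister lineages), two F1 hybrids of the derived lineages with the
#' outgroup, a dehydration-style stress time course of six timepoints
#' replicated four times, and planted regulatory differences with known mode,
#' cis/trans architecture and lineage of origin.
#'
#' @param n_genes number of genes to simulate.
#' @param timepoints_h ordered vector of sampling times in hours.
#' @param n_replicates independent trials per genotype and timepoint.
#' @param mean_depth expected read count per gene and sample at baseline.
#' @param depth_sdlog log-scale SD of the per-gene baseline expression level
#'   around `mean_depth` (moderate inter-gene variation).
#' @param nb_dispersion negative-binomial dispersion alpha of the counts,
#'   variance = mu + alpha * mu^2.
#' @param bb_overdispersion beta-binomial intraclass correlation rho in
#'   `[0, 1)` of the hybrid allele split.
#' @param mode_proportions named probability vector over [MODE_LABELS];
#'   must sum to 1. The defaults put about 23% of genes in a basal-change
#'   mode and 15% in a plastic-change mode, the fractions of
#'   differentially expressed and differentially plastic genes observed in
#'   interspecific Arabidopsis stress comparisons at the peak timepoint.
#' @param plastic_none_fraction fraction of mode-`none` genes that are
#'   nonetheless stress-plastic (identically in every species).
#' @param cis_fraction probability that a planted basal (resp. slope)
#'   difference is cis-acting rather than trans-acting; the two layers are
#'   decided independently.
#' @param origin_proportions named probability vector over
#'   `c("derived1", "derived2", "shared")`: in which lineage(s) a planted
#'   difference arose. `shared` plants identical effects in both lineages.
#' @param effect_log2 magnitude (log2) of planted basal and slope effects.
#' @param plast_log2 magnitude (log2) of the outgroup plastic response at the
#'   peak of the stress profile for plastic genes.
#' @param mapping_bias_sd SD of the per-gene, per-hybrid Gaussian shift on
#'   the DNA log-odds (alignment/mapping bias shared by the RNA samples of
#'   that gene, which is what makes the DNA baseline necessary).
#' @param seed master seed; all randomness derives from it through per-gene
#'   substreams.
#' @return a validated `sim_config` object (a list).
#' @export
sim_config <- function(n_genes = 1000,
                       timepoints_h = c(0, 1.5, 3, 6, 12, 24),
                       n_replicates = 4,
                       mean_depth = 200,
                       depth_sdlog = 0.35,
                       nb_dispersion = 0.05,
                       bb_overdispersion = 0.01,
                       mode_proportions = c(none = 0.68,
                                            `Only-Ortho` = 0.085,
                                            `Only-Para` = 0.085,
                                            `Only-Mag` = 0.045,
                                            `Only-Mit` = 0.045,
                                            `Ortho-Mag` = 0.015,
                                            `Ortho-Mit` = 0.015,
                                            `Para-Mag` = 0.015,
                                            `Para-Mit` = 0.015),
                       plastic_none_fraction = 1 / 3,
                       cis_fraction = 0.5,
                       origin_proportions = c(derived1 = 0.4,
                                              derived2 = 0.4,
                                              shared = 0.2),
                       effect_log2 = 1.5,
                       plast_log2 = 1.5,
                       mapping_bias_sd = 0.25,
                       seed = 1) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1 ||
      n_genes != floor(n_genes))
    stop_config("n_genes", "must be a positive integer")
  if (!is.numeric(timepoints_h) || length(timepoints_h) < 2 ||
      is.unsorted(timepoints_h, strictly = TRUE) || timepoints_h[1] != 0)
    stop_config("timepoints_h", "must be strictly increasing and start at 0")
  if (!is.numeric(n_replicates) || n_replicates < 2 ||
      n_replicates != floor(n_replicates))
    stop_config("n_replicates", "must be an integer >= 2")
  if (!is.numeric(mean_depth) || mean_depth <= 0)
    stop_config("mean_depth", "must be strictly positive")
  if (!is.numeric(depth_sdlog) || depth_sdlog < 0)
    stop_config("depth_sdlog", "must be >= 0")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stop_config("nb_dispersion", "must be strictly positive")
  if (!is.numeric(bb_overdispersion) || bb_overdispersion < 0 ||
      bb_overdispersion >= 1)
    stop_config("bb_overdispersion", "must lie in [0, 1)")
  if (length(mode_proportions) != length(MODE_LABELS) ||
      !setequal(names(mode_proportions), MODE_LABELS) ||
      any(mode_proportions < 0) ||
      abs(sum(mode_proportions) - 1) > 1e-9)
    stop_config("mode_proportions",
                "must be a probability vector named by the 9 mode labels summing to 1")
  if (!is.numeric(plastic_none_fraction) || plastic_none_fraction < 0 ||
      plastic_none_fraction > 1)
    stop_config("plastic_none_fraction", "must lie in [0, 1]")
  if (!is.numeric(cis_fraction) || cis_fraction < 0 || cis_fraction > 1)
    stop_config("cis_fraction", "must lie in [0, 1]")
  if (length(origin_proportions) != 3 ||
      !setequal(names(origin_proportions), c("derived1", "derived2", "shared")) ||
      any(origin_proportions < 0) ||
      abs(sum(origin_proportions) - 1) > 1e-9)
    stop_config("origin_proportions",
                "must be a probability vector over derived1/derived2/shared summing to 1")
  if (!is.numeric(effect_log2) || effect_log2 < 0)
    stop_config("effect_log2", "must be >= 0")
  if (!is.numeric(plast_log2) || plast_log2 < 0)
    stop_config("plast_log2", "must be >= 0")
  if (!is.numeric(mapping_bias_sd) || mapping_bias_sd < 0)
    stop_config("mapping_bias_sd", "must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1)
    stop_config("seed", "must be a single number")
  cfg <- list(n_genes = as.integer(n_genes), timepoints_h = timepoints_h,
              n_replicates = as.integer(n_replicates),
              mean_depth = mean_depth, depth_sdlog = depth_sdlog,
              nb_dispersion = nb_dispersion,
              bb_overdispersion = bb_overdispersion,
              mode_proportions = mode_proportions[MODE_LABELS],
              plastic_none_fraction = plastic_none_fraction,
              cis_fraction = cis_fraction,
              origin_proportions = origin_proportions[c("derived1", "derived2", "shared")],
              effect_log2 = effect_log2, plast_log2 = plast_log2,
              mapping_bias_sd = mapping_bias_sd, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

# Temporal weight of the stress response: ramps linearly to its peak at 6 h
# and decays slowly afterwards, mimicking an acute-dehydration profile in
# which the transcriptome response is strongest at intermediate timepoints.
stress_profile <- function(t_h, peak_h = 6, decay = 0.03) {
  w <- pmin(t_h / peak_h, 1)
  late <- t_h > peak_h
  w[late] <- exp(-decay * (t_h[late] - peak_h))
  w
}

rnbinom_mu <- function(n, mu, alpha) {
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

# Beta-binomial draw with intraclass correlation rho; rho = 0 collapses to
# plain binomial.
rbetabinom <- function(size, prob, rho) {
  n <- length(size)
  if (rho < 1e-12) return(stats::rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

#' Simulate a full F1-hybrid stress time-course experiment
#'
#' Generates negative-binomial RNA counts for the three parental genotypes
#' and the two hybrids over the full time course, beta-binomial allelic
#' counts (plus a DNA control) for the hybrids, and a table of planted truth.
#' Planted cis effects appear both in the parental contrast and in the hybrid
#' allelic ratio; trans effects appear only in the parental contrast.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `expression` (an `expression_matrix`),
#'   `alleles` (an `allele_count_table`) and `truth` (a `sim_truth`
#'   data frame, one row per gene).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  tp <- config$timepoints_h
  nt <- length(tp)
  nr <- config$n_replicates
  ng <- config$n_genes
  w <- stress_profile(tp)
  genes <- sprintf("g%05d", seq_len(ng))
  parents <- c("outgroup", "derived1", "derived2")
  hybrids <- c("hybrid1", "hybrid2")

  ## sample sheet ------------------------------------------------------
  rna <- expand.grid(replicate = seq_len(nr), timepoint_h = tp,
                     genotype = c(parents, hybrids),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rna$material <- "RNA"
  dna <- expand.grid(replicate = seq_len(nr), timepoint_h = 0,
                     genotype = hybrids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dna$material <- "DNA"
  sheet <- rbind(rna, dna)
  sheet$sample_id <- sprintf("%s_%s_t%g_r%d", sheet$genotype,
                             sheet$material, sheet$timepoint_h,
                             sheet$replicate)
  sheet <- sheet[, c("sample_id", "genotype", "material", "timepoint_h",
                     "replicate")]

  rna_ids <- sheet$sample_id[sheet$material == "RNA"]
  counts <- matrix(0L, nrow = ng, ncol = length(rna_ids),
                   dimnames = list(genes, rna_ids))
  # allele counts: hybrid RNA and DNA samples
  ha_ids <- sheet$sample_id[sheet$genotype %in% hybrids]
  n_ha <- length(ha_ids)
  count_a <- matrix(0L, ng, n_ha, dimnames = list(genes, ha_ids))
  count_b <- matrix(0L, ng, n_ha, dimnames = list(genes, ha_ids))

  truth <- data.frame(
    gene_id = genes, planted_mode = "none", planted_direction = "none",
    lineage = "none", origin = "none",
    cis_basal_d1 = 0, cis_slope_d1 = 0, trans_basal_d1 = 0, trans_slope_d1 = 0,
    cis_basal_d2 = 0, cis_slope_d2 = 0, trans_basal_d2 = 0, trans_slope_d2 = 0,
    baseline_mu = NA_real_, mapping_bias_h1 = 0, mapping_bias_h2 = 0,
    stringsAsFactors = FALSE)

  mode_p <- config$mode_proportions
  orig_p <- config$origin_proportions
  idx_sheet <- match(ha_ids, sheet$sample_id)
  ha_geno <- sheet$genotype[idx_sheet]
  ha_mat <- sheet$material[idx_sheet]
  ha_tp <- sheet$timepoint_h[idx_sheet]
  ha_w <- ifelse(ha_mat == "DNA", 0, stress_profile(ha_tp))

  for (g in seq_len(ng)) {
    ## gene-level parameters (substream salt 0)
    set.seed(substream_seed(config$seed, g, 0L))
    mu <- config$mean_depth *
      exp(stats::rnorm(1, 0, config$depth_sdlog) - config$depth_sdlog^2 / 2)
    mode <- sample(MODE_LABELS, 1, prob = mode_p)
    bias <- stats::rnorm(2, 0, config$mapping_bias_sd)  # hybrid1, hybrid2

    if (mode == "none") {
      dir <- if (stats::runif(1) < config$plastic_none_fraction)
        sample(c(1, -1), 1) else 0
      lineage <- "none"
      basal_eff <- slope_eff <- c(0, 0)
      basal_cis <- slope_cis <- FALSE
    } else {
      dir <- sample(c(1, -1), 1)
      lineage <- sample(names(orig_p), 1, prob = orig_p)
      has_basal <- grepl("Ortho|Para", mode)
      has_slope <- grepl("Mag|Mit", mode)
      b_sign <- if (!has_basal) 0 else if (grepl("Ortho", mode)) dir else -dir
      s_sign <- if (!has_slope) 0 else if (grepl("Mag", mode)) dir else -dir
      basal <- b_sign * config$effect_log2
      slope <- s_sign * config$effect_log2
      basal_cis <- has_basal && stats::runif(1) < config$cis_fraction
      slope_cis <- has_slope && stats::runif(1) < config$cis_fraction
      in_l <- switch(lineage, derived1 = c(TRUE, FALSE),
                     derived2 = c(FALSE, TRUE), shared = c(TRUE, TRUE))
      basal_eff <- basal * in_l
      slope_eff <- slope * in_l
    }
    cis_basal <- if (basal_cis) basal_eff else c(0, 0)
    cis_slope <- if (slope_cis) slope_eff else c(0, 0)
    trans_basal <- basal_eff - cis_basal
    trans_slope <- slope_eff - cis_slope
    any_cis <- any(cis_basal != 0) || any(cis_slope != 0)

    truth$planted_mode[g] <- mode
    truth$planted_direction[g] <-
      if (dir > 0) "up" else if (dir < 0) "down" else "none"
    truth$lineage[g] <- lineage
    truth$origin[g] <- if (any_cis) lineage else "none"
    truth$cis_basal_d1[g] <- cis_basal[1]; truth$cis_basal_d2[g] <- cis_basal[2]
    truth$cis_slope_d1[g] <- cis_slope[1]; truth$cis_slope_d2[g] <- cis_slope[2]
    truth$trans_basal_d1[g] <- trans_basal[1]
    truth$trans_basal_d2[g] <- trans_basal[2]
    truth$trans_slope_d1[g] <- trans_slope[1]
    truth$trans_slope_d2[g] <- trans_slope[2]
    truth$baseline_mu[g] <- mu
    truth$mapping_bias_h1[g] <- bias[1]
    truth$mapping_bias_h2[g] <- bias[2]

    ## counts (substream salt 1) --------------------------------------
    set.seed(substream_seed(config$seed, g, 1L))
    # parental RNA means per timepoint
    mu_out <- mu * 2^(dir * config$plast_log2 * w)
    mu_d <- lapply(1:2, function(l)
      mu * 2^((basal_eff[l]) +
                (dir * config$plast_log2 + slope_eff[l]) * w))
    for (sp in parents) {
      mus <- switch(sp, outgroup = mu_out, derived1 = mu_d[[1]],
                    derived2 = mu_d[[2]])
      ids <- sprintf("%s_RNA_t%g_r%d", sp, rep(tp, each = nr),
                     rep(seq_len(nr), nt))
      counts[g, ids] <- rnbinom_mu(nt * nr, rep(mus, each = nr),
                                   config$nb_dispersion)
    }
    # hybrid totals: alleles share the hybrid trans environment, so the
    # total follows the outgroup-like plastic profile scaled by the mean
    # allelic contribution of the planted cis effect
    for (h in 1:2) {
      sel <- ha_geno == hybrids[h]
      is_dna <- ha_mat[sel] == "DNA"
      wv <- ha_w[sel]
      cis_shift <- cis_basal[h] + cis_slope[h] * wv
      cis_shift[is_dna] <- 0
      tot_mu <- ifelse(is_dna, mu,
                       mu * 2^(dir * config$plast_log2 * wv) *
                         (1 + 2^cis_shift) / 2)
      tot <- rnbinom_mu(sum(sel), tot_mu, config$nb_dispersion)
      p_b <- inv_logit(bias[h] + log(2) * cis_shift)
      b <- rbetabinom(tot, p_b, config$bb_overdispersion)
      count_b[g, sel] <- b
      count_a[g, sel] <- tot - b
      # the hybrid's expression-matrix entry is the sum of its alleles
      rna_ids <- ha_ids[sel][!is_dna]
      counts[g, rna_ids] <- tot[!is_dna]
    }
  }

  em <- expression_matrix(counts,
                          sheet[sheet$material == "RNA", , drop = FALSE])
  at <- allele_count_table(
    data.frame(gene_id = rep(genes, n_ha),
               sample_id = rep(ha_ids, each = ng),
               hybrid = rep(ha_geno, each = ng),
               material = rep(ha_mat, each = ng),
               timepoint_h = rep(ha_tp, each = ng),
               count_a = as.integer(count_a),
               count_b = as.integer(count_b),
               stringsAsFactors = FALSE))
  class(truth) <- c("sim_truth", "data.frame")
  list(expression = em, alleles = at, truth = truth, samples = sheet)
}

#' Simulate population haplotypes under the neutral frequency spectrum
#'
#' Draws independent segregating sites whose minor/derived allele counts
#' follow the standard neutral site-frequency spectrum, P(i) proportional to
#' 1/i, the regime in which Watterson's theta and pi agree in expectation
#' (Tajima's D centred on 0). Sites are labelled synonymous or nonsynonymous
#' at a supplied ratio.
#'
#' @param n_haplotypes number of sampled haplotypes (>= 4).
#' @param n_sites number of sites in the region.
#' @param theta_per_site population-scaled mutation rate per site; the
#'   per-site probability of segregating is `theta_per_site * a1` where
#'   `a1 = sum(1/(1:(n-1)))`.
#' @param seed integer seed.
#' @param syn_fraction probability that a site is synonymous.
#' @return list with `haplotypes` (0/1 matrix, haplotypes x sites, only
#'   segregating sites), `positions`, and `annotation` data frame with the
#'   site class.
#' @export
simulate_population <- function(n_haplotypes, n_sites, theta_per_site, seed,
                                syn_fraction = 0.3) {
  if (n_haplotypes < 4) stop("n_haplotypes must be >= 4")
  if (!is.numeric(theta_per_site) || theta_per_site <= 0)
    stop("theta_per_site must be strictly positive")
  n <- as.integer(n_haplotypes)
  a1 <- sum(1 / seq_len(n - 1))
  p_seg <- theta_per_site * a1
  if (p_seg >= 1)
    stop("theta_per_site too large for the independent-sites model")
  set.seed(substream_seed(seed, 1L, 7L))
  seg <- which(stats::runif(n_sites) < p_seg)
  k <- length(seg)
  freq_p <- (1 / seq_len(n - 1)) / a1
  hap <- matrix(0L, nrow = n, ncol = k)
  if (k > 0) {
    ac <- sample(seq_len(n - 1), k, replace = TRUE, prob = freq_p)
    for (j in seq_len(k)) hap[sample.int(n, ac[j]), j] <- 1L
  }
  ann <- data.frame(
    position = seg,
    class = ifelse(stats::runif(k) < syn_fraction, "synonymous",
                   "nonsynonymous"),
    stringsAsFactors = FALSE)
  list(haplotypes = hap, positions = seg, annotation = ann,
       n_sites = n_sites)
}

# codon utilities ------------------------------------------------------

CODON_BASES <- c("t", "c", "a", "g")
STOP_CODONS <- c("taa", "tag", "tga")

codon_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

is_transition <- function(b1, b2) {
  (b1 %in% c("a", "g") && b2 %in% c("a", "g")) ||
    (b1 %in% c("c", "t") && b2 %in% c("c", "t"))
}

.codon_cache <- new.env(parent = emptyenv())

# Per-codon lookup: amino acid, and for each position the degeneracy count
# (number of alternative bases preserving the amino acid) plus the candidate
# substitution sets used by the generator (stop-creating changes excluded).
codon_table <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  codons <- apply(expand.grid(CODON_BASES, CODON_BASES, CODON_BASES,
                              stringsAsFactors = FALSE),
                  1, paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  tab <- lapply(codons, function(cd) {
    aa <- codon_translate(cd)
    pos_info <- lapply(1:3, function(pos) {
      base <- substr(cd, pos, pos)
      alt <- setdiff(CODON_BASES, base)
      variants <- vapply(alt, function(b) {
        x <- cd; substr(x, pos, pos) <- b; x
      }, character(1))
      is_stop <- variants %in% STOP_CODONS
      is_syn <- vapply(variants, function(x) codon_translate(x) == aa,
                       logical(1))
      ts <- vapply(alt, function(b) is_transition(base, b), logical(1))
      list(degeneracy = sum(is_syn),
           syn_alt = alt[is_syn & !is_stop],
           nonsyn_alt = alt[!is_syn & !is_stop],
           nonsyn_tv_alt = alt[!is_syn & !is_stop & !ts],
           ok_alt = alt[!is_stop])
    })
    list(aa = aa, pos = pos_info)
  })
  names(tab) <- codons
  .codon_cache$tab <- tab
  tab
}

#' Simulate a pair of aligned coding sequences with known divergence
#'
#' Builds a random stop-free coding sequence and introduces substitutions so
#' that the expected number of synonymous (resp. nonsynonymous) changes per
#' synonymous (resp. nonsynonymous) site, with sites counted by their
#' degeneracy class as in Li (1993), equals `ks` (resp. `ka`). Fourfold sites
#' receive any substitution with probability `ks`; strictly nondegenerate
#' sites receive a nonsynonymous substitution with probability `ka`; twofold
#' sites, counted as 1/3 synonymous and 2/3 nonsynonymous, receive their
#' synonymous transition with probability `ks/3` or a nonsynonymous
#' transversion with probability `2*ka/3`.
#'
#' @param n_codons number of codons (>= 50).
#' @param ka,ks requested per-site divergences, each in `[0, 0.5]`.
#' @param seed integer seed.
#' @return list with `seq1` and `seq2`, lowercase nucleotide strings of
#'   length `3 * n_codons`, and the realized substitution counts.
#' @export
simulate_codon_pair <- function(n_codons, ka, ks, seed) {
  if (n_codons < 50) stop("n_codons must be >= 50")
  if (!is.numeric(ka) || ka < 0 || ka > 0.5) stop("ka must lie in [0, 0.5]")
  if (!is.numeric(ks) || ks < 0 || ks > 0.5) stop("ks must lie in [0, 0.5]")
  tab <- codon_table()
  set.seed(substream_seed(seed, 1L, 11L))
  codons <- sample(names(tab), n_codons, replace = TRUE)
  seq2 <- codons
  n_syn <- 0L; n_non <- 0L
  for (i in seq_len(n_codons)) {
    cd <- codons[i]
    info <- tab[[cd]]
    for (pos in 1:3) {
      pinf <- info$pos[[pos]]
      # apply the change only if the realized codon (which may already
      # carry a hit at another position) does not become a stop
      apply_change <- function(b) {
        x <- seq2[i]
        substr(x, pos, pos) <- b
        if (x %in% STOP_CODONS) return(FALSE)
        seq2[i] <<- x
        TRUE
      }
      if (pinf$degeneracy >= 3) {        # fourfold: every change synonymous
        if (stats::runif(1) < ks && length(pinf$ok_alt) > 0) {
          if (apply_change(sample(pinf$ok_alt, 1))) n_syn <- n_syn + 1L
        }
      } else if (pinf$degeneracy == 0) { # nondegenerate: every change nonsyn
        if (stats::runif(1) < ka && length(pinf$nonsyn_alt) > 0) {
          if (apply_change(sample(pinf$nonsyn_alt, 1))) n_non <- n_non + 1L
        }
      } else {                           # twofold: 1/3 syn + 2/3 nonsyn site
        u <- stats::runif(1)
        if (u < ks / 3 && length(pinf$syn_alt) > 0) {
          if (apply_change(sample(pinf$syn_alt, 1))) n_syn <- n_syn + 1L
        } else if (u >= ks / 3 && u < ks / 3 + 2 * ka / 3 &&
                   length(pinf$nonsyn_tv_alt) > 0) {
          if (apply_change(sample(pinf$nonsyn_tv_alt, 1)))
            n_non <- n_non + 1L
        }
      }
    }
  }
  seq1 <- codons
  list(seq1 = paste(seq1, collapse = ""), seq2 = paste(seq2, collapse = ""),
       n_synonymous = n_syn, n_nonsynonymous = n_non)
}
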