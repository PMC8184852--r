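# Evolutionary classification of regulatory change.
#
# Directions are always read against the outgroup's plastic response, used
# as a proxy for the ancestral stress response: a basal change in the same
# direction is orthoplastic, opposite is paraplastic; a slope change in the
# direction of the outgroup response is a magnification, against it (or
# reversing it) a mitigation. Crossing the two layers yields eight modes
# plus "none". Note the relabelling symmetry: an orthoplastic change in one
# lineage is de facto paraplastic from the other side of the comparison.

#' Classify the basal layer: orthoplastic / paraplastic / none
#'
#' Orthoplastic when the basal interspecific difference is significant and
#' shares the sign of the outgroup's (significant) plastic response;
#' paraplastic when the signs oppose; none otherwise. An estimate of exactly
#' zero with a significant q (a probability-zero event in floats) is
#' classified none.
#'
#' @param basal data frame from [test_basal_difference()].
#' @param outgroup_plast data frame from [test_plasticity()] for the
#'   outgroup at the reference timepoint.
#' @param alpha_basal,alpha_plast FDR thresholds (boundary q counts as
#'   significant).
#' @return character vector in `c("ortho", "para", "none")`, aligned to
#'   `basal$gene_id`.
#' @export
classify_basal <- function(basal, outgroup_plast, alpha_basal = 0.05,
                           alpha_plast = 0.05) {
  m <- match(basal$gene_id, outgroup_plast$gene_id)
  s_out <- outgroup_plast$log2_slope[m]
  q_out <- outgroup_plast$q[m]
  sig <- !is.na(basal$q) & basal$q <= alpha_basal &
    !is.na(q_out) & q_out <= alpha_plast &
    basal$log2_basal != 0 & s_out != 0
  out <- rep("none", nrow(basal))
  same <- sign(basal$log2_basal) == sign(s_out)
  out[sig & same] <- "ortho"
  out[sig & !same] <- "para"
  out
}

#' Classify the plastic layer: magnified / mitigated / none
#'
#' Magnified when the interspecific plasticity difference is significant and
#' in the direction of the outgroup's (significant) plastic response, i.e.
#' the derived species responds more strongly; mitigated when it points the
#' other way, which covers both weakened and reversed responses. The sign
#' convention generalises to down-regulated genes: a derived slope of -3
#' against an outgroup slope of -2 is a magnification.
#'
#' @param delta data frame from [test_plasticity_difference()].
#' @param outgroup_plast data frame from [test_plasticity()] for the
#'   outgroup at the same timepoint.
#' @param alpha_delta,alpha_plast FDR thresholds.
#' @return character vector in `c("magnified", "mitigated", "none")`.
#' @export
classify_plastic <- function(delta, outgroup_plast, alpha_delta = 0.1,
                             alpha_plast = 0.05) {
  m <- match(delta$gene_id, outgroup_plast$gene_id)
  s_out <- outgroup_plast$log2_slope[m]
  q_out <- outgroup_plast$q[m]
  sig <- !is.na(delta$q) & delta$q <= alpha_delta &
    !is.na(q_out) & q_out <= alpha_plast &
    delta$log2_delta != 0 & s_out != 0
  out <- rep("none", nrow(delta))
  same <- sign(delta$log2_delta) == sign(s_out)
  out[sig & same] <- "magnified"
  out[sig & !same] <- "mitigated"
  out
}

#' Assign cis/trans architecture from parental and allelic evidence
#'
#' A cis-acting variant is inferred when both the parental difference and
#' the hybrid allelic imbalance are significant with concordant direction;
#' a significant parental difference without allelic support is a
#' trans-only change. Genes with allelic imbalance but no parental
#' difference, and genes whose preferred allele contradicts the parental
#' direction, are excluded from the cis/trans dichotomy (the hybrid has more
#' power than the parental contrast, and discordance suggests compensating
#' trans effects).
#'
#' @param par_est,par_q parental effect estimates (log2) and q-values.
#' @param ase_est,ase_q allelic effect estimates (log2) and q-values.
#' @param alpha_par,alpha_ase FDR thresholds for the two layers.
#' @return character vector in `c("cis", "trans_only", "excluded_ase_only",
#'   "excluded_discordant", "none")`.
#' @export
assign_cis_trans <- function(par_est, par_q, ase_est, ase_q,
                             alpha_par = 0.05, alpha_ase = 0.05) {
  par_sig <- !is.na(par_q) & par_q <= alpha_par & par_est != 0
  ase_sig <- !is.na(ase_q) & ase_q <= alpha_ase & ase_est != 0
  out <- rep("none", length(par_est))
  concord <- sign(par_est) == sign(ase_est)
  out[par_sig & ase_sig & concord] <- "cis"
  out[par_sig & ase_sig & !concord] <- "excluded_discordant"
  out[par_sig & !ase_sig] <- "trans_only"
  out[!par_sig & ase_sig] <- "excluded_ase_only"
  out
}

#' Cross basal and plastic classes into a mode label
#' @param basal_class vector in ortho/para/none.
#' @param plastic_class vector in magnified/mitigated/none.
#' @return factor over [MODE_LABELS].
#' @export
assign_mode <- function(basal_class, plastic_class) {
  b <- c(ortho = "Ortho", para = "Para", none = "")[basal_class]
  p <- c(magnified = "Mag", mitigated = "Mit", none = "")[plastic_class]
  lab <- ifelse(b == "" & p == "", "none",
                ifelse(b == "", paste0("Only-", p),
                       ifelse(p == "", paste0("Only-", b),
                              paste0(b, "-", p))))
  factor(lab, levels = MODE_LABELS)
}

#' Quadrant chi-squared test for ortho vs para counts
#'
#' Default is a 1-degree-of-freedom goodness-of-fit of the ortho/para split
#' against 1:1, `chi2 = (2 * n_ortho - n_total)^2 / n_total`. The
#' `"independence"` method instead tests a 2x2 table of outgroup direction
#' (up/down) against the side of the derived change, conditioning on each
#' gene's probability of being up- or down-regulated.
#'
#' @param n_ortho number of orthoplastic genes.
#' @param n_total total classified genes (ortho + para).
#' @param method `"gof"` (default) or `"independence"`.
#' @param table 2x2 matrix of counts, required for `"independence"`.
#' @return list with `statistic`, `df` and `p`.
#' @export
quadrant_test <- function(n_ortho, n_total, method = c("gof", "independence"),
                          table = NULL) {
  method <- match.arg(method)
  if (method == "gof") {
    stopifnot(n_ortho >= 0, n_total >= n_ortho)
    ht <- stats::chisq.test(c(n_ortho, n_total - n_ortho), p = c(0.5, 0.5),
                            correct = FALSE)
  } else {
    if (is.null(table) || !all(dim(table) == c(2, 2)))
      stop("method 'independence' needs a 2x2 count table")
    ht <- stats::chisq.test(table, correct = FALSE)
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Odds of success vs failure
#'
#' `k / (n - k)`: the odds used to report, e.g., how strongly cis variants
#' favour the orthoplastic side.
#' @param k successes.
#' @param n total.
#' @export
odds_ratio <- function(k, n) {
  stopifnot(all(k >= 0), all(n > k))
  k / (n - k)
}

#' Percentage with one-decimal rounding
#' @param k count.
#' @param n total.
#' @export
pct <- function(k, n) round(100 * k / n, 1)

#' Full per-gene classification for one derived lineage
#'
#' Drives the layer classifiers and the cis/trans assignment for one
#' lineage-vs-outgroup comparison at one reference timepoint.
#'
#' @param outgroup_plast [test_plasticity()] for the outgroup at `t`.
#' @param basal [test_basal_difference()] for the pair.
#' @param delta [test_plasticity_difference()] for the pair at `t`.
#' @param ase [test_ase()] result for the corresponding hybrid.
#' @param lineage label recorded in the output.
#' @param t reference timepoint (hours).
#' @param alpha_basal,alpha_plast,alpha_delta,alpha_ase_basal,alpha_ase_plastic
#'   the five FDR thresholds of the pipeline.
#' @return `gene_classification` data frame, one row per gene.
#' @export
classify_genes <- function(outgroup_plast, basal, delta, ase, lineage, t,
                           alpha_basal = 0.05, alpha_plast = 0.05,
                           alpha_delta = 0.1, alpha_ase_basal = 0.05,
                           alpha_ase_plastic = 0.1) {
  genes <- basal$gene_id
  stopifnot(identical(genes, delta$gene_id))
  m <- match(genes, outgroup_plast$gene_id)
  dirn <- outgroup_plast$direction[m]
  basal_class <- classify_basal(basal, outgroup_plast, alpha_basal,
                                alpha_plast)
  plastic_class <- classify_plastic(delta, outgroup_plast, alpha_delta,
                                    alpha_plast)
  ab <- ase[ase$contrast == "basal", ]
  ap <- ase[ase$contrast == sprintf("plastic_%g", t), ]
  mb <- match(genes, ab$gene_id)
  mp <- match(genes, ap$gene_id)
  cis_basal <- assign_cis_trans(basal$log2_basal, basal$q,
                                ab$log2_ratio[mb], ab$q[mb],
                                alpha_basal, alpha_ase_basal)
  cis_plastic <- assign_cis_trans(delta$log2_delta, delta$q,
                                  ap$log2_ratio[mp], ap$q[mp],
                                  alpha_delta, alpha_ase_plastic)
  out <- data.frame(
    gene_id = genes, lineage = lineage, timepoint_h = t,
    outgroup_direction = dirn,
    basal_class = basal_class, plastic_class = plastic_class,
    mode = assign_mode(basal_class, plastic_class),
    cis_status_basal = cis_basal, cis_status_plastic = cis_plastic,
    log2_basal = basal$log2_basal, q_basal = basal$q,
    log2_delta = delta$log2_delta, q_delta = delta$q,
    log2_ase_basal = ab$log2_ratio[mb], q_ase_basal = ab$q[mb],
    log2_ase_plastic = ap$log2_ratio[mp], q_ase_plastic = ap$q[mp],
    stringsAsFactors = FALSE)
  class(out) <- c("gene_classification", "data.frame")
  out
}

#' Summarize a classification into the headline tables
#'
#' Counts and one-decimal percentages per quadrant (ortho vs para among
#' basal-classified genes, magnified vs mitigated among plastic-classified
#' genes) and per mode, plus the same restricted to genes with a cis
#' variant in the matching layer, with odds ratios.
#'
#' @param cls a [classify_genes()] result.
#' @return list of summary tables.
#' @export
summarize_proportions <- function(cls) {
  basal_n <- sum(cls$basal_class != "none")
  n_ortho <- sum(cls$basal_class == "ortho")
  plast_n <- sum(cls$plastic_class != "none")
  n_mag <- sum(cls$plastic_class == "magnified")
  cis_b <- cls$cis_status_basal == "cis" & cls$basal_class != "none"
  cis_p <- cls$cis_status_plastic == "cis" & cls$plastic_class != "none"
  safe_pct <- function(k, n) if (n > 0) pct(k, n) else 0.0
  safe_or <- function(k, n) if (n > k && k >= 0) odds_ratio(k, n) else NA_real_
  list(
    basal = data.frame(
      n_classified = basal_n, n_ortho = n_ortho, n_para = basal_n - n_ortho,
      pct_ortho = safe_pct(n_ortho, basal_n),
      n_cis = sum(cis_b), n_cis_ortho = sum(cis_b & cls$basal_class == "ortho"),
      pct_cis_ortho = safe_pct(sum(cis_b & cls$basal_class == "ortho"),
                               sum(cis_b)),
      odds_cis_ortho = safe_or(sum(cis_b & cls$basal_class == "ortho"),
                               sum(cis_b))),
    plastic = data.frame(
      n_classified = plast_n, n_magnified = n_mag,
      n_mitigated = plast_n - n_mag,
      pct_mitigated = safe_pct(plast_n - n_mag, plast_n),
      n_cis = sum(cis_p),
      n_cis_mitigated = sum(cis_p & cls$plastic_class == "mitigated"),
      pct_cis_mitigated = safe_pct(
        sum(cis_p & cls$plastic_class == "mitigated"), sum(cis_p)),
      odds_cis_mitigated = safe_or(
        sum(cis_p & cls$plastic_class == "mitigated"), sum(cis_p))),
    modes = as.data.frame(table(mode = cls$mode), responseName = "n"))
}
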