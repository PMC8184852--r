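# Parental differential expression over the stress time course.
#
# The model is a negative-binomial GLM with log link on the cell-means
# (saturated) design genotype + genotype:timepoint, with log size factors as
# offset. On a saturated design the quasi-likelihood estimate of each cell
# rate is the ratio estimator sum(y)/sum(sf), so the fit is computed in
# closed form and scales to thousands of genes; the per-gene dispersion is
# method-of-moments with a floor, and contrasts are Wald t-tests on the log
# scale. No pseudocounts enter the fit; reported log2 ratios come from the
# fitted cell means, never from raw count ratios.

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: the reference is the per-gene geometric mean
#' over genes expressed in every sample, and each sample's factor is the
#' median ratio of its counts to that reference. When no gene is nonzero in
#' all samples the function falls back to total-count factors (each sample
#' total divided by the median total) with a warning.
#'
#' @param em an [expression_matrix()], or a bare counts matrix.
#' @return named vector of positive per-sample size factors.
#' @export
estimate_size_factors <- function(em) {
  counts <- if (inherits(em, "expression_matrix")) em$counts else as.matrix(em)
  if (any(colSums(counts) == 0))
    stop("every sample must have at least one nonzero gene")
  allpos <- rowSums(counts == 0) == 0
  if (!any(allpos)) {
    warning("no gene is nonzero in all samples; using total-count factors")
    tot <- colSums(counts)
    return(tot / stats::median(tot))
  }
  ref <- exp(rowMeans(log(counts[allpos, , drop = FALSE])))
  apply(counts[allpos, , drop = FALSE], 2,
        function(col) stats::median(col / ref))
}

#' Fit the nested time-course model to parental counts
#'
#' @param em an [expression_matrix()].
#' @param genotype_set genotypes to include (parents only by default; the
#'   hybrids are analysed by the allele-specific module).
#' @param min_mean_count genes with a mean count below this are flagged
#'   `excluded` and dropped from downstream testing.
#' @param size_factors optional precomputed factors; estimated from the
#'   selected samples when `NULL`.
#' @return a `nested_fit` object: per-gene log cell rates, their Wald
#'   variances, the method-of-moments NB dispersion, residual degrees of
#'   freedom and exclusion flags.
#' @export
fit_nested_model <- function(em,
                             genotype_set = c("outgroup", "derived1",
                                              "derived2"),
                             min_mean_count = 10,
                             size_factors = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  keep <- em$samples$material == "RNA" & em$samples$genotype %in% genotype_set
  if (!any(keep)) stop("no RNA samples for the requested genotypes")
  smp <- em$samples[keep, , drop = FALSE]
  counts <- em$counts[, smp$sample_id, drop = FALSE]
  cell <- interaction(smp$genotype, smp$timepoint_h, drop = TRUE, sep = "|")
  if (any(table(cell) < 2)) stop("need >= 2 replicates per cell")
  sf <- size_factors %||% estimate_size_factors(counts)
  sf <- sf[colnames(counts)]

  cells <- levels(cell)
  S1 <- tapply(sf, cell, sum)              # sum of size factors per cell
  S2 <- tapply(sf^2, cell, sum)
  # cell rate estimator: sum(y) / sum(sf), genes x cells (in levels order)
  ysum <- vapply(cells,
                 function(l) rowSums(counts[, cell == l, drop = FALSE]),
                 numeric(nrow(counts)))
  rate <- sweep(ysum, 2, as.numeric(S1), "/")

  # method-of-moments dispersion pooled over cells of a gene:
  # alpha = sum((y - mu)^2 * n_c/(n_c - 1) - mu) / sum(mu^2), floored; the
  # per-cell rescaling corrects for the fitted cell mean.
  mu_hat <- rate[, as.integer(cell), drop = FALSE] *
    rep(sf, each = nrow(counts))
  resid2 <- (counts - mu_hat)^2
  ncell <- as.numeric(table(cell)[cells])
  rss <- vapply(seq_along(cells), function(ci) {
    sel <- cell == cells[ci]
    rowSums(resid2[, sel, drop = FALSE]) * ncell[ci] / (ncell[ci] - 1)
  }, numeric(nrow(counts)))
  num <- rowSums(rss) - rowSums(mu_hat)
  den <- rowSums(mu_hat^2)
  alpha <- pmax(1e-8, ifelse(den > 0, num / den, NA))

  # model-based Wald variance of log(rate) per cell (delta method):
  # Var(log r) = 1/(r * S1) + alpha * S2 / S1^2
  varlog_pois <- 1 / sweep(rate, 2, as.numeric(S1), "*")
  varlog <- varlog_pois + outer(alpha, as.numeric(S2 / S1^2))
  varlog[!is.finite(varlog)] <- NA

  # testing route: cell means of log-normalized counts with the
  # within-cell variance pooled over all cells of the gene (the log scale
  # makes the within-cell variance approximately constant across cells for
  # NB counts, so pooling is appropriate and gives the contrast t-tests
  # their full residual degrees of freedom). Zeros are floored at 0.5
  # normalized counts for this variance machinery only; the NB fit itself
  # uses no pseudocounts.
  z <- sweep(counts, 2, sf, "/")
  lz <- log(pmax(z, 0.5))
  log_mean <- vapply(seq_along(cells), function(ci) {
    rowMeans(lz[, cell == cells[ci], drop = FALSE])
  }, numeric(nrow(counts)))
  ssq <- vapply(seq_along(cells), function(ci) {
    apply(lz[, cell == cells[ci], drop = FALSE], 1, stats::var) *
      (ncell[ci] - 1)
  }, numeric(nrow(counts)))
  s2_pooled <- rowSums(ssq) / sum(ncell - 1)

  mean_count <- rowMeans(counts)
  excluded <- mean_count < min_mean_count

  geno <- sub("\\|.*", "", cells)
  tps <- as.numeric(sub(".*\\|", "", cells))
  structure(list(log_rate = log(rate), varlog = varlog,
                 log_mean = log_mean, s2_pooled = s2_pooled,
                 dispersion = alpha, cell_n = ncell,
                 cells = cells, cell_genotype = geno, cell_timepoint = tps,
                 df = sum(ncell - 1),
                 mean_count = mean_count, excluded = excluded,
                 size_factors = sf, genes = rownames(counts)),
            class = "nested_fit")
}

#' @export
print.nested_fit <- function(x, ...) {
  cat(sprintf(
    "nested_fit: %d genes, %d cells (%s), %d excluded (mean count < cutoff)\n",
    length(x$genes), length(x$cells),
    paste(unique(x$cell_genotype), collapse = ", "), sum(x$excluded)))
  invisible(x)
}

cell_index <- function(fit, genotype, timepoint) {
  i <- which(fit$cell_genotype == genotype & fit$cell_timepoint == timepoint)
  if (length(i) != 1)
    stop(sprintf("no cell for genotype '%s' at t=%g h", genotype, timepoint))
  i
}

# Contrast t-test on the log scale; returns the estimate in log2 units.
# The reported effect is the contrast of fitted NB log cell means; its
# significance comes from the same contrast applied to the cell means of
# log-normalized counts, with the pooled within-cell variance on the
# residual degrees of freedom (a plugin-dispersion Wald reference proved
# slightly anti-conservative at four replicates per cell).
wald_contrast <- function(fit, plus, minus) {
  use <- c(plus, minus)
  est <- rowSums(fit$log_rate[, plus, drop = FALSE]) -
    rowSums(fit$log_rate[, minus, drop = FALSE])
  est_test <- rowSums(fit$log_mean[, plus, drop = FALSE]) -
    rowSums(fit$log_mean[, minus, drop = FALSE])
  v <- fit$s2_pooled * sum(1 / fit$cell_n[use])
  se <- sqrt(v)
  stat <- est_test / se
  p <- 2 * stats::pt(-abs(stat), df = fit$df)
  p[fit$excluded | !is.finite(stat)] <- NA
  list(log2_est = est / log(2), se = se / log(2), stat = stat, p = p)
}

#' Plasticity of one species at one timepoint
#'
#' The plastic slope is `s_t = log2(expr_t / expr_0)` from the fitted cell
#' means; `s_0` is identically zero. Significance is a Wald contrast of
#' timepoint t against 0 within the species, BH-corrected across genes.
#'
#' @param fit a [fit_nested_model()] result.
#' @param species genotype label.
#' @param t timepoint in hours.
#' @param alpha FDR threshold for calling a direction (boundary values,
#'   q equal to alpha, count as significant).
#' @return data frame with one row per gene: `log2_slope`, `se`, `p`, `q`
#'   and `direction` in up/down/none.
#' @export
test_plasticity <- function(fit, species, t, alpha = 0.05) {
  stopifnot(inherits(fit, "nested_fit"))
  if (t == 0) {
    return(data.frame(gene_id = fit$genes, species = species, timepoint_h = 0,
                      log2_slope = 0, se = NA_real_, p = NA_real_,
                      q = NA_real_, direction = "none",
                      stringsAsFactors = FALSE))
  }
  ct <- wald_contrast(fit, cell_index(fit, species, t),
                      cell_index(fit, species, 0))
  q <- bh_adjust(ct$p)
  dirn <- ifelse(!is.na(q) & q <= alpha,
                 ifelse(ct$log2_est > 0, "up",
                        ifelse(ct$log2_est < 0, "down", "none")),
                 "none")
  data.frame(gene_id = fit$genes, species = species, timepoint_h = t,
             log2_slope = ct$log2_est, se = ct$se, p = ct$p, q = q,
             direction = dirn, stringsAsFactors = FALSE)
}

#' Basal (0 h) expression difference between a species pair
#'
#' `b = log2(derived_0 / outgroup_0)`; antisymmetric under swapping the
#' pair. BH-corrected across genes.
#'
#' @param fit a [fit_nested_model()] result.
#' @param pair character vector `c(derived, outgroup)`.
#' @param alpha FDR threshold recorded in the `significant` column.
#' @export
test_basal_difference <- function(fit, pair, alpha = 0.05) {
  stopifnot(inherits(fit, "nested_fit"), length(pair) == 2)
  ct <- wald_contrast(fit, cell_index(fit, pair[1], 0),
                      cell_index(fit, pair[2], 0))
  q <- bh_adjust(ct$p)
  data.frame(gene_id = fit$genes, derived = pair[1], outgroup = pair[2],
             log2_basal = ct$log2_est, se = ct$se, p = ct$p, q = q,
             significant = !is.na(q) & q <= alpha, stringsAsFactors = FALSE)
}

#' Interspecific difference in plasticity at one timepoint
#'
#' `Delta_t = log2[(derived_t/derived_0) / (outgroup_t/outgroup_0)]`, the
#' log-ratio of response ratios; zero at t = 0 and antisymmetric under pair
#' swap. A positive value for an up-regulated gene means the derived species
#' responds more strongly (magnification); a negative one means a weaker or
#' reversed response (mitigation).
#'
#' @inheritParams test_basal_difference
#' @param t timepoint in hours.
#' @param alpha FDR threshold (default 0.1 for the plasticity-change layer).
#' @export
test_plasticity_difference <- function(fit, pair, t, alpha = 0.1) {
  stopifnot(inherits(fit, "nested_fit"), length(pair) == 2)
  if (t == 0) {
    return(data.frame(gene_id = fit$genes, derived = pair[1],
                      outgroup = pair[2], timepoint_h = 0, log2_delta = 0,
                      se = NA_real_, p = NA_real_, q = NA_real_,
                      significant = FALSE, stringsAsFactors = FALSE))
  }
  plus <- c(cell_index(fit, pair[1], t), cell_index(fit, pair[2], 0))
  minus <- c(cell_index(fit, pair[1], 0), cell_index(fit, pair[2], t))
  ct <- wald_contrast(fit, plus, minus)
  q <- bh_adjust(ct$p)
  data.frame(gene_id = fit$genes, derived = pair[1], outgroup = pair[2],
             timepoint_h = t, log2_delta = ct$log2_est, se = ct$se,
             p = ct$p, q = q, significant = !is.na(q) & q <= alpha,
             stringsAsFactors = FALSE)
}
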