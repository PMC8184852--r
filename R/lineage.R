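# Parsimony polarization of cis variants across the two hybrid comparisons.
#
# Both hybrids share the outgroup parent, so a cis signal seen in only one
# hybrid most parsimoniously arose on the corresponding derived branch
# after the sister-species split; a signal seen in both hybrids cannot be
# polarized (it may predate the split or sit on the outgroup branch) and is
# called undetermined.

#' Assign the lineage of origin of cis variants
#'
#' @param cis_basal_1,cis_plastic_1 logical vectors: cis detected in hybrid
#'   1 in the basal / plastic layer.
#' @param cis_basal_2,cis_plastic_2 same for hybrid 2.
#' @return data frame with `origin` in `c("derived1", "derived2",
#'   "undetermined", "none")` and `layer` in `c("basal", "plastic", "both",
#'   "none")` describing which layer carries the signal (in the hybrid(s)
#'   where it was seen).
#' @export
assign_origin <- function(cis_basal_1, cis_plastic_1, cis_basal_2,
                          cis_plastic_2) {
  cis1 <- cis_basal_1 | cis_plastic_1
  cis2 <- cis_basal_2 | cis_plastic_2
  origin <- ifelse(cis1 & cis2, "undetermined",
                   ifelse(cis1, "derived1",
                          ifelse(cis2, "derived2", "none")))
  b <- (cis_basal_1 & cis1) | (cis_basal_2 & cis2)
  p <- (cis_plastic_1 & cis1) | (cis_plastic_2 & cis2)
  layer <- ifelse(b & p, "both", ifelse(b, "basal",
                                        ifelse(p, "plastic", "none")))
  data.frame(origin = origin, layer = layer, stringsAsFactors = FALSE)
}

#' Origin assignment from two gene classifications
#'
#' Convenience driver over [assign_origin()] taking the per-lineage
#' classification tables; a gene carries a cis signal in a hybrid when
#' either its basal or its plastic layer was assigned `cis` there. A gene
#' with both layers cis still counts as a single variant.
#'
#' @param cls1,cls2 [classify_genes()] results for lineage 1 and 2
#'   (same gene universe).
#' @return data frame with `gene_id`, `origin`, `layer`, and the per-hybrid
#'   modes.
#' @export
origin_from_classifications <- function(cls1, cls2) {
  stopifnot(identical(cls1$gene_id, cls2$gene_id))
  oa <- assign_origin(cls1$cis_status_basal == "cis",
                      cls1$cis_status_plastic == "cis",
                      cls2$cis_status_basal == "cis",
                      cls2$cis_status_plastic == "cis")
  data.frame(gene_id = cls1$gene_id, origin = oa$origin, layer = oa$layer,
             mode1 = as.character(cls1$mode), mode2 = as.character(cls2$mode),
             stringsAsFactors = FALSE)
}

#' Compare the distribution of derived cis variants over modes
#'
#' Tests whether the proportion of derived cis-acting variants in each of
#' the eight modes differs between the two lineages: an overall 8x2
#' homogeneity chi-squared with 7 degrees of freedom (modes empty in both
#' lineages are dropped from the overall statistic, reducing the df), plus
#' a per-mode
#' "partial" 1-df test of that mode's two cells against the expectation
#' from the lineage marginals. When a mode's expected cell drops below 1
#' the partial test falls back to an exact binomial test of that mode's
#' lineage split against the overall lineage proportion.
#'
#' @param counts 8x2 matrix (modes x lineages) of derived-variant counts.
#' @param expected_from when `"margins"` (default) the overall test is the
#'   usual homogeneity test; `"lineage2"` instead compares lineage 1 counts
#'   to expectations scaled from the lineage 2 distribution.
#' @return list with `overall` (statistic, df, p) and `per_mode` data frame
#'   (mode, chisq, df, p, method).
#' @export
mode_rate_test <- function(counts, expected_from = c("margins", "lineage2")) {
  expected_from <- match.arg(expected_from)
  counts <- as.matrix(counts)
  if (ncol(counts) != 2) stop("counts must have two lineage columns")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("mode", seq_len(nrow(counts)))
  N <- sum(counts)
  rs <- rowSums(counts); cs <- colSums(counts)
  if (expected_from == "margins") {
    nz <- rs > 0
    if (sum(nz) < 2) stop("need at least two non-empty modes")
    ht <- suppressWarnings(
      stats::chisq.test(counts[nz, , drop = FALSE], correct = FALSE))
    overall <- list(statistic = unname(ht$statistic),
                    df = unname(ht$parameter), p = ht$p.value)
  } else {
    # expected lineage-1 counts proportional to the lineage-2 distribution
    expc <- counts[, 2] / sum(counts[, 2]) * sum(counts[, 1])
    stat <- sum((counts[, 1] - expc)^2 / expc)
    df <- nrow(counts) - 1
    overall <- list(statistic = stat, df = df,
                    p = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  per <- lapply(seq_len(nrow(counts)), function(m) {
    E <- rs[m] * cs / N
    if (rs[m] == 0) {
      return(data.frame(mode = rownames(counts)[m], chisq = NA_real_,
                        df = NA_real_, p = NA_real_, method = "no_data",
                        stringsAsFactors = FALSE))
    }
    if (any(E < 1)) {
      bt <- stats::binom.test(counts[m, 1], rs[m], p = cs[1] / N)
      data.frame(mode = rownames(counts)[m], chisq = NA_real_, df = NA_real_,
                 p = bt$p.value, method = "exact_binomial",
                 stringsAsFactors = FALSE)
    } else {
      stat <- sum((counts[m, ] - E)^2 / E)
      data.frame(mode = rownames(counts)[m], chisq = stat, df = 1,
                 p = stats::pchisq(stat, 1, lower.tail = FALSE),
                 method = "partial_chisq", stringsAsFactors = FALSE)
    }
  })
  list(overall = overall, per_mode = do.call(rbind, per))
}

#' Derived vs undetermined contrast between lineages
#'
#' 2x2 test of derived against undetermined (pre-split) cis-variant counts
#' in the two lineages; chi-squared without continuity correction, with a
#' Fisher exact fallback whenever a cell is zero.
#'
#' @param m 2x2 matrix: rows derived/undetermined, columns lineages.
#' @return list with `statistic` (NA for Fisher), `p` and `method`.
#' @export
derived_vs_shared_test <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2, 2))) stop("m must be a 2x2 count matrix")
  if (any(m == 0)) {
    ht <- stats::fisher.test(m)
    list(statistic = NA_real_, p = ht$p.value, method = "fisher")
  } else {
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "chisq")
  }
}
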