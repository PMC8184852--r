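# Population-genetic summary statistics per gene group, and the
# gene-resampling bootstrap used to compare groups.

#' Filter population variant data and equalize allele numbers
#'
#' Applies, in order: removal of indels; removal of sites with more than
#' two alleles; masking of genotypes with depth below `min_dp` or genotype
#' quality below `min_gq`; removal of sites with quality below `min_qual`;
#' removal of sites where more than `max_missing_frac` of the individuals
#' are missing. Finally every retained site is randomly down-sampled
#' (hypergeometric, seeded) to the same number of observed alleles - the
#' minimum across retained sites - so that frequency-spectrum statistics
#' are comparable across sites.
#'
#' @param pd a `population_data` object from [read_population()].
#' @param min_dp minimum per-genotype depth.
#' @param min_gq minimum per-genotype quality.
#' @param min_qual minimum site quality.
#' @param max_missing_frac maximum tolerated fraction of missing
#'   individuals at a site.
#' @param seed seed for the down-sampling.
#' @return data frame of retained sites: `chrom`, `pos`, `class`, `gene`,
#'   `ac` (alternate-allele count after down-sampling), `an` (allele number
#'   after down-sampling, constant), plus `ac_raw`/`an_raw`; the removal
#'   log sits in `attr(, "removed")`.
#' @export
filter_population <- function(pd, min_dp = 10, min_gq = 20, min_qual = 30,
                              max_missing_frac = 0.8, seed = 1) {
  sites <- pd$sites
  gt <- pd$gt
  removed <- data.frame(chrom = character(0), pos = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  note <- function(i, why) {
    if (length(i) > 0)
      removed <<- rbind(removed,
                        data.frame(chrom = sites$chrom[i], pos = sites$pos[i],
                                   reason = why, stringsAsFactors = FALSE))
  }
  drop <- sites$is_indel
  note(which(drop), "indel")
  keep1 <- !drop
  drop2 <- sites$is_multiallelic & keep1
  note(which(drop2), "multiallelic")
  keep <- keep1 & !drop2

  mask <- (!is.na(pd$dp) & pd$dp < min_dp) |
    (!is.na(pd$gq) & pd$gq < min_gq)
  gt[mask] <- NA

  lowq <- keep & (is.na(sites$qual) | sites$qual < min_qual)
  note(which(lowq), "low_site_quality")
  keep <- keep & !lowq

  miss_frac <- rowMeans(is.na(gt))
  manymiss <- keep & miss_frac > max_missing_frac
  note(which(manymiss), "excess_missing")
  keep <- keep & !manymiss

  idx <- which(keep)
  an_raw <- 2L * rowSums(!is.na(gt[idx, , drop = FALSE]))
  ac_raw <- rowSums(gt[idx, , drop = FALSE], na.rm = TRUE)
  target <- if (length(idx) > 0) min(an_raw) else 0L
  set.seed(substream_seed(seed, 1L, 23L))
  ac <- integer(length(idx))
  for (j in seq_along(idx)) {
    ac[j] <- if (an_raw[j] == target) ac_raw[j] else
      stats::rhyper(1, ac_raw[j], an_raw[j] - ac_raw[j], target)
  }
  out <- data.frame(chrom = sites$chrom[idx], pos = sites$pos[idx],
                    class = sites$class[idx], gene = sites$gene[idx],
                    ac = as.integer(ac), an = as.integer(target),
                    ac_raw = as.integer(ac_raw), an_raw = as.integer(an_raw),
                    stringsAsFactors = FALSE)
  attr(out, "removed") <- removed
  out
}

#' Fold a vector of allele counts into the minor-allele spectrum
#'
#' @param ac derived/alternate allele counts, each in `0..n`.
#' @param n number of sampled alleles.
#' @return integer vector of length `floor(n/2)`: the number of segregating
#'   sites in each minor-allele-count class (monomorphic sites, count 0 or
#'   n, are excluded).
#' @export
fold_sfs <- function(ac, n) {
  stopifnot(all(ac >= 0), all(ac <= n))
  seg <- ac[ac > 0 & ac < n]
  cls <- pmin(seg, n - seg)
  tabulate(cls, nbins = floor(n / 2))
}

#' Mean number of pairwise differences (pi)
#'
#' Per-gene total pi: the average over all haplotype pairs of the number of
#' differing sites, computed from the per-site allele counts as
#' `sum(ac * (n - ac)) / choose(n, 2)`.
#'
#' @param ac per-site allele counts.
#' @param n number of sampled alleles.
#' @param per_site divide by `n_sites` (total sequence length) if supplied.
#' @param n_sites sequence length for the per-site option.
#' @export
pi_diversity <- function(ac, n, per_site = FALSE, n_sites = NULL) {
  stopifnot(n >= 2)
  val <- sum(ac * (n - ac)) / choose(n, 2)
  if (per_site) {
    if (is.null(n_sites)) stop("per_site = TRUE needs n_sites")
    val <- val / n_sites
  }
  val
}

#' Tajima's D from S and pi
#'
#' Standard constants a1, a2, b1, b2, c1, c2, e1, e2 (Tajima 1989):
#' `D = (pi - S/a1) / sqrt(e1 * S + e2 * S * (S - 1))`. Valid on folded
#' data since both pi and S are polarization-free. Undefined (NA) when
#' S = 0.
#'
#' @param S number of segregating sites.
#' @param pi mean pairwise differences over the same sites.
#' @param n number of sampled alleles.
#' @export
tajimas_d <- function(S, pi, n) {
  stopifnot(n >= 4)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Per-gene diversity statistics from filtered population data
#'
#' @param filtered result of [filter_population()] (or any data frame with
#'   `gene`, `class`, `ac`, `an`).
#' @return data frame, one row per gene: segregating sites, pi, pi_n, pi_s,
#'   pi_n/pi_s and Tajima's D at synonymous and nonsynonymous sites
#'   (NA-flagged where undefined).
#' @export
popgen_gene_stats <- function(filtered) {
  by_gene <- split(filtered[!is.na(filtered$gene), , drop = FALSE],
                   filtered$gene[!is.na(filtered$gene)])
  rows <- lapply(names(by_gene), function(g) {
    d <- by_gene[[g]]
    n <- d$an[1]
    seg <- d$ac > 0 & d$ac < d$an
    syn <- d$class == "synonymous"
    non <- d$class == "nonsynonymous"
    S_syn <- sum(seg & syn); S_non <- sum(seg & non)
    pi_all <- pi_diversity(d$ac, n)
    pi_s <- pi_diversity(d$ac[syn], n)
    pi_n <- pi_diversity(d$ac[non], n)
    data.frame(
      gene = g, n_alleles = n, S = sum(seg), S_syn = S_syn, S_non = S_non,
      pi = pi_all, pi_n = pi_n, pi_s = pi_s,
      pn_ps = if (pi_s > 0) pi_n / pi_s else NA_real_,
      D_syn = tajimas_d(S_syn, pi_diversity(d$ac[syn & seg], n), n),
      D_non = tajimas_d(S_non, pi_diversity(d$ac[non & seg], n), n),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise Ka and Ks for a codon alignment
#'
#' Divergence at nonsynonymous and synonymous sites by the Li (1993) /
#' Pamilo-Bianchi counting method with Kimura two-parameter correction, as
#' implemented by [seqinr::kaks()]; codons containing gaps or stops are
#' skipped by that implementation.
#'
#' @param seq1,seq2 aligned lowercase nucleotide strings of equal length
#'   (complete codons).
#' @return list with `ka`, `ks` and `ka_ks` (NA when Ks is zero or not
#'   estimable).
#' @export
kaks_pair <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be aligned")
  al <- seqinr::as.alignment(nb = 2, nam = c("s1", "s2"),
                             seq = c(tolower(seq1), tolower(seq2)))
  r <- seqinr::kaks(al)
  ka <- as.numeric(r$ka)[1]
  ks <- as.numeric(r$ks)[1]
  # seqinr signals saturated / non-computable divergence with values near
  # 10 and negative values; both are undefined here
  if (!is.finite(ka) || ka < 0 || ka > 9.9) ka <- NA_real_
  if (!is.finite(ks) || ks < 0 || ks > 9.9) ks <- NA_real_
  list(ka = ka, ks = ks,
       ka_ks = if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks)
}

#' Gene-resampling bootstrap comparison of group statistics
#'
#' For each group, genes are resampled with replacement `B` times and the
#' group statistic recomputed; each pair of groups is compared through the
#' bootstrap distribution of the difference, with
#' `p = 2 * min(#(diff <= 0), #(diff >= 0)) / B` (the doubling accounts for
#' the one-sided construction), floored at `2/B` and capped at 1.
#'
#' @param groups named list of per-gene numeric vectors (NAs dropped).
#' @param B number of bootstrap replicates.
#' @param seed seed; the full procedure is reproducible from it.
#' @param statistic group-level statistic (default mean).
#' @param min_group_size groups smaller than this trigger a high-variance
#'   warning.
#' @return list with `observed`, `boot` (B x groups matrix), `p_matrix`
#'   (pairwise), `B` and `seed`.
#' @export
bootstrap_compare <- function(groups, B = 1000, seed = 1, statistic = mean,
                              min_group_size = 30) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  groups <- lapply(groups, function(x) x[!is.na(x)])
  small <- names(groups)[vapply(groups, length, integer(1)) < min_group_size]
  if (length(small) > 0)
    warning("groups with < ", min_group_size, " genes (high bootstrap ",
            "variance): ", paste(small, collapse = ", "))
  set.seed(substream_seed(seed, 1L, 31L))
  k <- length(groups)
  boot <- matrix(NA_real_, B, k, dimnames = list(NULL, names(groups)))
  for (j in seq_len(k)) {
    x <- groups[[j]]
    n <- length(x)
    for (b in seq_len(B))
      boot[b, j] <- statistic(x[sample.int(n, n, replace = TRUE)])
  }
  obs <- vapply(groups, statistic, numeric(1))
  p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      d <- boot[, i] - boot[, j]
      pv <- 2 * min(sum(d <= 0), sum(d >= 0)) / B
      p[i, j] <- p[j, i] <- min(1, max(pv, 2 / B))
    }
  }
  list(observed = obs, boot = boot, p_matrix = p, B = B, seed = seed)
}

#' Interspecific Tajima's D index
#'
#' `(D1 + 2) / (D2 + 2)`: the +2 offset keeps typical D values (rarely
#' below -2) positive so the ratio is interpretable. Values of D at or
#' below -2 are flagged with a warning.
#'
#' @param d1,d2 Tajima's D in species 1 (numerator) and species 2.
#' @export
d_index <- function(d1, d2) {
  if (any(c(d1, d2) <= -2, na.rm = TRUE))
    warning("Tajima's D <= -2 encountered; index is not interpretable")
  (d1 + 2) / (d2 + 2)
}
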