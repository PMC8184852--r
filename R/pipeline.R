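# End-to-end orchestration: simulate (or read) -> parental expression ->
# allele-specific expression -> classification per lineage -> parsimony
# origin -> summary report. Everything is deterministic given the config.

#' Pipeline run configuration
#'
#' @param t_ref reference timepoint in hours for the classification (the
#'   headline timepoint of the stress response).
#' @param alpha_basal,alpha_plast,alpha_delta FDR thresholds of the
#'   parental layers (basal difference, plasticity, plasticity difference).
#' @param alpha_ase_basal,alpha_ase_plastic FDR thresholds of the allelic
#'   layers.
#' @param min_mean_count low-expression cutoff.
#' @param sim a [sim_config()] for simulated runs, or `NULL` when the
#'   count/allele inputs are supplied to [run_pipeline()] directly.
#' @param seed pipeline seed (also the default simulation seed).
#' @export
run_config <- function(t_ref = 6, alpha_basal = 0.05, alpha_plast = 0.05,
                       alpha_delta = 0.1, alpha_ase_basal = 0.05,
                       alpha_ase_plastic = 0.1, min_mean_count = 10,
                       sim = NULL, seed = 1) {
  for (nm in c("alpha_basal", "alpha_plast", "alpha_delta",
               "alpha_ase_basal", "alpha_ase_plastic")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop_config(nm, "must lie in (0, 1)")
  }
  cfg <- list(t_ref = t_ref, alpha_basal = alpha_basal,
              alpha_plast = alpha_plast, alpha_delta = alpha_delta,
              alpha_ase_basal = alpha_ase_basal,
              alpha_ase_plastic = alpha_ase_plastic,
              min_mean_count = min_mean_count, sim = sim, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments
#'   (with an optional `sim:` block of [sim_config()] arguments).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(run_config, y)
}

# Stable short hash of the configuration for provenance stamping
# (multiplicative rolling hash over the deparsed config, kept in 31 bits).
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  h <- 17
  for (b in utf8ToInt(txt)) h <- ((h + b) * 16777619) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' With `config$sim` set, generates the experiment with
#' [simulate_experiment()]; otherwise `expression` and `alleles` inputs
#' must be supplied. Fits the parental model, tests plasticity for every
#' species, basal and plasticity differences for both lineage pairs, ASE
#' for both hybrids, classifies every gene per lineage at the reference
#' timepoint, assigns cis-variant origins, and runs the lineage rate tests.
#'
#' @param config a [run_config()].
#' @param expression,alleles optional pre-built inputs overriding
#'   simulation.
#' @return a results bundle (list) with per-stage outputs, the
#'   mode x lineage matrix, test results, summaries and provenance.
#' @export
run_pipeline <- function(config = run_config(), expression = NULL,
                         alleles = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  truth <- NULL
  if (is.null(expression)) {
    if (is.null(config$sim))
      stop("stage 'input': no expression data and no simulation config")
    sim <- simulate_experiment(config$sim)
    expression <- sim$expression
    alleles <- sim$alleles
    truth <- sim$truth
  }
  if (is.null(alleles))
    stop("stage 'ase': allele counts are required")

  fit <- fit_nested_model(expression, min_mean_count = config$min_mean_count)
  t_ref <- config$t_ref
  if (!t_ref %in% fit$cell_timepoint)
    stop_config("t_ref", "not among the fitted timepoints")
  plast <- lapply(stats::setNames(nm = unique(fit$cell_genotype)),
                  function(sp) test_plasticity(fit, sp, t_ref,
                                               config$alpha_plast))
  pairs <- list(derived1 = c("derived1", "outgroup"),
                derived2 = c("derived2", "outgroup"))
  basal <- lapply(pairs, function(p)
    test_basal_difference(fit, p, config$alpha_basal))
  delta <- lapply(pairs, function(p)
    test_plasticity_difference(fit, p, t_ref, config$alpha_delta))
  alleles_n <- normalize_alleles(alleles)
  ase <- list(
    derived1 = test_ase(alleles_n, "hybrid1", config$alpha_ase_basal,
                        config$alpha_ase_plastic, config$min_mean_count),
    derived2 = test_ase(alleles_n, "hybrid2", config$alpha_ase_basal,
                        config$alpha_ase_plastic, config$min_mean_count))
  cls <- lapply(c("derived1", "derived2"), function(l)
    classify_genes(plast$outgroup, basal[[l]], delta[[l]], ase[[l]], l,
                   t_ref, config$alpha_basal, config$alpha_plast,
                   config$alpha_delta, config$alpha_ase_basal,
                   config$alpha_ase_plastic))
  names(cls) <- c("derived1", "derived2")
  origin <- origin_from_classifications(cls$derived1, cls$derived2)

  # mode x lineage matrix of derived cis variants: each gene counted once,
  # under the mode observed in its lineage of origin
  derived <- origin$origin %in% c("derived1", "derived2")
  mode_of_origin <- ifelse(origin$origin == "derived1", origin$mode1,
                           origin$mode2)
  mm <- matrix(0L, nrow = 8, ncol = 2,
               dimnames = list(setdiff(MODE_LABELS, "none"),
                               c("derived1", "derived2")))
  tb <- table(factor(mode_of_origin[derived],
                     levels = setdiff(MODE_LABELS, "none")),
              factor(origin$origin[derived],
                     levels = c("derived1", "derived2")))
  mm[rownames(tb), colnames(tb)] <- tb
  rate_test <- if (sum(mm) > 0) mode_rate_test(mm) else NULL

  und <- sum(origin$origin == "undetermined")
  dvs <- matrix(c(colSums(mm), und, und), nrow = 2, byrow = TRUE,
                dimnames = list(c("derived", "undetermined"),
                                c("derived1", "derived2")))
  dvs_test <- if (all(rowSums(dvs) > 0)) derived_vs_shared_test(dvs) else NULL

  bundle <- list(
    provenance = list(config_hash = config_hash(config), seed = config$seed,
                      t_ref = t_ref,
                      package_version = as.character(
                        utils::packageVersion("cisplast")),
                      started = format(t0)),
    config = config, truth = truth, fit = fit, plasticity = plast,
    basal = basal, delta = delta, ase = ase, classification = cls,
    origin = origin, mode_matrix = mm, mode_rate_test = rate_test,
    derived_vs_undetermined = dvs, derived_vs_undetermined_test = dvs_test,
    summaries = lapply(cls, summarize_proportions))
  class(bundle) <- "cisplast_bundle"
  bundle
}

#' Human-readable summary of a pipeline bundle
#'
#' Prints the headline tables: ortho/para and magnified/mitigated quadrant
#' counts with one-decimal percentages and odds ratios, the mode x lineage
#' matrix of derived cis variants, and the lineage rate tests. Empty
#' classifications print all-zero tables with a warning rather than
#' failing.
#'
#' @param bundle a [run_pipeline()] result.
#' @return invisibly, a list of the printed tables.
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "cisplast_bundle"))
  tables <- list()
  for (l in names(bundle$summaries)) {
    s <- bundle$summaries[[l]]
    cat(sprintf("== %s vs outgroup (t = %g h) ==\n", l,
                bundle$provenance$t_ref))
    if (s$basal$n_classified == 0)
      warning("empty basal classification for ", l)
    cat(sprintf("  basal: %d ortho / %d classified (%.1f%%)",
                s$basal$n_ortho, s$basal$n_classified, s$basal$pct_ortho),
        sprintf(" | cis: %d ortho / %d (%.1f%%, odds %.2f)\n",
                s$basal$n_cis_ortho, s$basal$n_cis, s$basal$pct_cis_ortho,
                s$basal$odds_cis_ortho))
    cat(sprintf("  plastic: %d mitigated / %d classified (%.1f%%)",
                s$plastic$n_mitigated, s$plastic$n_classified,
                s$plastic$pct_mitigated),
        sprintf(" | cis: %d mitigated / %d (%.1f%%, odds %.2f)\n",
                s$plastic$n_cis_mitigated, s$plastic$n_cis,
                s$plastic$pct_cis_mitigated, s$plastic$odds_cis_mitigated))
    tables[[l]] <- s
  }
  cat("\n== derived cis variants: mode x lineage ==\n")
  print(bundle$mode_matrix)
  if (!is.null(bundle$mode_rate_test)) {
    ov <- bundle$mode_rate_test$overall
    cat(sprintf("homogeneity chi2 = %.2f, df = %d, p = %.3g\n",
                ov$statistic, ov$df, ov$p))
  }
  tables$mode_matrix <- bundle$mode_matrix
  invisible(tables)
}

#' Serialize the machine-readable part of a bundle to JSON
#' @param bundle a [run_pipeline()] result.
#' @param path output path.
#' @export
write_bundle <- function(bundle, path) {
  keep <- list(provenance = bundle$provenance,
               mode_matrix = as.data.frame(bundle$mode_matrix),
               summaries = bundle$summaries,
               mode_rate_test = bundle$mode_rate_test,
               derived_vs_undetermined_test =
                 bundle$derived_vs_undetermined_test)
  write_results(keep, path)
}
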