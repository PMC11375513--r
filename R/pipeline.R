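#' Pipeline configuration
#'
#' Bundles and validates every tunable threshold of the per-group analysis.
#' Defaults mirror the study design the pipeline emulates: DEG gate at
#' adjusted p < 0.05 and |log2 FC| > 0.5, variance filtering at the 25%
#' within-group quantile, species retained at relative abundance >= 0.01 in
#' >= 10% of a group's samples, penalties tuned by 5-fold cross-validation
#' over fractions 0.1..1.0 of the feasible L1 range, and component count by
#' permutation test at alpha = 0.05. Age-of-onset dichotomization at 18
#' years (`onset_threshold`) is carried as metadata for callers that derive
#' group labels from an age-of-onset column.
#'
#' @param alpha DEG adjusted-p threshold.
#' @param lfc_threshold DEG absolute log2 fold-change threshold.
#' @param variance_q variance-filter quantile.
#' @param min_abund,min_prev abundance-filter thresholds.
#' @param c1_fractions,c2_fractions penalty grid fractions.
#' @param folds cross-validation folds for tuning.
#' @param K_max maximum components tested.
#' @param n_perm permutations for component selection.
#' @param alpha_perm significance level for the sequential component rule.
#' @param top_n genes per component for the GSVA gene sets.
#' @param enrichment_rule `"nonzero"` or `"top_n"` for the Fisher stage.
#' @param pseudocount CLR pseudocount.
#' @param onset_threshold age (years) splitting early from late onset.
#' @param seed integer seed governing every stochastic stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, lfc_threshold = 0.5,
                            variance_q = 0.25, min_abund = 0.01,
                            min_prev = 0.10,
                            c1_fractions = seq(0.1, 1, by = 0.1),
                            c2_fractions = seq(0.1, 1, by = 0.1),
                            folds = 5L, K_max = 5L, n_perm = 99L,
                            alpha_perm = 0.05, top_n = 10L,
                            enrichment_rule = "nonzero",
                            pseudocount = 1e-6,
                            onset_threshold = 18, seed = 1L) {
  cfg <- list(alpha = alpha, lfc_threshold = lfc_threshold,
              variance_q = variance_q, min_abund = min_abund,
              min_prev = min_prev, c1_fractions = c1_fractions,
              c2_fractions = c2_fractions, folds = as.integer(folds),
              K_max = as.integer(K_max), n_perm = as.integer(n_perm),
              alpha_perm = alpha_perm, top_n = as.integer(top_n),
              enrichment_rule = enrichment_rule,
              pseudocount = pseudocount,
              onset_threshold = onset_threshold, seed = as.integer(seed))
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1,
            cfg$lfc_threshold >= 0,
            cfg$variance_q >= 0, cfg$variance_q < 1,
            cfg$min_abund >= 0, cfg$min_prev >= 0, cfg$min_prev <= 1,
            all(cfg$c1_fractions > 0), all(cfg$c1_fractions <= 1),
            all(cfg$c2_fractions > 0), all(cfg$c2_fractions <= 1),
            cfg$folds >= 2, cfg$n_perm >= 19,
            cfg$alpha_perm > 0, cfg$alpha_perm < 1,
            cfg$top_n >= 1, cfg$pseudocount > 0)
  if (cfg$K_max < 1) stop("K_max must be >= 1")
  if (!cfg$enrichment_rule %in% c("nonzero", "top_n"))
    stop("enrichment_rule must be 'nonzero' or 'top_n'")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis for one phenotype group
#'
#' Executes, on the samples carrying `group_label` in the clinical table:
#' optional DEG gating against a control cohort, within-group variance
#' filtering of expression, abundance/prevalence filtering plus CLR of the
#' microbial block, standardization of both blocks, penalty tuning,
#' permutation selection of the component count, the sparse CCA fit, Fisher
#' pathway enrichment of component genes, GSVA scoring of each component's
#' top-`top_n` gene set, and Spearman correlation of both component scores
#' and enrichment scores with the clinical variables.
#'
#' @param expression,abundance `omics_matrix` inputs covering (at least) the
#'   group's samples.
#' @param clinical data.frame with `sample_id`, `group`, and the clinical
#'   variables.
#' @param genesets a `gene_set_collection`.
#' @param group_label which `clinical$group` value to analyse.
#' @param config a [pipeline_config()].
#' @param clinical_variables columns correlated with scores/ES.
#' @param de_control optional control-cohort `omics_matrix` (same genes as
#'   `expression`): when supplied, genes are gated by
#'   [differential_expression()] + [select_degs()] before filtering.
#' @param out_dir optional directory; when given, every artifact is written
#'   as TSV alongside a JSON run manifest carrying the config and its hash.
#' @return invisible list ("bundle"): filtered matrices, tuning result,
#'   permutation result, `fit`, enrichment records, top-gene sets, ES
#'   matrix, correlation tables, config, group label, and feature universe.
#' @export
run_group_analysis <- function(expression, abundance, clinical, genesets,
                               group_label, config = pipeline_config(),
                               clinical_variables =
                                 c("sputum_neutrophil_pct",
                                   "sputum_eosinophil_pct"),
                               de_control = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  expression <- as_omics_matrix(expression, "expression")
  abundance <- as_omics_matrix(abundance, "abundance")
  if (!all(c("sample_id", "group") %in% names(clinical)))
    stop("clinical table needs 'sample_id' and 'group' columns")

  samples <- clinical$sample_id[clinical$group == group_label]
  if (length(samples) < 10)
    stop(sprintf("preprocess: group '%s' has %d samples; need >= 10",
                 group_label, length(samples)))
  if (length(setdiff(samples, sample_ids(expression))) ||
      length(setdiff(samples, sample_ids(abundance))))
    stop("preprocess: group samples missing from an omics input")

  expr_g <- omics_matrix(expression$values[samples, , drop = FALSE],
                         "expression")
  abun_g <- omics_matrix(abundance$values[samples, , drop = FALSE],
                         "abundance")

  # stage 1: feature gating and filtering
  de_results <- NULL
  if (!is.null(de_control)) {
    de_results <- differential_expression(expr_g, de_control)
    degs <- select_degs(de_results, alpha = config$alpha,
                        lfc_threshold = config$lfc_threshold)
    if (length(degs) < 2)
      stop("preprocess: fewer than 2 genes pass the DEG gate")
    expr_g <- subset_features(expr_g, degs)
  }
  expr_f <- variance_filter(expr_g, q = config$variance_q)
  abun_f <- abundance_filter(abun_g, min_abund = config$min_abund,
                             min_prev = config$min_prev)
  if (ncol(expr_f$values) < 2 || ncol(abun_f$values) < 2)
    stop("preprocess: filtering left fewer than 2 features in a block")

  x_std <- standardize(expr_f)
  y_std <- standardize(clr_transform(
    subset_features(abun_g, feature_ids(abun_f)),
    pseudocount = config$pseudocount))

  # stage 2: tune, select component count, fit
  tuning <- tune_penalties(x_std, y_std,
                           c1_fractions = config$c1_fractions,
                           c2_fractions = config$c2_fractions,
                           folds = config$folds, seed = config$seed)
  # component count is selected on the unpenalized sequence: with sparse
  # budgets a rank-one deflation removes the planted factor only partially
  # and the residual re-tests significant, inflating K
  perm <- permutation_component_test(x_std, y_std, K_max = config$K_max,
                                     n_perm = config$n_perm,
                                     alpha = config$alpha_perm,
                                     seed = config$seed + 1L)
  K <- perm$retained_K
  fit <- NULL; records <- NULL; top_sets <- NULL; es <- NULL
  score_cor <- NULL; es_cor <- NULL
  if (K >= 1) {
    fit <- fit_sparse_cca(x_std, y_std, K = K, c1 = tuning$c1,
                          c2 = tuning$c2)
    for (k in seq_len(K))
      fit$components[[k]]$permutation_p <- perm$p_values[k]

    # stage 3: enrichment, GSVA, clinical correlation
    records <- enrich_components(fit, genesets,
                                 universe = feature_ids(expr_f),
                                 phenotype = group_label,
                                 rule = config$enrichment_rule,
                                 n = if (config$enrichment_rule == "top_n")
                                   config$top_n else NULL)
    top_sets <- lapply(fit$components, component_gene_set,
                       rule = "top_n", n = config$top_n)
    names(top_sets) <- paste0(group_label, "C", seq_len(K), "_top",
                              config$top_n)
    es <- gsva_scores(expr_f, top_sets)
    clin_g <- clinical[clinical$sample_id %in% samples, , drop = FALSE]
    score_cor <- correlate_scores_clinical(fit, clin_g, clinical_variables)
    es_cor <- correlate_es_clinical(es, clin_g, clinical_variables)
  }

  bundle <- list(group = group_label, config = config,
                 samples = samples,
                 de_results = de_results,
                 expression_filtered = expr_f,
                 abundance_filtered = abun_f,
                 x = x_std, y = y_std,
                 universe = feature_ids(expr_f),
                 tuning = tuning, permutation = perm, retained_K = K,
                 fit = fit, enrichment = records,
                 top_sets = top_sets, es = es,
                 score_clinical = score_cor, es_clinical = es_cor)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir <- file.path(out_dir, bundle$group)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(bundle$config), cfg_path, digits = NA,
                       auto_unbox = TRUE)
  manifest <- list(group = bundle$group,
                   seed = bundle$config$seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   n_samples = length(bundle$samples),
                   n_genes = length(bundle$universe),
                   n_species = ncol(bundle$abundance_filtered$values),
                   retained_K = bundle$retained_K)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  rep_e <- attr(bundle$expression_filtered, "report")
  if (!is.null(rep_e)) write_tsv(rep_e, file.path(dir, "variance_filter.tsv"))
  rep_a <- attr(bundle$abundance_filtered, "report")
  if (!is.null(rep_a)) write_tsv(rep_a, file.path(dir, "abundance_filter.tsv"))
  if (!is.null(bundle$de_results))
    write_tsv(bundle$de_results, file.path(dir, "differential_expression.tsv"))
  if (!is.null(bundle$fit)) write_cca_tsv(bundle$fit, dir)
  if (!is.null(bundle$enrichment))
    write_tsv(bundle$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(bundle$es))
    write_tsv(data.frame(set = rownames(bundle$es), bundle$es,
                         check.names = FALSE),
              file.path(dir, "es_matrix.tsv"))
  if (!is.null(bundle$score_clinical))
    write_tsv(bundle$score_clinical, file.path(dir, "score_clinical.tsv"))
  if (!is.null(bundle$es_clinical))
    write_tsv(bundle$es_clinical, file.path(dir, "es_clinical.tsv"))
  invisible(dir)
}

#' Compare two group analyses
#'
#' Cross-applies each group's component gene sets to BOTH groups' samples:
#' every top-gene set is GSVA-scored in each sample cohort separately and
#' correlated with the clinical variables there, so a group-specific
#' host-microbial program shows a significant ES correlation in its own
#' group and not in the other. Also classifies enriched pathways as shared
#' or group-specific.
#'
#' @param bundle_a,bundle_b outputs of [run_group_analysis()] for the two
#'   groups; both fits must come from the same gene universe construction
#'   (overlapping gene axis).
#' @param clinical full clinical table covering both groups.
#' @param clinical_variables variables for the ES correlations.
#' @param expression full expression `omics_matrix` covering both groups.
#' @param out_dir optional output directory for TSV artifacts.
#' @return invisible list: `pathway_classes` (shared/unique table),
#'   `es_cross` (set x cohort correlation table with `set_origin` and
#'   `sample_group` columns).
#' @export
compare_groups <- function(bundle_a, bundle_b, clinical, expression,
                           clinical_variables =
                             c("sputum_neutrophil_pct",
                               "sputum_eosinophil_pct"),
                           out_dir = NULL) {
  expression <- as_omics_matrix(expression, "expression")
  common_genes <- intersect(feature_ids(expression),
                            union(bundle_a$universe, bundle_b$universe))
  if (length(common_genes) < 2)
    stop("universe mismatch: no common genes between bundles and expression")

  all_sets <- c(bundle_a$top_sets, bundle_b$top_sets)
  origins <- c(rep(bundle_a$group, length(bundle_a$top_sets)),
               rep(bundle_b$group, length(bundle_b$top_sets)))
  out <- list()
  if (length(all_sets)) {
    for (bundle in list(bundle_a, bundle_b)) {
      expr_g <- omics_matrix(
        expression$values[bundle$samples, common_genes, drop = FALSE],
        "expression")
      es <- gsva_scores(expr_g, all_sets)
      clin_g <- clinical[clinical$sample_id %in% bundle$samples, ,
                         drop = FALSE]
      tab <- correlate_es_clinical(es, clin_g, clinical_variables)
      tab$set_origin <- origins[match(tab$set, names(all_sets))]
      tab$sample_group <- bundle$group
      out[[length(out) + 1L]] <- tab
    }
  }
  es_cross <- if (length(out)) do.call(rbind, out) else NULL
  classes <- classify_shared_unique(bundle_a$enrichment,
                                    bundle_b$enrichment,
                                    eo_label = bundle_a$group,
                                    lo_label = bundle_b$group)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(classes, file.path(out_dir, "pathway_classes.tsv"))
    if (!is.null(es_cross))
      write_tsv(es_cross, file.path(out_dir, "es_cross_group.tsv"))
  }
  invisible(list(pathway_classes = classes, es_cross = es_cross))
}
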