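#' Per-gene differential expression between two arms
#'
#' Welch's unequal-variance two-sample t-test on log2-scale values, gene by
#' gene, with Benjamini-Hochberg adjustment across all genes. The fold
#' change is `mean(case) - mean(control)` on the log2 scale.
#'
#' @param case,control `omics_matrix` objects (or plain matrices) sharing
#'   the same feature set, each with at least 2 samples.
#' @return data.frame with columns `feature_id`, `log2_fold_change`,
#'   `p_value`, `adjusted_p`, ordered as the input features.
#' @export
differential_expression <- function(case, control) {
  case <- as_omics_matrix(case); control <- as_omics_matrix(control)
  X1 <- case$values; X2 <- control$values
  if (!identical(colnames(X1), colnames(X2)))
    stop("case and control must share an identical feature set")
  n1 <- nrow(X1); n2 <- nrow(X2)
  if (n1 < 2 || n2 < 2) stop("each arm needs at least 2 samples")

  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- col_vars(X1); v2 <- col_vars(X2)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  # Welch-Satterthwaite df; degenerate zero-variance genes handled explicitly
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  tstat <- lfc / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[se2 == 0 & lfc == 0] <- 1
  p[se2 == 0 & lfc != 0] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  data.frame(feature_id = colnames(X1),
             log2_fold_change = unname(lfc),
             p_value = unname(p),
             adjusted_p = unname(stats::p.adjust(p, method = "BH")),
             stringsAsFactors = FALSE)
}

#' Select differentially expressed genes
#'
#' Keeps features with `adjusted_p < alpha` and `|log2_fold_change| >
#' lfc_threshold` (two-sided gate: down-regulated genes count too).
#'
#' @param results data.frame from [differential_expression()].
#' @param alpha adjusted p-value cutoff.
#' @param lfc_threshold absolute log2 fold-change cutoff.
#' @return character vector of retained feature ids.
#' @export
select_degs <- function(results, alpha = 0.05, lfc_threshold = 0.5) {
  if (nrow(results) == 0) return(character())
  keep <- results$adjusted_p < alpha &
    abs(results$log2_fold_change) > lfc_threshold
  results$feature_id[keep]
}

#' Variance filter relative to a per-group quantile
#'
#' A feature is retained iff its within-group variance strictly exceeds the
#' `q`-quantile of that group's feature variances in at least one group.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). `q = 0` disables quantile filtering and drops
#' only degenerate (zero-variance-everywhere) features. Only features are
#' removed; the sample axis is untouched.
#'
#' @param x an `omics_matrix`.
#' @param groups per-sample group labels (named by sample id, or in sample
#'   order); a single group is allowed.
#' @param q quantile in `[0, 1)`.
#' @return filtered `omics_matrix`; the per-feature report (variances per
#'   group, kept flag) is in `attr(, "report")`.
#' @export
variance_filter <- function(x, groups = NULL, q = 0.25) {
  x <- as_omics_matrix(x)
  if (q < 0 || q >= 1) stop("q must be in [0, 1)")
  groups <- resolve_groups(x, groups)
  vals <- x$values
  labs <- unique(groups)
  keep <- rep(FALSE, ncol(vals))
  report <- data.frame(feature_id = feature_ids(x),
                       stringsAsFactors = FALSE)
  for (g in labs) {
    rows <- groups == g
    if (sum(rows) < 2)
      stop(sprintf("group '%s' has fewer than 2 samples", g))
    v <- col_vars(vals[rows, , drop = FALSE])
    thr <- if (q == 0) 0 else
      stats::quantile(v, probs = q, type = 7, names = FALSE)
    keep <- keep | (v > thr)
    report[[paste0("variance_", g)]] <- unname(v)
  }
  report$kept <- keep
  out <- subset_features(x, which(keep))
  attr(out, "report") <- report
  out
}

#' Abundance/prevalence filter for relative-abundance data
#'
#' A species is retained iff, in at least one group, its relative abundance
#' is `>= min_abund` in at least a `min_prev` fraction of that group's
#' samples (both comparisons inclusive at the boundary).
#'
#' @param y an `omics_matrix` of kind `abundance`.
#' @param groups per-sample group labels (see [variance_filter()]).
#' @param min_abund relative-abundance detection threshold.
#' @param min_prev minimum fraction of samples at or above `min_abund`.
#' @return filtered `omics_matrix` (kind becomes `transformed` since rows no
#'   longer sum to 1); report in `attr(, "report")`.
#' @export
abundance_filter <- function(y, groups = NULL, min_abund = 0.01,
                             min_prev = 0.10) {
  y <- as_omics_matrix(y, kind = "abundance")
  if (!y$kind %in% c("abundance", "transformed"))
    stop("abundance_filter expects an abundance matrix")
  groups <- resolve_groups(y, groups)
  vals <- y$values
  labs <- unique(groups)
  keep <- rep(FALSE, ncol(vals))
  report <- data.frame(feature_id = feature_ids(y),
                       stringsAsFactors = FALSE)
  for (g in labs) {
    rows <- groups == g
    if (!any(rows)) stop(sprintf("group '%s' is empty", g))
    prev <- colMeans(vals[rows, , drop = FALSE] >= min_abund)
    keep <- keep | (prev >= min_prev)
    report[[paste0("prevalence_", g)]] <- unname(prev)
  }
  report$kept <- keep
  out <- subset_features(y, which(keep))
  attr(out, "report") <- report
  out
}

resolve_groups <- function(x, groups) {
  n <- nrow(x$values)
  if (is.null(groups)) return(rep("all", n))
  groups <- if (!is.null(names(groups))) {
    missing <- setdiff(sample_ids(x), names(groups))
    if (length(missing))
      stop("unlabelled samples: ", paste(missing, collapse = ", "))
    unname(groups[sample_ids(x)])
  } else {
    if (length(groups) != n) stop("groups length must match sample count")
    as.character(groups)
  }
  groups
}

#' Column standardization
#'
#' Centers each feature to mean 0 and scales to unit variance using the
#' sample (n-1) standard deviation. Required so the cross-product matrix
#' entering the sparse CCA behaves as a correlation matrix.
#'
#' @param x an `omics_matrix` or matrix.
#' @return an `omics_matrix` of kind `transformed`.
#' @export
standardize <- function(x) {
  x <- as_omics_matrix(x)
  v <- col_vars(x$values)
  if (any(v == 0))
    stop("zero-variance column(s): ",
         paste(utils::head(feature_ids(x)[v == 0], 5), collapse = ", "))
  vals <- scale(x$values, center = TRUE, scale = sqrt(v))
  attr(vals, "scaled:center") <- NULL
  attr(vals, "scaled:scale") <- NULL
  omics_matrix(vals, "transformed")
}

#' Centered log-ratio transform
#'
#' The standard compositional treatment for relative abundances before
#' correlation-based analysis: `log(x + pseudocount)` minus the per-sample
#' mean of the logs.
#'
#' @param y an `omics_matrix` (abundance or filtered abundance).
#' @param pseudocount small constant added before taking logs.
#' @return an `omics_matrix` of kind `transformed`.
#' @export
clr_transform <- function(y, pseudocount = 1e-6) {
  y <- as_omics_matrix(y, kind = "abundance")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  lv <- log(y$values + pseudocount)
  lv <- lv - rowMeans(lv)
  omics_matrix(lv, "transformed")
}
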