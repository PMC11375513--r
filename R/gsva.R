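#' Kernel-ECDF expression statistic
#'
#' For each gene `i` and sample `j`, the Gaussian-kernel smoothed empirical
#' CDF evaluated at the sample's own value:
#' `mean_k Phi((x_ij - x_ik) / h_i)` with per-gene bandwidth
#' `h_i = sd_i / 4` (the conventional choice for continuous log-scale
#' expression). The statistic is monotone in the expression value within a
#' gene and exactly invariant to per-gene affine rescaling with positive
#' slope, since the bandwidth scales with the standard deviation and the
#' location cancels in the differences.
#'
#' @param x an `omics_matrix` (or matrix), samples x genes, with at least 3
#'   samples and strictly positive gene variances.
#' @return numeric matrix, samples x genes, entries in (0, 1).
#' @export
kernel_ecdf_statistic <- function(x) {
  x <- as_omics_matrix(x)
  X <- x$values
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  sds <- sqrt(col_vars(X))
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(colnames(X)[sds == 0], 5), collapse = ", "))
  out <- matrix(0, n, ncol(X), dimnames = dimnames(X))
  for (i in seq_len(ncol(X))) {
    xi <- X[, i]
    h <- sds[i] / 4
    # column j holds Phi((x_j - x_k) / h) over reference samples k
    out[, i] <- colMeans(stats::pnorm(outer(-xi, xi, "+") / h))
  }
  out
}

#' Rank random-walk enrichment score for one sample
#'
#' Genes are ordered by decreasing statistic; walking down the list, genes
#' inside the set add `|r|^tau / sum_set(|r|^tau)` with `r` the centered
#' rank `rank - (N + 1) / 2`, so list extremes carry the largest weight and
#' the weighting is symmetric under reversal of the ranking (mirroring a
#' configuration flips the score's sign and preserves its magnitude). Genes
#' outside the set subtract `1 / (N - m)`. The enrichment score is the
#' maximum positive deviation plus the minimum negative deviation of the
#' walk (max-deviation-difference form), which is bounded in `[-1, 1]`;
#' `method = "max"` returns the single largest-magnitude deviation instead.
#'
#' @param stat numeric vector of per-gene statistics for one sample, named
#'   by gene id (ties receive average ranks).
#' @param gene_set character vector of member gene ids; must intersect the
#'   ranked genes.
#' @param tau rank-weight exponent (>= 0).
#' @param method `"diff"` (default) or `"max"`.
#' @return scalar enrichment score in `[-1, 1]`.
#' @export
es_random_walk <- function(stat, gene_set, tau = 1,
                           method = c("diff", "max")) {
  method <- match.arg(method)
  if (is.null(names(stat))) stop("'stat' must be named by gene id")
  N <- length(stat)
  in_set <- names(stat) %in% gene_set
  m <- sum(in_set)
  if (m == 0) stop("gene set does not intersect the ranked genes")
  if (m == N) stop("gene set covers every ranked gene")
  r <- rank(stat, ties.method = "average") - (N + 1) / 2  # centered rank
  ord <- order(stat, decreasing = TRUE)
  step <- numeric(N)
  rw <- abs(r[ord])^tau
  inside <- in_set[ord]
  step[inside] <- rw[inside] / sum(rw[inside])
  step[!inside] <- -1 / (N - m)
  walk <- cumsum(step)
  vmax <- max(0, max(walk)); vmin <- min(0, min(walk))
  if (method == "diff") vmax + vmin
  else if (vmax >= -vmin) vmax else vmin
}

#' GSVA-style per-sample enrichment scores
#'
#' Composes [kernel_ecdf_statistic()] with the per-sample rank random walk
#' [es_random_walk()] for every gene set. Sets intersecting fewer than
#' `min_overlap` measured genes are skipped with a warning.
#'
#' @param x an `omics_matrix` (samples x genes) of continuous expression.
#' @param sets a `gene_set_collection` (or named list of gene-id vectors).
#' @param tau,method passed to [es_random_walk()].
#' @param min_overlap minimum measured genes per usable set.
#' @return numeric matrix, sets x samples ("ES matrix"), entries in
#'   `[-1, 1]`.
#' @export
gsva_scores <- function(x, sets, tau = 1, method = "diff",
                        min_overlap = 2L) {
  x <- as_omics_matrix(x)
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (length(sets) == 0) stop("no gene sets supplied")
  genes <- feature_ids(x)
  usable <- vapply(sets, function(s) {
    k <- length(intersect(s, genes))
    k >= min_overlap && k < length(genes)
  }, logical(1))
  if (any(!usable))
    warning("skipping ", sum(!usable),
            " set(s) with fewer than ", min_overlap,
            " measured genes (or covering the whole gene axis)")
  sets <- sets[usable]
  if (length(sets) == 0) stop("no usable gene sets after intersection")

  stat <- kernel_ecdf_statistic(x)
  es <- matrix(NA_real_, length(sets), nrow(stat),
               dimnames = list(names(sets), rownames(stat)))
  for (j in seq_len(nrow(stat))) {
    sj <- stat[j, ]
    for (i in seq_along(sets)) {
      es[i, j] <- es_random_walk(sj, sets[[i]], tau = tau, method = method)
    }
  }
  es
}

#' Spearman correlation of enrichment scores with clinical variables
#'
#' Same contract as [correlate_scores_clinical()]: average-ranked Spearman
#' rho, t-approximation p-values, pairwise deletion of missing values, at
#' least 4 complete pairs.
#'
#' @param es ES matrix from [gsva_scores()] (sets x samples).
#' @param clinical data.frame with a `sample_id` column covering the ES
#'   columns.
#' @param variables clinical column names.
#' @return data.frame `set`, `variable`, `spearman_rho`, `p_value`, `n`.
#' @export
correlate_es_clinical <- function(es, clinical, variables) {
  if (!"sample_id" %in% names(clinical))
    stop("clinical table needs a 'sample_id' column")
  idx <- match(colnames(es), clinical$sample_id)
  if (anyNA(idx)) stop("clinical table does not cover all ES samples")
  missing_vars <- setdiff(variables, names(clinical))
  if (length(missing_vars))
    stop("unknown clinical variable(s): ", paste(missing_vars, collapse = ", "))
  out <- list()
  for (s in rownames(es)) {
    for (v in variables) {
      st <- spearman_test(es[s, ], clinical[[v]][idx])
      out[[length(out) + 1L]] <- data.frame(
        set = s, variable = v, spearman_rho = st$rho,
        p_value = st$p_value, n = st$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
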