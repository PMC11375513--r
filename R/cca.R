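#' Elementwise soft-thresholding
#'
#' The lasso proximal operator `S(a, delta) = sign(a) * max(|a| - delta, 0)`
#' that realizes the L1 budget inside the penalized-matrix-decomposition
#' update.
#'
#' @param a numeric vector.
#' @param delta threshold, `>= 0`.
#' @return thresholded vector of the same length.
#' @export
#' @examples
#' soft_threshold(c(3, -1, 0.5), 1)  # 2, 0, 0
soft_threshold <- function(a, delta) {
  if (delta < 0) stop("delta must be non-negative")
  sign(a) * pmax(abs(a) - delta, 0)
}

#' Project a vector onto the unit L2 ball with an L1 budget
#'
#' Solves `max a'u  s.t. ||u||_2 <= 1, ||u||_1 <= c`: the PMD inner step.
#' The solution is `u = S(a, delta) / ||S(a, delta)||_2` with `delta = 0`
#' when the unconstrained unit vector already meets the L1 budget, otherwise
#' `delta` is found by bisection so that `||u||_1 = c` (within `tol`).
#'
#' @param a numeric vector, not all zero.
#' @param c L1 budget, in `[1, sqrt(length(a))]`.
#' @param tol bisection tolerance on the achieved L1 norm.
#' @param max_iter bisection iteration cap.
#' @return unit-L2 vector honoring the L1 budget.
#' @export
l1_constrained_unit <- function(a, c, tol = 1e-8, max_iter = 100L) {
  amax <- max(abs(a))
  if (amax == 0) stop("input vector is all zero")
  if (c < 1) stop("L1 budget below 1 is infeasible for a unit vector")
  u <- a / sqrt(sum(a^2))
  if (sum(abs(u)) <= c + tol) return(u)

  lo <- 0; hi <- amax
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    s <- soft_threshold(a, mid)
    nrm <- sqrt(sum(s^2))
    if (nrm == 0) { hi <- mid; next }
    u <- s / nrm
    l1 <- sum(abs(u))
    if (abs(l1 - c) <= tol) return(u)
    if (l1 > c) lo <- mid else hi <- mid
  }
  # fall back to the feasible side of the bracket
  s <- soft_threshold(a, hi)
  if (sqrt(sum(s^2)) == 0) {
    # keep only the largest-magnitude entry
    s <- numeric(length(a))
    j <- which.max(abs(a))
    s[j] <- sign(a[j])
  }
  s / sqrt(sum(s^2))
}

#' Fit one penalized rank-one factor of a cross-product matrix
#'
#' Alternating PMD updates: `u <- l1_constrained_unit(Z v, c1)`,
#' `v <- l1_constrained_unit(Z'u, c2)` until the largest coordinate change
#' falls below `tol` or `max_iter` sweeps. `v` is initialized from the
#' leading right singular vector of `Z` (deterministic) unless a numeric
#' start is supplied. At a fixed point `d = u'Zv = ||Zv||_2 >= 0`.
#'
#' @param Z p x q numeric cross-product matrix, nonzero.
#' @param c1,c2 L1 budgets for `u` (length p) and `v` (length q).
#' @param tol convergence tolerance on the max coordinate change.
#' @param max_iter sweep cap; non-convergence is flagged, not fatal.
#' @param init `"leading-right-singular"` or a numeric length-q start.
#' @return list `u`, `v`, `d`, `iterations`, `converged`.
#' @export
fit_component <- function(Z, c1, c2, tol = 1e-7, max_iter = 200L,
                          init = "leading-right-singular") {
  if (all(Z == 0)) stop("cross-product matrix is identically zero")
  if (is.numeric(init)) {
    v <- init
    if (length(v) != ncol(Z)) stop("init vector has wrong length")
    v <- v / sqrt(sum(v^2))
  } else {
    v <- svd(Z, nu = 0L, nv = 1L)$v[, 1L]
  }
  u <- rep(0, nrow(Z))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    u_new <- l1_constrained_unit(drop(Z %*% v), c1)
    v_new <- l1_constrained_unit(drop(crossprod(Z, u_new)), c2)
    delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
    u <- u_new; v <- v_new
    if (delta < tol) { converged <- TRUE; break }
  }
  d <- drop(crossprod(u, Z %*% v))
  if (d < 0) { v <- -v; d <- -d }  # cannot occur at a fixed point; guard only
  # reporting convention: largest-|u| entry positive, flipped jointly
  j <- which.max(abs(u))
  if (u[j] < 0) { u <- -u; v <- -v }
  list(u = u, v = v, d = d, iterations = it, converged = converged)
}

#' Sparse canonical correlation analysis by penalized matrix decomposition
#'
#' Computes up to `K` sparse component pairs of the cross-product
#' `Z = X'Y` of two column-standardized data blocks sharing samples.
#' Each component is fitted by [fit_component()]; the cross-product is then
#' deflated (`Z <- Z - d u v'`) so successive components are decorrelated.
#' Sample scores and their Pearson correlation are always computed against
#' the ORIGINAL (undeflated) `X` and `Y`, so they live in observable data
#' space.
#'
#' @param x,y `omics_matrix` objects (or matrices) with identical samples in
#'   identical order; columns should be standardized (see [standardize()]).
#' @param K number of components, `>= 1`.
#' @param c1,c2 L1 budgets; defaults are the unconstrained budgets
#'   `sqrt(p)`, `sqrt(q)`.
#' @param tol,max_iter,init passed to [fit_component()].
#' @return object of class `cca_fit`: list of `cca_component`s (fields
#'   `index`, `u`, `v`, `d`, `x_scores`, `y_scores`, `score_correlation`,
#'   `penalties`, `permutation_p`, `converged`) plus the penalties and the
#'   residual cross-product `Z_residual`.
#' @export
fit_sparse_cca <- function(x, y, K = 1L, c1 = NULL, c2 = NULL,
                           tol = 1e-7, max_iter = 200L,
                           init = "leading-right-singular") {
  x <- as_omics_matrix(x, "transformed"); y <- as_omics_matrix(y, "transformed")
  X <- x$values; Y <- y$values
  if (!identical(rownames(X), rownames(Y)))
    stop("x and y must contain the same samples in the same order")
  if (K < 1) stop("K must be >= 1")
  p <- ncol(X); q <- ncol(Y)
  if (is.null(c1)) c1 <- sqrt(p)
  if (is.null(c2)) c2 <- sqrt(q)

  Z <- crossprod(X, Y)
  components <- vector("list", K)
  for (k in seq_len(K)) {
    fit <- fit_component(Z, c1, c2, tol = tol, max_iter = max_iter,
                         init = init)
    Z <- Z - fit$d * tcrossprod(fit$u, fit$v)
    xs <- drop(X %*% fit$u); ys <- drop(Y %*% fit$v)
    r <- if (stats::sd(xs) > 0 && stats::sd(ys) > 0) stats::cor(xs, ys) else NA_real_
    components[[k]] <- structure(list(
      index = k,
      u = stats::setNames(fit$u, colnames(X)),
      v = stats::setNames(fit$v, colnames(Y)),
      d = fit$d,
      x_scores = stats::setNames(xs, rownames(X)),
      y_scores = stats::setNames(ys, rownames(Y)),
      score_correlation = r,
      penalties = c(c1 = c1, c2 = c2),
      permutation_p = NA_real_,
      converged = fit$converged
    ), class = "cca_component")
  }
  structure(list(components = components, c1 = c1, c2 = c2,
                 gene_ids = colnames(X), species_ids = colnames(Y),
                 sample_ids = rownames(X), Z_residual = Z),
            class = "cca_fit")
}

#' @export
print.cca_fit <- function(x, ...) {
  d <- vapply(x$components, `[[`, numeric(1), "d")
  r <- vapply(x$components, `[[`, numeric(1), "score_correlation")
  nz_u <- vapply(x$components, function(cc) sum(cc$u != 0), integer(1))
  nz_v <- vapply(x$components, function(cc) sum(cc$v != 0), integer(1))
  cat(sprintf("<cca_fit: %d component(s), c1=%.3g, c2=%.3g>\n",
              length(x$components), x$c1, x$c2))
  print(data.frame(component = seq_along(d), d = round(d, 4),
                   score_correlation = round(r, 4),
                   nonzero_genes = nz_u, nonzero_species = nz_v))
  invisible(x)
}

#' Tune L1 penalties by cross-validated held-out score correlation
#'
#' Penalties are parameterized as fractions of the feasible range:
#' `c = max(1, fraction * sqrt(dimension))`. For every grid cell the first
#' component is fitted on the training folds and scored by the absolute
#' Pearson correlation of the held-out sample scores. Degenerate held-out
#' scores (zero variance) contribute 0.
#'
#' The held-out correlation surface is typically near-flat across a wide
#' plateau of budgets once the informative features are covered, so the
#' plain argmax is decided by fold noise and drifts towards denser, less
#' interpretable solutions. The default selection rule is therefore the
#' paired one-standard-error parsimony rule: among all cells whose per-fold
#' criterion deficit to the best cell is within one standard error of that
#' paired difference (every cell is evaluated on the same folds, so the
#' paired deficit is the relevant noise scale), pick the sparsest (smallest
#' `c1 + c2` fraction sum, then smallest `c1` fraction). `rule = "max"`
#' restores the plain argmax with sparser-tie-breaking.
#'
#' @param x,y standardized data blocks sharing samples.
#' @param c1_fractions,c2_fractions candidate fractions in `(0, 1]`.
#' @param folds number of cross-validation folds (>= 2; every fold must
#'   leave >= 3 training samples).
#' @param seed integer seed for the fold assignment.
#' @param rule `"paired_1se"` (default) or `"max"`.
#' @param tol,max_iter passed to [fit_component()].
#' @return list `c1`, `c2` (selected budgets), `c1_fraction`,
#'   `c2_fraction`, `criterion` (the grid of mean held-out |r|), and
#'   `rule`.
#' @export
tune_penalties <- function(x, y,
                           c1_fractions = seq(0.1, 1, by = 0.1),
                           c2_fractions = seq(0.1, 1, by = 0.1),
                           folds = 5L, seed = 1,
                           rule = c("paired_1se", "max"),
                           tol = 1e-6, max_iter = 100L) {
  rule <- match.arg(rule)
  x <- as_omics_matrix(x, "transformed"); y <- as_omics_matrix(y, "transformed")
  X <- x$values; Y <- y$values
  if (!identical(rownames(X), rownames(Y))) stop("sample mismatch")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (folds < 2) stop("folds must be >= 2")
  if (n - ceiling(n / folds) < 3) stop("each fold must retain >= 3 training samples")

  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  # training cross-products are reused across all grid cells
  Z_train <- lapply(seq_len(folds), function(f)
    crossprod(X[fold_id != f, , drop = FALSE], Y[fold_id != f, , drop = FALSE]))

  per_fold <- array(0, c(length(c1_fractions), length(c2_fractions), folds),
                    dimnames = list(c1_fractions, c2_fractions, NULL))
  for (i in seq_along(c1_fractions)) {
    c1 <- max(1, c1_fractions[i] * sqrt(p))
    for (j in seq_along(c2_fractions)) {
      c2 <- max(1, c2_fractions[j] * sqrt(q))
      per_fold[i, j, ] <- vapply(seq_len(folds), function(f) {
        fit <- fit_component(Z_train[[f]], c1, c2, tol = tol,
                             max_iter = max_iter)
        te <- fold_id == f
        xs <- drop(X[te, , drop = FALSE] %*% fit$u)
        ys <- drop(Y[te, , drop = FALSE] %*% fit$v)
        if (length(xs) < 2 || stats::sd(xs) == 0 || stats::sd(ys) == 0)
          return(0)
        abs(stats::cor(xs, ys))
      }, numeric(1))
    }
  }
  crit <- apply(per_fold, c(1, 2), mean)
  bi <- which(crit == max(crit), arr.ind = TRUE)[1, , drop = TRUE]
  if (rule == "paired_1se") {
    best_folds <- per_fold[bi[1], bi[2], ]
    ok <- matrix(FALSE, length(c1_fractions), length(c2_fractions))
    for (i in seq_along(c1_fractions)) {
      for (j in seq_along(c2_fractions)) {
        d <- best_folds - per_fold[i, j, ]
        ok[i, j] <- mean(d) <= stats::sd(d) / sqrt(folds) + 1e-12
      }
    }
    cand <- which(ok, arr.ind = TRUE)
  } else {
    cand <- which(crit >= max(crit) - 1e-12, arr.ind = TRUE)
  }
  sums <- c1_fractions[cand[, 1]] + c2_fractions[cand[, 2]]
  cand <- cand[order(sums, c1_fractions[cand[, 1]]), , drop = FALSE]
  i <- cand[1, 1]; j <- cand[1, 2]
  list(c1 = max(1, c1_fractions[i] * sqrt(p)),
       c2 = max(1, c2_fractions[j] * sqrt(q)),
       c1_fraction = c1_fractions[i], c2_fraction = c2_fractions[j],
       criterion = crit, rule = rule)
}

#' Permutation test for the number of canonical components
#'
#' Builds the null distribution of each singular value `d_k` by re-fitting
#' the full deflated sequence on row-permuted `Y`, breaking the
#' sample pairing while preserving both marginal structures. The add-one
#' permutation p-value is `p_k = (1 + #{null d_k >= observed d_k}) /
#' (1 + n_perm)`; the retained component count is the largest `K` whose
#' first `K` p-values are all below `alpha` (sequential stopping).
#'
#' @param x,y standardized data blocks sharing samples.
#' @param K_max components to test.
#' @param n_perm number of permutations (>= 19).
#' @param c1,c2 L1 budgets (defaults: unconstrained).
#' @param alpha significance level for the sequential rule.
#' @param seed integer seed for the permutations.
#' @param tol,max_iter passed to the component fits.
#' @return list `p_values` (length `K_max`), `retained_K`, `observed_d`,
#'   `null_d` (`n_perm x K_max`), `alpha`.
#' @export
permutation_component_test <- function(x, y, K_max = 5L, n_perm = 99L,
                                       c1 = NULL, c2 = NULL, alpha = 0.05,
                                       seed = 1, tol = 1e-6,
                                       max_iter = 100L) {
  if (n_perm < 19) stop("n_perm must be >= 19")
  x <- as_omics_matrix(x, "transformed"); y <- as_omics_matrix(y, "transformed")
  X <- x$values; Y <- y$values
  if (!identical(rownames(X), rownames(Y))) stop("sample mismatch")
  n <- nrow(X)
  if (is.null(c1)) c1 <- sqrt(ncol(X))
  if (is.null(c2)) c2 <- sqrt(ncol(Y))

  d_sequence <- function(Xm, Ym) {
    Z <- crossprod(Xm, Ym)
    vapply(seq_len(K_max), function(k) {
      fit <- fit_component(Z, c1, c2, tol = tol, max_iter = max_iter)
      Z <<- Z - fit$d * tcrossprod(fit$u, fit$v)
      fit$d
    }, numeric(1))
  }

  observed <- d_sequence(X, Y)
  null_d <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      d_sequence(X, Y[sample.int(n), , drop = FALSE])
    }, numeric(K_max)))
  })
  null_d <- matrix(null_d, nrow = n_perm, ncol = K_max)
  p <- vapply(seq_len(K_max), function(k)
    (1 + sum(null_d[, k] >= observed[k])) / (1 + n_perm), numeric(1))
  below <- p < alpha
  retained <- if (all(below)) K_max else which.min(below) - 1L
  list(p_values = p, retained_K = as.integer(retained),
       observed_d = observed, null_d = null_d, alpha = alpha)
}

#' Spearman correlation of component scores with clinical variables
#'
#' For every (component, variable) pair: Spearman rho on average-ranked data
#' between the component's sample scores and the clinical variable, p-value
#' by the two-sided t-approximation, missing values dropped pairwise
#' (at least 4 complete pairs required).
#'
#' @param fit a `cca_fit` (or plain list of `cca_component`s).
#' @param clinical data.frame with a `sample_id` column covering all scored
#'   samples.
#' @param variables clinical column names to correlate.
#' @param scores which score side to use: `"x"` (gene side, default) or
#'   `"y"` (species side).
#' @return data.frame `component`, `variable`, `spearman_rho`, `p_value`,
#'   `n`.
#' @export
correlate_scores_clinical <- function(fit, clinical, variables,
                                      scores = c("x", "y")) {
  scores <- match.arg(scores)
  comps <- if (inherits(fit, "cca_fit")) fit$components else fit
  if (!"sample_id" %in% names(clinical))
    stop("clinical table needs a 'sample_id' column")
  missing_vars <- setdiff(variables, names(clinical))
  if (length(missing_vars))
    stop("unknown clinical variable(s): ", paste(missing_vars, collapse = ", "))
  out <- list()
  for (cc in comps) {
    sc <- if (scores == "x") cc$x_scores else cc$y_scores
    idx <- match(names(sc), clinical$sample_id)
    if (anyNA(idx)) stop("clinical table does not cover all scored samples")
    for (v in variables) {
      st <- spearman_test(sc, clinical[[v]][idx])
      out[[length(out) + 1L]] <- data.frame(
        component = cc$index, variable = v,
        spearman_rho = st$rho, p_value = st$p_value, n = st$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a fitted sparse CCA as TSV tables
#'
#' Emits one weight table per side (`feature_id` plus one column per
#' component), one score table (`sample_id` plus per-component x/y scores)
#' and one summary table (`d`, score correlation, permutation p, penalties).
#'
#' @param fit a `cca_fit`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_cca_tsv <- function(fit, dir, prefix = "cca") {
  stopifnot(inherits(fit, "cca_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- length(fit$components)
  kn <- paste0("component_", seq_len(K))
  U <- sapply(fit$components, `[[`, "u")
  V <- sapply(fit$components, `[[`, "v")
  colnames(U) <- colnames(V) <- kn
  paths <- c(
    file.path(dir, paste0(prefix, "_gene_weights.tsv")),
    file.path(dir, paste0(prefix, "_species_weights.tsv")),
    file.path(dir, paste0(prefix, "_scores.tsv")),
    file.path(dir, paste0(prefix, "_summary.tsv")))
  write_tsv(data.frame(feature_id = fit$gene_ids, U,
                       check.names = FALSE), paths[1])
  write_tsv(data.frame(feature_id = fit$species_ids, V,
                       check.names = FALSE), paths[2])
  sc <- data.frame(sample_id = fit$sample_ids, check.names = FALSE)
  for (k in seq_len(K)) {
    sc[[paste0("x_", kn[k])]] <- fit$components[[k]]$x_scores
    sc[[paste0("y_", kn[k])]] <- fit$components[[k]]$y_scores
  }
  write_tsv(sc, paths[3])
  write_tsv(data.frame(
    component = seq_len(K),
    d = vapply(fit$components, `[[`, numeric(1), "d"),
    score_correlation = vapply(fit$components, `[[`, numeric(1),
                               "score_correlation"),
    permutation_p = vapply(fit$components, `[[`, numeric(1),
                           "permutation_p"),
    c1 = fit$c1, c2 = fit$c2), paths[4])
  invisible(paths)
}
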