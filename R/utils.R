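# internal helpers shared across modules

# run expr under a local RNG state; caller's .Random.seed is untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# column variances with the usual n-1 denominator
col_vars <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows to compute variances")
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

# Spearman rho with average ranks and two-sided t-approximation p-value;
# missing values dropped pairwise
spearman_test <- function(x, y, min_n = 4L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n)
    stop(sprintf("need at least %d paired observations, got %d", min_n, n))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant ranks: Spearman correlation undefined")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  list(rho = rho, p_value = min(p, 1), n = n)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
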