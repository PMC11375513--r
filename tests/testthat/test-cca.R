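test_that("soft threshold matches its definition and limits", {
  expect_equal(soft_threshold(c(3, -1, 0.5), 1), c(2, 0, 0))
  a <- c(-2.5, 0.3, 1.1, 0)
  expect_equal(soft_threshold(a, 0), a)
  expect_equal(soft_threshold(a, max(abs(a))), rep(0, 4))
  expect_error(soft_threshold(a, -0.1), "non-negative")
})

test_that("L1-budgeted unit projection handles closed-form cases", {
  u <- l1_constrained_unit(c(1, 1), sqrt(2))
  expect_equal(u, c(1, 1) / sqrt(2), tolerance = 1e-8)
  # c = 1 forces a single surviving coordinate
  expect_equal(l1_constrained_unit(c(2, 1), 1), c(1, 0), tolerance = 1e-6)
  # inactive budget returns the plain unit vector
  set.seed(1)
  a <- rnorm(30)
  expect_equal(l1_constrained_unit(a, sqrt(30)), a / sqrt(sum(a^2)))
  expect_error(l1_constrained_unit(rep(0, 4), 1.5), "all zero")
})

test_that("bisection agrees with a fine delta-grid oracle on random inputs", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(5:40, 1))
    cc <- runif(1, 1, sqrt(length(a)))
    u <- l1_constrained_unit(a, cc)
    expect_lte(sum(u^2), 1 + 1e-8)
    expect_lte(sum(abs(u)), cc + 1e-6)
    # oracle: dense delta grid; the achieved objective a'u must be maximal
    deltas <- seq(0, max(abs(a)) * 0.999, length.out = 4000)
    obj <- vapply(deltas, function(d) {
      s <- soft_threshold(a, d)
      n2 <- sqrt(sum(s^2))
      if (n2 == 0) return(-Inf)
      v <- s / n2
      if (sum(abs(v)) > cc + 1e-6) return(-Inf)
      sum(a * v)
    }, numeric(1))
    expect_gte(sum(a * u), max(obj) - 1e-4)
  }
})

test_that("a noiseless rank-one cross-product is recovered exactly", {
  set.seed(2)
  u0 <- rnorm(25); u0 <- u0 / sqrt(sum(u0^2))
  v0 <- rnorm(12); v0 <- v0 / sqrt(sum(v0^2))
  Z <- 3.7 * tcrossprod(u0, v0)
  fit <- fit_component(Z, sqrt(25), sqrt(12))
  expect_true(fit$converged)
  expect_equal(fit$d, 3.7, tolerance = 1e-6)
  expect_equal(abs(sum(fit$u * u0)), 1, tolerance = 1e-6)
  expect_equal(abs(sum(fit$v * v0)), 1, tolerance = 1e-6)
})

test_that("inactive penalties reproduce the leading singular triple", {
  set.seed(3)
  Z <- matrix(rnorm(600), 30, 20)
  sv <- svd(Z)
  fit <- fit_component(Z, sqrt(30), sqrt(20), tol = 1e-10, max_iter = 500)
  expect_equal(fit$d, sv$d[1], tolerance = 1e-6)
  expect_equal(abs(sum(fit$u * sv$u[, 1])), 1, tolerance = 1e-6)
  expect_equal(abs(sum(fit$v * sv$v[, 1])), 1, tolerance = 1e-6)
})

test_that("deflation reconstructs the original cross-product exactly", {
  blocks <- rand_std_blocks(25, 15, 10, seed = 4)
  K <- 5
  fit <- fit_sparse_cca(blocks$x, blocks$y, K = K, c1 = 2.5, c2 = 2)
  Z1 <- crossprod(blocks$x$values, blocks$y$values)
  recon <- Reduce(`+`, lapply(fit$components, function(cc)
    cc$d * tcrossprod(cc$u, cc$v)))
  expect_lt(max(abs(Z1 - (recon + fit$Z_residual))), 1e-10)
})

test_that("K = 1 sparse CCA equals a single component fit", {
  blocks <- rand_std_blocks(20, 12, 8, seed = 5)
  Z <- crossprod(blocks$x$values, blocks$y$values)
  single <- fit_component(Z, 2, 2)
  fit <- fit_sparse_cca(blocks$x, blocks$y, K = 1, c1 = 2, c2 = 2)
  expect_equal(unname(fit$components[[1]]$u), unname(single$u))
  expect_equal(unname(fit$components[[1]]$v), unname(single$v))
  expect_equal(fit$components[[1]]$d, single$d)
})

test_that("components of two orthogonally planted factors stay decorrelated", {
  set.seed(6)
  reps <- replicate(5, {
    seed <- sample.int(1e6, 1)
    sim <- generate_paired_omics(100, 120, 40, 2, c(12, 6), 4, 1, seed = seed)
    x <- standardize(sim$expression)
    y <- standardize(clr_transform(sim$abundance))
    fit <- fit_sparse_cca(x, y, K = 2, c1 = 0.3 * sqrt(120),
                          c2 = 0.4 * sqrt(40))
    abs(cor(fit$components[[1]]$x_scores, fit$components[[2]]$x_scores))
  })
  expect_lt(mean(reps), 0.2)
})

test_that("fitted components always satisfy their norm and budget invariants", {
  set.seed(8)
  for (i in 1:15) {
    n <- sample(10:30, 1); p <- sample(5:25, 1); q <- sample(5:20, 1)
    blocks <- rand_std_blocks(n, p, q, seed = i * 100)
    c1 <- runif(1, 1, sqrt(p)); c2 <- runif(1, 1, sqrt(q))
    fit <- fit_sparse_cca(blocks$x, blocks$y, K = 2, c1 = c1, c2 = c2)
    for (cc in fit$components) {
      expect_lte(sum(cc$u^2), 1 + 1e-8)
      expect_lte(sum(cc$v^2), 1 + 1e-8)
      expect_lte(sum(abs(cc$u)), c1 + 1e-6)
      expect_lte(sum(abs(cc$v)), c2 + 1e-6)
      expect_gte(cc$d, 0)
    }
  }
})

test_that("penalty tuning returns the only cell of a singleton grid", {
  blocks <- rand_std_blocks(20, 10, 8, seed = 9)
  tn <- tune_penalties(blocks$x, blocks$y, c1_fractions = 0.5,
                       c2_fractions = 0.4, folds = 4, seed = 1)
  expect_equal(tn$c1_fraction, 0.5)
  expect_equal(tn$c2_fraction, 0.4)
  expect_equal(tn$c1, 0.5 * sqrt(10))
})

test_that("tuning picks a sparse budget when signal sits on a small support", {
  sim <- generate_paired_omics(100, 200, 50, 1, c(10, 6), 4, 1, seed = 10)
  x <- standardize(sim$expression)
  y <- standardize(clr_transform(sim$abundance))
  tn <- tune_penalties(x, y, seed = 1)
  expect_lte(tn$c1_fraction, 0.5)
})

test_that("permutation p-values follow the add-one formula at n_perm = 19", {
  sim <- generate_paired_omics(60, 40, 20, 1, c(8, 5), 6, 0.5, seed = 11)
  x <- standardize(sim$expression)
  y <- standardize(clr_transform(sim$abundance))
  pt <- permutation_component_test(x, y, K_max = 1, n_perm = 19, seed = 2)
  # signal is overwhelming: observed d beats every permuted d
  expect_true(all(pt$null_d[, 1] < pt$observed_d[1]))
  expect_equal(pt$p_values[1], 1 / 20)
  # the floor p of 19 permutations is exactly alpha, so the strict
  # sequential rule cannot retain the component at alpha = 0.05 ...
  expect_identical(pt$retained_K, 0L)
  # ... but does at any alpha above the add-one floor
  pt2 <- permutation_component_test(x, y, K_max = 1, n_perm = 19,
                                    alpha = 0.051, seed = 2)
  expect_identical(pt2$retained_K, 1L)
})

test_that("score-clinical Spearman matches the hand-computed example", {
  # rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d^2 = (1,1,1,1,0):
  # 1 - 24/120 = 0.8
  st <- microcca:::spearman_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(st$rho, 0.8, tolerance = 1e-12)
  ct <- suppressWarnings(
    cor.test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5), method = "spearman"))
  expect_equal(st$rho, unname(ct$estimate), tolerance = 1e-12)
})

test_that("component-clinical correlation handles monotone, reversed and short inputs", {
  blocks <- rand_std_blocks(12, 8, 6, seed = 12)
  fit <- fit_sparse_cca(blocks$x, blocks$y, K = 1, c1 = 2, c2 = 2)
  xs <- fit$components[[1]]$x_scores
  clin <- data.frame(sample_id = names(xs),
                     up = rank(xs)^3,          # monotone transform
                     down = -xs,
                     stringsAsFactors = FALSE)
  tab <- correlate_scores_clinical(fit, clin, c("up", "down"))
  expect_equal(tab$spearman_rho[tab$variable == "up"], 1)
  expect_equal(tab$spearman_rho[tab$variable == "down"], -1)
  short <- clin[1:3, ]
  fit3 <- fit
  fit3$components[[1]]$x_scores <- xs[1:3]
  expect_error(correlate_scores_clinical(fit3, short, "up"), "at least 4")
})

test_that("CCA tables round-trip through the TSV writer", {
  blocks <- rand_std_blocks(15, 10, 6, seed = 13)
  fit <- fit_sparse_cca(blocks$x, blocks$y, K = 2, c1 = 2, c2 = 2)
  dir <- withr::local_tempdir()
  paths <- write_cca_tsv(fit, dir)
  expect_true(all(file.exists(paths)))
  w <- read.delim(paths[1])
  expect_equal(w$component_1, unname(fit$components[[1]]$u), tolerance = 1e-10)
})
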