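#' Generate paired expression/abundance matrices with planted sparse
#' canonical components
#'
#' Emulates a paired sputum transcriptome + metagenome design: both data
#' blocks share `k_latent` latent per-sample scores, each loading onto a
#' small disjoint block of genes and of species. Expression is built on a
#' log2-microarray-like scale as gene-specific baseline + rank-one planted
#' signal + Gaussian noise. Abundance is built the same way on a latent log
#' scale and then pushed through a per-sample softmax, so every row is a
#' strictly positive composition summing to 1.
#'
#' Latent scores are orthogonalized after sampling (centered QR), so planted
#' components are mutually uncorrelated by construction. Supports of
#' different components are disjoint on both axes, which keeps
#' support-recovery scoring unambiguous.
#'
#' @param n_samples number of samples (>= 10).
#' @param p_genes,q_species feature-axis dimensions.
#' @param k_latent number of planted components.
#' @param support_size genes and species per component; a single count used
#'   for both axes, or a length-2 vector `c(genes, species)`.
#' @param signal_sd scale of the planted weights: supported features load
#'   with magnitude `signal_sd * U(0.5, 1.5)`, so `signal_sd / noise_sd` is
#'   the nominal per-feature SNR.
#' @param noise_sd Gaussian noise standard deviation.
#' @param gene_weight_signs `"positive"` (default) plants a coherent gene
#'   program per component — all supported genes rise with the latent score,
#'   as a co-regulated pathway would — so rank-based set scores of the
#'   support track the score; `"mixed"` randomizes signs. Species weights
#'   are always mixed-sign (taxa may rise or fall with the shared factor).
#' @param seed integer seed; identical seeds reproduce output exactly.
#'
#' @return list with elements `expression` (omics_matrix, log2 scale),
#'   `abundance` (omics_matrix on the simplex) and `truth`
#'   (`synthetic_truth`: supports, weights, latent scores, parameters).
#' @export
#' @examples
#' sim <- generate_paired_omics(n_samples = 30, p_genes = 60, q_species = 25,
#'                              k_latent = 2, support_size = c(8, 5),
#'                              signal_sd = 3, noise_sd = 1, seed = 1)
#' rowSums(sim$abundance$values)[1:3]
generate_paired_omics <- function(n_samples = 100, p_genes = 500,
                                  q_species = 80, k_latent = 2,
                                  support_size = c(20, 10),
                                  signal_sd = 3, noise_sd = 1,
                                  gene_weight_signs = c("positive", "mixed"),
                                  seed = 1) {
  gene_weight_signs <- match.arg(gene_weight_signs)
  if (n_samples < 10) stop("n_samples must be >= 10")
  if (p_genes < 1 || q_species < 1 || k_latent < 0)
    stop("dimensions must be positive")
  if (signal_sd < 0 || noise_sd <= 0)
    stop("signal_sd must be >= 0 and noise_sd > 0")
  support_size <- rep_len(as.integer(support_size), 2L)
  sg <- support_size[1L]; ss <- support_size[2L]
  if (k_latent * sg > p_genes || k_latent * ss > q_species)
    stop("disjoint supports do not fit: k_latent * support_size exceeds dimension")

  with_seed(seed, {
    sample_names <- sprintf("S%03d", seq_len(n_samples))
    gene_names <- sprintf("g%04d", seq_len(p_genes))
    species_names <- sprintf("sp%03d", seq_len(q_species))

    # latent scores: centered, orthogonalized, unit variance
    if (k_latent > 0) {
      Z <- matrix(stats::rnorm(n_samples * k_latent), n_samples, k_latent)
      Z <- scale(Z, center = TRUE, scale = FALSE)
      Z <- qr.Q(qr(Z)) * sqrt(n_samples - 1)
      dimnames(Z) <- list(sample_names, paste0("z", seq_len(k_latent)))
    } else {
      Z <- matrix(0, n_samples, 0, dimnames = list(sample_names, NULL))
    }

    pick_supports <- function(p, size) {
      idx <- sample.int(p, k_latent * size)
      split(idx, rep(seq_len(max(k_latent, 1L)), each = size))[seq_len(k_latent)]
    }
    gene_supports <- if (k_latent > 0) pick_supports(p_genes, sg) else list()
    species_supports <- if (k_latent > 0) pick_supports(q_species, ss) else list()

    planted_weights <- function(p, supports, signs) {
      W <- matrix(0, p, k_latent)
      for (k in seq_len(k_latent)) {
        m <- length(supports[[k]])
        sgn <- if (signs == "mixed") sample(c(-1, 1), m, replace = TRUE)
               else rep(1, m)
        W[supports[[k]], k] <- signal_sd * sgn * stats::runif(m, 0.5, 1.5)
      }
      W
    }
    Wg <- planted_weights(p_genes, gene_supports, gene_weight_signs)
    Ws <- planted_weights(q_species, species_supports, "mixed")

    gene_means <- stats::rnorm(p_genes, mean = 6, sd = 2)
    expr <- matrix(rep(gene_means, each = n_samples), n_samples, p_genes) +
      Z %*% t(Wg) +
      matrix(stats::rnorm(n_samples * p_genes, sd = noise_sd),
             n_samples, p_genes)
    dimnames(expr) <- list(sample_names, gene_names)

    species_means <- stats::rnorm(q_species, mean = 0, sd = 2)
    latent_log <- matrix(rep(species_means, each = n_samples),
                         n_samples, q_species) +
      Z %*% t(Ws) +
      matrix(stats::rnorm(n_samples * q_species, sd = noise_sd),
             n_samples, q_species)
    # row-wise softmax, guarded against overflow
    latent_log <- latent_log - apply(latent_log, 1L, max)
    abun <- exp(latent_log)
    abun <- abun / rowSums(abun)
    dimnames(abun) <- list(sample_names, species_names)

    truth <- structure(list(
      k_latent = k_latent,
      gene_supports = gene_supports,
      species_supports = species_supports,
      gene_weights = Wg,
      species_weights = Ws,
      latent_scores = Z,
      gene_ids = gene_names,
      species_ids = species_names,
      signal_sd = signal_sd,
      noise_sd = noise_sd,
      clinical_link = NULL,
      seed = seed
    ), class = "synthetic_truth")

    list(expression = omics_matrix(expr, "expression"),
         abundance = omics_matrix(abun, "abundance"),
         truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth: %d samples, %d components, seed %d>\n",
              nrow(x$latent_scores), x$k_latent, x$seed))
  invisible(x)
}

#' Generate clinical covariates linked to planted latent scores
#'
#' Each linked variable is `coefficient * z_k + noise`, then mapped onto the
#' 0-100 percent range through a monotone (rank-preserving) probit transform
#' `100 * pnorm(standardized value)`, mimicking sputum granulocyte
#' percentages. Group labels split the cohort in two (first `ceiling(n/2)`
#' samples early-onset, rest late-onset, overridable), mirroring an
#' age-of-onset dichotomy.
#'
#' @param truth a `synthetic_truth`.
#' @param links named list: variable name -> `c(component, coefficient)`
#'   (1-based component index into the planted scores).
#' @param noise_sd noise added before the monotone transform.
#' @param seed integer seed.
#' @param group_labels optional character vector of per-sample labels.
#' @return data.frame with `sample_id`, `group` and one column per linked
#'   variable, with the link map stored in `attr(, "links")`.
#' @export
generate_clinical <- function(truth,
                              links = list(
                                sputum_neutrophil_pct = c(1, 2),
                                sputum_eosinophil_pct = c(2, 2)),
                              noise_sd = 1, seed = 1,
                              group_labels = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- nrow(truth$latent_scores)
  for (nm in names(links)) {
    k <- links[[nm]][1L]
    if (k < 1 || k > truth$k_latent)
      stop(sprintf("link '%s' references component %d but only %d planted",
                   nm, k, truth$k_latent))
  }
  if (is.null(group_labels)) {
    n_eo <- ceiling(n / 2)
    group_labels <- rep(c("EO", "LO"), c(n_eo, n - n_eo))
  }
  if (length(group_labels) != n) stop("group_labels length mismatch")

  with_seed(seed, {
    df <- data.frame(sample_id = rownames(truth$latent_scores),
                     group = group_labels,
                     stringsAsFactors = FALSE)
    for (nm in names(links)) {
      k <- links[[nm]][1L]; beta <- links[[nm]][2L]
      raw <- beta * truth$latent_scores[, k] + stats::rnorm(n, sd = noise_sd)
      s <- stats::sd(raw)
      z <- if (s > 0) (raw - mean(raw)) / s else raw * 0
      df[[nm]] <- 100 * stats::pnorm(z)
    }
    attr(df, "links") <- links
    df
  })
}

#' Generate a gene-set collection overlapping planted supports
#'
#' Builds one "planted" set per latent component whose members are drawn
#' from that component's gene support (a fraction `overlap_fraction` of the
#' set) topped up with decoys, plus purely random decoy sets drawn uniformly
#' from the gene universe. Planted sets should test enriched downstream when
#' the sparse CCA recovers the support; decoys calibrate the null.
#'
#' @param truth a `synthetic_truth`.
#' @param n_sets total number of sets (planted sets count towards this).
#' @param set_size genes per set.
#' @param overlap_fraction fraction of each planted set drawn from the
#'   corresponding gene support (0-1).
#' @param decoy_universe number of genes (taken from the start of the truth
#'   gene axis) decoys are drawn from; defaults to all genes.
#' @param seed integer seed.
#' @return a `gene_set_collection`.
#' @export
generate_genesets <- function(truth, n_sets = 50, set_size = 15,
                              overlap_fraction = 0.8,
                              decoy_universe = NULL, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  universe <- truth$gene_ids
  if (!is.null(decoy_universe)) {
    if (decoy_universe > length(universe))
      stop("decoy_universe larger than the gene axis")
    universe <- universe[seq_len(decoy_universe)]
  }
  if (set_size > length(universe))
    stop("set_size exceeds the gene universe")
  if (n_sets == 0)
    return(gene_set_collection(list(), source = "synthetic"))

  with_seed(seed, {
    sets <- list(); descs <- character()
    n_planted <- if (overlap_fraction > 0) min(truth$k_latent, n_sets) else 0L
    for (k in seq_len(n_planted)) {
      support_genes <- truth$gene_ids[truth$gene_supports[[k]]]
      n_from <- min(round(overlap_fraction * set_size), length(support_genes))
      members <- sample(support_genes, n_from)
      pool <- setdiff(universe, support_genes)
      if (set_size - n_from > 0)
        members <- c(members, sample(pool, set_size - n_from))
      nm <- sprintf("PLANTED_C%d", k)
      sets[[nm]] <- sort(members)
      descs[nm] <- sprintf("seeded from component %d support", k)
    }
    for (j in seq_len(n_sets - n_planted)) {
      nm <- sprintf("DECOY_%03d", j)
      sets[[nm]] <- sort(sample(universe, set_size))
      descs[nm] <- "uniform decoy set"
    }
    gene_set_collection(sets, descriptions = descs, source = "synthetic")
  })
}

#' Write synthetic truth as a JSON sidecar
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- list(
    k_latent = truth$k_latent,
    gene_supports = lapply(truth$gene_supports, as.integer),
    species_supports = lapply(truth$species_supports, as.integer),
    latent_scores = truth$latent_scores,
    signal_sd = truth$signal_sd,
    noise_sd = truth$noise_sd,
    seed = truth$seed
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
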