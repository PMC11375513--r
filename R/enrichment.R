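#' Genes selected by a canonical component
#'
#' The lasso already performs selection, so the default rule returns every
#' gene with a nonzero weight. The `top_n` rule returns the `n` largest by
#' absolute weight among the nonzero genes (no padding when fewer are
#' available), with a deterministic lexicographic tie-break on gene id.
#'
#' @param component a `cca_component`.
#' @param rule `"nonzero"` or `"top_n"`.
#' @param n set size for `top_n`.
#' @return character vector of gene ids.
#' @export
component_gene_set <- function(component, rule = c("nonzero", "top_n"),
                               n = NULL) {
  rule <- match.arg(rule)
  u <- component$u
  nz <- u[u != 0]
  if (length(nz) == 0) stop("component has an all-zero gene weight vector")
  if (rule == "nonzero") return(sort(names(nz)))
  if (is.null(n)) stop("rule 'top_n' requires n")
  ord <- order(-abs(nz), names(nz))
  names(nz)[ord][seq_len(min(n, length(nz)))]
}

#' One-sided Fisher's exact (hypergeometric) enrichment test
#'
#' Tail probability `P(overlap >= observed)` for the 2x2 table crossing
#' selected-gene membership with pathway membership over a finite universe.
#' The pathway is intersected with the universe before testing; the selected
#' set must be contained in the universe.
#'
#' @param selected character vector of selected gene ids (subset of
#'   `universe`).
#' @param pathway character vector of pathway member ids.
#' @param universe character vector: the background gene list (here, all
#'   genes that entered the sparse CCA after filtering).
#' @return list `n_overlap`, `p_value`, `n_selected`,
#'   `n_pathway_in_universe`.
#' @export
fisher_enrichment <- function(selected, pathway, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  selected <- unique(selected)
  if (length(selected) == 0) stop("empty selected set")
  if (length(setdiff(selected, universe)))
    stop("selected genes must be contained in the universe")
  path_u <- intersect(unique(pathway), universe)
  k <- length(intersect(selected, path_u))
  K <- length(path_u); s <- length(selected)
  list(n_overlap = k, p_value = hyper_tail(k, K, N, s),
       n_selected = s, n_pathway_in_universe = K)
}

# upper-tail P(overlap >= k) for a 2x2 table over a universe of size N;
# vectorized over k/K/s (the computational core of fisher_enrichment)
hyper_tail <- function(k, K, N, s) {
  p <- stats::phyper(k - 1, K, N - K, s, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Pathway enrichment of every component in a fit
#'
#' Applies [fisher_enrichment()] to each (component, pathway) pair. The raw
#' `p < alpha` flag mirrors the conventional uncorrected reporting threshold
#' for component-level pathway calls; a BH-adjusted column is emitted
#' alongside for stricter use.
#'
#' @param fit a `cca_fit` (or list of `cca_component`s).
#' @param genesets a `gene_set_collection`.
#' @param universe background gene ids; defaults to the fit's gene axis.
#' @param phenotype label attached to every record (e.g. `"EO"`, `"LO"`).
#' @param component_ids optional display names (default `<phenotype>C<k>`).
#' @param rule,n passed to [component_gene_set()].
#' @param alpha enrichment call threshold on the raw p-value.
#' @return data.frame of enrichment records: `component`, `pathway`,
#'   `n_selected`, `n_pathway_in_universe`, `n_overlap`, `p_value`,
#'   `adjusted_p`, `enriched`, `phenotype`.
#' @export
enrich_components <- function(fit, genesets, universe = NULL,
                              phenotype = "all", component_ids = NULL,
                              rule = "nonzero", n = NULL, alpha = 0.05) {
  comps <- if (inherits(fit, "cca_fit")) fit$components else fit
  stopifnot(inherits(genesets, "gene_set_collection"))
  if (is.null(universe)) {
    if (!inherits(fit, "cca_fit"))
      stop("universe required when passing bare components")
    universe <- fit$gene_ids
  }
  if (is.null(component_ids))
    component_ids <- paste0(phenotype, "C",
                            vapply(comps, `[[`, integer(1), "index"))
  out <- list()
  for (i in seq_along(comps)) {
    sel <- intersect(component_gene_set(comps[[i]], rule = rule, n = n),
                     universe)
    for (nm in names(genesets$sets)) {
      fe <- fisher_enrichment(sel, genesets$sets[[nm]], universe)
      out[[length(out) + 1L]] <- data.frame(
        component = component_ids[i], pathway = nm,
        n_selected = fe$n_selected,
        n_pathway_in_universe = fe$n_pathway_in_universe,
        n_overlap = fe$n_overlap, p_value = fe$p_value,
        phenotype = phenotype, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res$enriched <- res$p_value < alpha
  res[, c("component", "pathway", "n_selected", "n_pathway_in_universe",
          "n_overlap", "p_value", "adjusted_p", "enriched", "phenotype")]
}

#' Classify enriched pathways as shared or phenotype-specific
#'
#' A pathway is `shared` when enriched in at least one component of both
#' phenotypes, `EO-only` / `LO-only` when enriched in components of exactly
#' one. Pathways enriched nowhere are absent from the output, so the
#' categories partition the enriched-pathway union.
#'
#' @param eo_records,lo_records enrichment record data.frames (see
#'   [enrich_components()]) for the two phenotypes.
#' @param eo_label,lo_label phenotype names used in the category labels.
#' @return data.frame `pathway`, `category`.
#' @export
classify_shared_unique <- function(eo_records, lo_records,
                                   eo_label = "EO", lo_label = "LO") {
  enriched_in <- function(rec) {
    if (is.null(rec) || nrow(rec) == 0) return(character())
    unique(rec$pathway[rec$enriched])
  }
  eo <- enriched_in(eo_records); lo <- enriched_in(lo_records)
  all_p <- union(eo, lo)
  if (length(all_p) == 0)
    return(data.frame(pathway = character(), category = character(),
                      stringsAsFactors = FALSE))
  category <- ifelse(all_p %in% eo & all_p %in% lo, "shared",
                     ifelse(all_p %in% eo, paste0(eo_label, "-only"),
                            paste0(lo_label, "-only")))
  data.frame(pathway = all_p, category = category,
             stringsAsFactors = FALSE)[order(all_p), ]
}

#' Link species to the pathways enriched in their components
#'
#' A species is linked to every pathway called enriched in any component
#' where that species carries a nonzero weight — the component couples the
#' species to the gene program the pathway describes.
#'
#' @param fit a `cca_fit` (or list of `cca_component`s).
#' @param records enrichment records for those components (the `component`
#'   ids must follow the same naming as in [enrich_components()]).
#' @param component_ids display names matching `records$component`.
#' @param phenotype label carried into the output.
#' @return data.frame `species`, `pathway`, `component`, `phenotype` (zero
#'   rows when nothing is enriched).
#' @export
species_pathway_links <- function(fit, records, component_ids = NULL,
                                  phenotype = "all") {
  comps <- if (inherits(fit, "cca_fit")) fit$components else fit
  if (is.null(component_ids))
    component_ids <- paste0(phenotype, "C",
                            vapply(comps, `[[`, integer(1), "index"))
  out <- list()
  for (i in seq_along(comps)) {
    sp <- names(comps[[i]]$v)[comps[[i]]$v != 0]
    if (length(sp) == 0) next
    enr <- records$pathway[records$component == component_ids[i] &
                             records$enriched]
    if (length(enr) == 0) next
    out[[length(out) + 1L]] <- expand.grid(
      species = sp, pathway = enr, stringsAsFactors = FALSE,
      KEEP.OUT.ATTRS = FALSE)
    out[[length(out)]]$component <- component_ids[i]
  }
  if (length(out) == 0)
    return(data.frame(species = character(), pathway = character(),
                      component = character(), phenotype = character(),
                      stringsAsFactors = FALSE))
  links <- do.call(rbind, out)
  links$phenotype <- phenotype
  links
}

#' Per-species pathway counts by phenotype
#'
#' Counts, for each species and phenotype, the number of distinct pathways
#' the species is linked to (deduplicated across components).
#'
#' @param links output of [species_pathway_links()] (possibly row-bound
#'   across phenotypes).
#' @return data.frame `species`, `phenotype`, `n_pathways`.
#' @export
species_pathway_counts <- function(links) {
  if (nrow(links) == 0)
    return(data.frame(species = character(), phenotype = character(),
                      n_pathways = integer(), stringsAsFactors = FALSE))
  uu <- unique(links[, c("species", "phenotype", "pathway")])
  agg <- stats::aggregate(pathway ~ species + phenotype, data = uu,
                          FUN = length)
  names(agg)[names(agg) == "pathway"] <- "n_pathways"
  agg[order(agg$species, agg$phenotype), ]
}
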