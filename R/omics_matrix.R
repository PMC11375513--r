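#' Construct an omics matrix
#'
#' A light container for a dense samples x features matrix with unique
#' sample and feature identifiers. The same container holds log2-scale
#' expression values (`kind = "expression"`), microbial relative abundances
#' whose rows lie on the unit simplex (`kind = "abundance"`), and
#' centered/scaled or log-ratio transformed matrices (`kind = "transformed"`).
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param kind one of `"expression"`, `"abundance"`, `"transformed"`.
#' @param sample_ids,feature_ids character identifiers; default to the
#'   dimnames of `values`.
#'
#' @return an object of class `omics_matrix` with elements `values`
#'   (dimnamed numeric matrix) and `kind`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
#' om <- omics_matrix(m, "expression")
#' dim(om)
omics_matrix <- function(values,
                         kind = c("expression", "abundance", "transformed"),
                         sample_ids = rownames(values),
                         feature_ids = colnames(values)) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(sample_ids) || is.null(feature_ids))
    stop("sample and feature identifiers are required")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values) ||
      length(feature_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers")
  dimnames(values) <- list(sample_ids, feature_ids)
  if (kind == "abundance") {
    if (any(values < 0)) stop("abundance values must be non-negative")
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-8))
      stop("abundance rows must sum to 1 (within 1e-8)")
  }
  structure(list(values = values, kind = kind), class = "omics_matrix")
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix [%s]: %d samples x %d features>\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Sample and feature identifiers of an omics matrix
#' @param x an `omics_matrix`.
#' @return character vector of identifiers.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(x) colnames(x$values)

#' Coerce to omics_matrix
#'
#' Plain matrices pass through [omics_matrix()]; existing objects are
#' returned unchanged (the `kind` argument is ignored for them).
#' @inheritParams omics_matrix
#' @param x matrix or `omics_matrix`.
#' @return an `omics_matrix`.
#' @export
as_omics_matrix <- function(x, kind = "expression") {
  if (inherits(x, "omics_matrix")) return(x)
  omics_matrix(as.matrix(x), kind = kind)
}

#' Subset the features of an omics matrix
#'
#' Removes features only; the sample axis and its ordering are never
#' altered. Abundance matrices become `kind = "transformed"` once rows no
#' longer sum to one unless `renormalize = TRUE`.
#'
#' @param x an `omics_matrix`.
#' @param features character vector of feature ids (order preserved as
#'   given) or logical/integer index into the feature axis.
#' @param renormalize logical; for abundance matrices, rescale rows to sum
#'   to 1 after subsetting.
#' @return an `omics_matrix`.
#' @export
subset_features <- function(x, features, renormalize = FALSE) {
  stopifnot(inherits(x, "omics_matrix"))
  vals <- x$values[, features, drop = FALSE]
  kind <- x$kind
  if (kind == "abundance") {
    if (renormalize) {
      rs <- rowSums(vals)
      if (any(rs <= 0)) stop("cannot renormalize: zero-sum row")
      vals <- vals / rs
    } else if (any(abs(rowSums(vals) - 1) > 1e-8)) {
      kind <- "transformed"
    }
  }
  omics_matrix(vals, kind)
}

#' Read / write an omics matrix as TSV
#'
#' The on-disk layout is one header row of feature identifiers preceded by a
#' `sample_id` column name, then one row per sample.
#'
#' @param x an `omics_matrix`.
#' @param path file path.
#' @param kind matrix kind used when reading back.
#' @return `write_omics_tsv` returns `path` invisibly; `read_omics_tsv`
#'   returns an `omics_matrix`.
#' @export
write_omics_tsv <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(sample_id = sample_ids(x), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_omics_tsv
#' @export
read_omics_tsv <- function(path, kind = "expression") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- ids
  omics_matrix(vals, kind)
}
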