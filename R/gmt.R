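#' Construct a gene-set collection
#'
#' Named gene sets as used for pathway enrichment and per-sample scoring
#' (KEGG/PID-style). Each set is a non-empty character vector without
#' duplicate members.
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional character vector (named by set, or in set
#'   order); defaults to the set names.
#' @param source free-text provenance tag (e.g. `"KEGG"`, `"synthetic"`).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                source = "custom") {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("sets must be uniquely named")
    for (nm in names(sets)) {
      if (length(sets[[nm]]) == 0)
        stop(sprintf("set '%s' is empty", nm))
      if (anyDuplicated(sets[[nm]]))
        stop(sprintf("set '%s' has duplicate genes", nm))
    }
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  } else if (is.null(names(descriptions))) {
    descriptions <- stats::setNames(rep_len(descriptions, length(sets)),
                                    names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection [%s]: %d set(s)>\n",
              x$source, length(x$sets)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated member gene ids.
#' Duplicate members within a line are dropped.
#'
#' @param path GMT file path.
#' @param source provenance tag stored on the collection.
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 60))
    sets[[parts[1L]]] <- unique(parts[-(1:2)])
    descs[parts[1L]] <- parts[2L]
  }
  gene_set_collection(sets, descriptions = descs, source = source)
}

#' Write gene sets as a GMT file
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
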