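#' OTU count table with taxonomy
#'
#' A light container for a samples x OTUs matrix of non-negative integer
#' counts, with optional per-OTU taxonomic lineages (semicolon-delimited,
#' kingdom to species, missing ranks allowed at the tail).
#'
#' @param counts numeric matrix of non-negative integers with unique rownames
#'   (sample ids) and colnames (OTU ids).
#' @param taxonomy optional character vector of lineages, one per OTU, named
#'   by OTU id or in column order.
#' @return An object of class `counts_table`: the integer matrix with a
#'   `taxonomy` attribute.
#' @export
counts_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique rownames (sample ids)")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique colnames (OTU ids)")
  if (any(is.na(counts))) stop("counts contain NA")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (!is.null(names(taxonomy))) {
      if (!all(colnames(counts) %in% names(taxonomy)))
        stop("taxonomy missing lineages for some OTUs")
      taxonomy <- taxonomy[colnames(counts)]
    } else {
      if (length(taxonomy) != ncol(counts))
        stop("taxonomy length does not match number of OTUs")
      names(taxonomy) <- colnames(counts)
    }
  }
  structure(counts, taxonomy = taxonomy, class = c("counts_table", "matrix", "array"))
}

#' @exportS3Method base::print
print.counts_table <- function(x, ...) {
  cat(sprintf("counts_table: %d samples x %d OTUs, total count %.0f\n",
              nrow(x), ncol(x), sum(as.numeric(x))))
  cat(sprintf("  taxonomy: %s\n",
              if (is.null(attr(x, "taxonomy"))) "absent" else "present"))
  invisible(x)
}

# Subset rows/columns with base-matrix drop semantics; matrix results keep
# the class and the matching taxonomy.
#' @export
`[.counts_table` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod(drop = drop)
  if (!is.matrix(out)) return(out)
  tax <- attr(x, "taxonomy")
  if (!is.null(tax)) tax <- tax[colnames(out)]
  structure(out, taxonomy = tax, class = class(x))
}

sample_ids <- function(ct) rownames(ct)
otu_ids <- function(ct) colnames(ct)

#' Taxonomy lineages of a counts table
#' @param ct a [counts_table()].
#' @return Named character vector of lineages, or NULL.
#' @export
taxonomy <- function(ct) attr(ct, "taxonomy")
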