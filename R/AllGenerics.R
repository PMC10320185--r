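#' Accessors for mirTEA data classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{edges} returns the deduplicated interaction table, \code{mirnas} the
#' miRNA ids, \code{targetsOf} one miRNA's target genes, \code{termIds} /
#' \code{termNames} / \code{termGenes} the term collection pieces,
#' \code{geneUniverse} the background gene list, \code{log2fcValues} the
#' gene-by-context matrix, \code{resourceTags} its per-context tags,
#' \code{screenHits} the parsed screen table, \code{screenDialect} its
#' dialect, \code{targetGenes} / \code{provenance} the combined target set.
#'
#' @param x a mirTEA data object.
#' @param mirna a single miRNA id.
#' @param term a single term id (or missing for the full named list).
#' @return The underlying vector, list or data.frame (see details per class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("mirnas", function(x) standardGeneric("mirnas"))
#' @rdname accessors
#' @export
setGeneric("targetsOf", function(x, mirna) standardGeneric("targetsOf"))
#' @rdname accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))
#' @rdname accessors
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))
#' @rdname accessors
#' @export
setGeneric("termGenes", function(x, term) standardGeneric("termGenes"))
#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
#' @rdname accessors
#' @export
setGeneric("log2fcValues", function(x) standardGeneric("log2fcValues"))
#' @rdname accessors
#' @export
setGeneric("resourceTags", function(x) standardGeneric("resourceTags"))
#' @rdname accessors
#' @export
setGeneric("screenHits", function(x) standardGeneric("screenHits"))
#' @rdname accessors
#' @export
setGeneric("screenDialect", function(x) standardGeneric("screenDialect"))
#' @rdname accessors
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setMethod("edges", "MirTargetSet", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("mirnas", "MirTargetSet", function(x) names(x@index))
#' @rdname accessors
#' @export
setMethod("targetsOf", "MirTargetSet", function(x, mirna) {
  stopifnot(length(mirna) == 1L)
  x@index[[mirna]]
})

#' @rdname accessors
#' @export
setMethod("termIds", "TermCollection", function(x) x@termIds)
#' @rdname accessors
#' @export
setMethod("termNames", "TermCollection",
          function(x) setNames(x@termNames, x@termIds))
#' @rdname accessors
#' @export
setMethod("termGenes", "TermCollection", function(x, term) {
  if (missing(term)) return(x@genes)
  if (!term %in% x@termIds) stop("unknown term id: ", term)
  x@genes[[term]]
})
#' @rdname accessors
#' @export
setMethod("geneUniverse", "TermCollection", function(x) x@universe)

#' @rdname accessors
#' @export
setMethod("log2fcValues", "ContextMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("resourceTags", "ContextMatrix", function(x) x@resourceTags)

#' @rdname accessors
#' @export
setMethod("screenHits", "ScreenTable", function(x) x@hits)
#' @rdname accessors
#' @export
setMethod("screenDialect", "ScreenTable", function(x) x@dialect)

#' @rdname accessors
#' @export
setMethod("targetGenes", "TargetSet", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("provenance", "TargetSet", function(x) x@provenance)

setMethod("show", "MirTargetSet", function(object) {
  cat(sprintf("MirTargetSet: %d interactions, %d miRNAs, %d genes\n",
              nrow(object@edges), length(object@index),
              length(unique(object@edges$gene))))
})

setMethod("show", "TermCollection", function(object) {
  sz <- lengths(object@genes)
  cat(sprintf("TermCollection: %d terms (sizes %d-%d), universe of %d genes\n",
              length(object@termIds), min(sz), max(sz),
              length(object@universe)))
})

setMethod("show", "ContextMatrix", function(object) {
  cat(sprintf("ContextMatrix: %d genes x %d contexts (log2FC, range %.2f..%.2f)\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "ScreenTable", function(object) {
  tab <- table(object@hits$type)
  cat(sprintf("ScreenTable (%s): %d elements (%d genes, %d miRNAs)\n",
              object@dialect, nrow(object@hits),
              sum(object@hits$type == "gene"),
              sum(object@hits$type == "mirna")))
})

setMethod("show", "TargetSet", function(object) {
  cat(sprintf("TargetSet (%s%s): %d genes from %d miRNAs\n",
              object@mode,
              if (object@mode == "intersection")
                sprintf(", n>=%d", object@nRequired) else "",
              length(object@genes),
              length(unique(unlist(object@provenance, use.names = FALSE)))))
})
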