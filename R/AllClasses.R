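#' @import methods
NULL

.checkIds <- function(x, what) {
  if (!is.character(x)) return(sprintf("%s must be character", what))
  if (any(is.na(x) | !nzchar(x))) return(sprintf("%s contains empty or NA ids", what))
  NULL
}

#' MirTargetSet: a deduplicated miRNA-to-gene interaction table
#'
#' Holds the regulatory evidence base all enrichment draws from: one row per
#' distinct (miRNA, gene) pair, with optional evidence tags and scores, plus
#' an index from each miRNA to its target genes.
#'
#' @slot edges data.frame with columns \code{mirna}, \code{gene},
#'   \code{evidence} (character, \code{NA} when absent) and \code{score}
#'   (numeric, \code{NA} when absent); rows are unique (mirna, gene) pairs.
#' @slot index named list mapping each miRNA id to the character vector of
#'   its target gene ids.
#'
#' @details Identifiers are opaque, case-sensitive strings; the package never
#' performs id-version conversion. Ids must not contain commas or tabs (they
#' are used as field separators in serialized outputs).
#'
#' @seealso [readInteractions()], [buildTargetSet()]
#' @export
setClass("MirTargetSet",
  representation(edges = "data.frame", index = "list"))

setValidity("MirTargetSet", function(object) {
  ed <- object@edges
  need <- c("mirna", "gene", "evidence", "score")
  if (!all(need %in% names(ed)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  msg <- .checkIds(ed$mirna, "mirna")
  if (is.null(msg)) msg <- .checkIds(ed$gene, "gene")
  if (!is.null(msg)) return(msg)
  if (anyDuplicated(paste0(ed$mirna, "\r", ed$gene)))
    return("duplicate (mirna, gene) pairs")
  idx <- split(ed$gene, ed$mirna)
  if (!identical(lapply(object@index[sort(names(object@index))], sort),
                 lapply(idx[sort(names(idx))], sort)))
    return("index does not match the deduplicated edge set")
  TRUE
})

#' Construct a MirTargetSet from an edge table
#'
#' Duplicated (miRNA, gene) pairs are collapsed; their evidence tags are
#' concatenated with \code{";"} and the maximum score is kept.
#'
#' @param mirna,gene character vectors of equal length (one interaction per
#'   element).
#' @param evidence optional character vector of evidence tags.
#' @param score optional numeric vector of interaction scores.
#' @return A [MirTargetSet-class] object.
#' @examples
#' ts <- MirTargetSet(c("miR-a", "miR-a", "miR-b"), c("g1", "g2", "g1"))
#' targetsOf(ts, "miR-a")
#' @export
MirTargetSet <- function(mirna, gene, evidence = NULL, score = NULL) {
  mirna <- as.character(mirna); gene <- as.character(gene)
  stopifnot(length(mirna) == length(gene))
  n <- length(mirna)
  if (is.null(evidence)) evidence <- rep(NA_character_, n)
  if (is.null(score)) score <- rep(NA_real_, n)
  key <- paste0(mirna, "\r", gene)
  if (anyDuplicated(key)) {
    grp <- match(key, key)
    keep <- !duplicated(key)
    ev <- vapply(split(evidence, grp), function(e) {
      e <- unique(e[!is.na(e)])
      if (length(e)) paste(e, collapse = ";") else NA_character_
    }, character(1))
    sc <- vapply(split(score, grp), function(s) {
      s <- s[!is.na(s)]
      if (length(s)) max(s) else NA_real_
    }, numeric(1))
    ord <- as.character(sort(unique(grp)))
    mirna <- mirna[keep]; gene <- gene[keep]
    evidence <- unname(ev[ord]); score <- unname(sc[ord])
  }
  ed <- data.frame(mirna = mirna, gene = gene,
                   evidence = as.character(evidence), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  new("MirTargetSet", edges = ed, index = split(ed$gene, ed$mirna))
}

#' TermCollection: named gene sets plus their gene universe
#'
#' A collection of terms (GO terms, pathways, signatures, families): each term
#' is a non-empty gene set; the universe is the background gene list used by
#' all urn-model tests and must contain every term's genes. By default the
#' universe is the union of all term gene sets (annotation-based testing).
#'
#' @slot termIds unique character term identifiers.
#' @slot termNames character descriptions, parallel to \code{termIds}.
#' @slot genes named list (by term id) of character gene-id vectors.
#' @slot universe character vector of background gene ids.
#' @seealso [readGMT()], [enrichTargets()]
#' @export
setClass("TermCollection",
  representation(termIds = "character", termNames = "character",
                 genes = "list", universe = "character"))

setValidity("TermCollection", function(object) {
  if (anyDuplicated(object@termIds)) return("term ids not unique")
  if (length(object@termNames) != length(object@termIds))
    return("termNames length mismatch")
  if (!identical(names(object@genes), object@termIds))
    return("genes list names must equal termIds")
  if (any(lengths(object@genes) == 0L)) return("empty term gene set")
  msg <- .checkIds(object@universe, "universe")
  if (!is.null(msg)) return(msg)
  if (anyDuplicated(object@universe)) return("duplicate genes in universe")
  allg <- unique(unlist(object@genes, use.names = FALSE))
  if (!all(allg %in% object@universe))
    return("universe must contain every term's genes")
  TRUE
})

#' Construct a TermCollection
#'
#' @param termIds,termNames character vectors of term ids and display names.
#' @param genes list of character gene-id vectors, one per term.
#' @param universe background gene ids; defaults to the union of all terms.
#' @return A [TermCollection-class] object.
#' @export
TermCollection <- function(termIds, genes, termNames = termIds,
                           universe = NULL) {
  termIds <- as.character(termIds)
  genes <- lapply(genes, function(g) unique(as.character(g)))
  names(genes) <- termIds
  if (is.null(universe))
    universe <- sort(unique(unlist(genes, use.names = FALSE)))
  new("TermCollection", termIds = termIds,
      termNames = as.character(termNames), genes = genes,
      universe = as.character(universe))
}

#' ContextMatrix: gene-by-context log2 fold-change values
#'
#' Stores, for each gene and expression context (cell type, tissue, disease
#' state), a finite log2 fold-change — typically the percent-expressing
#' log2FC computed by [percentExpressingLog2fc()] — plus a resource tag per
#' context (e.g. the atlas or cohort it came from).
#'
#' @slot values numeric matrix, rows = genes, columns = contexts; all finite.
#' @slot resourceTags named character vector, one tag per context column.
#' @export
setClass("ContextMatrix",
  representation(values = "matrix", resourceTags = "character"))

setValidity("ContextMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have gene rownames and context colnames")
  if (anyDuplicated(colnames(v))) return("duplicate context ids")
  if (anyDuplicated(rownames(v))) return("duplicate gene ids")
  if (any(!is.finite(v))) return("non-finite log2FC values")
  if (!identical(names(object@resourceTags), colnames(v)))
    return("resourceTags must be named by context id")
  TRUE
})

#' Construct a ContextMatrix
#' @param values numeric gene x context matrix of log2 fold-changes with
#'   dimnames.
#' @param resourceTags optional character vector of per-context resource tags.
#' @return A [ContextMatrix-class] object.
#' @export
ContextMatrix <- function(values, resourceTags = NULL) {
  if (is.null(resourceTags))
    resourceTags <- setNames(rep("custom", ncol(values)), colnames(values))
  nm <- names(resourceTags)
  resourceTags <- as.character(resourceTags)
  names(resourceTags) <- if (is.null(nm)) colnames(values) else nm
  if (all(colnames(values) %in% names(resourceTags)))
    resourceTags <- resourceTags[colnames(values)]
  new("ContextMatrix", values = values, resourceTags = resourceTags)
}

#' ScreenTable: ranked CRISPR knock-out screen results
#'
#' Parsed MAGeCK-style gene_summary results for a pooled knock-out screen of
#' a library targeting both genes and miRNAs. Each element carries a score,
#' p-value and rank for negative and for positive selection; within each
#' direction the ranks are a permutation of 1..n.
#'
#' @slot hits data.frame with columns \code{id}, \code{type} ("gene" or
#'   "mirna"), \code{neg_score}, \code{neg_p}, \code{neg_rank},
#'   \code{pos_score}, \code{pos_p}, \code{pos_rank}.
#' @slot dialect "rra" or "mle".
#' @seealso [readMageck()], [selectTopMirnas()], [oppositeRankTest()]
#' @export
setClass("ScreenTable",
  representation(hits = "data.frame", dialect = "character"))

setValidity("ScreenTable", function(object) {
  h <- object@hits
  need <- c("id", "type", "neg_score", "neg_p", "neg_rank",
            "pos_score", "pos_p", "pos_rank")
  if (!all(need %in% names(h))) return("missing screen columns")
  if (!object@dialect %in% c("rra", "mle")) return("dialect must be rra or mle")
  if (anyDuplicated(h$id)) return("duplicate element ids")
  if (!all(h$type %in% c("gene", "mirna"))) return("type must be gene or mirna")
  n <- nrow(h)
  for (cc in c("neg_rank", "pos_rank"))
    if (!identical(sort(as.integer(h[[cc]])), seq_len(n)))
      return(sprintf("%s is not a permutation of 1..n", cc))
  for (cc in c("neg_p", "pos_p"))
    if (any(h[[cc]] < 0 | h[[cc]] > 1)) return(sprintf("%s outside [0,1]", cc))
  TRUE
})

#' Construct a ScreenTable
#' @param hits data.frame as described in [ScreenTable-class]; ranks are
#'   re-derived from scores (ascending, ties broken by id) when absent.
#' @param dialect "rra" or "mle".
#' @return A [ScreenTable-class] object.
#' @export
ScreenTable <- function(hits, dialect = c("rra", "mle")) {
  dialect <- match.arg(dialect)
  for (dir in c("neg", "pos")) {
    rc <- paste0(dir, "_rank"); sc <- paste0(dir, "_score")
    if (is.null(hits[[rc]]) || all(is.na(hits[[rc]])))
      hits[[rc]] <- order(order(hits[[sc]], hits$id))
    hits[[rc]] <- as.integer(hits[[rc]])
  }
  rownames(hits) <- NULL
  new("ScreenTable", hits = hits, dialect = dialect)
}

#' TargetSet: a combined target set built from query miRNAs
#'
#' The gene set regulated by a miRNA query under union (targeted by at least
#' one query miRNA) or n-way intersection (targeted by at least
#' \code{nRequired} query miRNAs) semantics, with per-gene provenance.
#'
#' @slot genes character vector of targeted gene ids.
#' @slot provenance named list: for each gene, the query miRNAs targeting it.
#' @slot mode "union" or "intersection".
#' @slot nRequired integer, minimum number of query miRNAs per gene
#'   (1 for union).
#' @seealso [buildTargetSet()]
#' @export
setClass("TargetSet",
  representation(genes = "character", provenance = "list",
                 mode = "character", nRequired = "integer"))

setValidity("TargetSet", function(object) {
  if (!object@mode %in% c("union", "intersection")) return("bad mode")
  if (!identical(sort(names(object@provenance)), sort(object@genes)))
    return("provenance names must equal genes")
  if (any(lengths(object@provenance) < object@nRequired))
    return("gene with fewer contributing miRNAs than nRequired")
  TRUE
})
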