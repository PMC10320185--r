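## Readers/writers for the plain-text formats the engine touches:
## interaction TSVs, GMT term collections, expression matrices with
## sample-to-context maps, MAGeCK-style gene_summary tables, result tables.

.readTsv <- function(path, what = "file") {
  if (!file.exists(path)) stop(sprintf("%s not found: %s", what, path))
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Read a miRNA-gene interaction table
#'
#' Reads a tab-separated interaction table with a header row. Duplicate
#' (miRNA, gene) pairs are collapsed (evidence tags concatenated with ";",
#' maximum score kept) and the number of collapsed rows is reported via
#' \code{message()}.
#'
#' @param path path to the TSV file.
#' @param columns named character vector mapping the roles \code{mirna},
#'   \code{gene} and optionally \code{evidence}, \code{score} to column
#'   names in the file.
#' @return A [MirTargetSet-class].
#' @export
readInteractions <- function(path,
                             columns = c(mirna = "mirna", gene = "gene",
                                         evidence = "evidence",
                                         score = "score")) {
  df <- .readTsv(path, "interaction file")
  for (role in c("mirna", "gene")) {
    cn <- columns[[role]]
    if (is.null(cn) || !cn %in% names(df))
      stop(sprintf("interaction file lacks mandatory column '%s' (role %s)",
                   if (is.null(cn)) role else cn, role))
  }
  if (nrow(df) == 0L) stop("interaction file has a header but no rows")
  ev <- if (!is.na(columns["evidence"]) && columns[["evidence"]] %in% names(df))
    as.character(df[[columns[["evidence"]]]]) else NULL
  sc <- if (!is.na(columns["score"]) && columns[["score"]] %in% names(df))
    suppressWarnings(as.numeric(df[[columns[["score"]]]])) else NULL
  nIn <- nrow(df)
  x <- MirTargetSet(df[[columns[["mirna"]]]], df[[columns[["gene"]]]], ev, sc)
  nDup <- nIn - nrow(edges(x))
  if (nDup > 0) message(sprintf("collapsed %d duplicate interaction rows", nDup))
  x
}

#' Write a miRNA-gene interaction table
#' @param x a [MirTargetSet-class].
#' @param path output TSV path.
#' @export
writeInteractions <- function(x, path) {
  ed <- edges(x)
  ed$score <- ifelse(is.na(ed$score), NA, sprintf("%.17g", ed$score))
  utils::write.table(ed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a GMT term collection
#'
#' Standard GMT: one term per line, tab-separated fields
#' \code{term_id, term_name, gene, gene, ...}. Lines with fewer than three
#' fields (no genes) and duplicate term ids are format errors. The gene
#' universe is the union of all term gene sets.
#'
#' @param path path to the GMT file.
#' @return A [TermCollection-class].
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: fewer than 3 fields (term needs >= 1 gene)",
                 bad[1]))
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id in GMT: ", ids[duplicated(ids)][1])
  nm <- vapply(parts, `[[`, character(1), 2L)
  genes <- lapply(parts, function(p) unique(p[-(1:2)]))
  TermCollection(ids, genes, termNames = nm)
}

#' Write a term collection as GMT
#' @param x a [TermCollection-class].
#' @param path output path.
#' @export
writeGMT <- function(x, path) {
  nm <- termNames(x)
  lines <- vapply(termIds(x), function(id)
    paste(c(id, nm[[id]], termGenes(x, id)), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix with a sample-to-context map
#'
#' The expression file is a TSV matrix whose first column holds gene ids and
#' remaining columns one sample each. The context map is a two-column TSV
#' (\code{sample}, \code{context}) with an optional \code{resource} column.
#'
#' @param path expression matrix TSV.
#' @param contextMapPath sample-to-context map TSV.
#' @return list with \code{values} (numeric gene x sample matrix),
#'   \code{sampleContexts} (character, per sample) and \code{resourceTags}
#'   (per context).
#' @export
readExpression <- function(path, contextMapPath) {
  df <- .readTsv(path, "expression matrix")
  if (ncol(df) < 2L) stop("expression matrix needs a gene column plus samples")
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- as.character(df[[1]])
  cm <- .readTsv(contextMapPath, "context map")
  if (!all(c("sample", "context") %in% names(cm)))
    stop("context map needs columns 'sample' and 'context'")
  miss <- setdiff(colnames(mat), cm$sample)
  if (length(miss)) stop("samples missing from context map: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  ctx <- setNames(as.character(cm$context), cm$sample)[colnames(mat)]
  tags <- if ("resource" %in% names(cm))
    tapply(as.character(cm$resource), cm$context, `[[`, 1) else NULL
  list(values = mat, sampleContexts = unname(ctx), resourceTags = tags)
}

#' Read a precomputed gene-by-context log2FC matrix
#'
#' @param path TSV matrix, first column gene ids, remaining columns contexts.
#' @param metadataPath optional TSV with columns \code{context},
#'   \code{resource}.
#' @return A [ContextMatrix-class].
#' @export
readLog2fcMatrix <- function(path, metadataPath = NULL) {
  df <- .readTsv(path, "log2FC matrix")
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- as.character(df[[1]])
  tags <- NULL
  if (!is.null(metadataPath)) {
    md <- .readTsv(metadataPath, "context metadata")
    if (!all(c("context", "resource") %in% names(md)))
      stop("context metadata needs columns 'context' and 'resource'")
    tags <- setNames(as.character(md$resource), md$context)[colnames(mat)]
    names(tags) <- colnames(mat)
  }
  ContextMatrix(mat, tags)
}

.defaultMirnaPattern <- "(^hsa-)|(^mmu-)|mir"

#' Read MAGeCK-style gene_summary screen results
#'
#' Parses the tab-separated gene_summary output of a pooled CRISPR
#' knock-out screen analysis for a library targeting both genes and miRNAs.
#' The RRA dialect expects the pipe-separated columns \code{id},
#' \code{neg|score}, \code{neg|p-value}, \code{neg|rank}, \code{pos|score},
#' \code{pos|p-value}, \code{pos|rank}; the MLE dialect maps its
#' design-matrix-dependent column names through \code{columnSpec}
#' (roles \code{beta}, \code{neg_p}, \code{pos_p}); negative-selection score
#' is the beta itself and positive-selection score its negation. Rows are
#' classified as miRNA or gene by a case-insensitive regular expression on
#' the element id. Ranks are re-derived from scores (ascending, ties broken
#' by id) when absent or inconsistent.
#'
#' @param path path to the gene_summary TSV.
#' @param dialect "rra" or "mle".
#' @param mirnaPattern case-insensitive regex marking miRNA rows; the
#'   default matches miRBase-style "hsa-"/"mmu-" prefixes or a "mir"
#'   substring.
#' @param columnSpec (MLE only) named character vector with entries
#'   \code{beta}, \code{neg_p}, \code{pos_p} naming file columns.
#' @return A [ScreenTable-class].
#' @export
readMageck <- function(path, dialect = c("rra", "mle"),
                       mirnaPattern = .defaultMirnaPattern,
                       columnSpec = NULL) {
  dialect <- match.arg(dialect)
  df <- .readTsv(path, "screen file")
  if (!"id" %in% names(df)) stop("screen file lacks mandatory column 'id'")
  id <- as.character(df$id)
  if (dialect == "rra") {
    need <- c("neg|score", "neg|p-value", "pos|score", "pos|p-value")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("screen file lacks RRA column(s): ", paste(miss, collapse = ", "))
    hits <- data.frame(id = id,
                       neg_score = as.numeric(df[["neg|score"]]),
                       neg_p = as.numeric(df[["neg|p-value"]]),
                       neg_rank = if ("neg|rank" %in% names(df))
                         as.integer(df[["neg|rank"]]) else NA_integer_,
                       pos_score = as.numeric(df[["pos|score"]]),
                       pos_p = as.numeric(df[["pos|p-value"]]),
                       pos_rank = if ("pos|rank" %in% names(df))
                         as.integer(df[["pos|rank"]]) else NA_integer_,
                       stringsAsFactors = FALSE)
  } else {
    if (is.null(columnSpec) ||
        !all(c("beta", "neg_p", "pos_p") %in% names(columnSpec)))
      stop("MLE dialect needs columnSpec with roles beta, neg_p, pos_p")
    miss <- setdiff(unname(columnSpec[c("beta", "neg_p", "pos_p")]), names(df))
    if (length(miss))
      stop("screen file lacks p-value/beta column(s): ",
           paste(miss, collapse = ", "))
    beta <- as.numeric(df[[columnSpec[["beta"]]]])
    hits <- data.frame(id = id,
                       neg_score = beta,
                       neg_p = as.numeric(df[[columnSpec[["neg_p"]]]]),
                       neg_rank = NA_integer_,
                       pos_score = -beta,
                       pos_p = as.numeric(df[[columnSpec[["pos_p"]]]]),
                       pos_rank = NA_integer_,
                       stringsAsFactors = FALSE)
  }
  hits$type <- ifelse(grepl(mirnaPattern, id, ignore.case = TRUE),
                      "mirna", "gene")
  if (!any(hits$type == "mirna"))
    warning("no screen row matches the miRNA pattern; ",
            "screen analysis requires a separately supplied miRNA list")
  n <- nrow(hits)
  for (dir in c("neg", "pos")) {
    rc <- paste0(dir, "_rank")
    if (!all(is.na(hits[[rc]])) &&
        !identical(sort(as.integer(hits[[rc]])), seq_len(n))) {
      warning(sprintf("%s column is not a permutation of 1..n; re-deriving from scores", rc))
      hits[[rc]] <- NA_integer_
    }
  }
  ScreenTable(hits, dialect)
}

.collapseIdCols <- function(df) {
  for (cc in names(df))
    if (is.list(df[[cc]]))
      df[[cc]] <- vapply(df[[cc]], paste, character(1), collapse = ",")
  df
}

#' Write a result table as TSV or JSON
#'
#' TSV keeps the data.frame's column order; numeric columns are serialized
#' with 17 significant digits so probabilities survive a write/read
#' round-trip bit-exactly. JSON is an array of row objects mirroring the TSV
#' field-for-field.
#'
#' @param rows a data.frame of results (possibly zero rows).
#' @param path output path.
#' @param format "tsv" or "json".
#' @return \code{path}, invisibly.
#' @seealso [readResults()]
#' @export
writeResults <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.null(rows)) stop("rows must be a data.frame (possibly empty)")
  rows <- .collapseIdCols(as.data.frame(rows))
  if (format == "json") {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = I(17),
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  out <- rows
  for (cc in names(out))
    if (is.numeric(out[[cc]]) && !is.integer(out[[cc]]))
      out[[cc]] <- ifelse(is.na(out[[cc]]), NA, sprintf("%.17g", out[[cc]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a result table written by [writeResults()]
#' @param path input path.
#' @param format "tsv" or "json".
#' @return A data.frame.
#' @export
readResults <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json")
    return(jsonlite::fromJSON(path, simplifyDataFrame = TRUE))
  .readTsv(path, "result file")
}
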