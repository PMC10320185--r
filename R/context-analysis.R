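## Context-aware engine: percent-expressing log2FC computation from raw
## expression, and rank-based testing of targeted vs non-targeted term
## components per expression context.

#' Percent-expressing log2 fold-change per gene and context
#'
#' For each gene and context, computes the percentage of the context's
#' samples (cells for single-cell data) in which the gene is expressed at or
#' above a threshold, then contrasts it to the median of the percentages of
#' the remaining contexts on the log2 scale:
#' \deqn{\mathrm{log2FC}_{gc} = \log_2\frac{p_{gc} + \varepsilon}
#'   {\mathrm{median}_{c' \ne c}(p_{gc'}) + \varepsilon}}
#' The threshold is mode-dependent: one read for
#' \code{"single_cell_counts"}, 10 TPM for \code{"tissue_tpm"}, user-chosen
#' for \code{"generic"}. The pseudocount \eqn{\varepsilon} (percentage
#' points) keeps values finite for genes silent in some contexts; with 0%
#' everywhere the value is exactly 0.
#'
#' @param raw numeric gene x sample matrix (counts or TPM) with gene
#'   rownames.
#' @param sampleContexts character vector, one context label per sample
#'   column.
#' @param mode "single_cell_counts", "tissue_tpm" or "generic".
#' @param threshold expression threshold (required for \code{"generic"};
#'   ignored otherwise).
#' @param epsilon positive pseudocount in percentage points (default 0.01).
#' @param resourceTags optional named (by context) character tags.
#' @return A [ContextMatrix-class] of log2 fold-changes.
#' @examples
#' m <- rbind(g1 = c(5, 3, 0, 0, 1, 0))
#' percentExpressingLog2fc(m, c("A", "A", "B", "B", "C", "C"),
#'                         mode = "single_cell_counts")
#' @export
percentExpressingLog2fc <- function(raw, sampleContexts,
                                    mode = c("single_cell_counts",
                                             "tissue_tpm", "generic"),
                                    threshold = NULL, epsilon = 0.01,
                                    resourceTags = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(raw) || is.null(rownames(raw)))
    stop("raw must be a matrix with gene rownames")
  if (length(sampleContexts) != ncol(raw))
    stop("sampleContexts must label every sample column")
  if (epsilon <= 0) stop("epsilon must be positive")
  thr <- switch(mode, single_cell_counts = 1, tissue_tpm = 10,
                generic = threshold)
  if (is.null(thr) || thr < 0)
    stop("generic mode needs a nonnegative threshold")
  ctxs <- unique(sampleContexts)
  if (length(ctxs) < 2L) stop("need at least two contexts")
  pct <- vapply(ctxs, function(cc) {
    cols <- which(sampleContexts == cc)
    if (length(cols) == 0L) stop("context without samples: ", cc)
    100 * rowMeans(raw[, cols, drop = FALSE] >= thr)
  }, numeric(nrow(raw)))
  if (!is.matrix(pct)) pct <- matrix(pct, nrow = nrow(raw),
                                     dimnames = list(rownames(raw), ctxs))
  lfc <- vapply(seq_along(ctxs), function(j) {
    med <- apply(pct[, -j, drop = FALSE], 1, stats::median)
    log2((pct[, j] + epsilon) / (med + epsilon))
  }, numeric(nrow(raw)))
  if (!is.matrix(lfc)) lfc <- matrix(lfc, nrow = nrow(raw))
  dimnames(lfc) <- list(rownames(raw), ctxs)
  ContextMatrix(lfc, resourceTags)
}

#' Context testing of targeted vs non-targeted term components
#'
#' For each enriched term and each expression context, compares the log2FC
#' values of the term's targeted genes against its non-targeted genes with a
#' Mann-Whitney U (default) or Kolmogorov-Smirnov test. The default
#' one-sided alternative \code{"less"} (targeted first) detects contexts
#' where targets are expressed at lower levels, i.e. the repressive miRNA
#' effect; \code{"two_sided"} accommodates exploratory scenarios. Genes
#' missing from the expression matrix are excluded from both groups and
#' counted in \code{direction_note}. Terms whose targeted or non-targeted
#' group falls below \code{minGroup} usable genes are skipped and reported
#' in the \code{"skipped"} attribute (plus a warning). P-values are
#' BH-adjusted within each term across contexts (\code{adjust = "global"}
#' switches to one adjustment across all rows) and rows are sorted by
#' significance within term.
#'
#' @param enriched data.frame from [enrichTargets()] (or any table with
#'   columns \code{term_id} and comma-joined \code{targeted_genes}).
#' @param terms the [TermCollection-class] the enrichment was run against.
#' @param expr a [ContextMatrix-class].
#' @param test "mwu" or "ks".
#' @param alternative "less", "greater" or "two_sided"; the targeted group
#'   is always the first sample.
#' @param minGroup minimum usable genes per side (default 3).
#' @param adjust "within_term" or "global".
#' @return data.frame of per-(term, context) rows sorted by \code{p_raw}
#'   within term, with a \code{"skipped"} attribute listing untestable
#'   terms.
#' @export
contextTest <- function(enriched, terms, expr, test = c("mwu", "ks"),
                        alternative = c("less", "greater", "two_sided"),
                        minGroup = 3L, adjust = c("within_term", "global")) {
  test <- match.arg(test)
  alternative <- .normAlt(alternative)
  adjust <- match.arg(adjust)
  if (nrow(enriched) == 0L) stop("enriched table is empty")
  vals <- log2fcValues(expr)
  tags <- resourceTags(expr)
  tfun <- if (test == "mwu") mwuTest else ksTest
  skipped <- list()
  rows <- list()
  for (i in seq_len(nrow(enriched))) {
    id <- enriched$term_id[i]
    tgt <- strsplit(enriched$targeted_genes[i], ",", fixed = TRUE)[[1]]
    tg <- intersect(termGenes(terms, id), geneUniverse(terms))
    non <- setdiff(tg, tgt)
    tgtE <- intersect(tgt, rownames(vals))
    nonE <- intersect(non, rownames(vals))
    nMissing <- (length(tgt) - length(tgtE)) + (length(non) - length(nonE))
    if (length(tgtE) < minGroup || length(nonE) < minGroup) {
      skipped[[id]] <- data.frame(term_id = id, n_targeted = length(tgtE),
                                  n_nontargeted = length(nonE),
                                  stringsAsFactors = FALSE)
      next
    }
    note <- sprintf("%d gene(s) absent from expression matrix", nMissing)
    res <- lapply(colnames(vals), function(cc) {
      tr <- suppressWarnings(tfun(vals[tgtE, cc], vals[nonE, cc],
                                  alternative))
      data.frame(term_id = id, context_id = cc,
                 resource_tag = unname(tags[cc]), test = test,
                 alternative = alternative, statistic = tr$statistic,
                 p_raw = tr$p_value, p_adjusted = NA_real_,
                 n_targeted = length(tgtE), n_nontargeted = length(nonE),
                 direction_note = note, stringsAsFactors = FALSE)
    })
    rows[[id]] <- do.call(rbind, res)
  }
  if (length(skipped))
    warning(sprintf("%d term(s) skipped: fewer than %d usable genes per side (%s)",
                    length(skipped), minGroup,
                    paste(names(skipped), collapse = ", ")))
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), context_id = character(0),
                      resource_tag = character(0), test = character(0),
                      alternative = character(0), statistic = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      n_targeted = integer(0), n_nontargeted = integer(0),
                      direction_note = character(0), stringsAsFactors = FALSE)
  } else {
    if (adjust == "within_term") {
      out$p_adjusted <- stats::ave(out$p_raw, out$term_id, FUN = bhAdjust)
    } else {
      out$p_adjusted <- bhAdjust(out$p_raw)
    }
    out <- out[order(match(out$term_id, enriched$term_id), out$p_raw,
                     out$context_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "adjust") <- adjust
  out
}
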