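## CRISPR-KO screen engine: select top selected miRNAs, test term
## enrichment of their targets, then test the targets' trend in the
## opposite selection ranking.

#' Select the top positively or negatively selected miRNAs
#'
#' Returns the \code{topN} miRNA-type screen elements by the chosen
#' direction's rank column, in rank order.
#'
#' @param screen a [ScreenTable-class].
#' @param direction "positive" or "negative".
#' @param topN number of miRNAs to select.
#' @return Character vector of miRNA ids (a miRNA query).
#' @export
selectTopMirnas <- function(screen, direction = c("positive", "negative"),
                            topN) {
  direction <- match.arg(direction)
  h <- screenHits(screen)
  mh <- h[h$type == "mirna", , drop = FALSE]
  topN <- as.integer(topN)
  if (topN < 1L) stop("topN must be at least 1")
  if (nrow(mh) < topN)
    stop(sprintf("screen has only %d miRNA row(s); %d requested",
                 nrow(mh), topN))
  rc <- if (direction == "positive") "pos_rank" else "neg_rank"
  mh$id[order(mh[[rc]])][seq_len(topN)]
}

#' Term enrichment of selected screen miRNAs' targets
#'
#' Takes the union of the selected miRNAs' targets and runs classic
#' one-sided hypergeometric term enrichment — a delegation to
#' [buildTargetSet()] (union mode) plus [enrichTargets()] (classic method)
#' with identical contracts.
#'
#' @param selected character vector of miRNA ids (e.g. from
#'   [selectTopMirnas()]).
#' @param interactions a [MirTargetSet-class].
#' @param terms a [TermCollection-class].
#' @param minOverlap minimum targeted genes per tested term.
#' @return data.frame of enrichment rows (see [enrichTargets()]).
#' @export
screenEnrich <- function(selected, interactions, terms, minOverlap = 1L) {
  ts <- buildTargetSet(selected, interactions, "union")
  enrichTargets(ts, terms, method = "classic", minOverlap = minOverlap)
}

#' Test an enriched term's targets in the opposite selection ranking
#'
#' For miRNAs selected in one direction, asks whether their targets within
#' an enriched term trend toward the favorable extreme of the \emph{genes'}
#' opposite ranking (for positively selected miRNAs the negative gene
#' ranking is assessed, and vice versa) — the signature of the miRNAs' loss
#' de-repressing their targets. Two tests are offered: \code{"camera"}
#' (default) runs the competitive rank-based test [cameraRankTest()] on the
#' opposite direction's score, one-sided toward the top of that ranking;
#' \code{"fisher_topk"} requires \code{kTop} and tests the 2x2 of (within
#' the opposite ranking's top \code{kTop}) by (targeted) with the one-sided
#' hypergeometric upper tail. miRNA rows are excluded from the ranking —
#' targets are genes.
#'
#' @param row a single enrichment row (1-row data.frame from
#'   [enrichTargets()] / [screenEnrich()]).
#' @param screen a [ScreenTable-class].
#' @param selectedDirection direction the miRNAs were selected in
#'   ("positive" or "negative").
#' @param method "camera" or "fisher_topk".
#' @param kTop number of top opposite-ranked genes (mandatory for
#'   \code{"fisher_topk"}).
#' @param rho inter-gene correlation for \code{"camera"} (default 0.01).
#' @return 1-row data.frame: the enrichment columns plus \code{direction},
#'   \code{opposite_test}, \code{opposite_statistic}, \code{opposite_p},
#'   \code{k_top}.
#' @export
oppositeRankTest <- function(row, screen,
                             selectedDirection = c("positive", "negative"),
                             method = c("camera", "fisher_topk"),
                             kTop = NULL, rho = 0.01) {
  selectedDirection <- match.arg(selectedDirection)
  method <- match.arg(method)
  if (nrow(row) != 1L) stop("row must be a single enrichment row")
  h <- screenHits(screen)
  g <- h[h$type == "gene", , drop = FALSE]
  if (nrow(g) < 2L) stop("screen has fewer than two gene rows")
  opp <- if (selectedDirection == "positive") "neg" else "pos"
  score <- setNames(g[[paste0(opp, "_score")]], g$id)
  member <- intersect(strsplit(row$targeted_genes, ",", fixed = TRUE)[[1]],
                      g$id)
  if (length(member) == 0L)
    stop("no targeted gene of this term appears among the screen's gene rows")
  if (method == "camera") {
    ## small scores sit at the favorable extreme (rank 1) of a MAGeCK-style
    ## ranking, so "toward the extreme" is the lower rank tail
    tr <- cameraRankTest(score, member, rho = rho, alternative = "less")
    stat <- tr$statistic; p <- tr$p_value; kTop <- NA_integer_
  } else {
    if (is.null(kTop)) stop("fisher_topk requires kTop")
    kTop <- as.integer(kTop)
    if (kTop < 1L || kTop > nrow(g)) stop("kTop must lie in 1..#genes")
    if (length(member) >= nrow(g))
      stop("targeted genes cover every ranked gene")
    rnk <- rank(score, ties.method = "first")
    top <- g$id[rnk <= kTop]
    k <- length(intersect(member, top))
    tr <- hypergeomTest(nrow(g), length(member), kTop, k)
    stat <- k; p <- tr$p_value
  }
  out <- row
  out$direction <- selectedDirection
  out$opposite_test <- method
  out$opposite_statistic <- stat
  out$opposite_p <- p
  out$k_top <- kTop
  rownames(out) <- NULL
  out
}

#' Full screen workflow: select, enrich, opposite-rank test
#'
#' Convenience wrapper binding [selectTopMirnas()], [screenEnrich()] and
#' [oppositeRankTest()]: selects the top \code{topN} miRNAs in
#' \code{direction}, tests term enrichment of their target union, and runs
#' the opposite-ranking test on every term with adjusted enrichment p-value
#' at or below \code{alpha} (set \code{alpha = 1} to test every enriched
#' term).
#'
#' @inheritParams oppositeRankTest
#' @inheritParams screenEnrich
#' @param screen a [ScreenTable-class].
#' @param direction "positive" or "negative".
#' @param topN number of top miRNAs to select.
#' @param alpha adjusted-p threshold gating the opposite-ranking test.
#' @return data.frame of screen-analysis rows (one per gated term), with
#'   the selected miRNA ids in the \code{"selected"} attribute.
#' @export
screenAnalysis <- function(screen, interactions, terms,
                           direction = c("positive", "negative"), topN,
                           method = c("camera", "fisher_topk"), kTop = NULL,
                           rho = 0.01, minOverlap = 1L, alpha = 0.05) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  sel <- selectTopMirnas(screen, direction, topN)
  enr <- screenEnrich(sel, interactions, terms, minOverlap)
  gate <- enr[enr$p_adjusted <= alpha, , drop = FALSE]
  if (nrow(gate) == 0L) {
    warning("no term passes the enrichment significance gate")
    out <- enr[0, , drop = FALSE]
  } else {
    out <- do.call(rbind, lapply(seq_len(nrow(gate)), function(i)
      oppositeRankTest(gate[i, , drop = FALSE], screen, direction,
                       method, kTop, rho)))
  }
  attr(out, "selected") <- sel
  out
}
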