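## Term-centric engine: given terms of interest, rank every eligible miRNA
## by overrepresentation of its targets inside those terms.

#' Scan all miRNAs for overrepresented targets in terms of interest
#'
#' For every miRNA in the interaction set with at least \code{minTargets}
#' targets in the term universe, tests each requested term with the same
#' one-sided urn model as [enrichTargets()] run in the transposed direction
#' (universe = term universe, in-term genes = the term, draw = that miRNA's
#' targets in the universe). With several requested terms the per-term
#' p-values are combined per miRNA with Fisher's method; a term a miRNA does
#' not touch contributes p = 1. Combined p-values are BH-adjusted across
#' miRNAs and rows sorted ascending, ties broken by miRNA id. Per-(miRNA,
#' term) sub-rows are attached (see [subRows()]).
#'
#' @param termIdsOfInterest character vector of term ids (all must exist).
#' @param terms a [TermCollection-class].
#' @param interactions a [MirTargetSet-class].
#' @param method "classic" or "wallenius".
#' @param bias named covariate over the universe for \code{wallenius};
#'   defaults to [targetingBias()] on the full interaction set.
#' @param minTargets miRNA eligibility floor: minimum targets in the
#'   universe (default 5; set to 1 to scan every miRNA).
#' @return data.frame with one row per eligible miRNA (\code{combined_p},
#'   \code{p_adjusted}, target counts) and a \code{"subRows"} attribute of
#'   per-term p-values.
#' @export
termCentricScan <- function(termIdsOfInterest, terms, interactions,
                            method = c("classic", "wallenius"), bias = NULL,
                            minTargets = 5L) {
  method <- match.arg(method)
  termIdsOfInterest <- as.character(termIdsOfInterest)
  if (length(termIdsOfInterest) == 0L) stop("no term of interest given")
  unknown <- setdiff(termIdsOfInterest, termIds(terms))
  if (length(unknown))
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  if (length(mirnas(interactions)) == 0L) stop("empty interaction set")
  universe <- geneUniverse(terms)
  N <- length(universe)
  if (method == "wallenius" && is.null(bias))
    bias <- targetingBias(interactions, universe)
  termSets <- lapply(termIdsOfInterest,
                     function(id) intersect(termGenes(terms, id), universe))
  names(termSets) <- termIdsOfInterest
  allTermGenes <- unique(unlist(termSets, use.names = FALSE))
  rows <- list(); sub <- list()
  for (m in mirnas(interactions)) {
    tIn <- intersect(targetsOf(interactions, m), universe)
    n <- length(tIn)
    if (n < minTargets) next
    pwf <- if (method == "wallenius")
      .pwfFit(universe %in% tIn, as.numeric(bias[universe]), universe)
    else NULL
    ps <- vapply(termIdsOfInterest, function(id) {
      tg <- termSets[[id]]
      k <- length(intersect(tg, tIn))
      if (method == "classic")
        hypergeomTest(N, length(tg), n, k)$p_value
      else
        walleniusTest(N, length(tg), n, k,
                      odds = .oddsFromPwf(pwf, universe %in% tg))$p_value
    }, numeric(1))
    fc <- fisherCombine(unname(ps))
    sub[[m]] <- data.frame(mirna_id = m, term_id = termIdsOfInterest,
                           overlap = vapply(termSets, function(tg)
                             length(intersect(tg, tIn)), integer(1)),
                           p_raw = unname(ps), stringsAsFactors = FALSE)
    rows[[m]] <- data.frame(mirna_id = m,
                            targets_in_universe = n,
                            targets_in_terms =
                              length(intersect(tIn, allTermGenes)),
                            n_terms = length(termIdsOfInterest),
                            combined_statistic = fc$statistic,
                            combined_p = fc$p_value,
                            p_adjusted = NA_real_, method = method,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    warning("no miRNA passes the minimum-target floor")
    out <- data.frame(mirna_id = character(0), targets_in_universe = integer(0),
                      targets_in_terms = integer(0), n_terms = integer(0),
                      combined_statistic = numeric(0), combined_p = numeric(0),
                      p_adjusted = numeric(0), method = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "subRows") <- NULL
    return(out)
  }
  out$p_adjusted <- bhAdjust(out$combined_p)
  out <- out[order(out$combined_p, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  sub <- do.call(rbind, sub)
  rownames(sub) <- NULL
  attr(out, "subRows") <- sub
  out
}
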