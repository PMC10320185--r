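## miRNA-centric engine: combined target sets (union / n-way intersection)
## and term overrepresentation under classic hypergeometric or
## bias-corrected Wallenius testing, plus the per-miRNA meta-combined
## design.

#' Default Wallenius bias covariate: distinct targeting miRNAs per gene
#'
#' Counts, for each gene of \code{universe}, the number of distinct miRNAs
#' interacting with it in the full interaction set (0 for untargeted genes).
#' This is the default "targeting events" covariate handed to
#' [estimateBiasOdds()] by the Wallenius-corrected enrichment paths.
#'
#' @param interactions a [MirTargetSet-class].
#' @param universe character vector of background gene ids.
#' @return Named nonnegative integer vector over \code{universe}.
#' @export
targetingBias <- function(interactions, universe) {
  ed <- edges(interactions)
  tab <- table(ed$gene[ed$gene %in% universe])
  out <- setNames(integer(length(universe)), universe)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Build a combined target set from query miRNAs
#'
#' Union mode keeps genes targeted by at least one query miRNA; intersection
#' mode keeps genes targeted by at least \code{nRequired} of them (capturing
#' miRNAs that compensate each other by sharing targets). Query miRNAs
#' absent from the interaction set are collected into a warning, not
#' silently dropped; if none are present the call errors.
#'
#' @param query character vector of miRNA ids (non-empty, no duplicates).
#' @param interactions a [MirTargetSet-class].
#' @param mode "union" or "intersection".
#' @param nRequired minimum number of query miRNAs per gene (intersection
#'   mode; \code{nRequired = 1} is identical to union by definition).
#' @return A [TargetSet-class] with per-gene provenance.
#' @examples
#' ts <- MirTargetSet(c("m1", "m1", "m2", "m2"), c("A", "B", "B", "C"))
#' targetGenes(buildTargetSet(c("m1", "m2"), ts, "union"))
#' targetGenes(buildTargetSet(c("m1", "m2"), ts, "intersection", 2))
#' @export
buildTargetSet <- function(query, interactions,
                           mode = c("union", "intersection"),
                           nRequired = 2L) {
  mode <- match.arg(mode)
  query <- as.character(query)
  if (length(query) == 0L) stop("query must name at least one miRNA")
  if (anyDuplicated(query)) stop("query contains duplicate miRNA ids")
  if (mode == "union") nRequired <- 1L
  nRequired <- as.integer(nRequired)
  if (nRequired < 1L || nRequired > length(query))
    stop(sprintf("nRequired must lie in 1..%d (query size)", length(query)))
  missing <- setdiff(query, mirnas(interactions))
  if (length(missing) == length(query))
    stop("none of the query miRNAs are present in the interaction set")
  if (length(missing))
    warning("query miRNAs absent from the interaction set: ",
            paste(missing, collapse = ", "))
  present <- query[query %in% mirnas(interactions)]
  hits <- lapply(present, function(m) targetsOf(interactions, m))
  gene <- unlist(hits, use.names = FALSE)
  mir <- rep(present, lengths(hits))
  prov <- split(mir, gene)
  keep <- names(prov)[lengths(prov) >= nRequired]
  if (length(keep) == 0L)
    stop("no gene is targeted by the required number of query miRNAs")
  new("TargetSet", genes = sort(keep), provenance = prov[sort(keep)],
      mode = mode, nRequired = nRequired)
}

## One isotonic pwf fit per (flags, bias, universe); per-term odds are then
## cheap mean ratios. estimateBiasOdds() composes the two for the public
## single-term contract.
.pwfFit <- function(flags, bias, universe, nbins = NULL) {
  G <- length(universe)
  if (length(unique(bias)) == 1L)  # no usable covariate: pwf is flat
    return(setNames(rep(mean(flags), G), universe))
  if (is.null(nbins)) nbins <- max(1L, min(10L, floor(G / 20)))
  ord <- order(bias, universe)
  bin <- pmin(ceiling(seq_len(G) / (G / nbins)), nbins)
  prop <- tapply(flags[ord], bin, mean)
  idx <- as.integer(names(prop))
  up <- stats::isoreg(idx, prop)$yf
  dn <- rev(stats::isoreg(idx, rev(prop))$yf)
  fit <- if (sum((up - prop)^2) <= sum((dn - prop)^2)) up else dn
  pwf <- numeric(G)
  pwf[ord] <- fit[bin]
  names(pwf) <- universe
  pwf
}

.oddsFromPwf <- function(pwf, inTerm) {
  mT <- mean(pwf[inTerm]); mU <- mean(pwf[!inTerm])
  lo <- 1e-6; hi <- 1 - 1e-6
  if (mT < lo || mT > hi || mU < lo || mU > hi) {
    warning("degenerate pwf mean; clamping to [1e-6, 1-1e-6]")
    mT <- min(max(mT, lo), hi); mU <- min(max(mU, lo), hi)
  }
  (mT / (1 - mT)) / (mU / (1 - mU))
}

#' Term overrepresentation in a combined target set
#'
#' For every term with at least \code{minOverlap} targeted genes, tests
#' whether the target set overlaps the term more than expected when drawing
#' the same number of genes at random from the universe. \code{classic} uses
#' the one-sided hypergeometric (Fisher's exact) upper tail;
#' \code{wallenius} corrects for per-gene targeting bias via
#' [estimateBiasOdds()] with per-term odds. The universe is the term
#' collection's gene universe (annotation-based testing); target genes
#' outside it are excluded and reported via \code{message()}. P-values are
#' BH-adjusted across all tested terms and rows are sorted by
#' \code{p_raw}, ties broken by term id.
#'
#' @param targets a [TargetSet-class].
#' @param terms a [TermCollection-class].
#' @param method "classic" or "wallenius".
#' @param bias named nonnegative covariate over the universe (required for
#'   \code{wallenius}; see [targetingBias()]).
#' @param minOverlap minimum targeted genes in a term for it to be tested.
#' @param universe optional override of the background gene list (e.g. the
#'   intersection of annotated and interaction-covered genes).
#' @return data.frame with one row per tested term: counts, \code{p_raw},
#'   \code{p_adjusted}, Wallenius \code{odds} (NA for classic),
#'   comma-joined \code{targeted_genes} and \code{contributing_mirnas}.
#' @export
enrichTargets <- function(targets, terms, method = c("classic", "wallenius"),
                          bias = NULL, minOverlap = 1L, universe = NULL) {
  method <- match.arg(method)
  if (is.null(universe)) universe <- geneUniverse(terms)
  tgt <- targetGenes(targets)
  tIn <- intersect(tgt, universe)
  if (length(tIn) == 0L)
    stop("no target gene lies in the term universe")
  nOut <- length(tgt) - length(tIn)
  if (nOut > 0)
    message(sprintf("%d target gene(s) outside the universe excluded", nOut))
  N <- length(universe)
  n <- length(tIn)
  pwf <- NULL
  if (method == "wallenius") {
    if (is.null(bias))
      stop("wallenius needs a bias covariate; see targetingBias()")
    if (!all(universe %in% names(bias)))
      stop("bias must be named over the full universe")
    pwf <- .pwfFit(universe %in% tIn, as.numeric(bias[universe]), universe)
  }
  prov <- provenance(targets)
  rows <- lapply(termIds(terms), function(id) {
    tg <- intersect(termGenes(terms, id), universe)
    ov <- intersect(tg, tIn)
    k <- length(ov)
    if (k < minOverlap) return(NULL)
    if (method == "classic") {
      p <- hypergeomTest(N, length(tg), n, k)$p_value
      w <- NA_real_
    } else {
      w <- .oddsFromPwf(pwf, universe %in% tg)
      p <- walleniusTest(N, length(tg), n, k, odds = w)$p_value
    }
    mirs <- sort(unique(unlist(prov[ov], use.names = FALSE)))
    data.frame(term_id = id, term_name = unname(termNames(terms)[id]),
               genes_in_term = length(tg), targeted_in_term = k,
               targets_in_universe = n, universe_size = N,
               p_raw = p, p_adjusted = NA_real_, method = method,
               odds = w,
               targeted_genes = paste(sort(ov), collapse = ","),
               contributing_mirnas = paste(mirs, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    warning("no term passes the minimum-overlap filter")
    return(data.frame(term_id = character(0), term_name = character(0),
                      genes_in_term = integer(0), targeted_in_term = integer(0),
                      targets_in_universe = integer(0),
                      universe_size = integer(0), p_raw = numeric(0),
                      p_adjusted = numeric(0), method = character(0),
                      odds = numeric(0), targeted_genes = character(0),
                      contributing_mirnas = character(0),
                      stringsAsFactors = FALSE))
  }
  rows$p_adjusted <- bhAdjust(rows$p_raw)
  rows <- rows[order(rows$p_raw, rows$term_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Sub-rows (per-miRNA or per-term drill-down) of a combined result
#'
#' [pathwaysUnion()] and [termCentricScan()] attach the individual
#' significance rows their meta-combination was computed from; this
#' accessor retrieves them.
#'
#' @param x a result data.frame carrying a \code{"subRows"} attribute.
#' @return A data.frame of sub-rows (or NULL).
#' @export
subRows <- function(x) attr(x, "subRows")

#' Per-miRNA enrichment merged per term (meta-combined design)
#'
#' Tests each query miRNA's individual target set against every term, then
#' combines the per-miRNA p-values per term with Fisher's method into one
#' merged significance level, highlighting potent term regulators.
#' \code{combineFilter = "all"} (default) combines every tested miRNA's
#' p-value; \code{"significant_only"} combines only p-values below
#' \code{alpha} (terms left with none are dropped with a warning). Combined
#' values are BH-adjusted across terms; the per-(term, miRNA) sub-rows are
#' attached for drill-down (see [subRows()]).
#'
#' @inheritParams enrichTargets
#' @param query character vector of miRNA ids.
#' @param interactions a [MirTargetSet-class].
#' @param combineFilter "all" or "significant_only".
#' @param alpha per-miRNA significance threshold used by
#'   \code{"significant_only"}.
#' @return data.frame with one row per term (combined statistic and
#'   p-values, number of miRNAs combined) and a \code{"subRows"} attribute.
#' @export
pathwaysUnion <- function(query, interactions, terms,
                          method = c("classic", "wallenius"), bias = NULL,
                          minOverlap = 1L,
                          combineFilter = c("all", "significant_only"),
                          alpha = 0.05, universe = NULL) {
  method <- match.arg(method)
  combineFilter <- match.arg(combineFilter)
  if (length(query) == 0L) stop("query must name at least one miRNA")
  if (is.null(universe)) universe <- geneUniverse(terms)
  if (method == "wallenius" && is.null(bias))
    bias <- targetingBias(interactions, universe)
  present <- intersect(query, mirnas(interactions))
  if (length(present) == 0L)
    stop("none of the query miRNAs are present in the interaction set")
  if (length(present) < length(query))
    warning("query miRNAs absent from the interaction set: ",
            paste(setdiff(query, present), collapse = ", "))
  sub <- lapply(present, function(m) {
    ts <- buildTargetSet(m, interactions, "union")
    rows <- tryCatch(
      suppressWarnings(suppressMessages(
        enrichTargets(ts, terms, method, bias, minOverlap, universe))),
      error = function(e) NULL)
    if (is.null(rows) || nrow(rows) == 0L) return(NULL)
    rows$mirna_id <- m
    rows
  })
  sub <- do.call(rbind, sub)
  if (is.null(sub) || nrow(sub) == 0L)
    stop("no (miRNA, term) pair passes the minimum-overlap filter")
  sub <- sub[, c("term_id", "term_name", "mirna_id", "genes_in_term",
                 "targeted_in_term", "targets_in_universe", "p_raw",
                 "targeted_genes")]
  dropped <- character(0)
  comb <- lapply(split(sub, sub$term_id), function(d) {
    ps <- d$p_raw
    if (combineFilter == "significant_only") ps <- ps[ps < alpha]
    if (length(ps) == 0L) return(NULL)
    fc <- fisherCombine(ps)
    tgt <- sort(unique(unlist(strsplit(d$targeted_genes, ",", fixed = TRUE))))
    data.frame(term_id = d$term_id[1], term_name = d$term_name[1],
               genes_in_term = d$genes_in_term[1],
               n_mirnas_combined = length(ps),
               combined_statistic = fc$statistic, p_raw = fc$p_value,
               p_adjusted = NA_real_, method = method,
               combine_filter = combineFilter, alpha = alpha,
               targeted_genes = paste(tgt, collapse = ","),
               contributing_mirnas = paste(sort(d$mirna_id), collapse = ","),
               stringsAsFactors = FALSE)
  })
  dropped <- names(comb)[vapply(comb, is.null, logical(1))]
  if (length(dropped))
    warning("term(s) with no per-miRNA p-value after filtering dropped: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, comb)
  if (is.null(out) || nrow(out) == 0L)
    stop("no term retains a combinable p-value")
  out$p_adjusted <- bhAdjust(out$p_raw)
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  sub <- sub[order(sub$term_id, sub$mirna_id), , drop = FALSE]
  rownames(sub) <- NULL
  attr(out, "subRows") <- sub
  out
}
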