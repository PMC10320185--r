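## Seeded synthetic-data generator. One seed governs everything; each
## component (terms, interactions, expression, screen) draws from its own
## derived sub-stream so adding a component never perturbs the others. A
## planted mechanism threads through all components: a designated term whose
## genes are targeted by designated miRNAs above background density, whose
## targeted genes are repressed in one designated context, and whose
## miRNA/target selection signature is planted at the screen rank extremes.

#' Specification for the synthetic-fixture generator
#'
#' Collects and validates the study conditions the generator emulates; the
#' defaults are the conditions used throughout the package's tests (see the
#' methods vignette for the rationale behind each value).
#'
#' @param seed integer master seed; all randomness flows from it.
#' @param nGenes,nMirnas,nTerms numbers of genes, miRNAs and terms.
#' @param termSizeRange integer (min, max) of term gene-set sizes.
#' @param backgroundTargetDensity probability of a background (miRNA, gene)
#'   interaction edge.
#' @param plantedTermFold fold increase of edge density inside the planted
#'   (planted miRNAs x planted-term genes) block; the planted density is
#'   capped at 0.95 (with a warning when fold x density >= 1).
#' @param plantedMirnaCount number of planted miRNAs.
#' @param nContexts,samplesPerContext expression design.
#' @param plantedContextShift log2-scale repression of the planted term's
#'   targeted genes in the designated context.
#' @param expressionMode "single_cell_counts" or "tissue_tpm".
#' @param screenGenes number of gene rows in the synthetic screen
#'   (default: 400, capped at \code{nGenes}).
#' @param plantedScreenFraction fraction of the planted miRNAs' targets
#'   carrying the planted selection signature.
#' @param screenShift latent-scale (standard deviations) strength of the
#'   planted screen selection.
#' @return A validated list of class \code{"mirteaFixtureSpec"}.
#' @export
fixtureSpec <- function(seed = 1L, nGenes = 600L, nMirnas = 25L,
                        nTerms = 20L, termSizeRange = c(25L, 75L),
                        backgroundTargetDensity = 0.05,
                        plantedTermFold = 4, plantedMirnaCount = 4L,
                        nContexts = 6L, samplesPerContext = 40L,
                        plantedContextShift = 1.5,
                        expressionMode = c("single_cell_counts",
                                           "tissue_tpm"),
                        screenGenes = NULL, plantedScreenFraction = 0.6,
                        screenShift = 3) {
  expressionMode <- match.arg(expressionMode)
  if (is.null(screenGenes)) screenGenes <- min(400L, as.integer(nGenes))
  spec <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
               nMirnas = as.integer(nMirnas), nTerms = as.integer(nTerms),
               termSizeRange = as.integer(termSizeRange),
               backgroundTargetDensity = backgroundTargetDensity,
               plantedTermFold = plantedTermFold,
               plantedMirnaCount = as.integer(plantedMirnaCount),
               nContexts = as.integer(nContexts),
               samplesPerContext = as.integer(samplesPerContext),
               plantedContextShift = plantedContextShift,
               expressionMode = expressionMode,
               screenGenes = as.integer(screenGenes),
               plantedScreenFraction = plantedScreenFraction,
               screenShift = screenShift)
  with(spec, {
    stopifnot(nGenes >= 1, nMirnas >= 1, nTerms >= 1,
              length(termSizeRange) == 2, termSizeRange[1] >= 1,
              termSizeRange[2] >= termSizeRange[1],
              termSizeRange[2] <= nGenes,
              backgroundTargetDensity > 0, backgroundTargetDensity < 1,
              plantedTermFold >= 1, plantedMirnaCount >= 1,
              plantedMirnaCount <= nMirnas, nContexts >= 2,
              samplesPerContext >= 1, screenGenes >= 2,
              screenGenes <= nGenes, plantedScreenFraction > 0,
              plantedScreenFraction < 1)
  })
  structure(spec, class = "mirteaFixtureSpec")
}

## derived per-component sub-stream seeds (kept below 2^31 - 1)
.componentSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 16807) %% 2147483587)
}

#' Generate a synthetic study in memory
#'
#' Draws every component described by a [fixtureSpec()]: the term
#' collection (first term = planted), the interaction set (independent
#' Bernoulli edges, the planted block at fold x density capped at 0.95),
#' the raw expression matrix with its sample-to-context map (planted term's
#' targeted genes repressed by \code{plantedContextShift} log2 units in the
#' designated first context), and an RRA-style screen (standard-normal
#' latent selection; planted miRNAs pushed to the extreme of the negative
#' ranking and a fraction of their targets to the extreme of the positive
#' gene ranking). Identical spec and seed give identical output.
#'
#' @param spec a [fixtureSpec()].
#' @return list with elements \code{interactions} ([MirTargetSet-class]),
#'   \code{terms} ([TermCollection-class]), \code{expression} (list:
#'   \code{values} matrix, \code{sampleContexts}), \code{screen}
#'   ([ScreenTable-class]) and \code{manifest} (seed, spec, planted
#'   identities).
#' @export
simulateData <- function(spec = fixtureSpec()) {
  stopifnot(inherits(spec, "mirteaFixtureSpec"))
  genes <- sprintf("GENE%05d", seq_len(spec$nGenes))
  mirs <- sprintf("hsa-miR-%04d-sim", seq_len(spec$nMirnas))
  plantedMirs <- mirs[seq_len(spec$plantedMirnaCount)]

  ## terms -----------------------------------------------------------------
  set.seed(.componentSeed(spec$seed, 1L))
  sizes <- sample(seq(spec$termSizeRange[1], spec$termSizeRange[2]),
                  spec$nTerms, replace = TRUE)
  tsets <- lapply(sizes, function(s) sample(genes, s))
  tids <- sprintf("TERM%04d", seq_len(spec$nTerms))
  terms <- TermCollection(tids, tsets,
                          termNames = sprintf("synthetic term %d",
                                              seq_len(spec$nTerms)))
  plantedTerm <- tids[1]
  plantedGenes <- termGenes(terms, plantedTerm)

  ## interactions ----------------------------------------------------------
  set.seed(.componentSeed(spec$seed, 2L))
  d <- spec$backgroundTargetDensity
  pF <- spec$plantedTermFold * d
  if (pF >= 1) {
    warning("plantedTermFold x density >= 1; planted density capped at 0.95")
    pF <- 0.95
  } else pF <- min(pF, 0.95)
  adj <- matrix(stats::runif(spec$nMirnas * spec$nGenes) < d,
                nrow = spec$nMirnas, dimnames = list(mirs, genes))
  block <- matrix(stats::runif(spec$plantedMirnaCount *
                                 length(plantedGenes)) < pF,
                  nrow = spec$plantedMirnaCount)
  adj[plantedMirs, plantedGenes] <- block
  hit <- which(adj, arr.ind = TRUE)
  ord <- order(hit[, 1], hit[, 2])
  interactions <- MirTargetSet(mirs[hit[ord, 1]], genes[hit[ord, 2]])
  plantedTargets <- sort(unique(unlist(
    lapply(intersect(plantedMirs, mirnas(interactions)),
           function(m) intersect(targetsOf(interactions, m), plantedGenes)))))

  ## expression ------------------------------------------------------------
  set.seed(.componentSeed(spec$seed, 3L))
  ctxs <- sprintf("ctx%02d", seq_len(spec$nContexts))
  plantedCtx <- ctxs[1]
  sampleContexts <- rep(ctxs, each = spec$samplesPerContext)
  nS <- length(sampleContexts)
  shrink <- 2^(-spec$plantedContextShift)
  if (spec$expressionMode == "single_cell_counts") {
    rate <- stats::runif(spec$nGenes, 0.15, 0.7)  # baseline detection rate
    prob <- matrix(rate, spec$nGenes, nS)
    prob[genes %in% plantedTargets, sampleContexts == plantedCtx] <-
      rate[genes %in% plantedTargets] * shrink
    on <- matrix(stats::rbinom(spec$nGenes * nS, 1L, as.vector(prob)),
                 spec$nGenes, nS)
    counts <- on * (1L + matrix(stats::rpois(spec$nGenes * nS, 2),
                                spec$nGenes, nS))
    values <- counts
  } else {
    mu <- stats::runif(spec$nGenes, log(4), log(60))  # baseline TPM scale
    tpm <- matrix(stats::rlnorm(spec$nGenes * nS, meanlog = mu, sdlog = 1),
                  spec$nGenes, nS)
    tpm[genes %in% plantedTargets, sampleContexts == plantedCtx] <-
      tpm[genes %in% plantedTargets, sampleContexts == plantedCtx] * shrink
    values <- tpm
  }
  dimnames(values) <- list(genes,
                           sprintf("S%04d_%s", seq_len(nS), sampleContexts))

  ## screen ----------------------------------------------------------------
  set.seed(.componentSeed(spec$seed, 4L))
  extra <- sample(setdiff(genes, plantedTargets),
                  max(0L, spec$screenGenes - length(plantedTargets)))
  screenGeneIds <- sort(c(plantedTargets, extra))[seq_len(
    min(spec$screenGenes, length(plantedTargets) + length(extra)))]
  ids <- c(screenGeneIds, mirs)
  z <- stats::rnorm(length(ids))
  names(z) <- ids
  z[plantedMirs] <- z[plantedMirs] - spec$screenShift
  shifted <- plantedTargets[stats::runif(length(plantedTargets)) <
                              spec$plantedScreenFraction]
  shifted <- intersect(shifted, screenGeneIds)
  z[shifted] <- z[shifted] + spec$screenShift
  perm <- sample(length(ids))
  hits <- data.frame(id = ids[perm],
                     type = ifelse(ids[perm] %in% mirs, "mirna", "gene"),
                     neg_score = stats::pnorm(z[perm]),
                     neg_p = stats::pnorm(z[perm]),
                     neg_rank = NA_integer_,
                     pos_score = stats::pnorm(-z[perm]),
                     pos_p = stats::pnorm(-z[perm]),
                     pos_rank = NA_integer_, stringsAsFactors = FALSE)
  screen <- ScreenTable(hits, "rra")

  manifest <- list(seed = spec$seed, spec = unclass(spec),
                   planted = list(term_id = plantedTerm,
                                  mirna_ids = plantedMirs,
                                  context_id = plantedCtx,
                                  targeted_genes = plantedTargets,
                                  screen_shifted_genes = sort(shifted)))
  list(interactions = interactions, terms = terms,
       expression = list(values = values, sampleContexts = sampleContexts),
       screen = screen, manifest = manifest)
}

.writeMageckRRA <- function(screen, path) {
  h <- screenHits(screen)
  df <- data.frame(id = h$id,
                   `neg|score` = sprintf("%.17g", h$neg_score),
                   `neg|p-value` = sprintf("%.17g", h$neg_p),
                   `neg|rank` = h$neg_rank,
                   `pos|score` = sprintf("%.17g", h$pos_score),
                   `pos|p-value` = sprintf("%.17g", h$pos_p),
                   `pos|rank` = h$pos_rank,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.writeMatrixTsv <- function(values, path, idCol = "gene") {
  fmt <- if (is.integer(values) || all(values == round(values)))
    function(v) format(v, trim = TRUE, scientific = FALSE)
  else function(v) sprintf("%.17g", v)
  df <- data.frame(rownames(values),
                   apply(values, 2, fmt), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(idCol, colnames(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic fixture to disk
#'
#' Runs [simulateData()] and writes every workflow input as plain text:
#' \code{interactions.tsv}, \code{terms.gmt}, \code{expression.tsv} with
#' \code{contexts.tsv}, \code{screen_gene_summary.tsv}, and
#' \code{manifest.json} recording the seed, the spec and the planted
#' identities. Identical spec and seed give byte-identical files.
#'
#' @param spec a [fixtureSpec()].
#' @param outdir output directory (created if missing).
#' @return The manifest (with a \code{files} entry), invisibly.
#' @export
simulateFixture <- function(spec = fixtureSpec(), outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  dat <- simulateData(spec)
  files <- c(interactions = "interactions.tsv", terms = "terms.gmt",
             expression = "expression.tsv", contexts = "contexts.tsv",
             screen = "screen_gene_summary.tsv", manifest = "manifest.json")
  writeInteractions(dat$interactions, file.path(outdir, files["interactions"]))
  writeGMT(dat$terms, file.path(outdir, files["terms"]))
  .writeMatrixTsv(dat$expression$values, file.path(outdir, files["expression"]))
  utils::write.table(
    data.frame(sample = colnames(dat$expression$values),
               context = dat$expression$sampleContexts,
               resource = "synthetic"),
    file.path(outdir, files["contexts"]),
    sep = "\t", quote = FALSE, row.names = FALSE)
  .writeMageckRRA(dat$screen, file.path(outdir, files["screen"]))
  manifest <- dat$manifest
  manifest$files <- as.list(files)
  jsonlite::write_json(manifest, file.path(outdir, files["manifest"]),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
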