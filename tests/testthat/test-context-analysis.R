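# Percent-expressing log2FC metric and targeted-vs-non-targeted context
# testing.

# raw matrix in which gene g1 is detected in 50% / 10% / 20% of the
# samples of contexts A / B / C (10 samples each)
pctFixture <- function() {
  on <- c(rep(1, 5), rep(0, 5), 1, rep(0, 9), 1, 1, rep(0, 8))
  raw <- rbind(g1 = on * 3)
  list(raw = raw, ctx = rep(c("A", "B", "C"), each = 10))
}

test_that("percent-expressing log2FC matches the hand-computed ratio", {
  fx <- pctFixture()
  cm <- percentExpressingLog2fc(fx$raw, fx$ctx, "single_cell_counts")
  v <- log2fcValues(cm)
  expect_equal(v["g1", "A"], log2(50.01 / 15.01), tolerance = 1e-12)
  expect_equal(v["g1", "B"], log2(10.01 / 35.01), tolerance = 1e-12)
  expect_equal(v["g1", "C"], log2(20.01 / 30.01), tolerance = 1e-12)
  expect_equal(v["g1", "A"], 1.736, tolerance = 1e-3)
})

test_that("flat and silent genes land exactly at zero", {
  raw <- rbind(g_flat = rep(c(5, 0), 9),   # identical 50% everywhere
               g_zero = rep(0, 18))
  ctx <- rep(c("A", "B", "C"), each = 6)
  v <- log2fcValues(percentExpressingLog2fc(raw, ctx, "single_cell_counts"))
  expect_equal(unname(v["g_flat", ]), c(0, 0, 0))
  expect_equal(unname(v["g_zero", ]), c(0, 0, 0))
})

test_that("metric is invariant to sample order and non-focal context permutation", {
  set.seed(10)
  raw <- matrix(rpois(5 * 40, 1), 5,
                dimnames = list(paste0("g", 1:5), NULL))
  ctx <- rep(c("A", "B", "C", "D"), each = 10)
  v1 <- log2fcValues(percentExpressingLog2fc(raw, ctx, "single_cell_counts"))
  perm <- sample(ncol(raw))
  v2 <- log2fcValues(percentExpressingLog2fc(raw[, perm], ctx[perm],
                                             "single_cell_counts"))
  expect_equal(v2[, colnames(v1)], v1)
  # relabeling the non-focal contexts leaves the focal column unchanged
  ctx3 <- ctx
  ctx3[ctx == "B"] <- "D"; ctx3[ctx == "D"] <- "B"
  v3 <- log2fcValues(percentExpressingLog2fc(raw, ctx3, "single_cell_counts"))
  expect_equal(v3[, "A"], v1[, "A"])
})

test_that("tissue thresholding is scale-dependent unless co-scaled (documented non-invariance)", {
  set.seed(11)
  raw <- matrix(rlnorm(4 * 30, log(10), 1), 4,
                dimnames = list(paste0("g", 1:4), NULL))
  ctx <- rep(c("A", "B", "C"), each = 10)
  v <- log2fcValues(percentExpressingLog2fc(raw, ctx, "tissue_tpm"))
  vScaled <- log2fcValues(percentExpressingLog2fc(raw * 3, ctx, "tissue_tpm"))
  expect_false(isTRUE(all.equal(v, vScaled)))
  vCo <- log2fcValues(percentExpressingLog2fc(raw * 3, ctx, "generic",
                                              threshold = 30))
  expect_equal(vCo, v)
})

test_that("degenerate context designs are rejected", {
  raw <- rbind(g1 = rpois(10, 2))
  expect_error(percentExpressingLog2fc(raw, rep("A", 10),
                                       "single_cell_counts"),
               "two contexts")
  expect_error(percentExpressingLog2fc(raw, rep(c("A", "B"), 5), "generic"),
               "threshold")
})

# a two-context expression matrix in which the planted term's targeted
# genes carry chosen values in context "sig"
contextTestFixture <- function() {
  genes <- sprintf("g%02d", 1:12)
  terms <- TermCollection("T1", list(genes[1:6]), universe = genes)
  enr <- data.frame(term_id = "T1",
                    targeted_genes = paste(genes[1:3], collapse = ","),
                    stringsAsFactors = FALSE)
  vals <- matrix(0, 12, 2, dimnames = list(genes, c("sig", "null")))
  vals[genes[1:3], "sig"] <- c(-2, -1.5, -1)
  vals[genes[4:6], "sig"] <- c(0, 0.5, 1)
  vals[genes[1:6], "null"] <- c(0.3, -0.2, 0.1, 0.2, -0.1, 0)
  list(terms = terms, enr = enr, expr = ContextMatrix(vals))
}

test_that("context test reproduces the exact MWU worked case per context", {
  fx <- contextTestFixture()
  res <- contextTest(fx$enr, fx$terms, fx$expr, "mwu", "less")
  expect_equal(nrow(res), 2L)
  sig <- res[res$context_id == "sig", ]
  expect_equal(sig$p_raw, 1 / 20)
  expect_equal(sig$n_targeted, 3L)
  expect_equal(sig$n_nontargeted, 3L)
  # most significant context sorts first within the term
  expect_identical(res$context_id[1], "sig")
  # identical groups give p = 1 under two-sided testing
  same <- fx$expr
  vals <- log2fcValues(same)
  vals[4:6, "sig"] <- vals[1:3, "sig"]
  res2 <- contextTest(fx$enr, fx$terms, ContextMatrix(vals), "mwu",
                      "two_sided")
  expect_equal(res2$p_raw[res2$context_id == "sig"], 1)
})

test_that("recomputing the statistic from raw groups reproduces every row", {
  dat <- simulateData(fixtureSpec(seed = 8))
  enr <- enrichTargets(
    buildTargetSet(dat$manifest$planted$mirna_ids, dat$interactions,
                   "union"), dat$terms)
  expr <- percentExpressingLog2fc(dat$expression$values,
                                  dat$expression$sampleContexts,
                                  "single_cell_counts")
  res <- suppressWarnings(contextTest(enr, dat$terms, expr, "mwu", "less"))
  expect_gt(nrow(res), 0)
  vals <- log2fcValues(expr)
  for (i in sample(nrow(res), min(10, nrow(res)))) {
    id <- res$term_id[i]
    tgt <- strsplit(enr$targeted_genes[enr$term_id == id], ",")[[1]]
    tg <- intersect(termGenes(dat$terms, id), geneUniverse(dat$terms))
    tgtE <- intersect(tgt, rownames(vals))
    nonE <- intersect(setdiff(tg, tgt), rownames(vals))
    redo <- suppressWarnings(
      mwuTest(vals[tgtE, res$context_id[i]], vals[nonE, res$context_id[i]],
              "less"))
    expect_equal(res$p_raw[i], redo$p_value, tolerance = 0)
    expect_equal(res$statistic[i], redo$statistic, tolerance = 0)
  }
  # adjustment is within term across contexts
  for (id in unique(res$term_id)) {
    sel <- res$term_id == id
    expect_equal(res$p_adjusted[sel], bhAdjust(res$p_raw[sel]))
  }
})

test_that("undersized terms are skipped and reported, not silently dropped", {
  fx <- contextTestFixture()
  enrSmall <- data.frame(term_id = "T1",
                         targeted_genes = "g01,g02",  # one side below floor
                         stringsAsFactors = FALSE)
  expect_warning(res <- contextTest(enrSmall, fx$terms, fx$expr), "skipped")
  expect_equal(nrow(res), 0L)
  expect_identical(attr(res, "skipped")$term_id, "T1")
  # KS variant runs end to end on the same fixture
  resKs <- contextTest(fx$enr, fx$terms, fx$expr, "ks", "less")
  expect_equal(nrow(resKs), 2L)
  expect_identical(resKs$test, rep("ks", 2))
  expect_true(all(resKs$p_raw >= 0 & resKs$p_raw <= 1))
})
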