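# Target-set construction and term overrepresentation.

test_that("target sets follow union / at-least-n set algebra", {
  ints <- MirTargetSet(c("m1", "m1", "m2", "m2"), c("A", "B", "B", "C"))
  expect_equal(targetGenes(buildTargetSet(c("m1", "m2"), ints, "union")),
               c("A", "B", "C"))
  inter <- buildTargetSet(c("m1", "m2"), ints, "intersection", 2)
  expect_equal(targetGenes(inter), "B")
  expect_equal(provenance(inter)$B, c("m1", "m2"))
  # n-required of 1 is the union by definition
  expect_equal(targetGenes(buildTargetSet(c("m1", "m2"), ints,
                                          "intersection", 1)),
               targetGenes(buildTargetSet(c("m1", "m2"), ints, "union")))
  expect_error(buildTargetSet(c("m1", "m2"), ints, "intersection", 3),
               "nRequired")
  expect_warning(u <- buildTargetSet(c("m1", "mX"), ints, "union"), "mX")
  expect_equal(targetGenes(u), c("A", "B"))
  expect_error(buildTargetSet(c("mX", "mY"), ints, "union"), "none of the")
})

test_that("fixture union equals a brute-force union over the interaction index", {
  dat <- simulateData(fixtureSpec(seed = 1))
  q <- mirnas(dat$interactions)[1:6]
  ts <- buildTargetSet(q, dat$interactions, "union")
  brute <- sort(unique(unlist(lapply(q, function(m)
    targetsOf(dat$interactions, m)))))
  expect_identical(targetGenes(ts), brute)
  # order of input miRNAs is irrelevant
  ts2 <- buildTargetSet(rev(q), dat$interactions, "union")
  expect_identical(targetGenes(ts2), targetGenes(ts))
  expect_identical(provenance(ts2)[brute],
                   lapply(provenance(ts)[brute], rev)[brute])
})

test_that("enrichment reproduces the worked urn and honors the overlap filter", {
  fx <- tinyEnrichmentFixture()
  ts <- buildTargetSet("m1", fx$interactions, "union")
  enr <- enrichTargets(ts, fx$terms)
  expect_equal(nrow(enr), 1L)
  expect_equal(enr$p_raw, 3003 / 184756, tolerance = 1e-12)
  expect_equal(enr$targeted_in_term, 5L)
  expect_equal(enr$targets_in_universe, 10L)
  expect_identical(enr$contributing_mirnas, "m1")
  expect_identical(enr$targeted_genes, paste(fx$genes[1:5], collapse = ","))

  # a term with zero targeted genes is absent under minOverlap = 1
  terms2 <- TermCollection(c("T1", "T0"),
                           list(fx$genes[1:5], fx$genes[16:20]),
                           universe = fx$genes)
  ints2 <- MirTargetSet(rep("m1", 10), fx$genes[1:10])
  enr2 <- enrichTargets(buildTargetSet("m1", ints2, "union"), terms2)
  expect_identical(enr2$term_id, "T1")
  expect_warning(
    enrichTargets(buildTargetSet("m1", ints2, "union"), terms2,
                  minOverlap = 6L), "no term passes")
})

test_that("targeted counts re-add up from raw sets and p is monotone in overlap", {
  dat <- simulateData(fixtureSpec(seed = 4))
  ts <- buildTargetSet(mirnas(dat$interactions)[1:5], dat$interactions,
                       "union")
  enr <- enrichTargets(ts, dat$terms)
  uni <- geneUniverse(dat$terms)
  tIn <- intersect(targetGenes(ts), uni)
  recount <- vapply(enr$term_id, function(id)
    length(intersect(termGenes(dat$terms, id), tIn)), integer(1))
  expect_equal(enr$targeted_in_term, unname(recount))
  expect_equal(sum(enr$targeted_in_term), sum(recount))
  # more overlap at fixed margins never increases the one-sided p
  with(enr[1, ], {
    ks <- seq_len(min(genes_in_term, targets_in_universe))
    ps <- vapply(ks, function(k)
      hypergeomTest(universe_size, genes_in_term, targets_in_universe,
                    k)$p_value, numeric(1))
    expect_true(all(diff(ps) <= 1e-14))
  })
})

test_that("Wallenius with a flat covariate reduces to the classic test", {
  dat <- simulateData(fixtureSpec(seed = 2))
  ts <- buildTargetSet(mirnas(dat$interactions)[1:4], dat$interactions,
                       "union")
  uni <- geneUniverse(dat$terms)
  flat <- setNames(rep(3, length(uni)), uni)
  eC <- enrichTargets(ts, dat$terms, "classic")
  eW <- enrichTargets(ts, dat$terms, "wallenius", bias = flat)
  expect_identical(eW$term_id, eC$term_id)
  expect_equal(eW$p_raw, eC$p_raw, tolerance = 1e-9)
  expect_true(all(eW$odds == 1))
  # a real covariate moves the odds off 1
  eB <- enrichTargets(ts, dat$terms, "wallenius",
                      bias = targetingBias(dat$interactions, uni))
  expect_true(any(abs(eB$odds - 1) > 1e-6))
  expect_true(all(eB$p_raw >= 0 & eB$p_raw <= 1))
  expect_error(enrichTargets(ts, dat$terms, "wallenius"), "bias")
})

test_that("meta-combined design composes exactly from its sub-rows", {
  dat <- simulateData(fixtureSpec(seed = 5))
  q <- mirnas(dat$interactions)[1:4]
  pu <- pathwaysUnion(q, dat$interactions, dat$terms)
  sub <- subRows(pu)
  expect_true(all(pu$term_id %in% sub$term_id))
  for (i in seq_len(nrow(pu))) {
    ps <- sub$p_raw[sub$term_id == pu$term_id[i]]
    fc <- fisherCombine(ps)
    expect_equal(pu$p_raw[i], fc$p_value, tolerance = 0)
    expect_equal(pu$combined_statistic[i], fc$statistic, tolerance = 0)
    expect_equal(pu$n_mirnas_combined[i], length(ps))
  }
  # order of the query is irrelevant
  pu2 <- pathwaysUnion(rev(q), dat$interactions, dat$terms)
  expect_identical(pu2$term_id, pu$term_id)
  expect_equal(pu2$p_raw, pu$p_raw)
})

test_that("meta-combination with one miRNA is the single-set enrichment", {
  dat <- simulateData(fixtureSpec(seed = 6))
  m <- mirnas(dat$interactions)[3]
  pu <- pathwaysUnion(m, dat$interactions, dat$terms)
  enr <- enrichTargets(buildTargetSet(m, dat$interactions, "union"),
                       dat$terms)
  shared <- intersect(pu$term_id, enr$term_id)
  expect_setequal(pu$term_id, enr$term_id)
  expect_equal(pu$p_raw[match(shared, pu$term_id)],
               enr$p_raw[match(shared, enr$term_id)], tolerance = 1e-12)
})

test_that("significant-only combining filters sub-p-values and reports the count", {
  dat <- simulateData(fixtureSpec(seed = 7))
  q <- mirnas(dat$interactions)[1:5]
  res <- suppressWarnings(
    pathwaysUnion(q, dat$interactions, dat$terms,
                  combineFilter = "significant_only", alpha = 0.5))
  sub <- subRows(res)
  for (i in seq_len(nrow(res))) {
    ps <- sub$p_raw[sub$term_id == res$term_id[i]]
    ps <- ps[ps < 0.5]
    expect_equal(res$n_mirnas_combined[i], length(ps))
    expect_equal(res$p_raw[i], fisherCombine(ps)$p_value, tolerance = 0)
  }
  expect_true(all(res$combine_filter == "significant_only"))
})
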