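# Kernel-level checks against enumeration oracles and closed forms.

test_that("hypergeometric upper tail matches enumeration on worked urns", {
  expect_equal(hypergeomTest(20, 5, 10, 5)$p_value, 3003 / 184756,
               tolerance = 1e-12)
  expect_equal(hypergeomTest(6, 3, 3, 3)$p_value, 1 / 20, tolerance = 1e-12)
  expect_equal(hypergeomTest(15, 4, 7, 0)$p_value, 1)
  # random urns vs brute-force summation
  set.seed(11)
  for (i in 1:50) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeomTest(N, K, n, k)$p_value,
                 bruteHyperTail(N, K, n, k), tolerance = 1e-12)
  }
  expect_error(hypergeomTest(10, 12, 3, 1), "K <= N")
  expect_error(hypergeomTest(10, 5, 3, 4), "overlap")
})

test_that("Wallenius tail reduces to the central case and matches ordered-draw enumeration", {
  # central reduction
  set.seed(21)
  for (i in 1:40) {
    N <- sample(5:200, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(walleniusTest(N, K, n, k, odds = 1)$p_value,
                 hypergeomTest(N, K, n, k)$p_value, tolerance = 1e-9)
  }
  # worked example: all-white draw, w = 2
  expect_equal(walleniusTest(6, 3, 3, 3, odds = 2)$p_value,
               bruteWalleniusTail(6, 3, 3, 3, 2), tolerance = 1e-12)
  # biased-urn enumeration across small urns and odds
  for (w in c(0.4, 2.5)) {
    for (N in 3:7) for (K in 1:(N - 1)) for (n in 1:N) {
      k <- min(K, n)
      expect_equal(walleniusTest(N, K, n, k, odds = w)$p_value,
                   bruteWalleniusTail(N, K, n, k, w), tolerance = 1e-9)
    }
  }
  # strong-odds limit: in-term balls drawn first, so P(X >= K) -> 1
  expect_equal(walleniusTest(6, 3, 4, 3, odds = 1e8)$p_value, 1,
               tolerance = 1e-6)
  expect_error(walleniusTest(10, 3, 4, 2, odds = -1), "positive")
})

test_that("Wallenius integral and recursive evaluations agree", {
  for (w in c(0.5, 1, 3)) {
    pR <- walleniusTest(400, 60, 80, 20, odds = w, method = "recursive")$p_value
    pI <- walleniusTest(400, 60, 80, 20, odds = w, method = "integral")$p_value
    expect_equal(pI, pR, tolerance = 1e-8)
  }
})

test_that("bias-odds estimation recovers hand-computed and decile odds", {
  # spreadsheet-style manual computation, 8 genes, 2 bins:
  # bin1 rate 1/4, bin2 rate 3/4; term = two targeted high-bias genes
  genes <- paste0("g", 1:8)
  flags <- setNames(c(0, 0, 1, 0, 1, 1, 0, 1), genes)
  bias <- setNames(1:8, genes)
  w <- estimateBiasOdds(c("g5", "g6"), flags, bias, genes, nbins = 2)
  expect_equal(w, (0.75 / 0.25) / ((5 / 12) / (7 / 12)), tolerance = 1e-12)
  expect_equal(w, 4.2, tolerance = 1e-12)

  # top-decile target rate double the complement: w = (2p/(1-2p))/(p/(1-p))
  genes <- sprintf("G%03d", 1:200)
  bias <- setNames(seq_along(genes), genes)
  flags <- setNames(rep(c(1, 0, 0, 0), 50), genes)      # rate 1/4 per bin
  flags[181:200] <- rep(c(1, 1, 0, 0), 5)
  # top bin (genes 181..200) now at rate 1/2 with monotone lower bins
  w <- estimateBiasOdds(genes[181:200], flags, bias, genes)
  p <- mean(flags[1:180])
  expect_equal(w, (0.5 / 0.5) / (p / (1 - p)), tolerance = 1e-12)

  # constant covariate: flat pwf, no bias, odds exactly 1
  expect_equal(estimateBiasOdds(c("g1", "g2"),
                                setNames(c(1, 0, 1, 0, 1, 0, 1, 0), paste0("g", 1:8)),
                                setNames(rep(2, 8), paste0("g", 1:8)),
                                paste0("g", 1:8)), 1)
})

test_that("Fisher's method matches the df = 4 closed form and is permutation-invariant", {
  r <- fisherCombine(c(0.5, 0.5))
  x <- -2 * (log(0.5) + log(0.5))
  expect_equal(r$statistic, x, tolerance = 1e-12)
  expect_equal(r$p_value, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(r$p_value, 0.5965736, tolerance = 1e-6)
  expect_equal(fisherCombine(c(1, 1))$p_value, 1)
  expect_equal(fisherCombine(0.123)$p_value, 0.123, tolerance = 1e-12)
  set.seed(5)
  ps <- runif(7)
  expect_equal(fisherCombine(ps)$p_value, fisherCombine(rev(ps))$p_value)
  expect_equal(fisherCombine(ps)$p_value, fisherCombine(sample(ps))$p_value)
  expect_warning(p0 <- fisherCombine(c(0.5, 0))$p_value, "clamped")
  expect_true(p0 >= 0 && p0 < 1e-6)
  expect_error(fisherCombine(numeric(0)), "at least one")
})

test_that("exact MWU equals labeling enumeration for every small partition", {
  expect_equal(mwuTest(1:3, 4:6, "less")$p_value, 1 / 20)
  expect_equal(mwuTest(c(1, 2, 3), c(1, 2, 3), "two_sided")$p_value, 1)
  for (m in 1:5) for (n in m:(10 - m)) {
    if (n < 1) next
    vals <- seq_len(m + n)
    combs <- utils::combn(m + n, m)
    for (j in seq_len(ncol(combs))) {
      x <- vals[combs[, j]]; y <- vals[-combs[, j]]
      for (alt in c("less", "greater", "two_sided")) {
        got <- mwuTest(x, y, alt)
        expect_identical(got$method, "mwu_exact")
        expect_equal(got$p_value, bruteMwuP(x, y, alt), tolerance = 1e-12)
      }
    }
  }
})

test_that("MWU normal approximation tracks the exact tail and handles ties", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    for (alt in c("less", "greater", "two_sided")) {
      pe <- mwuTest(x, y, alt, exact = TRUE)$p_value
      pn <- mwuTest(x, y, alt, exact = FALSE)$p_value
      expect_lt(abs(pn - pe), 0.01)
    }
  }
  tied <- mwuTest(c(1, 1, 2, 2, 3), c(2, 3, 3, 4, 4), "less")
  expect_identical(tied$method, "mwu_normal")
  expect_true(tied$p_value > 0 && tied$p_value < 1)
  expect_warning(flat <- mwuTest(rep(2, 4), rep(2, 6), "two_sided"),
                 "identical")
  expect_equal(flat$p_value, 1)
})

test_that("KS test handles worked cases and matches permutation enumeration", {
  same <- ksTest(c(1, 5, 9), c(1, 5, 9), "two_sided")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ksTest(c(1, 2), c(3, 4), "two_sided")$statistic, 1)
  set.seed(7)
  x <- rnorm(4); y <- rnorm(4, 1)
  for (alt in c("less", "greater", "two_sided"))
    expect_equal(ksTest(x, y, alt)$p_value, bruteKsP(x, y, alt),
                 tolerance = 1e-10)
  expect_error(ksTest(numeric(0), 1:3), "non-empty")
})

test_that("competitive rank test is centred, tracks MWU, and is calibrated", {
  stat <- setNames(1:10, paste0("g", 1:10))
  sym <- cameraRankTest(stat, c("g1", "g10"), rho = 0, alternative = "less")
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 0.5)
  # rho = 0 is the Wilcoxon z-approximation
  set.seed(41)
  stat <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  for (i in 1:10) {
    member <- sample(names(stat), 20)
    for (alt in c("less", "greater")) {
      pc <- cameraRankTest(stat, member, rho = 0, alternative = alt)$p_value
      pm <- mwuTest(stat[member], stat[setdiff(names(stat), member)],
                    alt, exact = FALSE)$p_value
      expect_lt(abs(pc - pm), 0.02)
    }
  }
  # null p-values uniform over random memberships
  set.seed(42)
  stat <- setNames(rnorm(500), sprintf("g%03d", 1:500))
  ps <- replicate(500, cameraRankTest(stat, sample(names(stat), 20),
                                      rho = 0, alternative = "less")$p_value)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  expect_error(cameraRankTest(stat, names(stat)), "proper subset")
  expect_error(cameraRankTest(stat, character(0)), "empty")
})

test_that("BH adjustment reproduces step-up minima and dominates raw p", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(9)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    a <- bhAdjust(p)
    expect_true(all(a >= p - 1e-15))
    expect_true(all(a <= 1))
    expect_equal(a, stats::p.adjust(p, "BH"))
  }
})

test_that("randomized kernel calls always return probabilities in [0, 1]", {
  set.seed(77)
  for (i in 1:100) {
    N <- sample(2:80, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    w <- exp(runif(1, -2, 2))
    ps <- c(hypergeomTest(N, K, n, k)$p_value,
            walleniusTest(N, K, n, k, odds = w)$p_value,
            mwuTest(rnorm(sample(2:15, 1)), rnorm(sample(2:15, 1)),
                    sample(c("less", "greater", "two_sided"), 1))$p_value)
    expect_true(all(ps >= 0 & ps <= 1))
  }
})
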