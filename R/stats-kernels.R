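## Statistical kernels. Every test returns a "mirteaTest" record so callers
## and serializers see one shape: statistic, p_value, alternative, method,
## n_x, n_y.

.testResult <- function(statistic, p_value, alternative, method,
                        n_x = NA_integer_, n_y = NA_integer_) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value),
                 alternative = alternative, method = method,
                 n_x = as.integer(n_x), n_y = as.integer(n_y)),
            class = "mirteaTest")
}

#' @export
print.mirteaTest <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.6g, p = %.6g (n_x = %s, n_y = %s)\n",
              x$method, x$alternative, x$statistic, x$p_value,
              x$n_x, x$n_y))
  invisible(x)
}

.normAlt <- function(alternative) {
  alternative <- match.arg(gsub("\\.", "_", alternative),
                           c("less", "greater", "two_sided"))
  alternative
}

.checkUrn <- function(N, K, n, k) {
  if (any(c(N, K, n, k) != round(c(N, K, n, k))) || N < 1)
    stop("urn counts must be integers with N >= 1")
  if (K < 0 || K > N || n < 0 || n > N)
    stop("urn requires 0 <= K <= N and 0 <= n <= N")
  if (k < 0 || k > min(K, n))
    stop("overlap k must satisfy 0 <= k <= min(K, n)")
}

#' One-sided hypergeometric overrepresentation test
#'
#' Upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeometric}(N, K, n)}: the chance of observing at
#' least \code{k} in-term genes when \code{n} genes are drawn without
#' replacement from a universe of \code{N} genes of which \code{K} belong to
#' the term. This is the one-sided Fisher's exact test of the 2x2
#' term-membership by targeted-status table. Evaluation is exact (no normal
#' approximation).
#'
#' @param N universe size.
#' @param K number of universe genes in the term.
#' @param n number of genes drawn (e.g. miRNA targets in the universe).
#' @param k observed overlap between the draw and the term.
#' @return A \code{mirteaTest} record; \code{statistic} is \code{k}.
#' @examples
#' hypergeomTest(20, 5, 10, 5)$p_value  # 3003/184756
#' @export
hypergeomTest <- function(N, K, n, k) {
  .checkUrn(N, K, n, k)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  .testResult(k, min(1, p), "greater", "hypergeom", n_x = n, n_y = N - n)
}

## Wallenius DP: distribution of the number of white (in-term) balls after
## j sequential draws where each remaining white ball has weight `odds` and
## each black ball weight 1. State vector indexed by x = 0..min(j, K).
.walleniusPmfRecursive <- function(N, K, n, odds) {
  f <- 1  # P(x = 0 | 0 draws)
  for (j in seq_len(n) - 1L) {
    x <- seq_len(length(f)) - 1L
    remW <- K - x
    remB <- (N - K) - (j - x)
    ## unreachable states (negative remainders) carry f = 0; guard their
    ## transition weights so 0 * Inf cannot poison the recursion
    D <- odds * remW + remB
    pW <- ifelse(remW > 0 & D > 0, odds * remW / D, 0)
    pB <- ifelse(remB > 0 & D > 0, remB / D, 0)
    top <- min(j + 1L, K)
    g <- numeric(top + 1L)
    g[seq_along(f)] <- g[seq_along(f)] + f * pB
    g[seq_along(f) + 1L] <- g[seq_along(f) + 1L] + f * pW
    f <- g[seq_len(top + 1L)]
  }
  f  # P(X = x | n draws), x = 0..min(n, K)
}

## Integral representation of the Wallenius pmf. The textbook form
## f(x) = C(K,x) C(N-K,n-x) Int_0^1 (1-t^(w/d))^x (1-t^(1/d))^(n-x) dt
## (d = weight of the balls left in the urn) concentrates all mass in a
## boundary layer at t = 0; substituting t = u^d stretches it into a
## smooth Beta-like kernel that adaptive quadrature handles. Everything is
## assembled in log space so large-N binomial coefficients cannot overflow.
.walleniusPmfIntegral <- function(N, K, n, x, odds) {
  d <- odds * (K - x) + (N - K) - (n - x)
  if (d <= 0) d <- .Machine$double.eps
  L <- lchoose(K, x) + lchoose(N - K, n - x) + log(d)
  integrand <- function(u) {
    out <- numeric(length(u))
    pos <- u > 0 & u < 1
    up <- u[pos]
    out[pos] <- exp(L + (d - 1) * log(up) + x * log1p(-up^odds) +
                      (n - x) * log1p(-up))
    out
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, 1, rel.tol = 1e-10, abs.tol = 0,
                     subdivisions = 1000L)$value,
    error = function(e)
      stats::integrate(integrand, 0, 1, rel.tol = 1e-8,
                       subdivisions = 1000L)$value)
  val
}

#' Wallenius non-central hypergeometric upper tail
#'
#' Upper-tail probability \eqn{P(X \ge k)} under the Wallenius non-central
#' hypergeometric distribution: \code{n} balls are drawn sequentially without
#' replacement from an urn of \code{N} balls, \code{K} of which are "in-term"
#' and carry sampling weight \code{odds} relative to the rest. With
#' \code{odds = 1} this reduces exactly to the central hypergeometric test.
#' Used to correct term overrepresentation for per-gene targeting bias
#' (genes with many miRNA binding opportunities are more likely to appear in
#' any target set).
#'
#' The pmf is evaluated by a forward recursion over draws for
#' \code{N <= 2000} and by a log-space numerical-integral representation
#' above that; both give relative error below 1e-8 in the supported range.
#'
#' @inheritParams hypergeomTest
#' @param odds positive weight of in-term genes relative to out-of-term
#'   genes.
#' @param method "auto" (default), "recursive" or "integral".
#' @return A \code{mirteaTest} record; \code{statistic} is \code{k}.
#' @examples
#' walleniusTest(6, 3, 3, 3, odds = 2)$p_value
#' @export
walleniusTest <- function(N, K, n, k, odds = 1,
                          method = c("auto", "recursive", "integral")) {
  .checkUrn(N, K, n, k)
  method <- match.arg(method)
  if (!is.finite(odds) || odds <= 0) stop("odds must be a positive finite number")
  if (k == 0) return(.testResult(k, 1, "greater", "wallenius", n, N - n))
  if (method == "auto") method <- if (N <= 2000) "recursive" else "integral"
  xs <- k:min(n, K)
  if (method == "recursive") {
    f <- .walleniusPmfRecursive(N, K, n, odds)
    p <- sum(f[xs + 1L])
  } else {
    p <- sum(vapply(xs, function(x) .walleniusPmfIntegral(N, K, n, x, odds),
                    numeric(1)))
  }
  .testResult(k, min(1, max(0, p)), "greater", "wallenius", n, N - n)
}

#' Estimate per-term Wallenius odds from a targeting-bias covariate
#'
#' Fits a monotone probability-weighting function pwf(bias) describing how
#' the probability of a gene being targeted varies with a nonnegative
#' per-gene bias covariate (by default, the number of distinct miRNAs
#' interacting with the gene). Genes are split into equal-count bins by
#' covariate value, the per-bin targeted proportion is computed, and the bin
#' proportions are smoothed by isotonic regression (direction chosen by fit;
#' targeting bias may run either way). The returned odds are
#' \deqn{w = \frac{\bar p_T / (1 - \bar p_T)}{\bar p_U / (1 - \bar p_U)}}
#' where \eqn{\bar p_T} and \eqn{\bar p_U} are the mean fitted pwf over the
#' term's genes and over the rest of the universe.
#'
#' @param termGenes character vector of the term's gene ids (subset of
#'   \code{universe}).
#' @param targetFlags named 0/1 (or logical) vector over \code{universe}:
#'   was the gene targeted.
#' @param bias named nonnegative numeric covariate over \code{universe}.
#' @param universe character vector of background gene ids.
#' @param nbins number of equal-count bins; default
#'   \code{min(10, floor(length(universe)/20))}, at least 1.
#' @return Positive scalar odds \code{w} for [walleniusTest()]. Degenerate
#'   mean probabilities are clamped to \code{[1e-6, 1 - 1e-6]} with a
#'   warning.
#' @export
estimateBiasOdds <- function(termGenes, targetFlags, bias, universe,
                             nbins = NULL) {
  if (!all(termGenes %in% universe)) stop("termGenes must lie in universe")
  if (!all(universe %in% names(targetFlags)) ||
      !all(universe %in% names(bias)))
    stop("targetFlags and bias must be named over the full universe")
  flags <- as.numeric(targetFlags[universe]) > 0
  b <- as.numeric(bias[universe])
  if (any(!is.finite(b)) || any(b < 0)) stop("bias must be nonnegative finite")
  pwf <- .pwfFit(flags, b, universe, nbins)
  .oddsFromPwf(pwf, universe %in% termGenes)
}

#' Combine p-values with Fisher's method
#'
#' Computes \eqn{\chi^2 = -2 \sum_i \log p_i} and refers it to a chi-square
#' distribution with \eqn{2k} degrees of freedom. With a single p-value this
#' is the identity. Zero p-values (possible from exact tests at extreme
#' configurations) are clamped to the smallest positive double with a
#' warning rather than producing \code{-Inf}.
#'
#' @param pvals numeric vector of p-values in (0, 1]; non-empty.
#' @return A \code{mirteaTest} record with the chi-square statistic and
#'   combined p-value; \code{n_x} is the number of p-values combined.
#' @examples
#' fisherCombine(c(0.5, 0.5))$p_value  # about 0.5966
#' @export
fisherCombine <- function(pvals) {
  if (length(pvals) == 0L) stop("fisherCombine needs at least one p-value")
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  if (any(pvals == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  stat <- -2 * sum(log(pvals))
  p <- stats::pchisq(stat, df = 2 * length(pvals), lower.tail = FALSE)
  .testResult(stat, p, "greater", "fisher_combine", n_x = length(pvals))
}

#' Mann-Whitney U test (exact or tie-corrected normal approximation)
#'
#' Rank-sum comparison of two samples. \code{alternative = "less"} means the
#' first sample is stochastically smaller than the second (the default
#' orientation used throughout: "targeted" genes are passed first, so
#' "less" detects repression). The exact tie-free permutation null is used
#' when \code{length(x) + length(y) <= 20} and there are no ties; otherwise
#' a normal approximation with tie-corrected variance and a 0.5 continuity
#' correction.
#'
#' @param x,y numeric samples (first sample = \code{x}).
#' @param alternative "less", "greater" or "two_sided".
#' @param exact force the exact (\code{TRUE}; tie-free data only) or
#'   normal-approximation (\code{FALSE}) branch; \code{NULL} (default)
#'   applies the size rule above.
#' @return A \code{mirteaTest} record; \code{statistic} is the
#'   Mann-Whitney U of the first sample (number of (x, y) pairs with
#'   \eqn{x > y}, ties counted 1/2).
#' @examples
#' mwuTest(c(1, 2, 3), c(4, 5, 6), "less")$p_value  # 1/20
#' @export
mwuTest <- function(x, y, alternative = c("less", "greater", "two_sided"),
                    exact = NULL) {
  alternative <- .normAlt(alternative)
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  allEqual <- length(unique(c(x, y))) == 1L
  if (allEqual) {
    warning("all values identical in both samples; p = 1")
    return(.testResult(mu, 1, alternative, "mwu_normal", nx, ny))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  useExact <- if (is.null(exact)) nx + ny <= 20L && !ties else isTRUE(exact)
  if (useExact && ties) stop("exact branch requires tie-free data")
  if (useExact) {
    p <- switch(alternative,
      less = stats::pwilcox(U, nx, ny),
      greater = stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE),
      two_sided = {
        pl <- stats::pwilcox(U, nx, ny)
        pg <- stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
        min(1, 2 * min(pl, pg))
      })
    return(.testResult(U, p, alternative, "mwu_exact", nx, ny))
  }
  nt <- nx + ny
  tie <- table(c(x, y))
  sigma2 <- (nx * ny / 12) *
    ((nt + 1) - sum(tie^3 - tie) / (nt * (nt - 1)))
  sigma <- sqrt(sigma2)
  p <- switch(alternative,
    less = stats::pnorm((U - mu + 0.5) / sigma),
    greater = stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE),
    two_sided = {
      z <- (U - mu - sign(U - mu) * 0.5) / sigma
      min(1, 2 * stats::pnorm(-abs(z)))
    })
  .testResult(U, p, alternative, "mwu_normal", nx, ny)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares the empirical distribution functions of two samples.
#' \code{alternative = "less"} keeps the package-wide orientation (first
#' sample stochastically smaller), which corresponds to the ECDF of \code{x}
#' lying above that of \code{y}. Exact p-values are used when
#' \code{length(x) * length(y) <= 1e4} and there are no ties; the asymptotic
#' distribution otherwise.
#'
#' @inheritParams mwuTest
#' @return A \code{mirteaTest} record; \code{statistic} is the D statistic
#'   for the requested alternative.
#' @export
ksTest <- function(x, y, alternative = c("less", "greater", "two_sided")) {
  alternative <- .normAlt(alternative)
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical in both samples; p = 1")
    return(.testResult(0, 1, alternative, "ks", nx, ny))
  }
  ## R's two-sample alternatives are phrased on the CDF of x: "greater"
  ## means CDF(x) above CDF(y), i.e. x stochastically smaller.
  ralt <- switch(alternative, less = "greater", greater = "less",
                 two_sided = "two.sided")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (nx * ny <= 1e4) && !ties
  res <- suppressWarnings(stats::ks.test(x, y, alternative = ralt,
                                         exact = exact))
  .testResult(unname(res$statistic), res$p.value, alternative, "ks", nx, ny)
}

#' Competitive pre-ranked gene-set test (CAMERA-style, rank variant)
#'
#' Tests whether a gene set's members sit unusually high or low in a ranking
#' of all genes by a statistic, allowing for inter-gene correlation through
#' a variance-inflation factor \eqn{\mathrm{VIF} = 1 + (m - 1)\rho}. Genes
#' are ranked ascending by \code{stat}; the z-score compares the member mean
#' rank with its null mean \eqn{(G+1)/2} using the finite-population
#' variance of a mean of \code{m} ranks inflated by VIF, and the p-value is
#' a standard-normal tail. With \eqn{\rho = 0} this is the normal
#' approximation to the two-sample Wilcoxon test.
#'
#' @param stat named numeric vector: the ranking statistic for every gene.
#' @param member character vector of member gene ids (non-empty proper
#'   subset of \code{names(stat)}).
#' @param rho assumed inter-gene correlation in \code{[0, 1)}; default 0.01.
#' @param alternative "less" (members toward small ranks / small
#'   \code{stat}), "greater", or "two_sided".
#' @return A \code{mirteaTest} record; \code{statistic} is the z-score.
#' @export
cameraRankTest <- function(stat, member, rho = 0.01,
                           alternative = c("less", "greater", "two_sided")) {
  alternative <- .normAlt(alternative)
  if (is.null(names(stat))) stop("stat must be a named vector")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  member <- unique(member)
  G <- length(stat); m <- length(member)
  if (m == 0L) stop("member set is empty")
  if (!all(member %in% names(stat))) stop("member genes missing from stat")
  if (m >= G) stop("member set must be a proper subset of the ranked genes")
  r <- rank(stat)
  rbar <- mean(r[member])
  vif <- 1 + (m - 1) * rho
  v <- vif * (G + 1) * (G - m) / (12 * m)
  z <- (rbar - (G + 1) / 2) / sqrt(v)
  p <- switch(alternative,
    less = stats::pnorm(z),
    greater = stats::pnorm(z, lower.tail = FALSE),
    two_sided = min(1, 2 * stats::pnorm(-abs(z))))
  .testResult(z, p, alternative, "camera_pr", n_x = m, n_y = G - m)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input order is preserved and values are capped
#' at 1.
#'
#' @param pvals numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
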