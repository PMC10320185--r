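# Independent brute-force oracles. These deliberately take a different
# route than the package kernels: explicit enumeration instead of closed
# forms or dynamic programming.

# Upper tail of the central hypergeometric by direct summation of
# binomial-coefficient ratios.
bruteHyperTail <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Wallenius upper tail by exhaustive enumeration of ordered draw-type
# sequences: at each draw a white (weight w) or black (weight 1) ball is
# taken with probability proportional to the remaining group weight.
bruteWalleniusTail <- function(N, K, n, k, w) {
  rec <- function(wh, bl, left, drawn) {
    if (left == 0L) return(if (drawn >= k) 1 else 0)
    D <- w * wh + bl
    s <- 0
    if (wh > 0L) s <- s + (w * wh / D) * rec(wh - 1L, bl, left - 1L, drawn + 1L)
    if (bl > 0L) s <- s + (bl / D) * rec(wh, bl - 1L, left - 1L, drawn)
    s
  }
  rec(K, N - K, n, 0L)
}

# Mann-Whitney U for every labeling of the pooled sample: which subsets of
# size m could have been "x". Returns the U value of each labeling.
allLabelingU <- function(pooled, m) {
  r <- rank(pooled)
  combs <- utils::combn(length(pooled), m)
  colSums(matrix(r[combs], nrow = m)) - m * (m + 1) / 2
}

# Exact MWU p by enumeration over labelings.
bruteMwuP <- function(x, y, alternative) {
  pooled <- c(x, y)
  m <- length(x)
  Uall <- allLabelingU(pooled, m)
  Uobs <- sum(rank(pooled)[seq_len(m)]) - m * (m + 1) / 2
  pl <- mean(Uall <= Uobs)
  pg <- mean(Uall >= Uobs)
  switch(alternative,
         less = pl, greater = pg, two_sided = min(1, 2 * min(pl, pg)))
}

# Two-sample KS p by enumeration over labelings (tie-free data).
bruteKsP <- function(x, y, alternative) {
  pooled <- c(x, y)
  m <- length(x); n <- length(y)
  Dof <- function(xs, ys) {
    grid <- sort(pooled)
    Fx <- vapply(grid, function(g) mean(xs <= g), numeric(1))
    Fy <- vapply(grid, function(g) mean(ys <= g), numeric(1))
    switch(alternative,
           two_sided = max(abs(Fx - Fy)),
           less = max(Fx - Fy),     # x stochastically smaller: F_x above F_y
           greater = max(Fy - Fx))
  }
  Dobs <- Dof(x, y)
  combs <- utils::combn(length(pooled), m)
  Dall <- apply(combs, 2, function(ix) Dof(pooled[ix], pooled[-ix]))
  mean(Dall >= Dobs - 1e-12)
}

# Small deterministic study shared by module tests: a 20-gene universe, one
# 5-gene term, and a target set hitting all 5 term genes (the worked
# enrichment example p = 3003/184756).
tinyEnrichmentFixture <- function() {
  genes <- sprintf("g%02d", 1:20)
  terms <- TermCollection("T1", list(genes[1:5]), termNames = "tiny term",
                          universe = genes)
  ints <- MirTargetSet(rep("m1", 10), genes[1:10])
  list(genes = genes, terms = terms, interactions = ints)
}
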