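# Exact brute-force enumeration oracles, independent of the package's
# implementations. Used to validate the Wilcoxon-based statistics at small n.

# Two-sided exact signed-rank p by enumerating all 2^n sign assignments.
# Zero differences are dropped (the convention of the test implementation).
oracleSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wAll <- as.vector(signs %*% r)
  pLo <- mean(wAll <= wObs)
  pHi <- mean(wAll >= wObs)
  min(1, 2 * min(pLo, pHi))
}

# Two-sided exact rank-sum p by enumerating all C(n+m, n) group assignments.
oracleRankSumP <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(n)])
  sets <- utils::combn(n + m, n)
  wAll <- apply(sets, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(wAll <= wObs), mean(wAll >= wObs)))
}

# Direction (sign) of the rank-sum comparison: positive when x ranks higher.
oracleRankSumSign <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  sign(sum(r[seq_len(n)]) - n * (n + m + 1) / 2)
}

# Exact two-sided permutation p for Spearman's rho via full n! enumeration
# (doubling convention: 2 * min of the two tail probabilities).
oracleSpearmanP <- function(x, y) {
  rhoObs <- stats::cor(x, y, method = "spearman")
  perms <- permutations(length(y))
  rhoAll <- apply(perms, 1, function(i)
    stats::cor(x, y[i], method = "spearman"))
  min(1, 2 * min(mean(rhoAll >= rhoObs - 1e-12),
                 mean(rhoAll <= rhoObs + 1e-12)))
}

permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))))
}

# Small ready-made atlas shared across tests (cheap to build once).
tinyAtlas <- function(seed = 42, ...) {
  generateAtlas(synthConfig(nClusters = 3, nGenes = 30,
                            cellsPerReplicate = 150, replicatesPerSex = 3,
                            seed = seed, ...))
}
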