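# Shared fixtures and independent oracles, built in code.

AA <- ftszprov:::AA_ORDER

randSeq <- function(n, prob = NULL)
  paste(sample(AA, n, replace = TRUE, prob = prob), collapse = "")

randMsa <- function(nrow, ncol, gapFrac = 0.2, prefix = "s") {
  rows <- vapply(seq_len(nrow), function(i) {
    ch <- sample(AA, ncol, replace = TRUE)
    ch[runif(ncol) < gapFrac] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  ProteinMSA(setNames(rows, paste0(prefix, seq_len(nrow))))
}

# family-like MSA: noised copies of one consensus
familyMsa <- function(n, len, noise = 0.15, prefix = "f") {
  cons <- sample(AA, len, replace = TRUE)
  rows <- vapply(seq_len(n), function(i) {
    x <- cons
    m <- runif(len) < noise
    x[m] <- sample(AA, sum(m), replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
  ProteinMSA(setNames(rows, paste0(prefix, seq_len(n))))
}

logsum2 <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  max(a, b) + log1p(exp(-abs(a - b)))
}

# Independent forward oracle: exhaustive enumeration of all state
# paths (match-to-match moves with insert/delete runs; entries and
# exits as packed).  Tractable for M <= 3, L <= 6.
enumForwardBits <- function(hmm, seq, mode = "local") {
  pk <- ftszprov:::hmmLogPack(hmm, mode)
  M <- nrow(pk$lmat)
  x <- ftszprov:::aaEncode(seq) + 1L
  L <- length(x)
  em <- function(k, i) if (x[i] == 0) 0 else pk$lmat[k, x[i]]
  tot <- -Inf
  rec <- function(i, k, lp) {              # just emitted x[i] at match k
    tot <<- logsum2(tot, lp + pk$lexit[k])
    if (k < M && i < L)
      rec(i + 1, k + 1, lp + pk$lMM[k] + em(k + 1, i + 1))
    if (k < M && L - i - 1 >= 1) for (j in 1:(L - i - 1))
      rec(i + j + 1, k + 1, lp + pk$lMI[k] + (j - 1) * pk$lII[k] +
            pk$lIM[k] + em(k + 1, i + j + 1))
    if (i < L && M - k - 1 >= 1) for (d in 1:(M - k - 1)) {
      lpd <- lp + pk$lMD[k]
      if (d > 1) lpd <- lpd + sum(pk$lDD[(k + 1):(k + d - 1)])
      rec(i + 1, k + d + 1, lpd + pk$lDM[k + d] + em(k + d + 1, i + 1))
    }
  }
  for (i0 in seq_len(L)) for (k0 in seq_len(M))
    rec(i0, k0, pk$lentry[k0] + em(k0, i0))
  (tot - log(L)) / log(2)          # uniform start-offset normalisation
}

# Independent NW oracle: plain affine-gap DP returning the optimal
# score only (no traceback), for pairwise score cross-checks.
nwScoreOracle <- function(a, b, S, gapOpen, gapExt) {
  ea <- match(strsplit(a, "")[[1]], AA)
  eb <- match(strsplit(b, "")[[1]], AA)
  n <- length(ea); m <- length(eb)
  M <- matrix(-Inf, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gapOpen + gapExt * (i - 2)
  for (j in 2:(m + 1)) Y[1, j] <- gapOpen + gapExt * (j - 2)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
      S[ea[i - 1], eb[j - 1]]
    X[i, j] <- max(M[i - 1, j] + gapOpen, X[i - 1, j] + gapExt,
                   Y[i - 1, j] + gapOpen)
    Y[i, j] <- max(M[i, j - 1] + gapOpen, Y[i, j - 1] + gapExt,
                   X[i, j - 1] + gapOpen)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# distances implied by a phylo tree (additive matrix)
treeDistances <- function(phy) {
  d <- ape::dist.nodes(phy)[seq_along(phy$tip.label),
                            seq_along(phy$tip.label)]
  dimnames(d) <- list(phy$tip.label, phy$tip.label)
  d
}

# brute-force midpoint: scan every edge at 1e-4 steps for the point
# minimising the maximum distance to any leaf
bruteMidpoint <- function(phy) {
  nt <- length(phy$tip.label)
  dn <- ape::dist.nodes(phy)
  best <- list(val = Inf)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1]; b <- phy$edge[e, 2]
    len <- phy$edge.length[e]
    for (f in seq(0, 1, by = 1e-2)) {
      pos <- f * len
      m <- max(pmin(dn[a, seq_len(nt)] + pos,
                    dn[b, seq_len(nt)] + (len - pos)))
      if (m < best$val - 1e-12) best <- list(val = m, edge = e, f = f)
    }
  }
  best
}
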