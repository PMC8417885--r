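# Independent oracles used to freeze expected values; these deliberately
# use brute-force enumeration, not the package's own code paths.

# all compositions of N into k non-negative parts
compositions <- function(N, k) {
  if (k == 1L) return(matrix(N, 1L))
  out <- list()
  for (i in 0:N) {
    sub <- compositions(N - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, sub)
  }
  do.call(rbind, out)
}

# brute-force Dirichlet-multinomial pmf by integrating the Dirichlet
# density via the closed-form Polya urn product over a sequence, summed
# over all distinguishable orderings (i.e. direct gamma-ratio formula is
# avoided: we enumerate sequences)
dm_pmf_bruteforce <- function(x, alpha) {
  N <- sum(x)
  # enumerate all sequences of category labels with counts x
  seqs <- unique(combinat_perms(rep(seq_along(x), x)))
  A <- sum(alpha)
  total <- 0
  for (s in seqs) {
    p <- 1
    seen <- numeric(length(x))
    for (pos in seq_len(N)) {
      j <- s[pos]
      p <- p * (alpha[j] + seen[j]) / (A + pos - 1)
      seen[j] <- seen[j] + 1
    }
    total <- total + p
  }
  total
}

# all distinct permutations of a vector (small N only)
combinat_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in which(!duplicated(v))) {
    for (rest in combinat_perms(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# two-sided Fisher exact P by hypergeometric enumeration over all
# tables with the observed margins
fisher_enum <- function(tab) {
  r <- rowSums(tab); c1 <- colSums(tab)[1L]; n <- sum(tab)
  ks <- max(0L, c1 - r[2L]):min(r[1L], c1)
  probs <- dhyper(ks, r[1L], r[2L], c1)
  p_obs <- dhyper(tab[1L, 1L], r[1L], r[2L], c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# expected number of distinct species among N draws from DP(theta)
dp_expected_richness <- function(theta, N) {
  theta * (digamma(theta + N) - digamma(theta))
}
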