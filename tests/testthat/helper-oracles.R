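# Independent oracles used across the suite.

# Exact conditional HWE heterozygote distribution built by the recurrence
# P(h+2)/P(h) = (n_a - h)(n_b - h) / ((h+2)(h+1) / 4) ... implemented in the
# Wigginton style: start at the mid heterozygote count and propagate ratios
# in both directions, then normalise. Independent of the package's
# log-gamma closed form.
hwe_oracle_p <- function(n_hom_minor, n_het, n_hom_major) {
  n <- n_hom_minor + n_het + n_hom_major
  na <- 2 * n_hom_minor + n_het
  if (na > n) na <- 2 * n - na
  if (na == 0 || na == 2 * n) return(1)
  hets <- seq.int(na %% 2, na, by = 2)
  probs <- numeric(length(hets))
  mid <- hets[which.min(abs(hets - na * (2 * n - na) / (2 * n)))]
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  # downward: P(h-2) = P(h) * h(h-1) / (4 (hom_min+1)(hom_maj+1))
  h <- mid
  while (h >= 2) {
    hom_min <- (na - h) / 2; hom_maj <- n - h - hom_min
    i <- match(h, hets)
    probs[i - 1] <- probs[i] * h * (h - 1) /
      (4 * (hom_min + 1) * (hom_maj + 1))
    h <- h - 2
  }
  # upward: P(h+2) = P(h) * 4 hom_min hom_maj / ((h+2)(h+1))
  h <- mid
  while (h + 2 <= na && (n - (h + 2) - (na - h - 2) / 2) >= 0) {
    hom_min <- (na - h) / 2; hom_maj <- n - h - hom_min
    if (hom_min < 1 || hom_maj < 1) break
    i <- match(h, hets)
    probs[i + 1] <- probs[i] * 4 * hom_min * hom_maj / ((h + 2) * (h + 1))
    h <- h + 2
  }
  probs <- probs / sum(probs)
  obs <- match(n_het, hets)
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-10)]))
}

# All-pairs concordance probability (c-statistic) by brute force.
cstat_oracle <- function(score, y) {
  cases <- score[y == 1]; ctrls <- score[y == 0]
  tot <- 0
  for (s in cases) tot <- tot + sum(s > ctrls) + 0.5 * sum(s == ctrls)
  tot / (length(cases) * length(ctrls))
}

# Aligned sequences realising an additive 4-taxon tree: disjoint mutation
# sets per branch make every pairwise p-distance the sum of branch lengths.
additive_quartet <- function(len = 200, nA = 6, nB = 10, nC = 4, nD = 14,
                             nE = 8) {
  stopifnot(nA + nB + nC + nD + nE <= len)
  ref <- rep("A", len)
  bounds <- cumsum(c(nA, nB, nC, nD, nE))
  idx <- function(k) if (k == 1) seq_len(bounds[1]) else
    (bounds[k - 1] + 1):bounds[k]
  s <- list(A = ref, B = ref, C = ref, D = ref)
  s$A[idx(1)] <- "C"; s$B[idx(2)] <- "C"
  s$C[idx(3)] <- "C"; s$D[idx(4)] <- "C"
  s$A[idx(5)] <- "G"; s$B[idx(5)] <- "G"  # shared internal edge for clade AB
  seqs <- vapply(s, paste, character(1), collapse = "")
  attr(seqs, "branch") <- c(A = nA, B = nB, C = nC, D = nD, E = nE) / len
  seqs
}

make_null_cohort <- function(n = 600, m = 20, seed = 1) {
  set.seed(seed)
  g <- matrix(rbinom(n * m, 2, rep(runif(m, 0.15, 0.5), each = n)),
              nrow = n, dimnames = list(sprintf("S%04d", 1:n),
                                        sprintf("snp%03d", 1:m)))
  list(g = g, y = rep(0:1, length.out = n))
}
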