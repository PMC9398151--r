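# Independent oracles, deliberately naive and separate from the package
# implementation paths they check.

# Brute-force per-column majority vote for equal-length read families.
oracle_consensus <- function(reads, min_reads = 3L, min_agreement = 0.9) {
  if (length(reads) < min_reads) return(NULL)
  m <- do.call(rbind, strsplit(reads, ""))
  n <- nrow(m)
  paste(apply(m, 2, function(col) {
    tb <- table(col)
    top <- tb[tb == max(tb)]
    if (length(top) > 1L) return("N")
    if (max(tb) / n >= min_agreement - 1e-9) names(top) else "N"
  }), collapse = "")
}

# Plain dynamic-programming semi-global aligner (affine gaps, free end
# gaps, same cost convention as the package: a length-L gap costs
# open + ext * (L - 1)). Returns only the optimal score.
oracle_align_score <- function(q, r, match = 1, mismatch = -1,
                               open = 2, ext = 1) {
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  n <- length(qs); m <- length(rs)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1); E <- H; F <- H
  H[1, ] <- 0; H[, 1] <- 0
  sc <- function(a, b) {
    if (a == "N" || b == "N") 0 else if (a == b) match else mismatch
  }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
    H[i, j] <- max(H[i - 1, j - 1] + sc(qs[i - 1], rs[j - 1]),
                   E[i, j], F[i, j])
  }
  max(H[n + 1, ], H[, m + 1])
}

# Naive factorial-based two-sided Fisher exact P (minimum-likelihood
# convention), enumerating x over the support directly.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(support, function(x) {
    (factorial(r1) / (factorial(x) * factorial(r1 - x))) *
      (factorial(r2) / (factorial(c1 - x) * factorial(r2 - c1 + x))) /
      (factorial(n) / (factorial(c1) * factorial(n - c1)))
  }, 0)
  pobs <- pr[support == a]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
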