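# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms (brute force, enumeration,
# numeric root finding) than the code paths they validate.

# O(n^2) single-linkage clustering by transitive closure (union-find over
# all anchor pairs closer than max_gap), per (contig, direction, family).
oracle_cluster_members <- function(anchors, contig, direction, family,
                                   max_gap = 225, min_support = 3) {
  n <- length(anchors)
  parent <- seq_len(n)
  find <- function(i, p) { while (p[i] != i) i <- p[i]; i }
  key <- paste(contig, direction, tolower(family))
  for (i in seq_len(max(n - 1L, 0L))) {
    js <- which(key == key[i] & abs(anchors - anchors[i]) < max_gap)
    for (j in js) {
      ri <- find(i, parent); rj <- find(j, parent)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1), p = parent)
  sizes <- table(root)
  keep <- root %in% as.integer(names(sizes)[sizes >= min_support])
  # canonical cluster signature: sorted anchor multiset per component
  split(seq_len(n)[keep], root[keep])
}

# Tajima's D from per-window allele-count matrices, via literal Tajima
# (1989) formulas and brute-force pairwise differences over an explicitly
# reconstructed sample of sequences.
oracle_tajima_d <- function(count_mat, n, min_count = 1) {
  stopifnot(all(rowSums(count_mat) == n))
  S <- 0L; pi_sum <- 0
  for (r in seq_len(nrow(count_mat))) {
    cnt <- count_mat[r, ]
    sample_alleles <- rep(seq_along(cnt), cnt)
    if ((n - max(cnt)) >= min_count && sum(cnt > 0) >= 2) S <- S + 1L
    pairs <- utils::combn(n, 2)
    diffs <- sum(sample_alleles[pairs[1, ]] != sample_alleles[pairs[2, ]])
    pi_sum <- pi_sum + diffs / choose(n, 2)
  }
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  if (S == 0) return(list(S = 0L, pi = pi_sum, D = NA_real_))
  D <- (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(S = S, pi = pi_sum, D = D)
}

# Detection model inverted numerically: root of the ratio equation
# n1/n2 = 2(1-p)/p in p, then nT from the n2 equation.
oracle_detection_model <- function(n1, n2) {
  f <- function(p) n1 * p^2 - 2 * p * (1 - p) * n2
  p <- uniroot(f, c(1e-9, 1), tol = 1e-12)$root
  nT <- n2 / p^2
  list(p = p, nT = nT, n0 = nT - n1 - n2)
}

# Central binomial interval of the truth for parameter-recovery checks.
binom_interval99 <- function(q, n) {
  c(qbinom(0.005, n, q), qbinom(0.995, n, q)) / n
}
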