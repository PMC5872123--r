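# Independent reference implementations used as oracles. These are kept
# deliberately separate from the package code paths: plain-R dynamic
# programming, brute-force union-find, and exhaustive enumeration.

# full-matrix Smith-Waterman with affine gaps, plain R
sw_oracle <- function(a, b, scheme = scoring_scheme()) {
  S <- scheme$matrix
  open <- scheme$gap_open
  extend <- scheme$gap_extend
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

maxbit_oracle <- function(a, b, scheme = scoring_scheme()) {
  sw_oracle(a, b, scheme) / max(sw_oracle(a, a, scheme),
                                sw_oracle(b, b, scheme))
}

# brute-force union-find over all qualifying SMGC pairs
unionfind_families <- function(group_sets, threshold) {
  n <- length(group_sets)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- 1 - length(intersect(group_sets[[i]], group_sets[[j]])) /
        length(union(group_sets[[i]], group_sets[[j]]))
      if (d <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# exhaustive minimum-change count for a binary character on a rooted tree
fitch_oracle <- function(tree, presence) {
  n <- length(tree$tip.label)
  k <- tree$Nnode
  edges <- tree$edge
  tip_state <- as.integer(presence[tree$tip.label] > 0)
  best <- Inf
  for (mask in 0:(2^k - 1)) {
    internal <- as.integer(intToBits(mask))[seq_len(k)]
    states <- c(tip_state, internal)
    changes <- sum(states[edges[, 1]] != states[edges[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# adjusted Rand index between two label vectors
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- b * cc / choose(n, 2)
  if ((b + cc) / 2 - e == 0) return(1)
  (a - e) / ((b + cc) / 2 - e)
}

# two-sample KS D statistic computed directly from the ECDF definition
ks_d_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(fx - fy))
}
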