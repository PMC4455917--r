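# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately share no code with the package
# internals: plain loops and direct tail inversions only.

# weighted-mean strength by explicit looping over genes
oracle_strength <- function(diff, mechanisms, min_genes = 4) {
  samples <- names(diff)[-1]
  sets <- unique(mechanisms$set)
  out <- list()
  for (s in sets) {
    mem <- mechanisms[mechanisms$set == s, ]
    used <- mem[mem$gene %in% diff$gene, ]
    if (nrow(used) < min_genes) next
    row <- numeric(length(samples))
    for (j in seq_along(samples)) {
      acc <- 0
      for (i in seq_len(nrow(used))) {
        acc <- acc + used$sign[i] * diff[[samples[j]]][match(used$gene[i], diff$gene)]
      }
      row[j] <- acc / nrow(used)
    }
    out[[s]] <- row
  }
  out
}

# AUROC by exhaustive pair enumeration
oracle_auroc <- function(nr, r) {
  wins <- 0
  for (a in nr) {
    for (b in r) {
      if (a > b) wins <- wins + 1
      else if (a == b) wins <- wins + 0.5
    }
  }
  wins / (length(nr) * length(r))
}

# Clopper-Pearson by bisection on the exact binomial tails
oracle_clopper_pearson <- function(k, n, level = 0.95, tol = 1e-12) {
  alpha <- 1 - level
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else {
    # largest p with P(X >= k | p) <= alpha/2
    bisect(function(p) sum(stats::dbinom(k:n, n, p)) - alpha / 2, 0, 1)
  }
  upper <- if (k == n) 1 else {
    bisect(function(p) -(sum(stats::dbinom(0:k, n, p)) - alpha / 2), 0, 1)
  }
  c(lower = lower, upper = upper)
}

# exact one-sided rank-sum p by full enumeration of rank assignments
# (no ties; n1 + n2 small)
oracle_wilcox_p <- function(nr, r) {
  n1 <- length(nr)
  n <- n1 + length(r)
  pooled <- c(nr, r)
  stopifnot(!anyDuplicated(pooled))
  obs <- sum(rank(pooled)[seq_len(n1)])
  combos <- utils::combn(n, n1)
  stats_all <- apply(combos, 2, sum)
  mean(stats_all >= obs)
}
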