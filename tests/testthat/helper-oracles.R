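# Independent oracles: closed-form decomposable MLE assembled from clique and
# separator blocks, and a loop-based shrinkage-intensity estimate. Both are
# deliberately written from the definitions, not via the package's kernels.

# K-hat = sum_C pad((S_CC)^-1) - sum_S pad((S_SS)^-1) over junction-tree
# cliques and separators; Sigma-hat = K-hat^-1.
oracle_decomposable_mle <- function(S, jt) {
  genes <- rownames(S)
  P <- length(genes)
  K <- matrix(0, P, P, dimnames = dimnames(S))
  for (cl in jt$cliques) {
    idx <- match(cl, genes)
    K[idx, idx] <- K[idx, idx] + solve(S[idx, idx])
  }
  for (sep in jt$separators) {
    idx <- match(sep, genes)
    K[idx, idx] <- K[idx, idx] - solve(S[idx, idx])
  }
  list(concentration = K, sigma = solve(K))
}

# decomposable profile log-likelihood: (n/2) * [ sum_C log det(S_CC)^-1
#   - sum_S log det(S_SS)^-1 - P ]  (same additive convention as ggm_loglik)
oracle_decomposable_loglik <- function(S, jt, n) {
  ld <- function(idx) as.numeric(determinant(S[idx, idx, drop = FALSE],
                                             logarithm = TRUE)$modulus)
  genes <- rownames(S)
  acc <- 0
  for (cl in jt$cliques) acc <- acc - ld(match(cl, genes))
  for (sep in jt$separators) acc <- acc + ld(match(sep, genes))
  (n / 2) * (acc - length(genes))
}

# analytic shrinkage intensity for correlations toward identity, written as
# plain loops over the definition
oracle_shrink_lambda <- function(x) {
  n <- ncol(x)
  p <- nrow(x)
  xc <- x - rowMeans(x)
  s <- sqrt(apply(x, 1, var))
  z <- xc / s
  num <- 0
  den <- 0
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      w <- z[i, ] * z[j, ]
      r <- sum(w) / (n - 1)
      num <- num + n / ((n - 1)^3) * sum((w - mean(w))^2)
      den <- den + r^2
    }
  }
  max(0, min(1, num / den))
}
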