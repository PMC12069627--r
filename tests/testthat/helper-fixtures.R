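## Shared fixture builders. Everything is generated in code at test time.

## Small cohort of MZ pairs with a clustered linear relationship
## y = beta * x + pair-shared + individual noise; used by the GEE tests.
make_clustered_pairs <- function(n_pairs, beta = 0.3, alpha = 0.5,
                                 seed = 1) {
  set.seed(seed)
  pair <- rep(seq_len(n_pairs), each = 2)
  x <- stats::rnorm(2 * n_pairs)
  resid <- sqrt(alpha) * stats::rnorm(n_pairs)[pair] +
    sqrt(1 - alpha) * stats::rnorm(2 * n_pairs)
  data.frame(pair_id = sprintf("P%05d", pair), x = x,
             y = beta * x + resid, stringsAsFactors = FALSE)
}

## Dense feasible-GLS solve under block-exchangeable covariance: the
## independent oracle for the GEE coefficient path with alpha held fixed.
gls_oracle <- function(y, X, pair, alpha) {
  n <- length(y)
  V <- diag(n)
  for (p in unique(pair)) {
    idx <- which(pair == p)
    V[idx, idx] <- alpha
    diag(V)[idx] <- 1
  }
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

## Brute-force Benjamini-Hochberg step-up, evaluated from the definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

## Ct table for hand-built qPCR examples.
ct_table <- function(sample_id, gene, ct) {
  data.frame(sample_id = sample_id, gene = gene, ct = ct,
             stringsAsFactors = FALSE)
}
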