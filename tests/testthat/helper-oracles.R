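# Brute-force oracles, kept independent of the package internals.

# Fisher exact p by explicit enumeration with binomial-coefficient
# products (the package uses dhyper in log space).
oracle_fisher <- function(a, b, c, d, tail = "right") {
  K <- a + c; n1 <- a + b; N <- a + b + c + d
  if (N == 0 || K == 0 || K == N || n1 == 0 || n1 == N) return(1)
  lo <- max(0, K - (N - n1)); hi <- min(K, n1)
  xs <- lo:hi
  lp <- lchoose(n1, xs) + lchoose(N - n1, K - xs) - lchoose(N, K)
  if (tail == "right") {
    min(1, sum(exp(lp[xs >= a])))
  } else {
    min(1, sum(exp(lp[lp <= lp[xs == a] + log1p(1e-7)])))
  }
}

# Penalized log-likelihood evaluated from its definition, for grid
# search oracles (duplicates the math on purpose, not the code path).
oracle_pll <- function(x, y, beta) {
  eta <- drop(x %*% beta)
  p <- 1 / (1 + exp(-eta))
  w <- p * (1 - p)
  info <- t(x) %*% (x * w)
  sum(y * log(p) + (1 - y) * log(1 - p)) +
    0.5 * log(det(info))
}

# two-stage 2-D grid search maximizer of the penalized log-likelihood
oracle_grid_fit <- function(x, y, lim = 10, steps = 3) {
  centre <- c(0, 0); width <- lim
  for (s in seq_len(steps)) {
    b0 <- seq(centre[1] - width, centre[1] + width, length.out = 81)
    b1 <- seq(centre[2] - width, centre[2] + width, length.out = 81)
    vals <- outer(seq_along(b0), seq_along(b1), Vectorize(function(i, j)
      oracle_pll(x, y, c(b0[i], b1[j]))))
    best <- arrayInd(which.max(vals), dim(vals))
    centre <- c(b0[best[1]], b1[best[2]])
    width <- width / 20
  }
  centre
}
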