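#' Fisher's exact test for a 2x2 carrier table
#'
#' Exact hypergeometric test on a 2x2 case/control by carrier/non-carrier
#' table. The right tail is the probability, under the central
#' hypergeometric distribution with the table's margins, of observing at
#' least as many case carriers as seen; this is the test applied to the
#' per-gene CAST carrier table. The two-sided p-value uses the
#' probability-mass definition: the total probability of all tables with
#' the same margins whose point probability does not exceed that of the
#' observed table (with a relative tolerance of 1e-7 on the comparison,
#' so ties arising from floating-point noise are counted).
#'
#' Point masses are evaluated in log space, so the test is stable for
#' strongly unbalanced designs (for example 94 cases against 1246
#' controls).
#'
#' @param a Case carriers, or a 2x2 matrix `rbind(c(a, b), c(c, d))`
#'   (rows: case, control; columns: carrier, non-carrier).
#' @param b Case non-carriers.
#' @param c Control carriers.
#' @param d Control non-carriers.
#' @param tail `"right"` (enrichment of case carriers) or `"two.sided"`.
#' @return A single p-value in (0, 1].
#' @examples
#' fisher_exact(6, 54, 0, 1246, tail = "right")
#' fisher_exact(1, 9, 11, 3, tail = "two.sided")
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         tail = c("right", "two.sided")) {
  tail <- match.arg(tail)
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2L, 2L)))
      stop("matrix input must be 2x2")
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cell <- c(a, b, c, d)
  if (length(cell) != 4L || anyNA(cell) || !is.numeric(cell))
    stop("need four non-missing counts")
  if (any(cell < 0))
    stop("contingency table entries must be non-negative")
  if (any(cell != round(cell)))
    stop("contingency table entries must be integers")

  K <- a + c               # carriers
  n1 <- a + b              # cases
  N <- a + b + c + d
  if (N == 0 || K == 0 || K == N || n1 == 0 || n1 == N)
    return(1)              # single admissible table

  lo <- max(0, K - (N - n1))
  hi <- min(K, n1)
  xs <- lo:hi
  logd <- stats::dhyper(xs, K, N - K, n1, log = TRUE)
  logd_obs <- logd[xs == a]

  keep <- if (tail == "right") xs >= a else logd <= logd_obs + log1p(1e-7)
  m <- max(logd[keep])
  p <- exp(m) * sum(exp(logd[keep] - m))
  min(p, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q(i) = min over j >= i of m * p(j) / j on the
#' sorted p-values, clipped to 1, returned in the input order. Declaring
#' genes with q <= 0.005 significant implements an FDR threshold of 0.5%.
#' Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `pvals`.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (anyNA(pvals) || !is.numeric(pvals))
    stop("p-values must be numeric and non-missing")
  if (any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
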