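# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 33.3
  out[big] <- x[big]
  mid <- !big & x > -37
  out[mid] <- log1p(exp(x[mid]))
  out
}

# penalized log-likelihood l(beta) + 0.5 * log det X'WX
firth_pll <- function(x, y, beta) {
  eta <- drop(x %*% beta)
  pr <- stats::plogis(eta)
  w <- pr * (1 - pr)
  ll <- sum(y * eta - log1pexp(eta))
  xtwx <- crossprod(x * sqrt(w))
  ll + 0.5 * as.numeric(determinant(xtwx, logarithm = TRUE)$modulus)
}

#' Firth bias-reduced logistic regression (matrix interface)
#'
#' Maximizes the Jeffreys-penalized binomial log-likelihood
#' l(beta) + 0.5 * log det I(beta) by Newton iteration on the modified
#' score U*(beta) = X' (y - p + h (1/2 - p)), where p are the fitted
#' probabilities and h the leverages of the weighted hat matrix. The
#' penalty keeps the estimates finite under complete separation -- the
#' regime a gene with several case carriers and zero control carriers
#' produces -- where the ordinary maximum-likelihood estimate diverges.
#'
#' Step-halving is applied when a Newton step fails to increase the
#' penalized log-likelihood, and the raw step is capped at `max_step`
#' per coordinate. Zero-variance and collinear columns are dropped with
#' a warning before fitting.
#'
#' @param x Numeric design matrix, including the intercept column.
#' @param y Binary outcome vector (0/1 or logical), one per row of `x`.
#' @param tol Convergence tolerance on the maximum absolute modified
#'   score component.
#' @param max_iter Maximum Newton iterations.
#' @param max_halvings Maximum step-halvings per iteration.
#' @param max_step Cap on the absolute size of a raw Newton step
#'   component (log-odds units).
#' @return An object of class `"firth_fit"`: a list with elements
#'   `coefficients`, `cov` (inverse penalized information at the
#'   optimum), `converged`, `n_iter`, `max_score`, `loglik_pen`,
#'   `fitted`, `n`, `dropped` (names of removed degenerate columns).
#' @seealso [firth_logit()] for the formula interface,
#'   [wald_inference()], [firth_lrt()].
#' @export
fit_firth <- function(x, y, tol = 1e-6, max_iter = 100L,
                      max_halvings = 5L, max_step = 5) {
  x <- as.matrix(x)
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))

  # drop zero-variance (non-intercept) and collinear columns
  dec <- qr(x)
  dropped <- character(0)
  if (dec$rank < ncol(x)) {
    keep <- sort(dec$pivot[seq_len(dec$rank)])
    dropped <- colnames(x)[-keep]
    warning("dropping degenerate column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("design matrix has no usable columns")

  p <- ncol(x)
  beta <- rep(0, p)
  pll <- firth_pll(x, y, beta)
  converged <- FALSE
  iter <- 0L
  max_score <- Inf
  prev_score <- Inf
  damp <- 1

  repeat {
    eta <- drop(x %*% beta)
    pr <- stats::plogis(eta)
    w <- pr * (1 - pr)
    xw <- x * sqrt(w)
    xtwx <- crossprod(xw)
    inv <- tryCatch(chol2inv(chol(xtwx)), error = function(e) solve(xtwx))
    h <- rowSums((xw %*% inv) * xw)
    ustar <- drop(crossprod(x, y - pr + h * (0.5 - pr)))
    max_score <- max(abs(ustar))
    if (max_score < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L

    # X'WX only approximates the Jacobian of the modified score; in
    # near-degenerate directions the step can overshoot by up to a
    # factor 2, giving a persistent oscillation. Damp the step while
    # the score is not contracting, and relax the damping again once
    # it is.
    damp <- if (max_score > 0.7 * prev_score) max(damp / 2, 2^-10)
            else min(1, damp * 1.5)
    prev_score <- max_score

    delta <- drop(inv %*% ustar) * damp
    biggest <- max(abs(delta))
    if (biggest > max_step) delta <- delta * (max_step / biggest)

    # step-halve on a genuine decrease of the penalized log-likelihood;
    # tolerate rounding noise near the optimum so the full step is kept
    for (half in 0:max_halvings) {
      cand <- beta + delta
      pll_new <- firth_pll(x, y, cand)
      if (pll_new >= pll - 1e-8 * (abs(pll) + 1) || half == max_halvings)
        break
      delta <- delta / 2
    }
    beta <- cand
    pll <- pll_new
  }

  if (!converged)
    warning("Firth fit did not converge in ", max_iter,
            " iterations (max |score| = ", signif(max_score, 3), ")")

  eta <- drop(x %*% beta)
  pr <- stats::plogis(eta)
  w <- pr * (1 - pr)
  xtwx <- crossprod(x * sqrt(w))
  cov <- tryCatch(chol2inv(chol(xtwx)), error = function(e) solve(xtwx))
  dimnames(cov) <- list(colnames(x), colnames(x))
  names(beta) <- colnames(x)

  structure(list(coefficients = beta, cov = cov, converged = converged,
                 n_iter = iter, max_score = max_score, loglik_pen = pll,
                 fitted = pr, n = length(y), dropped = dropped),
            class = "firth_fit")
}

#' Firth logistic regression with a model formula
#'
#' Formula-and-data front end to [fit_firth()]. The response may be a
#' 0/1 numeric, logical, or two-level factor (second level is the
#' event). Typical use in a burden analysis: case/control status on a
#' per-gene CAST carrier indicator, adjusted for sex, standardized age,
#' and family history.
#'
#' @param formula Model formula.
#' @param data Data frame holding the variables.
#' @param ... Passed to [fit_firth()] (`tol`, `max_iter`, ...).
#' @return An object of class `c("firth_logit", "firth_fit")` with the
#'   usual accessor methods (`coef`, `vcov`, `confint`, `summary`,
#'   `predict`, `logLik`).
#' @examples
#' d <- data.frame(case = rep(c(1, 0), c(10, 40)),
#'                 carrier = rep(c(1, 0, 0), c(6, 4, 40)))
#' fit <- firth_logit(case ~ carrier, data = d)
#' summary(fit)
#' @export
firth_logit <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data = data, drop.unused.levels = TRUE)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("factor response must have two levels")
    y <- as.integer(y) - 1L
  } else if (is.logical(y)) {
    y <- as.integer(y)
  }
  x <- stats::model.matrix(mt, mf)
  fit <- fit_firth(x, y, ...)
  fit$call <- match.call()
  fit$formula <- formula
  fit$terms <- mt
  fit$xlevels <- stats::.getXlevels(mt, mf)
  class(fit) <- c("firth_logit", "firth_fit")
  fit
}

#' Wald inference for a Firth fit
#'
#' Odds ratios, Wald confidence intervals, and two-sided normal-tail
#' p-values for each retained coefficient: OR = exp(beta),
#' CI = exp(beta +/- z * se), p = 2 * Phi(-|beta / se|), with the
#' standard errors taken from the inverse penalized information.
#'
#' @param fit A converged `"firth_fit"`.
#' @param level Confidence level (default 0.95).
#' @return Data frame with one row per coefficient: `term`, `estimate`,
#'   `se`, `or`, `ci_low`, `ci_high`, `p`.
#' @export
wald_inference <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "firth_fit"))
  if (!isTRUE(fit$converged))
    stop("Wald inference requires a converged fit")
  beta <- fit$coefficients
  se <- sqrt(diag(fit$cov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(beta),
             estimate = unname(beta),
             se = unname(se),
             or = exp(unname(beta)),
             ci_low = exp(unname(beta) - z * se),
             ci_high = exp(unname(beta) + z * se),
             p = 2 * stats::pnorm(-abs(unname(beta) / se)),
             row.names = NULL)
}

#' Penalized likelihood-ratio test between nested Firth fits
#'
#' Chi-square test on twice the difference in penalized log-likelihood
#' between a full and a nested null fit, with degrees of freedom equal
#' to the difference in retained columns. More robust than the Wald
#' test near separation, where Wald standard errors are unstable.
#'
#' @param fit_full Firth fit of the larger model.
#' @param fit_null Firth fit of the nested model (its columns must be a
#'   subset of the full model's and both must use the same samples).
#' @return List with `statistic`, `df`, `p`.
#' @export
firth_lrt <- function(fit_full, fit_null) {
  stopifnot(inherits(fit_full, "firth_fit"), inherits(fit_null, "firth_fit"))
  full_terms <- names(fit_full$coefficients)
  null_terms <- names(fit_null$coefficients)
  if (!all(null_terms %in% full_terms))
    stop("null model is not nested in the full model")
  if (fit_full$n != fit_null$n)
    stop("fits use different numbers of samples")
  df <- length(full_terms) - length(null_terms)
  stat <- max(0, 2 * (fit_full$loglik_pen - fit_null$loglik_pen))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' @export
print.firth_fit <- function(x, digits = 4, ...) {
  cat("Firth bias-reduced logistic regression\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat("\nCoefficients (log-odds):\n")
  print(round(x$coefficients, digits))
  cat("\nPenalized log-likelihood:", format(x$loglik_pen, digits = digits),
      " iterations:", x$n_iter,
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' @export
summary.firth_fit <- function(object, level = 0.95, ...) {
  out <- list(fit = object,
              table = wald_inference(object, level = level),
              level = level)
  class(out) <- "summary.firth_fit"
  out
}

#' @export
print.summary.firth_fit <- function(x, digits = 4, ...) {
  cat("Firth bias-reduced logistic regression\n")
  if (!is.null(x$fit$call)) cat("Call: ", deparse(x$fit$call), "\n")
  cat("\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  cat("\nConfidence level:", x$level,
      "  penalized logLik:", format(x$fit$loglik_pen, digits = digits), "\n")
  if (length(x$fit$dropped))
    cat("Dropped degenerate column(s):",
        paste(x$fit$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.firth_fit <- function(object, ...) object$coefficients

#' @export
vcov.firth_fit <- function(object, ...) object$cov

#' @export
logLik.firth_fit <- function(object, ...) {
  structure(object$loglik_pen, df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.firth_fit <- function(object, parm, level = 0.95, ...) {
  beta <- object$coefficients
  se <- sqrt(diag(object$cov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(beta - z * se, beta + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.firth_logit <- function(object, newdata = NULL,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- stats::qlogis(object$fitted)
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    x <- stats::model.matrix(tt, mf)
    x <- x[, names(object$coefficients), drop = FALSE]
    eta <- drop(x %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}
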