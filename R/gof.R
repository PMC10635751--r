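#' Goodness-of-fit statistics for a fitted Lindley distribution
#'
#' `ad_statistic` computes the Anderson-Darling statistic
#' \deqn{A^2 = -n - \frac1n \sum_{i=1}^n (2i-1)\,[\ln F(x_{(i)}) +
#'   \ln(1 - F(x_{(n+1-i)}))]}
#' and `cvm_statistic` the Cramer-von Mises statistic
#' \deqn{W^2 = \frac{1}{12n} + \sum_{i=1}^n \Big(F(x_{(i)}) -
#'   \frac{2i-1}{2n}\Big)^2,}
#' both with \eqn{F} the Lindley cdf at `theta`.  Fitted cdf values are
#' clipped away from \{0, 1\} by 1e-300 before taking logs.  Both
#' statistics depend on the data only through the order statistics.
#'
#' @param x sample of strictly positive values (at least 2).
#' @param theta positive Lindley shape of the hypothesised law.
#' @return the nonnegative statistic value.
#' @examples
#' set.seed(1); x <- rlindley(50, 0.5)
#' ad_statistic(x, lindley_mle(x))
#' cvm_statistic(x, lindley_mle(x))
#' @export
ad_statistic <- function(x, theta) {
  .check_sample(x)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  n <- length(x)
  Fv <- pmin(pmax(plindley(sort(x), theta), 1e-300), 1 - 1e-16)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(Fv) + log(1 - rev(Fv))))
}

#' @rdname ad_statistic
#' @export
cvm_statistic <- function(x, theta) {
  .check_sample(x)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  n <- length(x)
  Fv <- plindley(sort(x), theta)
  i <- seq_len(n)
  1 / (12 * n) + sum((Fv - (2 * i - 1) / (2 * n))^2)
}

#' Parametric-bootstrap p-value for a Lindley goodness-of-fit statistic
#'
#' Because `theta` is estimated from the data, the asymptotic null tables
#' of the classical EDF statistics do not apply; the p-value is obtained
#' by a parametric bootstrap instead.  Each of the `B` replicates draws a
#' sample of the original size from Lindley(\eqn{\hat\theta}), refits
#' \eqn{\theta} by closed-form maximum likelihood, and recomputes the
#' statistic; the p-value is \eqn{(1 + \#\{stat^* \ge stat\}) / (B + 1)}.
#'
#' @param x sample of strictly positive values.
#' @param statistic `"ad"`, `"cvm"`, or a function `f(x, theta)`
#'   returning a scalar statistic.
#' @param B number of bootstrap replicates (at least 99).
#' @param seed optional integer seed.
#' @return a p-value in (0, 1].
#' @examples
#' set.seed(2); x <- rlindley(40, 1)
#' bootstrap_pvalue(x, "cvm", B = 199, seed = 1)
#' @export
bootstrap_pvalue <- function(x, statistic = c("ad", "cvm"), B = 1000,
                             seed = NULL) {
  .check_sample(x)
  if (B < 99) stop("'B' must be at least 99", call. = FALSE)
  stat_fun <- if (is.function(statistic)) statistic
  else switch(match.arg(statistic), ad = ad_statistic, cvm = cvm_statistic)
  if (!is.null(seed)) set.seed(seed)
  th <- lindley_mle(x)
  obs <- stat_fun(x, th)
  n <- length(x)
  stars <- vapply(seq_len(B), function(b) {
    xs <- rlindley(n, th)
    stat_fun(xs, lindley_mle(xs))
  }, numeric(1))
  (1 + sum(stars >= obs)) / (B + 1)
}

#' Goodness of fit of the Lindley model to one sample
#'
#' Fits `theta` by closed-form maximum likelihood, computes the
#' Anderson-Darling and Cramer-von Mises statistics, and attaches
#' parametric-bootstrap p-values ([bootstrap_pvalue()]).
#'
#' @inheritParams bootstrap_pvalue
#' @return an object of class `"lindley_gof"`: a list with `theta`, `n`,
#'   `A2`, `W2`, `p.A2`, `p.W2`, and `B`.
#' @examples
#' set.seed(3); lindley_gof(rlindley(40, 0.5), B = 199, seed = 1)
#' @export
lindley_gof <- function(x, B = 1000, seed = NULL) {
  .check_sample(x)
  th <- lindley_mle(x)
  out <- list(theta = th, n = length(x),
              A2 = ad_statistic(x, th), W2 = cvm_statistic(x, th),
              p.A2 = bootstrap_pvalue(x, "ad", B = B, seed = seed),
              p.W2 = bootstrap_pvalue(x, "cvm", B = B,
                                      seed = if (is.null(seed)) NULL else seed + 1L),
              B = B)
  class(out) <- "lindley_gof"
  out
}

#' @export
print.lindley_gof <- function(x, digits = 4, ...) {
  cat(sprintf("Lindley goodness of fit (n = %d, theta = %.*f, %d bootstrap replicates)\n",
              x$n, digits, x$theta, x$B))
  cat(sprintf("  Anderson-Darling  A2 = %.*f, p = %.*f\n", digits, x$A2,
              digits, x$p.A2))
  cat(sprintf("  Cramer-von Mises  W2 = %.*f, p = %.*f\n", digits, x$W2,
              digits, x$p.W2))
  invisible(x)
}

#' Q-Q data for a Lindley fit
#'
#' Theoretical Lindley quantiles at plotting positions
#' \eqn{(i - 0.5)/n} against the sorted sample.
#'
#' @param x sample of strictly positive values.
#' @param theta Lindley shape; defaults to the closed-form MLE of `x`.
#' @return a data frame with columns `theoretical` and `empirical`,
#'   both nondecreasing.
#' @examples
#' head(lindley_qq(rlindley(20, 1)))
#' @export
lindley_qq <- function(x, theta = NULL) {
  .check_sample(x)
  if (is.null(theta)) theta <- lindley_mle(x)
  n <- length(x)
  pp <- (seq_len(n) - 0.5) / n
  data.frame(theoretical = qlindley(pp, theta), empirical = sort(x))
}
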