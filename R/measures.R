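#' Fuzzy membership of the strength surplus
#'
#' Graded degree to which strength `x` exceeds stress `y`:
#' \eqn{\mu_A(x, y) = 1 - e^{-k(x-y)}} for \eqn{x > y} and 0 otherwise.
#' The sensitivity `k` recovers the crisp indicator \eqn{1\{y < x\}} as
#' \eqn{k \to \infty} and vanishes as \eqn{k \to 0^+}.
#'
#' @param x,y nonnegative numeric vectors (recycled).
#' @param k positive sensitivity of the membership function.
#' @return values in \eqn{[0, 1)}.
#' @examples
#' fuzzy_membership(2, 1, log(2))   # 0.5
#' fuzzy_membership(1, 1, 10)       # 0: no surplus
#' @export
fuzzy_membership <- function(x, y, k) {
  if (any(k <= 0)) stop("'k' must be positive", call. = FALSE)
  ifelse(y >= x, 0, -expm1(-k * (x - y)))
}

# Shared exponential-polynomial building blocks.  All four measures are
# integrals of (polynomial in x, y) * exp(-theta1 x - theta2 y) over
# {0 < y < x}; integrating out the inner variable leaves
#   J(a) = c * (A/a   + B/a^2)       = E[ e^{-(a - theta1)(X-Y)} 1{Y<X} ]
#   N(a) = c * (A/a^2 + 2B/a^3)      = E[ (X-Y) e^{-(a - theta1)(X-Y)} 1{Y<X} ]
# with s = theta1 + theta2, A = 1/s + 2/s^2 + 2/s^3, B = 1/s + 1/s^2 and
# c = theta1^2 theta2^2 / ((1+theta1)(1+theta2)).  Then R = J(theta1),
# FSS(k) = J(theta1) - J(theta1 + k), MRS = N(theta1)/R and
# FMRS(k) = (N(theta1) - N(theta1 + k)) / FSS(k).
.ss_const <- function(theta1, theta2) {
  s <- theta1 + theta2
  list(A = 1 / s + 2 / s^2 + 2 / s^3,
       B = 1 / s + 1 / s^2,
       c = theta1^2 * theta2^2 / ((1 + theta1) * (1 + theta2)))
}

.ss_J <- function(theta1, theta2, a) {
  w <- .ss_const(theta1, theta2)
  w$c * (w$A / a + w$B / a^2)
}

.ss_N <- function(theta1, theta2, a) {
  w <- .ss_const(theta1, theta2)
  w$c * (w$A / a^2 + 2 * w$B / a^3)
}

.check_pair <- function(theta1, theta2) {
  if (any(!is.finite(theta1)) || any(theta1 <= 0) ||
      any(!is.finite(theta2)) || any(theta2 <= 0))
    stop("'theta1' and 'theta2' must be positive finite", call. = FALSE)
}

.check_k <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop("'k' must be positive finite", call. = FALSE)
}

#' Stress-strength measures for two independent Lindley laws
#'
#' Exact closed forms for the classical reliability
#' \eqn{R = P(Y < X)}, the mean remaining strength
#' \eqn{MRS = E[X - Y \mid Y < X]}, and their fuzzy counterparts
#' FSS(k) and FMRS(k) under the membership [fuzzy_membership()],
#' when strength \eqn{X \sim} Lindley(`theta1`) and stress
#' \eqn{Y \sim} Lindley(`theta2`) are independent.
#'
#' The fuzzy measures weight the defining integrals by
#' \eqn{1 - e^{-k(x-y)}}, so for every finite `k`
#' \eqn{0 < FSS(k) < R} with \eqn{FSS(k) \uparrow R}, and
#' \eqn{FMRS(k) > MRS} with \eqn{FMRS(k) \downarrow MRS} as
#' \eqn{k \to \infty}.  All four are elementary expressions (the
#' integrands are polynomial times exponential); beyond `k = 1e6` the
#' fuzzy forms are numerically indistinguishable from their classical
#' limits, which are returned directly.
#'
#' `ss_reliability`, `ss_mrs`, `ss_fss` and `ss_fmrs` are vectorised
#' workhorses; `ss_measures` bundles them for one parameter pair and a
#' vector of `k` into a small container with a print method.
#'
#' @param theta1 positive Lindley shape of the strength variable.
#' @param theta2 positive Lindley shape of the stress variable.
#' @param k positive membership sensitivity (vector allowed).
#' @return `ss_reliability` and `ss_fss` return probabilities in (0, 1);
#'   `ss_mrs` and `ss_fmrs` positive reals.  `ss_measures` returns an
#'   object of class `"ss_measures"`: a list with `theta1`, `theta2`,
#'   `R`, `MRS` and a data frame `fuzzy` with columns `k`, `FSS`, `FMRS`.
#' @examples
#' ss_reliability(0.5, 1.5)          # 0.825
#' ss_mrs(0.5, 0.5)                  # 2.8889
#' ss_fss(0.5, 0.5, k = 1)           # 0.3827
#' ss_measures(2, 0.5, k = c(1, 5, 10, 20))
#' @export
ss_reliability <- function(theta1, theta2) {
  .check_pair(theta1, theta2)
  .ss_J(theta1, theta2, theta1)
}

#' @rdname ss_reliability
#' @export
ss_mrs <- function(theta1, theta2) {
  .check_pair(theta1, theta2)
  .ss_N(theta1, theta2, theta1) / .ss_J(theta1, theta2, theta1)
}

#' @rdname ss_reliability
#' @export
ss_fss <- function(theta1, theta2, k) {
  .check_pair(theta1, theta2)
  .check_k(k)
  n <- max(length(theta1), length(theta2), length(k))
  theta1 <- rep_len(theta1, n); theta2 <- rep_len(theta2, n)
  k <- rep_len(k, n)
  R <- .ss_J(theta1, theta2, theta1)
  out <- R - .ss_J(theta1, theta2, theta1 + k)
  big <- k > 1e6          # classical limit, exact beyond numerical relevance
  out[big] <- R[big]
  out
}

#' @rdname ss_reliability
#' @export
ss_fmrs <- function(theta1, theta2, k) {
  .check_pair(theta1, theta2)
  .check_k(k)
  n <- max(length(theta1), length(theta2), length(k))
  theta1 <- rep_len(theta1, n); theta2 <- rep_len(theta2, n)
  k <- rep_len(k, n)
  N0 <- .ss_N(theta1, theta2, theta1)
  R <- .ss_J(theta1, theta2, theta1)
  out <- (N0 - .ss_N(theta1, theta2, theta1 + k)) /
    (R - .ss_J(theta1, theta2, theta1 + k))
  big <- k > 1e6
  out[big] <- (N0 / R)[big]
  out
}

#' @rdname ss_reliability
#' @export
ss_measures <- function(theta1, theta2, k = c(1, 5, 10, 20)) {
  .check_pair(theta1, theta2)
  if (length(theta1) != 1L || length(theta2) != 1L)
    stop("'ss_measures' takes a single parameter pair", call. = FALSE)
  .check_k(k)
  out <- list(theta1 = theta1, theta2 = theta2,
              R = ss_reliability(theta1, theta2),
              MRS = ss_mrs(theta1, theta2),
              fuzzy = data.frame(k = k,
                                 FSS = ss_fss(theta1, theta2, k),
                                 FMRS = ss_fmrs(theta1, theta2, k)))
  class(out) <- "ss_measures"
  out
}

#' @export
print.ss_measures <- function(x, digits = 4, ...) {
  cat(sprintf("Lindley stress-strength measures (theta1 = %g, theta2 = %g)\n",
              x$theta1, x$theta2))
  cat(sprintf("  R   = %.*f   (classical reliability P(Y < X))\n", digits, x$R))
  cat(sprintf("  MRS = %.*f   (mean remaining strength)\n", digits, x$MRS))
  if (nrow(x$fuzzy)) {
    cat("  fuzzy measures:\n")
    print(format(x$fuzzy, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.ss_measures <- function(x, ...) {
  data.frame(theta1 = x$theta1, theta2 = x$theta2, R = x$R, MRS = x$MRS,
             k = x$fuzzy$k, FSS = x$fuzzy$FSS, FMRS = x$fuzzy$FMRS)
}
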