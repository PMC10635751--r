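#' Defining-integral quadrature oracle for the stress-strength measures
#'
#' Evaluates all four measures by adaptive numerical integration of their
#' defining double integrals over \eqn{\{0 < y < x\}} — no closed forms
#' anywhere on this code path.  The outer integral runs over
#' \eqn{[0, \infty)} and every inner integral is itself an adaptive 1-D
#' pass (accuracy over speed), so the oracle is slow by design and is
#' meant for validating the closed forms in [ss_measures()], not for
#' production use.
#'
#' @inheritParams ss_reliability
#' @param k vector of positive membership sensitivities (may be empty,
#'   in which case only `R` and `MRS` are computed).
#' @param abs.tol absolute tolerance requested from each 1-D pass.
#' @return a list with components `R`, `MRS`, and (per `k`) `FSS`,
#'   `FMRS`.  Errors if the quadrature reports failure to reach `abs.tol`.
#' @examples
#' \donttest{
#' ss_measures_numeric(0.5, 0.5, k = 1)$FSS   # 0.38272 by quadrature
#' }
#' @export
ss_measures_numeric <- function(theta1, theta2, k = numeric(0),
                                abs.tol = 1e-10) {
  .check_pair(theta1, theta2)
  if (length(k)) .check_k(k)
  inner <- function(g, upper) {
    r <- stats::integrate(g, 0, upper, abs.tol = abs.tol,
                          rel.tol = .Machine$double.eps^0.5,
                          subdivisions = 400L, stop.on.error = FALSE)
    if (!r$message %in% c("OK", "roundoff error was detected"))
      stop("inner quadrature failed: ", r$message, call. = FALSE)
    r$value
  }
  outer_int <- function(fx) {
    r <- stats::integrate(function(x) vapply(x, fx, numeric(1)),
                          0, Inf, abs.tol = abs.tol,
                          rel.tol = .Machine$double.eps^0.5,
                          subdivisions = 400L, stop.on.error = FALSE)
    if (!r$message %in% c("OK", "roundoff error was detected"))
      stop("outer quadrature failed: ", r$message, call. = FALSE)
    r$value
  }
  R <- outer_int(function(x)
    dlindley(x, theta1) * inner(function(y) dlindley(y, theta2), x))
  # numerator of MRS = E[(X - Y) 1{Y < X}]
  num0 <- outer_int(function(x)
    dlindley(x, theta1) * inner(function(y) (x - y) * dlindley(y, theta2), x))
  FSS <- FMRS <- numeric(length(k))
  for (i in seq_along(k)) {
    ki <- k[i]
    FSS[i] <- outer_int(function(x)
      dlindley(x, theta1) *
        inner(function(y) fuzzy_membership(x, y, ki) * dlindley(y, theta2), x))
    numk <- outer_int(function(x)
      dlindley(x, theta1) *
        inner(function(y) (x - y) * fuzzy_membership(x, y, ki) *
                dlindley(y, theta2), x))
    FMRS[i] <- numk / FSS[i]
  }
  list(R = R, MRS = num0 / R, FSS = FSS, FMRS = FMRS)
}
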