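#' Monte Carlo comparison of the stress-strength estimators
#'
#' For every cell of a grid of sample sizes and generating parameters,
#' repeatedly draws independent Lindley strength/stress samples, runs the
#' requested estimators, and reports bias and mean squared error of each
#' measure estimate against its analytic true value from
#' [ss_measures()].
#'
#' Defaults mirror a standard design for this model: sizes
#' (5,5), (10,10), (30,30), (50,50), (100,100); parameter pairs
#' (0.5,0.5), (0.5,1.5), (2,0.5), (1.5,1.5); k in \{1, 5, 10, 20\}.
#' The default replication count is 1000; Monte Carlo standard errors of
#' the mean estimate are always reported so scaled-down runs remain
#' interpretable.  Each cell is seeded independently (`seed` plus a
#' cell-index offset), so any cell can be re-run in isolation and two
#' runs with the same seed are identical.  Per-replication estimator
#' failures are caught, counted in `reps_failed`, and excluded from the
#' summaries — never silently dropped.
#'
#' @param sizes list of length-2 size vectors `c(n, m)`.
#' @param params list of length-2 parameter vectors `c(theta1, theta2)`.
#' @param k vector of membership sensitivities.
#' @param methods subset of `c("mle", "mps", "is", "mcmc")`.
#' @param reps replications per cell (at least 2).
#' @param prior [ss_prior()] for the Bayesian methods (default: gamma
#'   Gamma(3,4) x Gamma(2,3) for `"is"`, noninformative for `"mcmc"`).
#' @param draws,burnin Bayesian budget per replication (kept modest by
#'   default because they run inside the replication loop).
#' @param seed integer master seed.
#' @param keep if TRUE, the raw per-replication estimates are attached as
#'   attribute `"raw"` (a list of matrices, one per cell x method).
#' @return a long-format data frame of class `"ss_simstudy"` with columns
#'   `n`, `m`, `theta1`, `theta2`, `method`, `measure`, `k` (NA for the
#'   classical measures), `true`, `mean_est`, `bias`, `mse`, `mc_se`,
#'   `reps_ok`, `reps_failed`.
#' @examples
#' \donttest{
#' s <- ss_simstudy(sizes = list(c(5, 5), c(50, 50)),
#'                  params = list(c(0.5, 0.5)), k = 1,
#'                  methods = "mle", reps = 200, seed = 1)
#' subset(s, measure == "R")
#' }
#' @export
ss_simstudy <- function(sizes = list(c(5, 5), c(10, 10), c(30, 30),
                                     c(50, 50), c(100, 100)),
                        params = list(c(0.5, 0.5), c(0.5, 1.5),
                                      c(2, 0.5), c(1.5, 1.5)),
                        k = c(1, 5, 10, 20),
                        methods = c("mle", "mps"),
                        reps = 1000, prior = NULL,
                        draws = 2000, burnin = 500,
                        seed = 1, keep = FALSE) {
  methods <- match.arg(methods, c("mle", "mps", "is", "mcmc"),
                       several.ok = TRUE)
  if (reps < 2) stop("'reps' must be at least 2", call. = FALSE)
  .check_k(k)
  meas_names <- c("R", "MRS", paste0("FSS.k", k), paste0("FMRS.k", k))
  kcol <- c(NA, NA, k, k)
  mname <- c("R", "MRS", rep("FSS", length(k)), rep("FMRS", length(k)))

  est_one <- function(method, x, y) {
    if (method %in% c("mle", "mps")) {
      th1 <- if (method == "mle") lindley_mle(x) else lindley_mps(x)$theta
      th2 <- if (method == "mle") lindley_mle(y) else lindley_mps(y)$theta
      c(ss_reliability(th1, th2), ss_mrs(th1, th2),
        ss_fss(th1, th2, k), ss_fmrs(th1, th2, k))
    } else {
      fit <- ssfit(x, y, method = method, k = k, prior = prior,
                   draws = draws, burnin = burnin)
      c(fit$measures$R, fit$measures$MRS,
        fit$measures$fuzzy$FSS, fit$measures$fuzzy$FMRS)
    }
  }

  rows <- list(); raw <- list(); cell <- 0L
  for (pp in params) for (nm in sizes) {
    cell <- cell + 1L
    n <- nm[1]; m <- nm[2]; th1 <- pp[1]; th2 <- pp[2]
    tv <- c(ss_reliability(th1, th2), ss_mrs(th1, th2),
            ss_fss(th1, th2, k), ss_fmrs(th1, th2, k))
    set.seed((seed + 9973 * cell) %% (2^31 - 1))
    res <- matrix(NA_real_, nrow = reps, ncol = length(meas_names),
                  dimnames = list(NULL, meas_names))
    fails <- stats::setNames(integer(length(methods)), methods)
    for (method in methods) {
      for (r in seq_len(reps)) {
        x <- rlindley(n, th1); y <- rlindley(m, th2)
        est <- tryCatch(est_one(method, x, y), error = function(e) NULL)
        if (is.null(est)) fails[method] <- fails[method] + 1L
        else res[r, ] <- est
      }
      ok <- stats::complete.cases(res)
      if (!any(ok))
        stop(sprintf("all %d replications failed for method '%s' in cell %d",
                     reps, method, cell), call. = FALSE)
      mean_est <- colMeans(res[ok, , drop = FALSE])
      mse <- colMeans((res[ok, , drop = FALSE] -
                         matrix(tv, sum(ok), length(tv), byrow = TRUE))^2)
      mc_se <- apply(res[ok, , drop = FALSE], 2, stats::sd) / sqrt(sum(ok))
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, m = m, theta1 = th1, theta2 = th2, method = method,
        measure = mname, k = kcol, true = tv, mean_est = mean_est,
        bias = mean_est - tv, mse = mse, mc_se = mc_se,
        reps_ok = sum(ok), reps_failed = unname(fails[method]),
        row.names = NULL)
      if (keep) raw[[paste(cell, method, sep = ".")]] <- res[ok, , drop = FALSE]
      res[] <- NA_real_
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ss_simstudy", "data.frame")
  if (keep) attr(out, "raw") <- raw
  out
}

#' @export
print.ss_simstudy <- function(x, digits = 4, ...) {
  cat(sprintf("Stress-strength simulation study: %d cells x measures\n",
              length(unique(paste(x$n, x$theta1, x$theta2, x$method)))))
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}
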