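#' Fit a Lindley stress-strength reliability model
#'
#' Estimates the Lindley shapes \eqn{(\theta_1, \theta_2)} of an
#' independent strength sample `x` and stress sample `y` (unequal sizes
#' allowed) and, through them, the classical and fuzzy stress-strength
#' measures R, MRS, FSS(k) and FMRS(k).
#'
#' Four estimation methods are available:
#' \describe{
#'   \item{`"mle"`}{closed-form maximum likelihood per sample
#'     ([lindley_mle()]); measures by plug-in (invariance).}
#'   \item{`"mps"`}{maximum product of spacings per sample
#'     ([lindley_mps()]); the two-sample objective is additively
#'     separable, so each shape solves an independent 1-D problem;
#'     measures by plug-in.}
#'   \item{`"is"`}{self-normalised importance sampling under a gamma
#'     prior: `draws` pairs from the posterior gamma kernels, weights
#'     proportional to \eqn{(1+\theta_1)^{-n}(1+\theta_2)^{-m}}; every
#'     reported estimate is the weighted posterior mean (squared-error
#'     loss).}
#'   \item{`"mcmc"`}{random-walk Metropolis on \eqn{\log\theta} for each
#'     univariate full conditional (step adapted during burn-in, Jacobian
#'     included so the chain targets the stated density in \eqn{\theta});
#'     estimates are means over the retained draws.}
#' }
#' For the Bayesian methods the parameter estimates are posterior means
#' and the measure estimates are posterior means of the measures (not
#' plug-ins at the posterior mean).  Bayesian runs are reproducible via
#' `seed`; the frequentist methods are deterministic.
#'
#' @param x strength sample, strictly positive.
#' @param y stress sample, strictly positive.
#' @param method one of `"mle"`, `"mps"`, `"is"`, `"mcmc"`.
#' @param k vector of positive membership sensitivities at which the
#'   fuzzy measures are evaluated.
#' @param prior an [ss_prior()]; defaults to the gamma prior
#'   Gamma(3, 4) x Gamma(2, 3) for `"is"` and the noninformative prior
#'   for `"mcmc"`.  Ignored by the frequentist methods.
#' @param draws number of importance draws (`"is"`) or retained MCMC
#'   draws (`"mcmc"`).
#' @param burnin number of discarded initial MCMC iterations (the chain
#'   runs for `draws + burnin` total).
#' @param seed optional integer seed for the Bayesian methods.
#' @param tie tie-handling rule for `"mps"`, see [lindley_spacings()].
#' @return an object of class `"ssfit"`: a list with `method`, `theta`
#'   (named length-2 vector), `measures` (an [ss_measures()]-shaped
#'   container holding the method's estimates), `diagnostics`
#'   (objective values, effective sample size, acceptance rates, MC
#'   standard errors as applicable), `draws` (posterior draws and weights
#'   for the Bayesian methods), the data, and the call.
#' @examples
#' set.seed(1)
#' x <- rlindley(40, 0.5); y <- rlindley(40, 1.5)
#' fit <- ssfit(x, y, method = "mle", k = c(1, 5, 10, 20))
#' fit
#' coef(fit)
#' summary(fit)
#' @seealso [ss_measures()], [lindley_gof()], [ss_simstudy()]
#' @export
ssfit <- function(x, y, method = c("mle", "mps", "is", "mcmc"),
                  k = c(1, 5, 10, 20), prior = NULL,
                  draws = 10000, burnin = 1000, seed = NULL,
                  tie = c("density", "none")) {
  method <- match.arg(method)
  tie <- match.arg(tie)
  .check_sample(x, "x"); .check_sample(y, "y")
  .check_k(k)
  cl <- match.call()

  if (method %in% c("mle", "mps")) {
    if (method == "mle") {
      th1 <- lindley_mle(x); th2 <- lindley_mle(y)
      diag <- list(loglik = lindley_loglik(th1, x) + lindley_loglik(th2, y))
    } else {
      f1 <- lindley_mps(x, tie = tie); f2 <- lindley_mps(y, tie = tie)
      th1 <- f1$theta; th2 <- f2$theta
      diag <- list(objective = c(x = f1$objective, y = f2$objective))
    }
    meas <- ss_measures(th1, th2, k)
    post <- NULL
  } else {
    if (is.null(prior))
      prior <- if (method == "is") ss_prior("gamma") else ss_prior("noninformative")
    if (!inherits(prior, "ss_prior")) stop("'prior' must be an ss_prior object",
                                           call. = FALSE)
    if (method == "is") {
      post <- .is_fit(x, y, prior, N = draws, seed = seed)
      W <- post$weights
      wmean <- function(psi) .is_mean(psi, W)
      diag <- list(ess = post$ess, prior = prior)
    } else {
      post <- .mcmc_fit(x, y, prior, M = draws + burnin, M0 = burnin,
                        seed = seed)
      wmean <- function(psi) c(est = mean(psi), se = .bm_se(psi))
      diag <- list(acceptance = post$acceptance, prior = prior,
                   retained = draws, burnin = burnin)
    }
    t1d <- post$theta1; t2d <- post$theta2
    est <- list(theta1 = wmean(t1d), theta2 = wmean(t2d),
                R = wmean(ss_reliability(t1d, t2d)),
                MRS = wmean(ss_mrs(t1d, t2d)))
    fz <- data.frame(k = k,
                     FSS = vapply(k, function(kk)
                       wmean(ss_fss(t1d, t2d, kk))["est"], numeric(1)),
                     FMRS = vapply(k, function(kk)
                       wmean(ss_fmrs(t1d, t2d, kk))["est"], numeric(1)))
    th1 <- est$theta1["est"]; th2 <- est$theta2["est"]
    meas <- structure(list(theta1 = unname(th1), theta2 = unname(th2),
                           R = unname(est$R["est"]), MRS = unname(est$MRS["est"]),
                           fuzzy = fz),
                      class = "ss_measures")
    diag$mc_se <- c(theta1 = unname(est$theta1["se"]),
                    theta2 = unname(est$theta2["se"]),
                    R = unname(est$R["se"]), MRS = unname(est$MRS["se"]))
  }

  structure(list(method = method,
                 theta = c(theta1 = unname(th1), theta2 = unname(th2)),
                 measures = meas, diagnostics = diag, draws = post,
                 data = list(x = x, y = y), k = k, seed = seed, call = cl),
            class = "ssfit")
}

#' @export
print.ssfit <- function(x, digits = 4, ...) {
  cat(sprintf("Lindley stress-strength fit (%s), n = %d strength / m = %d stress\n",
              toupper(x$method), length(x$data$x), length(x$data$y)))
  cat(sprintf("  theta1 = %.*f, theta2 = %.*f\n", digits, x$theta[1],
              digits, x$theta[2]))
  cat(sprintf("  R = %.*f, MRS = %.*f\n", digits, x$measures$R,
              digits, x$measures$MRS))
  print(format(x$measures$fuzzy, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.ssfit <- function(object, ...) object$theta

#' Summarise a stress-strength fit
#'
#' @param object an [ssfit()] object.
#' @param ... unused.
#' @return a `summary.ssfit` list with the estimates and diagnostics.
#' @export
summary.ssfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ssfit")
}

#' @export
print.summary.ssfit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  d <- f$diagnostics
  if (f$method == "mle")
    cat(sprintf("  log-likelihood: %.4f\n", d$loglik))
  if (f$method == "mps")
    cat(sprintf("  mean-log spacing objective: x %.4f, y %.4f\n",
                d$objective["x"], d$objective["y"]))
  if (f$method == "is") {
    cat(sprintf("  importance draws: %d, effective sample size: %.1f\n",
                f$draws$N, d$ess))
    print(d$prior)
  }
  if (f$method == "mcmc") {
    cat(sprintf("  retained draws: %d (burn-in %d), acceptance: %.2f / %.2f\n",
                d$retained, d$burnin, d$acceptance[1], d$acceptance[2]))
    print(d$prior)
  }
  if (!is.null(d$mc_se))
    cat(sprintf("  MC standard errors: theta1 %.2g, theta2 %.2g, R %.2g, MRS %.2g\n",
                d$mc_se["theta1"], d$mc_se["theta2"], d$mc_se["R"],
                d$mc_se["MRS"]))
  invisible(x)
}

#' Quantile-quantile diagnostics for a stress-strength fit
#'
#' Plots the sample quantiles of both samples against the quantiles of
#' their fitted Lindley laws (plotting positions \eqn{(i - 0.5)/n}).
#'
#' @param x an [ssfit()] object.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a list with the two Q-Q data frames.
#' @export
plot.ssfit <- function(x, ...) {
  qx <- lindley_qq(x$data$x, x$theta["theta1"])
  qy <- lindley_qq(x$data$y, x$theta["theta2"])
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (nm in c("strength (x)", "stress (y)")) {
    q <- if (startsWith(nm, "strength")) qx else qy
    graphics::plot(q$theoretical, q$empirical,
                   xlab = "Lindley quantiles", ylab = "sample quantiles",
                   main = nm, ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(list(x = qx, y = qy))
}

#' Simulate stress-strength datasets from a fitted model
#'
#' Draws `nsim` new (strength, stress) datasets of the original sizes
#' from the fitted Lindley laws.
#'
#' @param object an [ssfit()] object.
#' @param nsim number of datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of length `nsim`; each element is a list with vectors
#'   `x` and `y`.
#' @export
simulate.ssfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    list(x = rlindley(length(object$data$x), object$theta["theta1"]),
         y = rlindley(length(object$data$y), object$theta["theta2"])))
}

#' Quantile residuals of a stress-strength fit
#'
#' Probability-integral-transform residuals
#' \eqn{\Phi^{-1}(F(x_i; \hat\theta))}; approximately standard normal
#' when the Lindley model fits.
#'
#' @param object an [ssfit()] object.
#' @param ... unused.
#' @return a list with residual vectors `x` and `y`.
#' @export
residuals.ssfit <- function(object, ...) {
  list(x = stats::qnorm(plindley(object$data$x, object$theta["theta1"])),
       y = stats::qnorm(plindley(object$data$y, object$theta["theta2"])))
}
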