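#' Prior specification for Bayesian stress-strength estimation
#'
#' Two prior families are supported for the pair of Lindley shapes.
#' Independent conjugate-style gamma priors
#' \eqn{\theta_1 \sim Gamma(a_1, b_1)}, \eqn{\theta_2 \sim Gamma(a_2, b_2)}
#' (shape/rate), or the scale-invariant noninformative prior
#' \eqn{\pi(\theta_i) \propto 1/\theta_i}.  The importance-sampling
#' estimator requires a gamma prior (its proposal is the gamma kernel of
#' the posterior); MCMC accepts either.
#'
#' The gamma-prior posterior used throughout is
#' \eqn{\pi(\theta_1 \mid x) \propto \theta_1^{a_1 + 2n - 2}
#' (1+\theta_1)^{-n} e^{-\theta_1 (b_1 + \sum x_i)}}, i.e. the gamma
#' kernel has shape \eqn{a_1 + 2n - 1} and rate \eqn{b_1 + \sum x_i},
#' with the residual factor \eqn{(1+\theta_1)^{-n}} handled by weighting
#' (IS) or by Metropolis (MCMC); analogously for \eqn{\theta_2}.  Under
#' the noninformative prior the target is
#' \eqn{\theta_1^{2n-1}(1+\theta_1)^{-n} e^{-\theta_1 \sum x_i}}.
#'
#' @param kind `"gamma"` or `"noninformative"`.
#' @param a1,b1,a2,b2 positive gamma hyperparameters (shape, rate) for
#'   `theta1` and `theta2`; ignored for the noninformative prior.
#' @return an object of class `"ss_prior"`.
#' @examples
#' ss_prior("gamma", a1 = 3, b1 = 4, a2 = 2, b2 = 3)
#' ss_prior("noninformative")
#' @export
ss_prior <- function(kind = c("gamma", "noninformative"),
                     a1 = 3, b1 = 4, a2 = 2, b2 = 3) {
  kind <- match.arg(kind)
  if (kind == "gamma") {
    hp <- c(a1 = a1, b1 = b1, a2 = a2, b2 = b2)
    if (any(!is.finite(hp)) || any(hp <= 0))
      stop("gamma hyperparameters must be positive finite", call. = FALSE)
  }
  structure(list(kind = kind, a1 = a1, b1 = b1, a2 = a2, b2 = b2),
            class = "ss_prior")
}

#' @export
print.ss_prior <- function(x, ...) {
  if (x$kind == "gamma")
    cat(sprintf("gamma prior: theta1 ~ Gamma(%g, %g), theta2 ~ Gamma(%g, %g)\n",
                x$a1, x$b1, x$a2, x$b2))
  else cat("noninformative prior: pi(theta_i) proportional to 1/theta_i\n")
  invisible(x)
}

# posterior "shape-like" exponent c and rate d so that the target is
# theta^(c-1) (1+theta)^(-n) exp(-d theta); see ?ss_prior
.posterior_cd <- function(n, sumx, prior, which) {
  if (prior$kind == "gamma") {
    a <- if (which == 1L) prior$a1 else prior$a2
    b <- if (which == 1L) prior$b1 else prior$b2
    c(c = a + 2 * n - 1, d = b + sumx)
  } else {
    c(c = 2 * n, d = sumx)
  }
}

# Self-normalised importance sampling: gamma-kernel proposals, weights
# proportional to (1+theta1)^(-n) (1+theta2)^(-m).  Empty samples are
# permitted (the draws then follow the prior-implied n = 0 kernel).
.is_fit <- function(x, y, prior, N, seed = NULL) {
  if (prior$kind != "gamma")
    stop("importance sampling requires a gamma prior", call. = FALSE)
  if (N < 100) stop("'draws' must be at least 100 for importance sampling",
                    call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x); m <- length(y)
  p1 <- .posterior_cd(n, sum(x), prior, 1L)
  p2 <- .posterior_cd(m, sum(y), prior, 2L)
  if (p1["c"] <= 0 || p2["c"] <= 0)
    stop("posterior gamma shape is not positive; increase the prior shape",
         call. = FALSE)
  th1 <- stats::rgamma(N, shape = p1["c"], rate = p1["d"])
  th2 <- stats::rgamma(N, shape = p2["c"], rate = p2["d"])
  logw <- -n * log1p(th1) - m * log1p(th2)
  w <- exp(logw - max(logw))
  W <- w / sum(w)
  ess <- 1 / sum(W^2)
  if (ess < 10)
    stop(sprintf(paste0("importance weights are degenerate (effective sample ",
                        "size %.1f < 10); use MCMC or a better-matched prior"),
                 ess), call. = FALSE)
  list(theta1 = th1, theta2 = th2, weights = W, ess = ess, N = N)
}

# weighted posterior mean and its MC standard error for one function value
.is_mean <- function(psi, W) {
  est <- sum(W * psi)
  se <- sqrt(sum(W^2 * (psi - est)^2))
  c(est = est, se = se)
}

# Random-walk Metropolis on log(theta) for one conditional
# theta^(c-1) (1+theta)^(-n) exp(-d theta).  The Jacobian of the log
# transform adds one power of theta, so the log target in z = log(theta)
# is c*z - n*log(1+e^z) - d*e^z and the chain, mapped back, targets the
# stated density in theta.  Step scale is adapted during burn-in toward
# ~35% acceptance and then frozen.
.mh_chain <- function(cc, n, d, M, M0, start) {
  lp <- function(z) {
    ez <- exp(z)
    cc * z - n * (if (z > 30) z else log1p(ez)) - d * ez
  }
  z <- log(start)
  cur <- lp(z)
  out <- numeric(M)
  sigma <- 0.5
  acc_win <- 0L; acc_post <- 0L
  for (i in seq_len(M)) {
    zp <- z + sigma * stats::rnorm(1)
    prop <- lp(zp)
    if (is.finite(prop) && log(stats::runif(1)) < prop - cur) {
      z <- zp; cur <- prop
      acc_win <- acc_win + 1L
      if (i > M0) acc_post <- acc_post + 1L
    }
    out[i] <- z
    if (i <= M0 && i %% 50L == 0L) {
      rate <- acc_win / 50
      sigma <- sigma * exp(rate - 0.35)
      acc_win <- 0L
    }
  }
  list(theta = exp(out[(M0 + 1L):M]), sigma = sigma,
       acceptance = acc_post / (M - M0))
}

.mcmc_fit <- function(x, y, prior, M, M0, seed = NULL) {
  if (M <= M0 || M0 < 0) stop("need draws > 0 and burnin >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x); m <- length(y)
  p1 <- .posterior_cd(n, sum(x), prior, 1L)
  p2 <- .posterior_cd(m, sum(y), prior, 2L)
  start1 <- if (n) lindley_mle(x) else 1
  start2 <- if (m) lindley_mle(y) else 1
  ch1 <- .mh_chain(p1["c"], n, p1["d"], M, M0, start1)
  ch2 <- .mh_chain(p2["c"], m, p2["d"], M, M0, start2)
  for (ch in list(ch1, ch2))
    if (ch$acceptance < 0.05 || ch$acceptance > 0.95)
      warning(sprintf(paste0("Metropolis acceptance rate %.3f outside ",
                             "[0.05, 0.95] after adaptation (step %.3g); ",
                             "inspect the chain"),
                      ch$acceptance, ch$sigma), call. = FALSE)
  list(theta1 = ch1$theta, theta2 = ch2$theta,
       acceptance = c(theta1 = ch1$acceptance, theta2 = ch2$acceptance),
       M = M, M0 = M0)
}

# batch-means MC standard error of the mean of a (possibly autocorrelated)
# chain of function values
.bm_se <- function(v, nbatch = 50L) {
  nb <- min(nbatch, length(v) %/% 2L)
  if (nb < 2L) return(stats::sd(v) / sqrt(length(v)))
  bs <- length(v) %/% nb
  means <- vapply(seq_len(nb), function(b)
    mean(v[((b - 1L) * bs + 1L):(b * bs)]), numeric(1))
  stats::sd(means) / sqrt(nb)
}
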