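test_that("importance weights normalise and the effective sample size is reported", {
  set.seed(61)
  x <- rlindley(20, 0.5); y <- rlindley(20, 1.5)
  f <- ssfit(x, y, method = "is", draws = 2000, seed = 7)
  W <- f$draws$weights
  expect_lt(abs(sum(W) - 1), 1e-12)
  expect_true(all(W >= 0))
  expect_gt(f$diagnostics$ess, 10)
  # a constant functional is estimated without error because weights normalise
  expect_equal(sum(W * rep(3.7, length(W))), 3.7, tolerance = 1e-12)
})

test_that("with no data the importance draws follow the stated n = 0 kernel", {
  # the posterior gamma shape is a + 2n - 1, so at n = 0 the draws follow
  # Gamma(a - 1, b) with mean (a - 1)/b and all weights equal
  pr <- ss_prior("gamma", a1 = 3, b1 = 4, a2 = 2, b2 = 3)
  f <- lindleySS:::.is_fit(numeric(0), numeric(0), pr, N = 20000, seed = 5)
  expect_lt(abs(sum(f$weights) - 1), 1e-12)
  expect_equal(f$ess, 20000, tolerance = 1e-6)
  expect_lt(abs(mean(f$theta1) - (3 - 1) / 4), 3 * sd(f$theta1) / sqrt(20000))
  expect_lt(abs(mean(f$theta2) - (2 - 1) / 3), 3 * sd(f$theta2) / sqrt(20000))
})

test_that("degenerate importance weights raise a diagnostic error", {
  set.seed(77)
  x <- rlindley(400, 0.5); y <- rlindley(400, 1.5)
  expect_error(ssfit(x, y, method = "is", draws = 1000, seed = 1),
               "effective sample size")
})

test_that("the importance-sampling posterior concentrates near the truth", {
  set.seed(8)
  x <- rlindley(30, 0.5); y <- rlindley(30, 1.5)
  f <- ssfit(x, y, method = "is",
             prior = ss_prior("gamma", a1 = 3, b1 = 4, a2 = 2, b2 = 3),
             draws = 10000, seed = 9)
  expect_lt(abs(f$measures$R - 0.825), 0.05)
})

test_that("MCMC chains are reproducible and mix acceptably", {
  set.seed(31)
  x <- rlindley(25, 0.7); y <- rlindley(25, 1.2)
  f1 <- ssfit(x, y, method = "mcmc", draws = 3000, burnin = 500, seed = 3)
  f2 <- ssfit(x, y, method = "mcmc", draws = 3000, burnin = 500, seed = 3)
  expect_identical(f1$draws$theta1, f2$draws$theta1)
  expect_identical(f1$measures$fuzzy, f2$measures$fuzzy)
  expect_true(all(f1$diagnostics$acceptance > 0.05 &
                    f1$diagnostics$acceptance < 0.95))
  expect_length(f1$draws$theta1, 3000)
})

test_that("the MCMC marginal matches the analytic conditional density", {
  set.seed(15)
  x <- rlindley(20, 0.8)
  n <- length(x); d <- sum(x)
  # noninformative target: theta^(2n-1) (1+theta)^(-n) exp(-d theta)
  dens <- function(th) exp((2 * n - 1) * log(th) - n * log1p(th) - d * th)
  Z <- integrate(dens, 0, Inf, abs.tol = 1e-12)$value

  fit <- ssfit(x, rlindley(20, 0.8), method = "mcmc",
               draws = 1e5, burnin = 5000, seed = 16)
  ch <- fit$draws$theta1

  # posterior mean by 1-D numerical integration, within 1%
  post_mean <- integrate(function(t) t * dens(t), 0, Inf,
                         abs.tol = 1e-12)$value / Z
  expect_lt(abs(mean(ch) - post_mean) / post_mean, 0.01)

  # central histogram bins match the normalised density within 5% relative
  qs <- quantile(ch, c(0.05, 0.95))
  breaks <- seq(qs[1], qs[2], length.out = 9)
  emp <- vapply(seq_len(length(breaks) - 1), function(i)
    mean(ch >= breaks[i] & ch < breaks[i + 1]), numeric(1))
  thr <- vapply(seq_len(length(breaks) - 1), function(i)
    integrate(dens, breaks[i], breaks[i + 1], abs.tol = 1e-12)$value / Z,
    numeric(1))
  expect_lt(max(abs(emp - thr) / thr), 0.05)
})

test_that("importance sampling and MCMC agree on the same posterior", {
  set.seed(23)
  x <- rlindley(30, 0.5); y <- rlindley(30, 1.5)
  pr <- ss_prior("gamma", a1 = 3, b1 = 4, a2 = 2, b2 = 3)
  fis <- ssfit(x, y, method = "is", prior = pr, draws = 20000, seed = 24)
  fmc <- ssfit(x, y, method = "mcmc", prior = pr, draws = 20000,
               burnin = 2000, seed = 25)
  se <- sqrt(fis$diagnostics$mc_se["R"]^2 + fmc$diagnostics$mc_se["R"]^2)
  expect_lt(abs(fis$measures$R - fmc$measures$R), 2 * se)
})

test_that("the posterior for the reliability contracts as data accumulate", {
  set.seed(41)
  small <- ssfit(rlindley(20, 0.5), rlindley(20, 1.5), method = "mcmc",
                 draws = 5000, burnin = 1000, seed = 42)
  big <- ssfit(rlindley(500, 0.5), rlindley(500, 1.5), method = "mcmc",
               draws = 5000, burnin = 1000, seed = 42)
  sd_small <- sd(ss_reliability(small$draws$theta1, small$draws$theta2))
  sd_big <- sd(ss_reliability(big$draws$theta1, big$draws$theta2))
  expect_lt(sd_big, sd_small)
})
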