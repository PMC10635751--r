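endocrine_x <- c(6, 6, 7, 3, 3, 4, 1, 50, 7, 9, 13, 14, 16, 31, 28, 59, 13,
                 13, 11, 9, 12, 9, 5)
endocrine_y <- c(1, 1, 1, 3, 3, 1, 1, 18, 4, 5, 6, 6, 4, 5, 5, 9, 15, 24, 4,
                 2, 5, 5, 7, 1)

test_that("two-sample MLE uses the closed form per sample and plugs into the measures", {
  f <- ssfit(rep(1, 8), rep(1, 5), method = "mle", k = 1)
  expect_equal(unname(coef(f)), c(sqrt(2), sqrt(2)))
  expect_equal(f$measures$R, 0.5, tolerance = 1e-12)

  f2 <- ssfit(endocrine_x, endocrine_y, method = "mle", k = c(1, 5, 10, 20))
  expect_equal(unname(coef(f2)["theta1"]), 0.13168, tolerance = 1e-4)
  expect_equal(unname(coef(f2)["theta2"]), 0.31107, tolerance = 1e-4)
  expect_equal(f2$measures$R, 0.7849, tolerance = 1e-3)
  # invariance: measures recomputed exactly from the estimated shapes
  expect_identical(f2$measures$R,
                   ss_reliability(coef(f2)[["theta1"]], coef(f2)[["theta2"]]))
  expect_identical(f2$measures$fuzzy$FMRS,
                   ss_fmrs(coef(f2)[["theta1"]], coef(f2)[["theta2"]],
                           c(1, 5, 10, 20)))
})

test_that("MLE of the reliability is consistent at large samples", {
  set.seed(314)
  f <- ssfit(rlindley(5000, 0.5), rlindley(5000, 1.5), method = "mle", k = 1)
  expect_lt(abs(f$measures$R - 0.825), 0.02)
})

test_that("spacings telescope, handle the single-observation case, and flag ties", {
  set.seed(21)
  x <- rlindley(40, 0.8)                  # continuous, so untied
  sp <- lindley_spacings(x, 0.8)
  expect_equal(sum(sp$D), 1, tolerance = 1e-12)
  expect_true(all(sp$D > 0))

  t <- qlindley(0.5, 2)
  sp1 <- lindley_spacings(t, 2)
  expect_equal(sp1$objective, log(0.5), tolerance = 1e-9)

  tied <- c(3, 3, 5)
  expect_identical(lindley_spacings(tied, 0.5, tie = "none")$objective, -Inf)
  subst <- lindley_spacings(tied, 0.5, tie = "density")
  expect_true(is.finite(subst$objective))
  expect_equal(subst$D[2], dlindley(3, 0.5))
})

test_that("the spacing optimiser matches a brute-force grid search", {
  set.seed(99)
  for (r in 1:5) {
    x <- rlindley(sample(15:40, 1), runif(1, 0.3, 2.5))
    fit <- lindley_mps(x)
    brute <- grid_maximise(function(th) lindley_spacings(x, th)$objective,
                           1e-3, 10)
    expect_lt(abs(fit$theta - brute), 1e-3)
    # maximality spot-check against random probes
    probes <- exp(runif(100, log(1e-2), log(50)))
    vals <- vapply(probes, function(th) lindley_spacings(x, th)$objective,
                   numeric(1))
    expect_gte(fit$objective, max(vals))
  }
})

test_that("spacing estimation is consistent and close to the MLE on clean data", {
  set.seed(512)
  x <- rlindley(2000, 0.5)
  expect_lt(abs(lindley_mps(x)$theta - 0.5), 0.05)
  y <- rlindley(1000, 1.4)
  expect_lt(abs(lindley_mps(y)$theta - lindley_mle(y)) / lindley_mle(y), 0.05)
})

test_that("frequentist fits are deterministic and respect the measure bounds", {
  f1 <- ssfit(endocrine_x, endocrine_y, method = "mps", k = c(1, 5, 10, 20))
  f2 <- ssfit(endocrine_x, endocrine_y, method = "mps", k = c(1, 5, 10, 20))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$measures$fuzzy, f2$measures$fuzzy)
  for (f in list(f1, ssfit(endocrine_x, endocrine_y, method = "mle"))) {
    expect_true(all(f$measures$fuzzy$FSS < f$measures$R))
    expect_true(all(diff(f$measures$fuzzy$FSS) > 0))
    expect_true(all(diff(f$measures$fuzzy$FMRS) < 0))
  }
  expect_error(ssfit(c(1, -1), endocrine_y), "positive")
})

test_that("fit methods expose the usual model-object interface", {
  set.seed(2)
  f <- ssfit(rlindley(30, 0.6), rlindley(25, 1.1), method = "mle")
  expect_output(print(f), "theta1")
  expect_output(print(summary(f)), "log-likelihood")
  r <- residuals(f)
  expect_length(r$x, 30)
  sims <- simulate(f, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_length(sims[[1]]$x, 30)
  expect_length(sims[[1]]$y, 25)
  sims2 <- simulate(f, nsim = 2, seed = 4)
  expect_identical(sims, sims2)
})
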