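test_that("fuzzy membership has the exponential-surplus form", {
  expect_identical(fuzzy_membership(1, 1, 5), 0)
  expect_identical(fuzzy_membership(0.5, 2, 5), 0)
  expect_equal(fuzzy_membership(2, 1, log(2)), 0.5)
  expect_lt(abs(fuzzy_membership(1e4, 0, 1) - 1), 1e-12)
  expect_error(fuzzy_membership(1, 0, -1), "positive")
})

test_that("closed forms reproduce the published true-value grid at printed precision", {
  # reference values are truncated (not rounded) to 4 dp, so agreement at
  # the printed precision means |difference| <= 1e-4
  ref <- reference_measure_grid()
  for (i in seq_len(nrow(ref))) {
    r <- ref[i, ]
    if (is.na(r$k)) {
      expect_lt(abs(ss_reliability(r$theta1, r$theta2) - r$prob), 1.0e-4)
      expect_lt(abs(ss_mrs(r$theta1, r$theta2) - r$strength), 1.0e-4)
    } else {
      expect_lt(abs(ss_fss(r$theta1, r$theta2, r$k) - r$prob), 1.0e-4)
      expect_lt(abs(ss_fmrs(r$theta1, r$theta2, r$k) - r$strength), 1.0e-4)
    }
  }
})

test_that("equal shapes give even odds and complementary pairs sum to one", {
  for (theta in c(0.1, 0.5, 1, 2, 5)) {
    expect_equal(ss_reliability(theta, theta), 0.5, tolerance = 1e-12)
  }
  grid <- expand.grid(t1 = c(0.2, 0.7, 1.5, 4), t2 = c(0.3, 1, 2.5))
  for (i in seq_len(nrow(grid))) {
    s <- ss_reliability(grid$t1[i], grid$t2[i]) +
      ss_reliability(grid$t2[i], grid$t1[i])
    expect_lt(abs(s - 1), 1e-10)
  }
})

test_that("fuzzy measures are monotone in k and bounded by the classical ones", {
  kgrid <- c(0.1, 1, 5, 10, 20, 100)
  for (pp in list(c(0.5, 0.5), c(0.5, 1.5), c(2, 0.5), c(1.2, 0.8))) {
    R <- ss_reliability(pp[1], pp[2]); M <- ss_mrs(pp[1], pp[2])
    fss <- ss_fss(pp[1], pp[2], kgrid)
    fmrs <- ss_fmrs(pp[1], pp[2], kgrid)
    expect_true(all(diff(fss) > 0))
    expect_true(all(diff(fmrs) < 0))
    expect_true(all(fss > 0 & fss < R))
    expect_true(all(fmrs > M))
  }
})

test_that("fuzzy measures reach their classical limits", {
  for (pp in list(c(0.5, 1.5), c(2, 0.5))) {
    R <- ss_reliability(pp[1], pp[2]); M <- ss_mrs(pp[1], pp[2])
    expect_lt(abs(ss_fss(pp[1], pp[2], 1e5) - R) / R, 1e-4)
    expect_lt(abs(ss_fmrs(pp[1], pp[2], 1e5) - M) / M, 1e-4)
    # beyond the stability threshold the classical values are returned exactly
    expect_identical(ss_fss(pp[1], pp[2], 1e7), R)
    expect_identical(ss_fmrs(pp[1], pp[2], 1e7), M)
    # k -> 0: membership vanishes and so does FSS
    expect_lt(ss_fss(pp[1], pp[2], 1e-6), 1e-5)
  }
})

test_that("closed forms agree with the defining-integral oracle", {
  for (pp in list(c(0.5, 0.5), c(0.5, 1.5), c(2, 0.5))) {
    o <- ss_measures_numeric(pp[1], pp[2], k = c(1, 10))
    expect_lt(abs(o$R - ss_reliability(pp[1], pp[2])), 1e-6)
    expect_lt(abs(o$MRS - ss_mrs(pp[1], pp[2])), 1e-6)
    expect_lt(max(abs(o$FSS - ss_fss(pp[1], pp[2], c(1, 10)))), 1e-6)
    expect_lt(max(abs(o$FMRS - ss_fmrs(pp[1], pp[2], c(1, 10)))), 1e-6)
  }
})

test_that("hand-integrated exponential-polynomial cases are reproduced", {
  # at theta1 = theta2 = 0.5 the double integral reduces to
  # 1/2 - (10/3 + 8/9)/36 at k = 1 and to 1/2 - (10/11 + 8/121)/36 at k = 5
  expect_equal(ss_fss(0.5, 0.5, 1), 0.5 - (10 / 3 + 8 / 9) / 36,
               tolerance = 1e-12)
  expect_equal(round(ss_fss(0.5, 0.5, 1), 5), 0.38272)
  expect_equal(ss_fss(0.5, 0.5, 5), 0.5 - (10 / 11 + 8 / 121) / 36,
               tolerance = 1e-12)
  expect_equal(round(ss_fss(0.5, 0.5, 5), 5), 0.47291)
})

test_that("measure workhorses vectorise over parameter vectors with scalar k", {
  set.seed(88)
  t1 <- runif(200, 0.05, 3); t2 <- runif(200, 0.05, 3)
  R <- ss_reliability(t1, t2)
  for (k in c(1, 20)) {
    fss <- ss_fss(t1, t2, k)
    fmrs <- ss_fmrs(t1, t2, k)
    expect_length(fss, 200)
    expect_true(all(fss < R))
    expect_true(all(fmrs > ss_mrs(t1, t2)))
    expect_equal(fss[7], ss_fss(t1[7], t2[7], k))
  }
})

test_that("the measure container bundles all four measures consistently", {
  m <- ss_measures(0.8, 1.2, k = c(1, 5))
  expect_s3_class(m, "ss_measures")
  expect_equal(m$R, ss_reliability(0.8, 1.2))
  expect_equal(m$fuzzy$FSS, ss_fss(0.8, 1.2, c(1, 5)))
  d <- as.data.frame(m)
  expect_equal(nrow(d), 2L)
  expect_output(print(m), "classical reliability")
  expect_error(ss_measures(-1, 1), "positive")
})
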