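test_that("bandpass DF cost matches the closed-form continuum and edge cases", {
  # continuum: fraction removed -> 1 - (0.1 - 0.01)/0.5 = 0.82 at TR = 1 s
  big <- bandpass_df(10000, 1, 0.01, 0.1)
  expect_equal(big$frac_removed, 0.82, tolerance = 0.01)
  # full band removes nothing
  expect_equal(bandpass_df(100, 2, 0, 0.25)$df_removed, 0L)
  # LFF band on 242 volumes at TR = 2 s: ~64% of DFs, comfortably over 60%
  lff2 <- bandpass_df(242, 2, 0.01, 0.1)
  expect_gte(lff2$frac_removed, 0.60)
  expect_equal(lff2$frac_removed, 154 / 242, tolerance = 1e-12)
  # same band at TR = 1 s: ~82%, over 80%
  lff1 <- bandpass_df(242, 1, 0.01, 0.1)
  expect_gte(lff1$frac_removed, 0.80)
  expect_error(bandpass_df(100, 2, 0.1, 0.5), "Nyquist")
})

test_that("bandpass DF count converges to the continuum limit", {
  cont <- 1 - (0.1 - 0.01) / 0.25          # TR = 2 s continuum fraction
  got <- bandpass_df(10000, 2, 0.01, 0.1)$frac_removed
  expect_equal(got, cont, tolerance = 0.01)
})

test_that("the DF ledger reproduces the printed 242-TR accounting", {
  cv <- make_censor(replace(rep(0, 242), c(50, 51, 120), 1), NULL,
                    censor_prev = FALSE)
  led <- df_ledger(242, censor = cv, design = 13)
  expect_equal(led$df_left, 226L)
  expect_equal(round(led$frac_left, 6), 0.933884)
  rd <- review_from_ledger(led)
  expect_identical(rd[["degrees of freedom left"]], 226L)
  expect_identical(rd[["final DF fraction"]], 0.933884)
  expect_identical(rd[["degrees of freedom used"]], 13L)
})

test_that("an empty model leaves every degree of freedom", {
  led <- df_ledger(100)
  expect_equal(led$df_left, 100L)
  expect_equal(led$frac_left, 1)
  expect_equal(led$warn$level, "none")
})

test_that("ledger arithmetic identity holds for randomized inputs", {
  set.seed(30)
  for (rep in 1:25) {
    n <- sample(50:300, 1)
    nc <- sample(0:20, 1)
    p_base <- sample(0:6, 1); p_mot <- sample(c(0, 6), 1); p_int <- sample(0:4, 1)
    des <- if (p_base + p_mot + p_int > 0)
      design_matrix(matrix(rnorm(n * (p_base + p_mot + p_int)), nrow = n),
                    groups = rep(c("baseline", "motion", "interest"),
                                 c(p_base, p_mot, p_int)))
    bp <- if (runif(1) < 0.4) list(tr_s = 2, f_low_hz = 0.01, f_high_hz = 0.1)
    led <- df_ledger(n, censor = nc, design = des, bandpass = bp)
    expect_equal(led$df_used,
                 led$n_censored + led$df_drift + led$df_motion +
                   led$df_bandpass + led$df_other)
    expect_equal(led$df_left, led$n_total - led$df_used)
    expect_equal(led$frac_left, led$df_left / led$n_total)
  }
})

test_that("overdrawn models warn severely instead of erroring", {
  led <- df_ledger(50, censor = 10, design = 13,
                   bandpass = list(tr_s = 2, f_low_hz = 0.01, f_high_hz = 0.02))
  expect_lt(led$df_left, 0)
  expect_equal(led$warn$level, "severe")
})

test_that("collinearity grading flags duplicates, planted r and rank deficiency", {
  set.seed(31)
  n <- 100
  a <- rnorm(n)
  des_dup <- design_matrix(cbind(a, a, rnorm(n)), labels = c("a", "a2", "b"))
  out <- collinearity_check(des_dup)
  pair <- out[out$type == "pair" & out$label1 == "a" & out$label2 == "a2", ]
  expect_equal(pair$value, 1, tolerance = 1e-12)
  expect_equal(pair$level, "severe")
  expect_equal(out$level[out$type == "cond"], "severe")   # rank-deficient

  # mutually orthogonal columns: no pair warnings
  q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  out2 <- collinearity_check(design_matrix(q))
  expect_equal(nrow(out2[out2$type == "pair", ]), 0L)

  # planted correlation 0.7 -> medium
  b <- 0.7 * scale(a) + sqrt(1 - 0.49) * scale(rnorm(n))
  des3 <- design_matrix(cbind(a, b), labels = c("a", "b"))
  out3 <- collinearity_check(des3)
  pr <- out3[out3$type == "pair", ]
  expect_equal(pr$value, abs(as.numeric(cor(a, b))), tolerance = 1e-12)
  expect_equal(pr$level, "medium")

  des0 <- design_matrix(cbind(a, rep(1, n) * 0), labels = c("a", "z"))
  expect_equal(collinearity_check(des0)$type[1], "zero_var")
})

test_that("per-stimulus censor fractions reproduce the printed 2/136 and 0/210", {
  nt <- 400
  ideal <- matrix(0, nt, 2)
  ideal[1:136, 1] <- 1
  ideal[150:359, 2] <- 0.8
  keep <- rep(0, nt)
  keep[c(10, 20)] <- 1                       # censor two response TRs of stim 1
  cv <- make_censor(keep, NULL, censor_prev = FALSE)
  out <- stim_censor_fraction(ideal, cv, labels = c("vis", "aud"))
  expect_equal(out$n_resp, c(136L, 210L))
  expect_equal(out$n_censored, c(2L, 0L))
  expect_equal(out$fraction, c(0.015, 0.000))
})

test_that("stimulus censor fractions are monotone and handle edge cases", {
  nt <- 50
  ideal <- matrix(c(rep(1, 20), rep(0, 30)), ncol = 1)
  all_cens <- make_censor(rep(1, nt), NULL, censor_prev = FALSE)
  expect_equal(stim_censor_fraction(ideal, all_cens)$fraction, 1)
  none <- make_censor(rep(0, nt), NULL)
  expect_equal(stim_censor_fraction(ideal, none)$fraction, 0)
  # monotone nondecreasing as the censored set grows
  set.seed(32)
  cens <- rep(0, nt)
  prev <- 0
  for (step in 1:5) {
    cens[sample(which(cens == 0), 4)] <- 1
    f <- stim_censor_fraction(ideal, make_censor(cens, NULL,
                                                 censor_prev = FALSE))$fraction
    expect_gte(f, prev)
    prev <- f
  }
  z <- stim_censor_fraction(matrix(0, nt, 1), none)
  expect_true(is.na(z$fraction))
  expect_equal(z$flag, "empty_regressor")
})

test_that("pre-steady-state detection flags elevated leading volumes only", {
  set.seed(33)
  d <- c(8, 8, 4)
  nt <- 40
  mask <- ellipsoid_mask(d)
  arr <- array(1000 + rnorm(prod(d) * nt, sd = 2), dim = c(d, nt))
  vol <- tiny_vol(arr)
  expect_length(pre_steady_check(vol, mask), 0L)

  arr2 <- arr
  arr2[, , , 1] <- arr2[, , , 1] * 1.05
  arr2[, , , 2] <- arr2[, , , 2] * 1.05
  expect_equal(pre_steady_check(tiny_vol(arr2), mask), c(1L, 2L))

  # strictly-at-threshold is not flagged
  arr3 <- array(1000, dim = c(d, nt))
  arr3[, , , 1] <- 1000 * 1.02
  expect_length(pre_steady_check(tiny_vol(arr3), mask), 0L)
  arr3[, , , 1] <- 1000 * 1.0201
  expect_equal(pre_steady_check(tiny_vol(arr3), mask), 1L)

  # scanning stops at the first steady volume and respects run breaks
  arr4 <- arr
  arr4[, , , 3] <- arr4[, , , 3] * 1.10      # elevated but not leading
  expect_length(pre_steady_check(tiny_vol(arr4), mask), 0L)
  arr5 <- arr
  arr5[, , , 21] <- arr5[, , , 21] * 1.08    # first volume of run 2
  vol5 <- tiny_vol(arr5, run_lengths = c(20, 20))
  expect_equal(pre_steady_check(vol5, mask), 21L)
})
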