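test_that("shift estimate handles trivial configurations", {
  same <- mann_whitney_shift(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$hl_shift, 0)
  expect_identical(same$z, 0)
  expect_identical(same$p_value, 1)

  shifted <- mann_whitney_shift(c(11, 12, 13), c(1, 2, 3))
  expect_identical(shifted$hl_shift, 10)

  expect_error(mann_whitney_shift(numeric(0), 1:3), "non-empty")

  # antisymmetry under swapping the samples
  set.seed(45)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  ab <- mann_whitney_shift(x, y)
  ba <- mann_whitney_shift(y, x)
  expect_equal(ba$hl_shift, -ab$hl_shift)
  expect_equal(ba$z, -ab$z)
  expect_equal(ba$p_value, ab$p_value)
  expect_equal(sort(c(ba$ci_low, ba$ci_high)),
               sort(-c(ab$ci_low, ab$ci_high)))
})

test_that("normal-approximation p agrees with exact enumeration", {
  # the exact two-sided p is coarse for tiny groups (granularity 2/C(N,n)),
  # so the normal approximation is only loosely bounded there; at group
  # sizes >= 7 the two agree within 0.05 absolute
  set.seed(46)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    m <- sample(2:(8 - n), 1)
    vals <- if (rep %% 2 == 0) round(rnorm(n + m), 1) else rnorm(n + m)
    x <- vals[seq_len(n)]
    y <- vals[-seq_len(n)]
    approx_p <- mann_whitney_shift(x, y)$p_value
    expect_lt(abs(approx_p - exact_mw_p(x, y)), 0.2)
  }
  for (rep in 1:20) {
    n <- sample(7:8, 1)
    m <- sample(7:8, 1)
    vals <- if (rep %% 2 == 0) round(rnorm(n + m), 1) else rnorm(n + m)
    x <- vals[seq_len(n)]
    y <- vals[-seq_len(n)]
    approx_p <- mann_whitney_shift(x, y)$p_value
    expect_lt(abs(approx_p - exact_mw_p(x, y)), 0.05)
  }
})

test_that("U, z, and p match the reference rank-sum implementation", {
  set.seed(47)
  for (rep in 1:15) {
    x <- round(rnorm(sample(5:25, 1)), if (rep %% 3 == 0) 0 else 4)
    y <- round(rnorm(sample(5:25, 1), 0.5), if (rep %% 3 == 0) 0 else 4)
    ours <- mann_whitney_shift(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$u_statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Hodges-Lehmann interval brackets the estimate and the reference", {
  set.seed(48)
  for (rep in 1:10) {
    x <- rnorm(20, 1)
    y <- rnorm(25)
    ours <- mann_whitney_shift(x, y)
    expect_lte(ours$ci_low, ours$hl_shift)
    expect_gte(ours$ci_high, ours$hl_shift)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, conf.int = TRUE))
    expect_lte(ours$ci_low, unname(ref$estimate))
    expect_gte(ours$ci_high, unname(ref$estimate))
    expect_lte(abs(ours$hl_shift - unname(ref$estimate)), 0.05)
  }
})

test_that("the large-sample selection path equals explicit enumeration", {
  set.seed(49)
  x <- rnorm(1500, 0.4)
  y <- rnorm(1400)  # n*m just above the dense-path cutoff
  big <- mann_whitney_shift(x, y)
  diffs <- sort(as.vector(outer(x, y, "-")))
  expect_equal(big$hl_shift, median(diffs), tolerance = 1e-12)
})
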