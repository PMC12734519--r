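test_that("pooled t-test matches the closed form and the reference", {
  eq <- pooled_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(eq$statistic, 0)
  expect_identical(eq$p_value, 1)

  # x = {0,2}, y = {1,3}: pooled variance 2, t = -1/sqrt(2), df = 2
  hand <- pooled_t_test(c(0, 2), c(1, 3))
  expect_equal(hand$statistic, -1 / sqrt(2))
  expect_identical(hand$df, 2)

  set.seed(50)
  x <- rnorm(14, 1); y <- rnorm(11)
  ours <- pooled_t_test(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  swapped <- pooled_t_test(y, x)
  expect_equal(swapped$statistic, -ours$statistic)
  expect_equal(swapped$p_value, ours$p_value)

  expect_error(pooled_t_test(1, c(1, 2)), "at least 2")
  expect_error(pooled_t_test(c(2, 2), c(2, 2)), "degenerate")
})

test_that("normality routing rejects uniform and accepts normal samples", {
  route_for <- function(seed, rdist) {
    set.seed(seed)
    normality_route(rdist(200))$route
  }
  non_normal <- sum(vapply(1:100, route_for, character(1),
                           rdist = function(n) runif(n)) == "non_normal")
  expect_gte(non_normal, 95)

  normal <- sum(vapply(1:100, route_for, character(1),
                       rdist = function(n) rnorm(n)) == "normal")
  expect_gte(normal, 88)
  # the 5% level should actually reject sometimes over many seeds
  expect_lte(normal, 99)
})

test_that("KS distance matches the reference Lilliefors statistic", {
  skip_if_not_installed("nortest")
  set.seed(51)
  for (rep in 1:10) {
    x <- rnorm(sample(10:80, 1), sample(0:3, 1), runif(1, 0.5, 2))
    ours <- normality_route(x)
    ref <- nortest::lillie.test(x)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    # routing decision agrees with the reference p-value away from the margin
    if (abs(ref$p.value - 0.05) > 0.02) {
      expect_identical(ours$route,
                       if (ref$p.value < 0.05) "non_normal" else "normal")
    }
  }
})

test_that("degenerate spreads and tiny samples are handled", {
  expect_identical(normality_route(rep(5, 10))$route, "non_normal")
  set.seed(52)
  tiny_noise <- 5 + rnorm(10, sd = 1e-12)
  expect_true(normality_route(tiny_noise)$route %in%
              c("normal", "non_normal"))
  expect_error(normality_route(c(1, 2, 3)), "at least 4")
  expect_error(normality_route(rnorm(20), alpha = 0.07), "alpha")
})
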