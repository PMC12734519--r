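#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio for a 2x2 exposure-by-outcome table, with the
#' Woolf (log-scale normal) confidence interval
#' \eqn{\exp(\ln OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})} and a two-sided Wald
#' p-value on \eqn{\ln OR}.  This equals the exponentiated coefficient of a
#' univariate binary-exposure logistic regression.  If any single cell is
#' zero, the Haldane-Anscombe correction adds 0.5 to all four cells (flagged
#' in the result); a zero diagonal (`a = d = 0` or `b = c = 0`) leaves the
#' odds ratio undefined and is an error.
#'
#' @param tab a [contingency_2x2()].
#' @param conf_level confidence level, default 0.95.
#' @return list of class `or_result`: `or`, `ci_low`, `ci_high`,
#'   `conf_level`, `p_value`, `continuity_adjusted`.
#' @examples
#' odds_ratio(contingency_2x2(23, 9, 4, 22))
#' @export
odds_ratio <- function(tab, conf_level = 0.95) {
  stopifnot(inherits(tab, "contingency_2x2"))
  if (conf_level <= 0 || conf_level >= 1) {
    abort_input("`conf_level` must be in (0, 1)")
  }
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  if ((a == 0 && d == 0) || (b == 0 && c == 0)) {
    abort_input("odds ratio undefined: both cells of a diagonal are zero")
  }
  adjusted <- any(c(a, b, c, d) == 0)
  if (adjusted) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    conf_level = conf_level,
    p_value = 2 * pnorm(-abs(log(or)) / se),
    continuity_adjusted = adjusted), class = "or_result")
}

#' Chi-square test for a 2x2 table
#'
#' Pearson chi-square with Yates continuity correction by default:
#' \eqn{\sum (\max(0, |O - E| - 0.5))^2 / E} over the four cells, with
#' expected counts from the row/column margins, 1 degree of freedom, and an
#' upper-tail p-value.  The correction term is clamped at zero so that
#' proportional tables give a statistic of exactly 0.  Set `correct = FALSE`
#' for the uncorrected Pearson statistic.
#'
#' @param tab a [contingency_2x2()].
#' @param correct apply the Yates continuity correction (default `TRUE`).
#' @return list of class `chisq_result`: `statistic`, `df` (always 1),
#'   `p_value`, `corrected`.
#' @examples
#' chi_square_corrected(contingency_2x2(23, 9, 4, 22))
#' @export
chi_square_corrected <- function(tab, correct = TRUE) {
  stopifnot(inherits(tab, "contingency_2x2"))
  O <- matrix(c(tab$a, tab$c, tab$b, tab$d), nrow = 2)
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0)) {
    abort_input("chi-square undefined: a margin of the 2x2 table is zero")
  }
  E <- outer(rs, cs) / sum(O)
  dev <- abs(O - E) - if (correct) 0.5 else 0
  statistic <- sum(pmax(0, dev)^2 / E)
  structure(list(statistic = statistic, df = 1L,
                 p_value = pchisq(statistic, df = 1L, lower.tail = FALSE),
                 corrected = correct), class = "chisq_result")
}

#' Mann-Whitney U test with Hodges-Lehmann shift estimate
#'
#' Rank-sum test (midranks for ties) with the normal approximation:
#' the variance of U is tie-corrected,
#' \eqn{Var(U) = nm/12\,[(N+1) - \sum(t^3 - t)/(N(N-1))]}, and the z score
#' optionally uses a 0.5 continuity correction.  The location shift between
#' the samples is estimated by the Hodges-Lehmann statistic (median of all
#' pairwise differences \eqn{x_i - y_j}) with a confidence interval read off
#' the ordered pairwise differences at the rank cutoffs implied by the
#' normal-approximation critical value.
#'
#' @param x,y non-empty numeric samples.
#' @param conf_level confidence level for the shift interval, default 0.95.
#' @param continuity apply the 0.5 continuity correction to z (default `TRUE`).
#' @return list of class `shift_estimate`: `hl_shift`, `ci_low`, `ci_high`,
#'   `conf_level`, `u_statistic`, `z`, `p_value`.
#' @examples
#' mann_whitney_shift(c(11, 12, 13), c(1, 2, 3))
#' @export
mann_whitney_shift <- function(x, y, conf_level = 0.95, continuity = TRUE) {
  if (length(x) == 0L || length(y) == 0L) {
    abort_input("both samples must be non-empty")
  }
  if (anyNA(x) || anyNA(y)) abort_input("samples must not contain NA")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  tie_sizes <- table(c(x, y))
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  var_u <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (var_u <= 0) {
    z <- 0
    p <- 1
  } else {
    cc <- if (continuity) 0.5 else 0
    num <- u - mu
    z <- if (num == 0) 0 else (num - sign(num) * cc) / sqrt(var_u)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  nm <- as.numeric(n) * m
  zc <- qnorm(1 - (1 - conf_level) / 2)
  k <- floor(mu - zc * sqrt(if (var_u > 0) var_u else nm * (N + 1) / 12))
  k <- max(0, min(k, ceiling(mu) - 1))
  hl_ranks <- if (nm %% 2 == 0) c(nm / 2, nm / 2 + 1) else (nm + 1) / 2
  wanted <- c(hl_ranks, k + 1, nm - k)
  if (nm <= 2e6) {
    diffs <- sort(as.vector(outer(x, y, "-")))
    d <- diffs[wanted]
  } else {
    # large samples: select order statistics of the pairwise differences by
    # value bisection, O((n + m) log) per rank, without materialising them
    d <- vapply(wanted, function(kk) kth_pairwise_diff(sort(x), sort(y), kk),
                numeric(1))
  }
  hl <- mean(d[seq_along(hl_ranks)])
  ci_low <- d[length(d) - 1L]
  ci_high <- d[length(d)]
  structure(list(hl_shift = hl, ci_low = ci_low, ci_high = ci_high,
                 conf_level = conf_level, u_statistic = u, z = z,
                 p_value = p), class = "shift_estimate")
}

#' Pooled-variance two-sample t-test
#'
#' Classical Student t-test with pooled variance (not Welch), two-sided.
#'
#' @param x,y numeric samples, each of size at least 2.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
pooled_t_test <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n < 2L || m < 2L) abort_input("each sample needs at least 2 values")
  sp2 <- ((n - 1) * var(x) + (m - 1) * var(y)) / (n + m - 2)
  if (sp2 == 0) abort_input("degenerate samples: pooled variance is zero")
  statistic <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n + 1 / m))
  df <- n + m - 2
  list(statistic = statistic, df = df,
       p_value = 2 * pt(-abs(statistic), df = df))
}

# k-th smallest value of {xs_i - ys_j} for sorted xs, ys, found by bisection
# on the value axis; count_le is monotone, so the infimum t with
# count_le(t) >= k is exactly the k-th pairwise difference
kth_pairwise_diff <- function(xs, ys, k) {
  n <- length(xs); m <- length(ys)
  stopifnot(k >= 1, k <= as.numeric(n) * m)
  count_le <- function(t) {
    sum(m - findInterval(xs - t, ys, left.open = TRUE))
  }
  lo <- xs[1L] - ys[m]
  hi <- xs[n] - ys[1L]
  for (iter in 1:100) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break
    if (count_le(mid) >= k) hi <- mid else lo <- mid
  }
  hi
}

# Lilliefors critical value for the one-sample KS distance against a normal
# with estimated mean/sd, via Stephens' modified-statistic approximation:
# crit = c_alpha / (sqrt(n) - 0.01 + 0.85/sqrt(n)).
LILLIEFORS_CONSTANTS <- c("0.15" = 0.775, "0.1" = 0.819, "0.05" = 0.895,
                          "0.025" = 0.955, "0.01" = 1.035)

lilliefors_critical <- function(n, alpha = 0.05) {
  idx <- which(vapply(as.numeric(names(LILLIEFORS_CONSTANTS)),
                      function(a) isTRUE(all.equal(a, alpha)), logical(1)))
  if (length(idx) != 1L) {
    abort_input("alpha must be one of ",
                paste(names(LILLIEFORS_CONSTANTS), collapse = ", "))
  }
  LILLIEFORS_CONSTANTS[[idx]] / (sqrt(n) - 0.01 + 0.85 / sqrt(n))
}

lilliefors_statistic <- function(x) {
  n <- length(x)
  s <- sort(x)
  z <- pnorm(s, mean(x), sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

#' Normality routing for group comparisons
#'
#' Kolmogorov-Smirnov distance of a sample against a normal distribution
#' with estimated mean and SD, compared to the Lilliefors-corrected critical
#' value (plain KS critical values are anti-conservative when the parameters
#' are estimated).  The routing decision selects the rank test
#' ([mann_whitney_shift()]) and median \[min-max\] summaries for non-normal
#' variables, versus [pooled_t_test()] and mean (SD) summaries.
#'
#' @param x numeric sample, size at least 4.
#' @param alpha significance level; one of 0.15, 0.1, 0.05, 0.025, 0.01.
#' @return list: `route` (`"normal"` or `"non_normal"`), `statistic` (the KS
#'   distance D), `critical`, `n`, `alpha`.
#' @export
normality_route <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 4L) abort_input("normality routing needs at least 4 observations")
  if (anyNA(x)) abort_input("sample must not contain NA")
  crit <- lilliefors_critical(n, alpha)
  if (sd(x) == 0) {
    # a constant sample has no normal fit; route to the rank test
    return(list(route = "non_normal", statistic = Inf, critical = crit,
                n = n, alpha = alpha))
  }
  d <- lilliefors_statistic(x)
  list(route = if (d > crit) "non_normal" else "normal",
       statistic = d, critical = crit, n = n, alpha = alpha)
}
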