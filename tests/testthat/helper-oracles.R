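# Independent oracles used across test files.

# exact two-sided Mann-Whitney p-value by full enumeration of all ways to
# assign the pooled values to the two groups
exact_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  N <- length(pooled)
  r <- rank(pooled)
  mu <- n * (N - n) / 2
  u_of <- function(ii) sum(r[ii]) - n * (n + 1) / 2
  u_all <- apply(utils::combn(N, n), 2, u_of)
  u_obs <- u_of(seq_len(n))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# random all-nonzero 2x2 table
random_table <- function(max_count = 40) {
  contingency_2x2(sample(max_count, 1), sample(max_count, 1),
                  sample(max_count, 1), sample(max_count, 1))
}

table1_printed <- list(
  or = c(longterm_control = 14, exam_regularity = 29.7,
         onset_age = 9.8, duration = 7),
  or_digits = c(longterm_control = 0, exam_regularity = 1,
                onset_age = 1, duration = 0),
  chisq = c(longterm_control = 16.2, exam_regularity = 24.7,
            onset_age = 11.7, duration = 9.9))
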