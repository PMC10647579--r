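# Independent oracles used to freeze expected values.

# Brute-force exact two-sided Mann-Whitney p-value: enumerate every
# assignment of the combined sample to the two groups and tabulate the
# rank-sum-based U statistic. Only valid without ties.
mwu_enum_oracle <- function(x, y) {
  m <- length(x)
  combined <- c(x, y)
  n_tot <- length(combined)
  ranks <- rank(combined)
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  labelings <- utils::combn(n_tot, m)
  u_all <- apply(labelings, 2, function(idx) sum(ranks[idx]) - m * (m + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Explicit normal-equations OLS: coefficients and classical standard errors.
ols_oracle <- function(X, y) {
  xtx_inv <- solve(crossprod(X))
  beta <- drop(xtx_inv %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coef = beta, se = sqrt(s2 * diag(xtx_inv)))
}

# Small deterministic cohort-shaped table for comparison and IO tests.
toy_cohort <- function() {
  tibble::tibble(
    id = 1:6,
    age = c(50, 60, 65, 75, 80, 85),
    sex = c("female", "male", "female", "female", "male", "male"),
    bmi = c(31, 29, 33, 26, 24, 27),
    sbp = c(140, 135, 150, 138, 142, 136),
    dbp = c(88, 84, 90, 76, 72, 70),
    cavi = c(7.5, 7.9, 8.2, 9.8, 10.4, 10.9),
    cavi0 = c(11.0, 11.5, 12.1, 17.2, 18.8, 20.1),
    hypertension = c(1L, 0L, 1L, 1L, 1L, 0L),
    diabetes = c(0L, 0L, 1L, 0L, 1L, 0L),
    dyslipidemia = c(1L, 1L, 0L, 1L, 0L, 1L),
    smoking = c(0L, 1L, 0L, 0L, 1L, 1L)
  )
}
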