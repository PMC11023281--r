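# Independent oracles and fixture builders used across the test files.

# Bateman curve evaluated directly (independent of the package's bateman()).
bateman_ref <- function(t, scale, ka, ke) {
  scale * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
}

# Closed-form AUC of the Bateman curve on [0, Inf).
bateman_auc_inf <- function(scale, ka, ke) {
  scale * ka / (ka - ke) * (1 / ke - 1 / ka)   # = scale / ke
}

# Least-squares slope/intercept from the explicit normal equations.
ols_ref <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Exact two-sided signed-rank p by literal recursion over sign vectors:
# counts every one of the 2^n assignments, no convolution shortcut.
# Feasible for n <= 12.
brute_force_signrank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(r)
  count <- function(i, w) {
    if (i > n) return(c(ge = w >= w_obs - 1e-9, le = w <= w_obs + 1e-9))
    count(i + 1, w + r[i]) + count(i + 1, w)
  }
  tails <- count(1, 0) / 2^n
  min(1, 2 * min(tails))
}

# Study-like profile from an exact exponential decline (no absorption phase).
exp_profile <- function(times, c0, ke, subject = "E", lloq = 0.625) {
  conc_profile(subject, "oral", 15, times, c0 * exp(-ke * times), lloq = lloq)
}

oral_params <- function(cv = 0) simulation_params(cv = cv)
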