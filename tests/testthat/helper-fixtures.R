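# Shared fixtures: the fitted human parameter set and small utilities.

human_params <- function(L = Inf) continuous_params(D = 0.004, V = 0.051, L = L)

median_supply <- function() 3.23e5

# One-sample Kolmogorov-Smirnov statistic of samples against a CDF vector
# evaluated at the sorted samples.
ks_stat <- function(x, cdf_fun) {
  x <- sort(x)
  n <- length(x)
  Fv <- cdf_fun(x)
  max(abs(seq_len(n) / n - Fv), abs((seq_len(n) - 1L) / n - Fv))
}

# Empirical survival of exit times at given ages.
empirical_survival <- function(exit_times, ages)
  vapply(ages, function(a) mean(exit_times > a), numeric(1))
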