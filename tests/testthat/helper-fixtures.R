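# Shared fixtures and independent oracles.

kamahi <- function() species_params("WEIRAC", 4.53, 16.6, 3.3e-5, 0.08)

default_forest <- function(density = 300, meanlog = 3.1, sdlog = 0.35,
                           L_mean = 1.0, L_sd = 0.25) {
  site_forest_state(density, meanlog, sdlog, L_mean, L_sd)
}

# Negative-binomial pmf from the Gamma-function definition, independent
# of stats::dnbinom and of the pbeta-based implementation under test.
nb_pmf_oracle <- function(k, mu, h) {
  p <- h / (h + mu)
  exp(lgamma(k + h) - lgamma(h) - lfactorial(k) +
        h * log(p) + k * log1p(-p))
}

# Brute-force tail P(X > K) by pmf summation. Summing the tail forward
# (rather than 1 - head sum) avoids catastrophic cancellation when the
# head mass is close to one; successive terms shrink by roughly
# mu/(mu + h), which sets how many are needed.
nb_tail_oracle <- function(mu, h, K) {
  if (mu == 0) return(0)
  n_terms <- min(ceiling(60 / log1p(h / mu)) + 1000, 5e6)
  sum(nb_pmf_oracle((K + 1):(K + n_terms), mu, h))
}

# Bisection root of the foliar rate on [lo, hi], independent of
# equilibrium_tau's uniroot call.
bisect_equilibrium <- function(sp, B, I, lo, hi, iter = 200) {
  g <- function(tau) foliar_rate(tau, I, sp, B)
  stopifnot(g(lo) > 0, g(hi) < 0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
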