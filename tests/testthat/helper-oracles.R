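# Shared fixtures and independent oracles for the test suite.

# Measured per-repeat dissociation constants (uM) of the four-operator
# autoregulation promoter, in promoter order IR1..IR4.
IR_KDS <- c(IR1 = 0.0205, IR2 = 0.862, IR3 = 11.0, IR4 = 0.121)

# Poisson-binomial oracle: distribution of the number of successes among
# independent Bernoulli trials with probabilities p, by direct convolution.
# Deliberately independent of the package's configuration enumeration.
pois_binom_oracle <- function(p) {
  probs <- 1
  for (pi in p) {
    probs <- c(probs * (1 - pi), 0) + c(0, probs * pi)
  }
  probs
}

# Random independent-site model with kds log-uniform in [1e-3, 1e3].
random_model <- function(n) {
  promoter_model(10^stats::runif(n, -3, 3))
}

# Saturation curve sampled without noise from an exact Hill law
# theta = (conc / kd)^n, i.e. Y = theta / (1 + theta).
hill_law_curve <- function(kd, n, n_points = 12, decades = 2) {
  conc <- 10^seq(log10(kd) - decades, log10(kd) + decades,
                 length.out = n_points)
  theta <- (conc / kd)^n
  saturation_curve(conc, theta / (1 + theta))
}

# Noiseless single-site titration table (zero lane + 12 log-spaced lanes
# spanning two decades around the generating kd).
single_site_table <- function(kd, n_lanes = 12, decades = 2) {
  simulate_emsa(promoter_model(kd),
                titration_design(center = kd, n_lanes = n_lanes,
                                 decades = decades, replicates = 1),
                noise_model(0))
}
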