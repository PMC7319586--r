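test_that("model construction validates sites and coupling", {
  expect_error(promoter_model(c(A = 1, A = 2)), "unique")
  expect_error(promoter_model(c(1, -2)), class = "coopfit_invalid_model")
  expect_error(promoter_model(c(1, 0)), class = "coopfit_invalid_model")
  m <- promoter_model(c(a = 1, b = 2),
                      coupling = list(list(i = "a", j = "b", omega = 5)))
  expect_equal(m$omega["a", "b"], 5)
  expect_equal(m$omega["b", "a"], 5)
  expect_error(
    promoter_model(c(a = 1, b = 2),
                   coupling = list(list(i = "a", j = "b", omega = -1))),
    "omega")
})

test_that("configuration distribution matches closed forms", {
  m1 <- promoter_model(1)
  # zero ligand: all probability on the empty configuration
  cd0 <- configuration_distribution(m1, 0)
  expect_equal(cd0$prob[rowSums(cd0$configs) == 0], 1)
  # conc = kd: bound and unbound equally likely
  cd <- configuration_distribution(m1, 1)
  expect_equal(unname(cd$prob), c(0.5, 0.5))
  # four heterogeneous independent sites: P(empty) equals the closed-form
  # product of per-site vacancies
  conc <- 0.121
  m4 <- promoter_model(IR_KDS)
  cd4 <- configuration_distribution(m4, conc)
  p_empty_expected <- prod(1 - conc / (conc + IR_KDS))
  expect_equal(unname(cd4$prob[rowSums(cd4$configs) == 0]), p_empty_expected,
               tolerance = 1e-12)
  expect_equal(p_empty_expected, 0.0628, tolerance = 1e-2)
  expect_error(configuration_distribution(m4, -1),
               class = "coopfit_domain_error")
})

test_that("band distribution reduces to known cases", {
  expect_equal(unname(band_distribution(promoter_model(c(1, 2)), 0)$probs),
               c(1, 0, 0))
  # two identical independent sites at conc = kd: symmetric binomial
  expect_equal(unname(band_distribution(promoter_model(c(1, 1)), 1)$probs),
               c(0.25, 0.5, 0.25), tolerance = 1e-12)
})

test_that("distributions are normalised and match the Poisson-binomial oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(1:6, 1)
    kds <- 10^runif(n, -3, 3)
    omega <- matrix(1, n, n)
    if (n > 1) {
      i <- sample(n, 2)
      omega[i[1], i[2]] <- omega[i[2], i[1]] <- 10^runif(1, -3, 3)
    }
    m <- promoter_model(kds, coupling = omega)
    conc <- 10^runif(1, -3, 3)
    cd <- configuration_distribution(m, conc)
    expect_equal(sum(cd$prob), 1, tolerance = 1e-12)
    expect_true(all(cd$prob >= 0))
    bd <- band_distribution(m, conc)
    expect_equal(sum(bd$probs), 1, tolerance = 1e-12)

    # independent version of the same sites must equal the convolution oracle
    m_ind <- promoter_model(kds)
    bd_ind <- band_distribution(m_ind, conc)
    expect_lt(max(abs(unname(bd_ind$probs) -
                        pois_binom_oracle(conc / (conc + kds)))), 1e-12)
  }
})

test_that("fractional saturation is monotone with the right limits", {
  m <- promoter_model(IR_KDS)
  expect_equal(fractional_saturation(m, 0), 0)
  expect_equal(fractional_saturation(promoter_model(2), 2), 0.5)
  # four-site model at the tightest site's kd: closed-form per-site average
  expect_equal(fractional_saturation(m, 0.0205),
               mean(0.0205 / (0.0205 + IR_KDS)), tolerance = 1e-12)
  expect_equal(fractional_saturation(m, 0.0205), 0.167, tolerance = 1e-2)
  grid <- 10^seq(-4, 3, length.out = 40)
  y <- vapply(grid, function(cc) fractional_saturation(m, cc), numeric(1))
  expect_true(all(diff(y) > 0))
  expect_gt(fractional_saturation(m, 1e6), 0.9999)
})

test_that("apparent Hill coefficient has the textbook limits", {
  set.seed(7)
  for (kd in 10^runif(3, -2, 2)) {
    expect_equal(apparent_hill_coefficient(promoter_model(kd)), 1,
                 tolerance = 1e-6)
  }
  # strong positive coupling of two identical sites approaches n = 2
  m_coop <- promoter_model(c(1, 1), coupling = matrix(c(1, 1e6, 1e6, 1), 2))
  expect_gte(apparent_hill_coefficient(m_coop), 1.99)
  # heterogeneous independent sites: apparent negative cooperativity
  expect_lt(apparent_hill_coefficient(promoter_model(IR_KDS)), 1)
  # n identical independent sites stay at exactly 1
  expect_equal(apparent_hill_coefficient(promoter_model(rep(1, 4))), 1,
               tolerance = 1e-6)
})

test_that("Hill coefficient decreases as affinities spread at fixed geometric mean", {
  spreads <- list(c(1, 1, 1), c(0.1, 1, 10), c(0.01, 1, 100))
  nh <- vapply(spreads, function(k) apparent_hill_coefficient(promoter_model(k)),
               numeric(1))
  expect_equal(nh[1], 1, tolerance = 1e-6)
  expect_true(all(diff(nh) < 0))
  expect_true(all(nh > 0 & nh <= 3))
})

test_that("single-site fitting round-trips noiseless data and rejects degenerate input", {
  for (kd in c(1, 0.0205)) {
    curve <- band_table_to_saturation(single_site_table(kd))
    fit <- fit_single_site(curve)
    expect_equal(fit$kds, kd, tolerance = 1e-6)
    expect_lt(fit$residual, 1e-12)
  }
  flat <- saturation_curve(c(0, 1, 2, 3), c(0, 0, 0, 0))
  expect_error(fit_single_site(flat), class = "coopfit_nonidentifiable")
  sat <- saturation_curve(c(1, 2, 3), c(1, 1, 1))
  expect_error(fit_single_site(sat), class = "coopfit_nonidentifiable")
})

test_that("multisite fitting recovers heterogeneous and degenerate kds", {
  m <- promoter_model(IR_KDS)
  design <- titration_design(center = exp(mean(log(IR_KDS))), n_lanes = 15,
                             decades = 3, replicates = 1)
  tab <- simulate_emsa(m, design, noise_model(0))
  fit <- fit_multisite(tab, 4)
  expect_equal(fit$kds, sort(unname(IR_KDS)), tolerance = 0.01)

  m2 <- promoter_model(c(1, 1))
  tab2 <- simulate_emsa(m2, titration_design(center = 1, n_lanes = 12,
                                             replicates = 1),
                        noise_model(0))
  fit2 <- fit_multisite(tab2, 2)
  expect_equal(fit2$kds, c(1, 1), tolerance = 0.01)

  # model mismatch is detectable: lumping the high-occupancy species of the
  # four-site gel and fitting 2 sites leaves a residual far above the
  # noiseless tolerance
  td <- as.data.frame(tab)
  lumped <- cbind(td$band_0, td$band_1, td$band_2 + td$band_3 + td$band_4)
  fit_wrong <- fit_multisite(band_table(td$conc, lumped,
                                        replicate = td$replicate), 2)
  expect_gt(fit_wrong$residual, 1e-4)
  expect_lt(fit$residual, 1e-12)

  # too few distinct concentrations
  small <- band_table(c(0, 1, 2), matrix(1, 3, 3))
  expect_error(fit_multisite(small, 2), class = "coopfit_nonidentifiable")
})
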