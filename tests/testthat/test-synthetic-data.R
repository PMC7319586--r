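test_that("noiseless simulated gels reproduce the model distribution exactly", {
  m <- promoter_model(IR_KDS)
  design <- titration_design(center = 0.5, n_lanes = 8, replicates = 1)
  tab <- as.data.frame(simulate_emsa(m, design, noise_model(0)))
  bands <- grep("^band_", names(tab), value = TRUE)
  frac <- as.matrix(tab[bands]) / rowSums(as.matrix(tab[bands]))
  for (r in seq_len(nrow(tab))) {
    expect_equal(unname(frac[r, ]),
                 unname(band_distribution(m, tab$conc[r])$probs),
                 tolerance = 1e-12)
  }
})

test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  m <- promoter_model(c(0.1, 2))
  design <- titration_design(center = 0.5)
  t1 <- simulate_emsa(m, design, noise_model(0.05, seed = 77))
  t2 <- simulate_emsa(m, design, noise_model(0.05, seed = 77))
  expect_identical(t1, t2)
  t3 <- simulate_emsa(m, design, noise_model(0.05, seed = 78))
  expect_false(identical(t1, t3))

  p1 <- plant_inverted_repeats(100, list(list(arm_length = 6, spacer = 3,
                                              position = 10)), seed = 4)
  p2 <- plant_inverted_repeats(100, list(list(arm_length = 6, spacer = 3,
                                              position = 10)), seed = 4)
  expect_identical(p1$sequence$sequence, p2$sequence$sequence)

  r1 <- simulate_reporter(promoter_model(1), 1, noise_sd = 1e-3, seed = 9)
  r2 <- simulate_reporter(promoter_model(1), 1, noise_sd = 1e-3, seed = 9)
  expect_identical(r1, r2)
})

test_that("noisy band fractions stay centred on the model value", {
  m <- promoter_model(c(0.05, 0.5))
  conc <- 0.2
  sigma <- 0.05
  design <- titration_design(concentrations = conc, replicates = 1e4)
  tab <- as.data.frame(simulate_emsa(m, design, noise_model(sigma, seed = 21)))
  tab <- tab[tab$conc > 0, ]
  bands <- grep("^band_", names(tab), value = TRUE)
  frac <- as.matrix(tab[bands]) / rowSums(as.matrix(tab[bands]))

  # independent Monte-Carlo oracle built directly from the noise law
  probs <- band_distribution(m, conc)$probs
  set.seed(900)
  oracle <- t(replicate(1e4, {
    noisy <- probs * rlnorm(length(probs), 0, sigma)
    noisy / sum(noisy)
  }))
  for (k in seq_along(probs)) {
    se <- sqrt(var(frac[, k]) / nrow(frac) + var(oracle[, k]) / nrow(oracle))
    expect_lt(abs(mean(frac[, k]) - mean(oracle[, k])), 3 * se)
    # and the simulated mean sits within 3 combined SEs + the O(sigma^2)
    # ratio bias of the exact model value
    expect_lt(abs(mean(frac[, k]) - probs[k]), 3 * se + 2 * sigma^2)
  }
})

test_that("polyC knockouts remove sites and preserve order", {
  m <- rv2827c_promoter_model()
  m3 <- mutate_probe(m, "IR3")
  expect_equal(m3$site_ids, c("IR1", "IR2", "IR4"))
  expect_equal(unname(m3$kds), unname(m$kds[c("IR1", "IR2", "IR4")]))
  # knocking out everything leaves a zero-site model that never shifts
  m0 <- mutate_probe(m, c("IR1", "IR2", "IR3", "IR4"))
  expect_equal(length(m0$kds), 0)
  expect_equal(unname(band_distribution(m0, 100)$probs), 1)
  expect_equal(fractional_saturation(m0, 100), 0)
  # no knockout is the identity
  expect_identical(mutate_probe(m, character()), m)
  expect_error(mutate_probe(m, "IR9"), class = "coopfit_input_error")
})

test_that("planted-repeat plans validate overlap and fit", {
  expect_error(
    plant_inverted_repeats(50, list(list(arm_length = 23, spacer = 13,
                                         position = 10))),
    class = "coopfit_design_error")
  expect_error(
    plant_inverted_repeats(
      200, list(list(arm_length = 23, spacer = 3, position = 10),
                list(arm_length = 23, spacer = 3, position = 20))),
    class = "coopfit_design_error")
  # planted mismatches equal the requested mutation count
  pl <- plant_inverted_repeats(120, list(list(arm_length = 20, spacer = 5,
                                              position = 30, mutations = 2)),
                               seed = 3)
  left <- substr(pl$sequence$sequence, 30, 49)
  right <- substr(pl$sequence$sequence, 55, 74)
  rc_right <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(right)))
  mm <- sum(strsplit(left, "")[[1]] != strsplit(rc_right, "")[[1]])
  expect_equal(mm, 2)
})

test_that("simulated reporter activity follows promoter occupancy", {
  m <- promoter_model(IR_KDS)
  # no repressor: slope equals the basal slope
  r0 <- simulate_reporter(m, 0, basal_slope = 0.01, od600_first = 1)
  expect_equal(miller_units(r0)$slope, 0.01, tolerance = 1e-10)
  # saturating repressor: activity collapses towards zero
  rsat <- simulate_reporter(m, 1e4, basal_slope = 0.01, od600_first = 1)
  expect_lt(miller_units(rsat)$mu, 0.1)
  # intermediate concentration: slope = basal * P(0 bound), closed form
  cc <- 0.121
  p0 <- prod(1 - cc / (cc + IR_KDS))
  rmid <- simulate_reporter(m, cc, basal_slope = 0.01, od600_first = 1)
  expect_equal(miller_units(rmid)$slope, 0.01 * p0, tolerance = 1e-10)
})

test_that("the noiseless pipeline closes the loop on the generating Kd", {
  for (kd in c(0.0205, 0.862)) {
    res <- analyze_emsa(single_site_table(kd))$result
    expect_equal(res$kd, kd, tolerance = 1e-6)
    expect_equal(res$n_h, 1, tolerance = 1e-6)
  }
})

test_that("with 5% noise and triplicates the Kd comes back within 10% (median)", {
  kd <- 0.862
  m <- promoter_model(kd)
  design <- titration_design(center = kd, n_lanes = 12, replicates = 3)
  errs <- vapply(1:200, function(s) {
    tab <- simulate_emsa(m, design, noise_model(0.05, seed = s))
    abs(analyze_emsa(tab)$result$kd - kd) / kd
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})
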