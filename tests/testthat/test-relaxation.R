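test_that("monoexponential fitting is exact on clean data and scale-equivariant", {
  delays <- seq(0.004, 0.04, length.out = 10)
  y <- 100 * exp(-50 * delays)
  f <- fit_monoexponential(delays, y)
  expect_equal(f$rate, 50, tolerance = 1e-8)
  expect_equal(f$amplitude, 100, tolerance = 1e-8)
  expect_equal(f$status, "OK")

  # scaling intensities leaves the rate unchanged
  f2 <- fit_monoexponential(delays, 7.3 * y)
  expect_equal(f2$rate, f$rate, tolerance = 1e-9)

  expect_error(fit_monoexponential(delays, rep(5, 10)), "constant")
  expect_error(fit_monoexponential(delays[1:3], y[1:3]), "at least 4")
})

test_that("noisy-rate recovery stays within 3 sigma of truth in >=99% of refits", {
  # sigma = 2% of I0, fixed seed, 200 replicates at one representative rate
  delays <- c(4, 4, 6, 8, 10, 12, 15, 20, 20, 25, 30) / 1000
  hits <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    sim <- gen_decay_tables(40, delays = delays, sigma = 2, seed = 1000L + i)
    s <- sim$decays[[1]]
    f <- fit_monoexponential(s$delays, s$intensities)
    sr <- cr_sigma_rate(delays, 100, 40, 2)
    hits <- hits + (f$status == "OK" && abs(f$rate - 40) <= 3 * sr)
  }
  expect_gte(hits / n_rep, 0.99)
})

test_that("duplicate-delay noise estimation matches its closed form and pools", {
  base <- gen_decay_tables(c(30, 50), sigma = 0, seed = 1)$decays
  # identical duplicates -> zero noise
  expect_equal(estimate_noise(base), 0)
  # shift one replicate of each duplicated delay by exactly d -> sigma = d/sqrt(2)
  d <- 3.2
  shifted <- lapply(base, function(s) {
    idx <- which(s$duplicate_mask & s$replicate == 2)
    s$intensities[idx] <- s$intensities[idx] + d
    s
  })
  expect_equal(estimate_noise(shifted), d / sqrt(2), tolerance = 1e-12)
  # pooling over residues equals the estimate from the concatenated pairs
  expect_equal(estimate_noise(shifted), estimate_noise(shifted[1]),
               tolerance = 1e-12)
  # no duplicates -> explicit instruction to supply sigma
  nodup <- lapply(base, function(s) {
    keep <- !(s$duplicate_mask & s$replicate == 2)
    list(residue = s$residue, delays = s$delays[keep],
         intensities = s$intensities[keep],
         duplicate_mask = rep(FALSE, sum(keep)),
         replicate = rep(1L, sum(keep)))
  })
  expect_error(estimate_noise(nodup), "explicit")
})

test_that("Monte Carlo rate uncertainty is deterministic, CR-consistent and monotone in noise", {
  delays <- c(4, 4, 6, 8, 10, 12, 15, 20, 20, 25, 30) / 1000
  s <- gen_decay_tables(40, delays = delays, sigma = 1, seed = 3)$decays[[1]]
  expect_equal(monte_carlo_uncertainty(s$delays, s$intensities, 0), 0)
  a <- monte_carlo_uncertainty(s$delays, s$intensities, 2, n_draws = 200, seed = 9)
  b <- monte_carlo_uncertainty(s$delays, s$intensities, 2, n_draws = 200, seed = 9)
  expect_identical(a, b)

  # 500 draws against the asymptotic Cramer-Rao value (within 25%)
  clean <- gen_decay_tables(40, delays = delays, sigma = 0, seed = 1)$decays[[1]]
  mc <- monte_carlo_uncertainty(clean$delays, clean$intensities, 2,
                                n_draws = 500, seed = 11)
  cr <- cr_sigma_rate(delays, 100, 40, 2)
  expect_lt(abs(mc - cr) / cr, 0.25)

  # sigma_rate decreases as noise drops through 4% -> 2% -> 1% of I0
  mcs <- vapply(c(4, 2, 1), function(sg)
    monte_carlo_uncertainty(clean$delays, clean$intensities, sg,
                            n_draws = 300, seed = 13), numeric(1))
  expect_true(all(diff(mcs) < 0))
})

test_that("mobility regression recovers slopes, flags displaced residues only", {
  # identity data: slope 1, r = 1, no outliers
  apo <- data.frame(residue = c(2:15, 60:80), rate = seq(8, 40, length.out = 35),
                    sigma = 0.1, status = "OK")
  bound <- apo
  mr <- mobility_regression(apo, bound)
  expect_equal(mr$fits$WW$slope, 1, tolerance = 1e-12)
  expect_equal(mr$fits$WW$corr_coeff, 1, tolerance = 1e-12)
  expect_length(mr$fits$WW$outliers, 0)

  # planted slope 0.8 with small noise recovers within +/- 0.02
  set.seed(21)
  bound2 <- apo
  bound2$rate <- 0.8 * apo$rate + 1 + rnorm(nrow(apo), 0, 0.1)
  mr2 <- mobility_regression(apo, bound2)
  expect_lt(abs(mr2$fits$WW$slope - 0.8), 0.02)
  expect_lt(abs(mr2$fits$PPIASE$slope - 0.8), 0.02)

  # one point displaced by +10 SD is flagged; the fit is not refit without it
  bound3 <- bound2
  i31 <- which(bound3$residue == 70)
  bound3$rate[i31] <- bound3$rate[i31] + 10
  mr3 <- mobility_regression(apo, bound3)
  expect_true(70 %in% mr3$fits$PPIASE$outliers)
  expect_false(70 %in% mr3$fits$WW$outliers)

  # slope unchanged by adding a residue exactly on the fitted line
  fit <- mr2$fits$WW
  new_apo <- rbind(apo, data.frame(residue = 25, rate = 50, sigma = 0.1, status = "OK"))
  new_bound <- rbind(bound2, data.frame(residue = 25,
                                        rate = fit$intercept + fit$slope * 50,
                                        sigma = 0.1, status = "OK"))
  mr4 <- mobility_regression(new_apo, new_bound)
  expect_equal(mr4$fits$WW$slope, fit$slope, tolerance = 1e-9)

  # degenerate horizontal variance errors
  flat <- data.frame(residue = 2:10, rate = 5, sigma = 0.1, status = "OK")
  expect_error(mobility_regression(flat, flat, fit_domains = "WW"), "degenerate")
})

test_that("R2-R1/2 maps to J_eff(0) and tau_c consistently with the forward model", {
  k <- nmr_constants()
  # algebraic inverse: tau_c -> rate -> tau_c to 1e-12 relative, 1-20 ns
  taus <- seq(1e-9, 20e-9, length.out = 25)
  back <- jeff0_tauc(rate_from_tauc(taus, k), k)$tau_c
  expect_equal(back, taus, tolerance = 1e-12)
  # linearity: doubling the rate doubles tau_c
  expect_equal(jeff0_tauc(20, k)$tau_c, 2 * jeff0_tauc(10, k)$tau_c,
               tolerance = 1e-12)
  expect_equal(jeff0_tauc(10, k)$tau_c * 2 / 5, jeff0_tauc(10, k)$jeff0 * 1,
               tolerance = 1e-12)

  # independent constant-by-constant evaluation of the 10-ns forward value:
  # C_N = (omega_N * -170 ppm)^2/3, D_IN = ((mu0/4pi) hbar gI gN / r^3)^2/4
  b0 <- 2 * pi * 700.13e6 / 2.6752218744e8
  omega_n <- 2.7116189e7 * b0
  c_n <- (omega_n * 170e-6)^2 / 3
  d_in <- (1e-7 * 1.054571817e-34 * 2.6752218744e8 * 2.7116189e7 /
             (1.02e-10)^3)^2 / 4
  rate10 <- (2 * c_n / 3) * (1 + 3 * d_in / c_n) * (2 * 1e-8 / 5)
  expect_equal(rate_from_tauc(1e-8, k), rate10, tolerance = 1e-10)
  # and the recovered tumbling time is within 15% of 10 ns
  expect_lt(abs(jeff0_tauc(rate10, k)$tau_c - 1e-8) / 1e-8, 0.15)
})

test_that("combined CSP follows the weighted-amide convention with a switch", {
  expect_equal(combined_csp(0, 0), 0)
  expect_equal(combined_csp(0.1, 0), 0.1)
  expect_equal(combined_csp(0, 1.0), 0.154)
  expect_equal(combined_csp(3, 4, weight = 1), 5)
  # alternate rendering: scale the squared nitrogen term instead
  expect_equal(combined_csp(0, 1.0, convention = "scale_squared"), sqrt(0.154))
  expect_error(combined_csp(Inf, 0), "finite")
})
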