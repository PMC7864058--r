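mk_rates <- function(residue, rate, sigma = 0.5, status = "OK")
  data.frame(residue = residue, rate = rate, sigma = sigma, status = status,
             stringsAsFactors = FALSE)

test_that("Gamma2 differencing propagates uncertainty and status", {
  para <- mk_rates(1:4, c(30, 45, 20, 15), sigma = 3)
  dia <- mk_rates(1:4, c(30, 25, 18, 12), sigma = 4)
  g <- compute_gamma2(para, dia)
  expect_equal(g$gamma2, c(0, 20, 2, 3))
  expect_equal(g$sigma, rep(5, 4))  # 3-4-5 quadrature
  expect_true(all(g$status == "QUANTIFIED"))

  # PARA overflow with visible DIA -> OVERFLOW, no numeric Gamma2
  para$status[2] <- "OVERFLOW"
  dia$status[3] <- "MISSING"
  g2 <- compute_gamma2(para, dia)
  expect_equal(g2$status, c("QUANTIFIED", "OVERFLOW", "MISSING", "QUANTIFIED"))
  expect_true(is.na(g2$gamma2[2]))

  # antisymmetry under PARA/DIA swap for quantified residues
  gs <- compute_gamma2(dia, para)
  ok <- g2$status == "QUANTIFIED"
  expect_equal(gs$gamma2[ok], -g2$gamma2[ok])
})

test_that("disappeared-peak classification follows the noise-floor rule", {
  expect_equal(flag_disappeared(100, 0.5, 1), "OVERFLOW")
  expect_equal(flag_disappeared(100, 100, 1), "QUANTIFIED")
  expect_equal(flag_disappeared(0.5, 0.5, 1), "MISSING")
  expect_equal(flag_disappeared(c(100, 100, 0.5), c(0.5, 100, 0.5), 1),
               c("OVERFLOW", "QUANTIFIED", "MISSING"))
  # boundary: intensity exactly at k*floor counts as undetected
  expect_equal(flag_disappeared(100, 3, 1, k = 3), "OVERFLOW")
  expect_error(flag_disappeared(1, 1, 0), "noise_floor")
})

test_that("three-pass threshold reproduces the hand trace and brute force", {
  # hand trace: pass 1 drops the 10, core is the four 1s, threshold 1 +/- 0
  th <- twice_filtered_threshold(c(1, 1, 1, 1, 10))
  expect_equal(th$m3, 1)
  expect_equal(th$std3, 0)
  expect_equal(th$upper, 1)
  expect_equal(th$n_core, 4)

  # constant list -> c +/- 0
  thc <- twice_filtered_threshold(rep(2.5, 6))
  expect_equal(c(thc$m3, thc$std3), c(2.5, 0))

  # order invariance
  set.seed(5)
  v <- rnorm(40, 5, 3)
  t1 <- twice_filtered_threshold(v)
  t2 <- twice_filtered_threshold(sample(v))
  expect_equal(t1[c("m3", "std3", "upper", "lower", "n_core")],
               t2[c("m3", "std3", "upper", "lower", "n_core")])

  # appending the pass-1 mean leaves the pass-1 mean unchanged
  t3 <- twice_filtered_threshold(c(v, mean(v)))
  expect_equal(t3$m[1], t1$m[1], tolerance = 1e-12)

  # 500 random lists against the independent brute-force trace
  set.seed(77)
  for (i in 1:500) {
    n <- sample(5:60, 1)
    v <- switch(sample(3, 1),
                rnorm(n, 10, 4),
                c(rnorm(n - 2, 5, 1), rnorm(2, 40, 5)),  # spiked
                runif(n, 0, 30))
    a <- twice_filtered_threshold(v)
    b <- bf_threshold(v)
    expect_equal(a$m3, b$m3, tolerance = 1e-12)
    expect_equal(a$std3, b$std3, tolerance = 1e-12)
    expect_equal(a$n_core, b$n_core)
  }
  expect_error(twice_filtered_threshold(c(1, 2)), "at least 3")
})

test_that("delta-Gamma2 thresholds the differences and reports reappearances", {
  apo <- data.frame(residue = 1:12,
                    gamma2 = c(rep(2, 9), 12, NA, 5), sigma = 0.3,
                    status = c(rep("QUANTIFIED", 10), "OVERFLOW", "QUANTIFIED"),
                    stringsAsFactors = FALSE)
  cdc <- apo
  cdc$status <- "QUANTIFIED"
  cdc$gamma2 <- c(rep(2, 9), 12, 1, NA)
  cdc$status[12] <- "OVERFLOW"

  dg <- delta_gamma2(apo, cdc)
  expect_equal(dg$delta$delta_gamma2, rep(0, 10))
  expect_equal(c(dg$threshold$m3, dg$threshold$std3), c(0, 0))
  expect_equal(dg$qualitative$change[dg$qualitative$residue == 11], "reappeared")
  expect_equal(dg$qualitative$change[dg$qualitative$residue == 12], "disappeared")

  # two planted 10-rad/s spikes are exactly the residues beyond the bound;
  # the balanced +/-0.8 background survives the trimming intact (hand trace:
  # pass 1 drops the spikes, core SD 0.815, bounds +/-1.63)
  base <- rep(c(-0.8, 0.8), 14)
  apo2 <- data.frame(residue = 1:30, gamma2 = c(base, 10, 10),
                     sigma = 0.3, status = "QUANTIFIED", stringsAsFactors = FALSE)
  cdc2 <- data.frame(residue = 1:30, gamma2 = rep(0, 30), sigma = 0.3,
                     status = "QUANTIFIED", stringsAsFactors = FALSE)
  dg2 <- delta_gamma2(apo2, cdc2)
  sig <- classify_significant(
    data.frame(residue = dg2$delta$residue, gamma2 = dg2$delta$delta_gamma2,
               status = "QUANTIFIED", stringsAsFactors = FALSE),
    dg2$threshold, two_sided = TRUE)
  expect_equal(sig$residue[sig$significance == "significant"], c(29L, 30L))
  expect_error(delta_gamma2(apo2[1:2, ], cdc2[1:2, ]), "fewer than 3")
})

test_that("significance classification is strict at the bound and flags overflow", {
  th <- list(m3 = 5, std3 = 1, upper = 7, lower = 3, n_core = 10)
  vals <- data.frame(residue = 1:4,
                     gamma2 = c(7, 7 + 1e-9, 2, NA),
                     status = c("QUANTIFIED", "QUANTIFIED", "QUANTIFIED", "OVERFLOW"),
                     stringsAsFactors = FALSE)
  s1 <- classify_significant(vals, th)
  expect_equal(s1$significance,
               c("ns", "significant", "ns", "significant_qualitative"))
  s2 <- classify_significant(vals, th, two_sided = TRUE)
  expect_equal(s2$significance[3], "significant")
})

test_that("Solomon-Bloembergen forward model obeys its scaling laws", {
  k <- sb_constants()
  # r^-6 law: doubling the distance divides Gamma2 by 64
  expect_equal(sb_gamma2(10, 5e-9, k) / sb_gamma2(20, 5e-9, k), 64,
               tolerance = 1e-12)
  # harmonic composition of correlation times
  expect_equal(combine_tau(10e-9, 10e-9), 5e-9)

  # literal constant-by-constant re-derivation at 15 A, 5 ns, 700.13 MHz
  mu_b <- 9.2740100783e-24; g <- 2.00231930; gi <- 2.6752218744e8
  wh <- 2 * pi * 700.13e6; tc <- 5e-9
  ref <- (1e-7)^2 * 0.5 * 1.5 * (g * mu_b * gi)^2 / 15 * (15e-10)^-6 *
    (4 * tc + 3 * tc / (1 + (wh * tc)^2))
  expect_equal(sb_gamma2(15, 5e-9, k), ref, tolerance = 1e-6)

  # strictly decreasing in r, strictly increasing in tau_c over 5-20 ns
  rr <- seq(8, 30, length.out = 40)
  expect_true(all(diff(sb_gamma2(rr, 8e-9, k)) < 0))
  tt <- seq(5e-9, 20e-9, length.out = 40)
  expect_true(all(diff(sb_gamma2(15, tt, k)) > 0))
  expect_error(sb_gamma2(-1, 5e-9, k), "r_is")
})

test_that("ensemble averaging uses <r^-6> and dominates the mean-distance value", {
  k <- sb_constants()
  # single frame equals the fixed-distance model
  expect_equal(ensemble_gamma2(12, 5e-9, constants = k),
               sb_gamma2(12, 5e-9, k), tolerance = 1e-12)
  # two equal-weight frames at 10 and 30 A: direct arithmetic on <r^-6>
  expect_equal(ensemble_gamma2(c(10, 30), 5e-9, constants = k),
               sb_gamma2(1, 5e-9, k) * (10^-6 + 30^-6) / 2, tolerance = 1e-12)
  # uniform weights and explicit 1/N weights agree
  d <- c(11, 14, 19, 25)
  expect_equal(ensemble_gamma2(d, 5e-9, constants = k),
               ensemble_gamma2(d, 5e-9, weights = rep(0.25, 4), constants = k),
               tolerance = 1e-15)
  # Jensen: <r^-6> average exceeds the value at <r> for 100 random ensembles
  set.seed(19)
  for (i in 1:100) {
    d <- runif(sample(3:50, 1), 8, 40)
    expect_gte(ensemble_gamma2(d, 5e-9, constants = k),
               sb_gamma2(mean(d), 5e-9, k))
  }
  expect_error(ensemble_gamma2(numeric(0), 5e-9), "empty")
})
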