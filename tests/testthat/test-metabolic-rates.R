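test_that("sliding-window chase MMR handles exact lines and hopeless noise", {
  t <- seq(0, 300, by = 5)
  # exact line: every window ties, MMR equals the full-cycle conversion
  m <- estimate_mmr_chase(t, 10 - 0.002 * t, 98, 3.5, 3.5)
  expect_equal(as.numeric(m), 0.002 * 60 * 94.5 / 3.5, tolerance = 1e-12)
  # pure white noise around a constant: no window reaches r^2 > 0.9
  set.seed(1)
  miss <- estimate_mmr_chase(t, 8 + rnorm(length(t), 0, 0.05), 98, 3.5, 3.5)
  expect_true(is.na(miss))
  expect_match(missing_reason(miss), "no window")
  # cycle shorter than the minimum window
  short <- estimate_mmr_chase(t[1:10], (10 - 0.002 * t)[1:10], 98, 3.5, 3.5)
  expect_true(is.na(short))
  expect_match(missing_reason(short), "shorter")
})

test_that("two-phase decay puts the steepest qualifying window early", {
  t <- seq(0, 300, by = 5)
  o2 <- 10 - ifelse(t <= 120, 0.004 * t, 0.48 + 0.001 * (t - 120))
  m <- estimate_mmr_chase(t, o2, 98, 3.5, 3.5)
  expect_lte(attr(m, "window_start_s"), 30)
  expect_equal(as.numeric(m),
               brute_force_mmr(t, o2, 98, 3.5, 3.5), tolerance = 1e-10)
})

test_that("sliding-window search equals brute-force enumeration on random fixtures", {
  set.seed(2024)
  for (rep in 1:12) {
    n <- sample(25:40, 1)
    t <- seq(0, by = sample(4:8, 1), length.out = n)
    k <- runif(1, 0.002, 0.02)
    o2 <- 9.5 - cumsum(runif(n, 0, 0.03) * exp(-k * t)) +
      rnorm(n, 0, 0.01)
    fast <- estimate_mmr_chase(t, o2, 98, 3.5, 3.5)
    slow <- brute_force_mmr(t, o2, 98, 3.5, 3.5)
    if (is.na(slow)) {
      expect_true(is.na(fast))
    } else {
      expect_equal(as.numeric(fast), slow, tolerance = 1e-9)
    }
  }
})

test_that("overall MMR is the maximum over chases and eligible overnight values", {
  overnight <- rep(5, 80)
  expect_equal(estimate_mmr_overall(overnight, mmr_1h = 9, mmr_18h = 7), 9)
  # forced overnight burst above the chase value wins
  overnight[40] <- 12.5
  expect_equal(estimate_mmr_overall(overnight, mmr_1h = 9, mmr_18h = 7), 12.5)
  # strictly more than 60 overnight values are required
  m59 <- estimate_mmr_overall(rep(5, 59), mmr_1h = 9)
  expect_true(is.na(m59))
  expect_match(missing_reason(m59), "59")
  m60 <- estimate_mmr_overall(rep(5, 60), mmr_1h = 9)
  expect_true(is.na(m60))
  expect_false(is.na(estimate_mmr_overall(rep(5, 61), mmr_1h = 9)))
})

test_that("a simulated overnight burst raises MMR_overall above the chase value", {
  ph <- fish_phenotype(rmr12 = 2, mmr_true = 10, epoc_rate_k = 0.08,
                       q10_true = 1.7)
  cfg <- sim_config(noise_sd = 0, cycle_count = 8, test_temperature = 12)
  burst <- data.frame(start = 75, duration = 10, mo2 = 11.5)
  s <- simulate_o2_trace(ph, cfg, bursts = burst)
  ser <- process_trace(s$trace)
  chase_truth <- s$truth$mo2_true[1L]
  over <- estimate_mmr_overall(ser$mo2[ser$cycle > 0], mmr_1h = chase_truth,
                               min_measurements = 3)
  expect_equal(over, 11.5, tolerance = 1e-6)
  expect_gt(over, chase_truth)
})

test_that("RMR is the low quantile of validated measurements", {
  expect_equal(estimate_rmr(rep(3, 80)), 3)
  expect_equal(estimate_rmr(c(rep(3, 90), rep(6, 10))), 3)
  # linear-interpolation convention on 1..100
  expect_equal(estimate_rmr(as.numeric(1:100)), 10.9)
  expect_equal(estimate_rmr(as.numeric(1:100)),
               unname(quantile(1:100, 0.10, type = 7)))
  # alternative reading: mean of the lowest decile
  expect_equal(estimate_rmr(as.numeric(1:100), method = "lowest_decile_mean"),
               mean(1:10))
  r <- estimate_rmr(rep(3, 59))
  expect_true(is.na(r))
  expect_match(missing_reason(r), "at least 60")
})

test_that("aerobic scope reproduces printed group arithmetic and the mortality rule", {
  sc <- aerobic_scope(11.26, 2.70, survived = TRUE)
  expect_equal(sc$aas, 8.56, tolerance = 1e-12)
  sc2 <- aerobic_scope(11.41, 2.06, survived = TRUE)
  expect_equal(round(sc2$fas, 2), 5.54)
  # mortality: zero scope regardless of recorded rates
  set.seed(3)
  for (i in 1:20) {
    dead <- aerobic_scope(runif(1, 0, 20), runif(1, 0, 5), survived = FALSE)
    expect_identical(dead[c("aas", "fas")], list(aas = 0, fas = 0))
  }
  # a survivor with RMR >= MMR is computed but flagged
  odd <- aerobic_scope(2, 3, survived = TRUE)
  expect_equal(odd$aas, -1)
  expect_true(odd$flagged)
})

test_that("allometric adjustment scales by (mass/ref)^(1 - b)", {
  expect_equal(mass_adjust(5, 3.5, 0.58), 5)
  expect_equal(mass_adjust(1, 7.0, 0.58), 2^0.42, tolerance = 1e-12)
  expect_equal(mass_adjust(1, 1.75, 0.67), 0.5^0.33, tolerance = 1e-12)
  expect_error(mass_adjust(1, -1, 0.58), "mass")
  expect_error(mass_adjust(1, 3.5, 2), "exponent")
})

test_that("Q10 computation matches closed forms and inverts generation", {
  expect_equal(compute_q10(2, 12, 4, 22), 2)
  expect_equal(compute_q10(2, 12, 3, 18), 1.5^(10 / 6), tolerance = 1e-12)
  expect_equal(compute_q10(2, 12, 3, 18), 1.9656, tolerance = 1e-4)
  expect_equal(compute_q10(2, 12, 5, 22), 2.5) # exponent exactly 1
  expect_error(compute_q10(2, 12, 3, 12), "differ")
  # round trip: rates generated under a known Q10 return it for any temp pair
  set.seed(4)
  for (i in 1:20) {
    q <- runif(1, 1.2, 3); t1 <- runif(1, 5, 15); t2 <- runif(1, 16, 28)
    r1 <- runif(1, 1, 5)
    r2 <- r1 * q^((t2 - t1) / 10)
    expect_equal(compute_q10(r1, t1, r2, t2), q, tolerance = 1e-10)
  }
})

test_that("scaling exponent estimation recovers known allometries", {
  set.seed(5)
  mass <- runif(200, 1.4, 7.2)
  # noiseless power law
  expect_equal(estimate_scaling_exponent(2.1 * mass^0.58, mass)$b, 0.58,
               tolerance = 1e-10)
  # lognormal noise, n = 200
  noisy <- 2.1 * mass^0.58 * rlnorm(200, 0, 0.1)
  expect_equal(estimate_scaling_exponent(noisy, mass)$b, 0.58,
               tolerance = 0.05)
  # two groups, different intercepts, shared slope
  grp <- rep(c("a", "b"), each = 100)
  y <- ifelse(grp == "a", 2.1, 3.4) * mass^0.67
  expect_equal(estimate_scaling_exponent(y, mass, grp)$b, 0.67,
               tolerance = 1e-10)
  expect_error(estimate_scaling_exponent(c(1, 2, 3), rep(2, 3)), "variation")
})

test_that("per-fish summaries recover simulated truth without noise", {
  s <- sim_fish(cycle_count = 66, noise_sd = 0, rmr12 = 2.4, mmr_true = 11,
                epoc_rate_k = 0.05, temperature = 18)
  ms <- metabolic_summary(s$series, NULL, s$trace, survived = TRUE)
  truth_rmr <- s$phenotype$rmr12 * s$phenotype$q10_true^(0.6)
  expect_equal(ms$rmr, truth_rmr, tolerance = 1e-6)
  expect_equal(ms$mmr_1h, s$truth$mo2_true[1L], tolerance = 1e-6)
  expect_equal(ms$mmr_overall, s$truth$mo2_true[1L], tolerance = 1e-6)
  expect_equal(ms$aas, ms$mmr_overall - ms$rmr)
  expect_equal(ms$fas, ms$mmr_overall / ms$rmr)
  # mass 3.5 kg: adjusted values equal unadjusted
  expect_equal(ms$aas_adj, ms$aas, tolerance = 1e-9)
})
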