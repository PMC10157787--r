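test_that("recovery trajectory follows the mono-exponential model with Q10-scaled RMR", {
  ph <- fish_phenotype(rmr12 = 2, q10_true = 2, mmr_true = 10,
                       epoc_rate_k = 0.05)
  # asymptote at the Q10-scaled RMR: doubling over 10 C
  expect_equal(simulate_mo2_trajectory(ph, 22, c(0, 1e6))[2L], 4.0,
               tolerance = 1e-10)
  # boundary: MO2(0) is the instantaneous chase maximum
  expect_equal(simulate_mo2_trajectory(ph, 12, 0), 10.0)
  # closed-form interior point: 2 + 8 exp(-0.693)
  expect_equal(simulate_mo2_trajectory(ph, 12, c(0, 13.86))[2L],
               2 + 8 * exp(-0.05 * 13.86), tolerance = 1e-12)
  expect_equal(simulate_mo2_trajectory(ph, 12, c(0, 13.86))[2L], 6.0,
               tolerance = 1e-3)
  # strictly decreasing without bursts
  tr <- simulate_mo2_trajectory(ph, 18, seq(0, 200, 5))
  expect_true(all(diff(tr) < 0))
  expect_error(simulate_mo2_trajectory(ph, 12, c(0, 10, 10)), "increasing")
  expect_error(simulate_mo2_trajectory(ph, 35, c(0, 1)), "temperature")
})

test_that("noise-free traces encode MO2 exactly as closed-phase slopes", {
  s <- sim_fish(cycle_count = 4, noise_sd = 0, rmr12 = 2, mmr_true = 10,
                epoc_rate_k = 0.05)
  m <- s$phenotype$body_mass
  v_r <- s$config$respirometer_volume
  # within every closed window the slope equals -MO2 m / (v_R - v_F) exactly
  for (i in seq_len(nrow(s$truth))) {
    win <- s$series[i, ]
    sel <- s$trace$time_s >= win$t_start & s$trace$time_s <= win$t_end
    sl <- unname(coef(lm(s$trace$o2[sel] ~ s$trace$time_s[sel]))[2L]) * 60
    expect_equal(sl, -s$truth$mo2_true[i] * m / (v_r - m), tolerance = 1e-9)
  }
  # flush phases rise back toward saturation
  fl <- s$trace[s$trace$phase == "flush", ]
  expect_true(all(diff(fl$o2[fl$time_s < 900]) >= 0))
})

test_that("trace simulation is deterministic given the seed", {
  ph <- fish_phenotype()
  cfg <- sim_config(noise_sd = 0.02, cycle_count = 3)
  a <- simulate_o2_trace(ph, cfg, seed = 42)
  b <- simulate_o2_trace(ph, cfg, seed = 42)
  c <- simulate_o2_trace(ph, cfg, seed = 43)
  expect_identical(a$trace$o2, b$trace$o2)
  expect_false(identical(a$trace$o2, c$trace$o2))
})

test_that("oversized fish are rejected by the trace simulator", {
  ph <- fish_phenotype(body_mass = 3.5)
  cfg <- sim_config(respirometer_volume = 3.0)
  expect_error(simulate_o2_trace(ph, cfg), "too large")
})

test_that("survival simulation follows the log-logistic curve", {
  # definition of M50
  expect_equal(survival_probability(21, 21, 25), 0.5)
  # closed form at m50 = 21, slope 25, T = 24
  expect_equal(survival_probability(24, 21, 25),
               1 / (1 + exp(25 * log(24 / 21))), tolerance = 1e-12)
  expect_equal(survival_probability(24, 21, 25), 0.0343, tolerance = 1e-3)
  # step limit: very steep slope
  expect_gt(survival_probability(20.9, 21, 1e4), 0.999)
  # empirical frequencies at n = 1e4 inside the binomial 99% CI
  temps <- c(12, 18, 21, 24)
  out <- simulate_survival_outcomes(temps, 1e4, m50 = 21, slope = 25,
                                    seed = 11)
  for (tt in temps) {
    p <- survival_probability(tt, 21, 25)
    k <- sum(out$survived[out$temperature == tt])
    ci <- qbinom(c(0.005, 0.995), 1e4, p)
    expect_gte(k, ci[1L])
    expect_lte(k, ci[2L])
  }
  expect_error(simulate_survival_outcomes(21, 0, 21, 25), ">= 1")
})

test_that("cohort simulation is reproducible and respects the study design", {
  cfg <- sim_config(cycle_count = 4, noise_sd = 0.01, n_per_temperature = 2)
  a <- simulate_cohort(cfg, temperatures = c(12, 21), seed = 5)
  b <- simulate_cohort(cfg, temperatures = c(12, 21), seed = 5)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$traces[[1L]]$stage1$o2, b$traces[[1L]]$stage1$o2)
  expect_equal(nrow(a$cohort), 2 * 2 * 2) # pops x temps x n
  # survivors have a second-stage trace and a longer first stage; deaths not
  for (i in seq_len(nrow(a$cohort))) {
    id <- a$cohort$fish_id[i]
    if (a$cohort$survived[i]) {
      expect_named(a$traces[[id]], c("stage1", "stage2"))
    } else {
      expect_named(a$traces[[id]], "stage1")
    }
    expect_true(all(c("rmr_true", "mmr_overall_true", "epoc_true") %in%
                      names(a$truth[[id]])))
  }
  # empty design
  e <- simulate_cohort(cfg, temperatures = c(12, 21), n_per_temperature = 0)
  expect_equal(nrow(e$cohort), 0)
})

test_that("simulated deaths concentrate at temperatures above M50", {
  out <- simulate_survival_outcomes(c(12, 18, 21, 24), 1e4, m50 = 21,
                                    slope = 25, seed = 3)
  died <- tapply(!out$survived, out$temperature, mean)
  expect_lt(died[["12"]], 0.01)
  expect_equal(died[["21"]], 0.5, tolerance = 0.05)
  expect_gt(died[["24"]], 0.9)
})

test_that("cohort files round-trip through delimited text", {
  cfg <- sim_config(cycle_count = 3, noise_sd = 0, n_per_temperature = 1)
  sim <- simulate_cohort(cfg, temperatures = c(12, 18, 21), seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  expect_true(file.exists(file.path(dir, "cohort.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read.delim(file.path(dir, "cohort.tsv"))
  expect_equal(nrow(back), nrow(sim$cohort))
  # a written trace reloads identically through read_trace
  id <- sim$cohort$fish_id[1L]
  tr0 <- sim$traces[[id]]$stage1
  tr1 <- read_trace(file.path(dir, "traces", paste0(id, "_stage1.tsv")),
                    volume_l = attr(tr0, "volume_l"),
                    mass_kg = attr(tr0, "mass_kg"))
  expect_equal(tr1$o2, tr0$o2, tolerance = 1e-12)
  expect_equal(tr1$phase, tr0$phase)
})
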