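test_that("trace I/O round-trips and reports structural errors by row", {
  tr <- o2_trace(time_s = 0:99, o2 = 10 - 0.001 * (0:99), temp_c = 12,
                 phase = rep(c("measure", "flush"), each = 50),
                 volume_l = 98, mass_kg = 3.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read_trace(path, volume_l = 98, mass_kg = 3.5)
  expect_equal(back$time_s, tr$time_s)
  expect_equal(back$o2, tr$o2, tolerance = 1e-12)
  expect_equal(back$phase, tr$phase)

  # non-monotone time names the offending row
  t_bad <- 0:99; t_bad[57] <- t_bad[55]
  expect_error(o2_trace(t_bad, 10 - 0.001 * (0:99), 12, volume_l = 98,
                        mass_kg = 3.5), "row 57")
  # missing column
  writeLines("a\tb\n1\t2", path)
  expect_error(read_trace(path, volume_l = 98, mass_kg = 3.5),
               "missing column")
  # v_R must exceed v_F
  expect_error(o2_trace(0:9, rep(10, 10), 12, volume_l = 3, mass_kg = 3.5),
               "too large")
})

test_that("schedule segmentation produces the arithmetic window count", {
  t <- seq(0, 3600, by = 5)
  tr <- o2_trace(t, rep(10, length(t)), 12, volume_l = 98, mass_kg = 3.5)
  # 60 min, 9 min flush + 6 min measure, flush first: 4 closed windows
  win <- segment_cycles(tr, flush_min = 9, measure_min = 6,
                        first_phase = "flush")
  expect_equal(nrow(win), 4L)
  expect_equal(win$t_start, c(540, 1440, 2340, 3240))
  expect_equal(win$t_end[1:3], c(900, 1800, 2700))
  # trace shorter than one cycle: truncation policy drops short windows
  t2 <- seq(0, 120, by = 5)
  tr2 <- o2_trace(t2, rep(10, length(t2)), 12, volume_l = 98, mass_kg = 3.5)
  expect_error(segment_cycles(tr2, flush_min = 9, measure_min = 6,
                              first_phase = "flush"), "no usable")
  # but a measure-first trace covering 60% of the nominal window is kept
  t3 <- seq(0, 240, by = 5)
  tr3 <- o2_trace(t3, rep(10, length(t3)), 12, volume_l = 98, mass_kg = 3.5)
  win3 <- segment_cycles(tr3, flush_min = 9, measure_min = 6,
                         first_phase = "measure")
  expect_equal(nrow(win3), 1L)
  expect_equal(win3$t_end, 240)
})

test_that("auto-detection finds sealed windows from the O2 pattern alone", {
  s <- sim_fish(cycle_count = 5, noise_sd = 0)
  unlabelled <- s$trace
  unlabelled$phase <- NULL
  win <- segment_cycles(unlabelled, auto = TRUE)
  expect_gte(nrow(win), 5L)
  # every true sealed window overlaps a detected one
  truth <- segment_cycles(s$trace)
  for (i in seq_len(nrow(truth))) {
    expect_true(any(win$t_start <= truth$t_end[i] &
                      win$t_end >= truth$t_start[i]))
  }
  flat <- o2_trace(0:199, rep(10, 200), 12, volume_l = 98, mass_kg = 3.5)
  expect_error(segment_cycles(flat, auto = TRUE), "no measurement cycles")
})

test_that("phase labels dominate any schedule", {
  t <- seq(0, 1799, by = 1)
  phase <- ifelse(t %% 600 < 360, "measure", "flush")
  tr <- o2_trace(t, rep(10, length(t)), 12, phase = phase, volume_l = 98,
                 mass_kg = 3.5)
  win <- segment_cycles(tr, flush_min = 9, measure_min = 6)
  expect_equal(nrow(win), 3L)
  expect_equal(win$t_start, c(0, 600, 1200))
  expect_equal(win$t_end, c(359, 959, 1559))
})

test_that("slope fitting matches exact lines and flags pathologies", {
  t <- seq(0, 300, by = 5)
  f <- fit_slope(t, 10 - 0.001 * t)
  expect_equal(f$slope, -0.06, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_true(f$negative && f$linear && f$artifact_free)

  # constant O2: zero slope, flagged non-negative
  f0 <- fit_slope(t, rep(8, length(t)))
  expect_equal(f0$slope, 0)
  expect_false(f0$negative)

  # line + single 0.5 mg/L spike: artifact flag set
  o2 <- 10 - 0.001 * t
  o2[30] <- o2[30] + 0.5
  fs <- fit_slope(t, o2)
  expect_false(fs$artifact_free)

  # too few points: invalid, not an error
  f4 <- fit_slope(t[1:4], o2[1:4])
  expect_false(f4$valid)
  expect_true(is.na(f4$slope))
})

test_that("MO2 conversion implements |slope| (vR - vF) / m", {
  expect_equal(compute_mo2(-0.12, 54.5, 2.5, 2.5), 0.12 * 52 / 2.5)
  expect_equal(compute_mo2(-0.12, 54.5, 2.5, 2.5), 2.496)
  expect_equal(compute_mo2(0, 98, 3.5, 3.5), 0)
  # inverse of the simulator example: slope 0.1111 in a 98 L chamber
  expect_equal(compute_mo2(-3.0 * 3.5 / 94.5, 98, 3.5, 3.5), 3.0,
               tolerance = 1e-12)
  # increasing O2 has no metabolic meaning
  expect_true(is.na(compute_mo2(0.05, 98, 3.5, 3.5)))
  expect_error(compute_mo2(-0.1, 3, 3.5, 3.5), "exceed")
})

test_that("MO2 conversion is linear in |slope| and volume, inverse in mass", {
  set.seed(42)
  for (i in 1:25) {
    sl <- -runif(1, 0.01, 0.5); vr <- runif(1, 40, 120)
    vf <- runif(1, 1, 8); m <- vf
    base <- compute_mo2(sl, vr, vf, m)
    expect_equal(compute_mo2(3 * sl, vr, vf, m), 3 * base, tolerance = 1e-12)
    expect_equal(compute_mo2(sl, vr + (vr - vf), vf, m), 2 * base,
                 tolerance = 1e-12)
    expect_equal(compute_mo2(sl, vr, vf, 2 * m), base / 2 * 1, # v_F fixed
                 tolerance = 1e-12)
  }
})

test_that("background correction is off by default and clips at zero", {
  s <- make_series(seq(5, 50, 5), rep(3, 10))
  id <- correct_background(s, 0, 0, 98, 3.5, 3.5)
  expect_equal(id$mo2, s$mo2)
  expect_false(any(id$background_clipped))
  # constant background b reduces every MO2 by b (vR - vF) / m
  adj <- correct_background(s, 0.01, 0.01, 98, 3.5, 3.5)
  expect_equal(adj$mo2, s$mo2 - 0.01 * 94.5 / 3.5, tolerance = 1e-12)
  # background exceeding MO2 clips to zero with a flag
  expect_warning(
    big <- correct_background(s, 0.2, 0.2, 98, 3.5, 3.5), "clipped")
  expect_true(all(big$mo2 == 0))
  expect_true(all(big$background_clipped))
})

test_that("full processing of noise-free simulator output recovers truth", {
  s <- sim_fish(cycle_count = 5, noise_sd = 0, rmr12 = 2.2, mmr_true = 12,
                epoc_rate_k = 0.06, temperature = 18)
  expect_equal(nrow(s$series), nrow(s$truth))
  expect_true(all(abs(s$series$mo2 / s$truth$mo2_true - 1) <= 1e-6))
  expect_true(all(s$series$validated))
})

test_that("raising the r-squared threshold never validates more cycles", {
  s <- sim_fish(cycle_count = 8, noise_sd = 0.05, seed = 9)
  counts <- vapply(c(0.5, 0.7, 0.85, 0.95, 0.99), function(r2) {
    sum(process_trace(s$trace, r2_min = r2)$validated)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
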