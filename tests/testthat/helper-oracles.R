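# Independent oracles and fixture builders used across the suite.

# Brute-force sliding-window MMR: direct per-window lm over every (start, end)
# pair with span >= min_window_s and >= 5 points. Deliberately naive.
brute_force_mmr <- function(time_s, o2, volume_l, fish_volume_l, mass_kg,
                            min_window_s = 90, r2_min = 0.9) {
  best <- -Inf
  n <- length(time_s)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i + 1 < 5 || time_s[j] - time_s[i] < min_window_s) next
      ft <- stats::lm(o2[i:j] ~ time_s[i:j])
      sl <- unname(stats::coef(ft)[2L])
      r2 <- suppressWarnings(summary(ft)$r.squared)
      if (!is.na(sl) && sl < 0 && r2 > r2_min && abs(sl) > best) best <- abs(sl)
    }
  }
  if (!is.finite(best)) return(NA_real_)
  abs(best) * 60 * (volume_l - fish_volume_l) / mass_kg
}

# Grid-search MLE for the two-parameter log-logistic survival curve:
# coarse grid over (m50, b), then a 0.01-step local refinement.
grid_mle_survival <- function(deaths, n, temperature,
                              m50_range = c(10, 30), b_range = c(0.1, 100)) {
  ll <- function(m50, b) {
    p <- 1 / (1 + exp(b * (log(temperature) - log(m50))))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum((n - deaths) * log(p) + deaths * log(1 - p))
  }
  eval_grid <- function(m50s, bs) {
    best <- c(-Inf, NA, NA)
    for (m in m50s) for (b in bs) {
      v <- ll(m, b)
      if (v > best[1L]) best <- c(v, m, b)
    }
    best
  }
  coarse <- eval_grid(seq(m50_range[1L], m50_range[2L], by = 0.05),
                      exp(seq(log(b_range[1L]), log(b_range[2L]),
                              length.out = 120)))
  m0 <- coarse[2L]; b0 <- coarse[3L]
  fine <- eval_grid(seq(max(m50_range[1L], m0 - 0.1),
                        min(m50_range[2L], m0 + 0.1), by = 0.01),
                    b0 * exp(seq(-0.3, 0.3, length.out = 121)))
  list(m50 = fine[2L], b = fine[3L], loglik = fine[1L])
}

# A processed-series-shaped data frame from raw (t, mo2) values, as if every
# cycle had validated.
make_series <- function(t_mid_min, mo2, validated = TRUE) {
  data.frame(cycle = seq_along(t_mid_min) - 1L, t_mid_min = t_mid_min,
             mo2 = mo2, r_squared = 1, validated = validated)
}

# Small noise-free simulated fish + processed series for round-trip tests.
sim_fish <- function(cycle_count = 6, noise_sd = 0, temperature = 12,
                     seed = 1, ...) {
  ph <- fish_phenotype(...)
  cfg <- sim_config(noise_sd = noise_sd, cycle_count = cycle_count,
                    test_temperature = temperature, seed = seed)
  s <- simulate_o2_trace(ph, cfg, seed = seed)
  s$series <- process_trace(s$trace)
  s$phenotype <- ph
  s$config <- cfg
  s
}
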