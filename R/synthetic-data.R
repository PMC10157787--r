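#' Fish phenotype ground truth for simulation
#'
#' Holds the generative ("true") physiology of one simulated fish: resting
#' metabolic rate at the 12 deg C acclimation temperature (`rmr12`), its
#' thermal sensitivity (`q10_true`), the instantaneous maximum metabolic rate
#' reached at the end of an exhaustive chase (`mmr_true`), the mono-exponential
#' recovery rate constant (`epoc_rate_k`), and the per-cycle probability of a
#' spontaneous-activity burst during overnight recovery (`burst_prob`).
#'
#' @param fish_id Identifier.
#' @param population Population label.
#' @param sex `"M"` or `"F"`.
#' @param body_mass Body mass in kg.
#' @param fork_length Fork length in mm.
#' @param rmr12 True RMR at 12 deg C, mg O2 kg^-1 min^-1.
#' @param q10_true Q10 governing RMR(T) = rmr12 * q10^((T - 12)/10).
#' @param mmr_true Instantaneous post-chase maximum MO2, mg O2 kg^-1 min^-1.
#' @param epoc_rate_k Recovery rate constant, min^-1.
#' @param burst_prob Per-cycle probability of a spontaneous burst in [0, 1].
#' @param organ_masses Named numeric (g): `gonads`, `ventricle`, `spleen`,
#'   `liver`.
#' @param hematocrit Hematocrit, %.
#' @return A list of class `fish_phenotype`.
#' @export
fish_phenotype <- function(fish_id = "fish", population = "pop", sex = "M",
                           body_mass = 3.5, fork_length = 650,
                           rmr12 = 2.4, q10_true = 1.7, mmr_true = 11,
                           epoc_rate_k = 0.05, burst_prob = 0,
                           organ_masses = c(gonads = 245, ventricle = 7,
                                            spleen = 6.5, liver = 58),
                           hematocrit = 55) {
  assert_scalar_num(body_mass, "body_mass", positive = TRUE)
  assert_scalar_num(rmr12, "rmr12", positive = TRUE)
  assert_scalar_num(q10_true, "q10_true", positive = TRUE)
  assert_scalar_num(mmr_true, "mmr_true", positive = TRUE)
  if (mmr_true <= rmr12) stop_input("mmr_true must exceed rmr12")
  assert_scalar_num(epoc_rate_k, "epoc_rate_k", positive = TRUE)
  if (burst_prob < 0 || burst_prob > 1) stop_input("burst_prob must lie in [0, 1]")
  structure(list(fish_id = fish_id, population = population, sex = sex,
                 body_mass = body_mass, fork_length = fork_length,
                 rmr12 = rmr12, q10_true = q10_true, mmr_true = mmr_true,
                 epoc_rate_k = epoc_rate_k, burst_prob = burst_prob,
                 organ_masses = organ_masses, hematocrit = hematocrit),
            class = "fish_phenotype")
}

#' Simulation configuration
#'
#' Protocol and instrument parameters for the trace simulator, mirroring a
#' typical large-salmonid intermittent-flow setup: a 54.5 or 98 L chamber and
#' 10- or 15-min cycles made of a 6-9 min flush and a 4-6 min closed
#' measurement phase, with the first post-chase window closed immediately.
#'
#' @param respirometer_volume Chamber volume, L.
#' @param flush_minutes Flush phase length, min.
#' @param measure_minutes Closed measurement phase length, min.
#' @param cycle_count Number of flush+measure cycles after cycle 0.
#' @param test_temperature Test temperature, deg C.
#' @param noise_sd SD of i.i.d. Gaussian probe noise on O2 readings, mg L^-1.
#' @param drift Optional linear probe drift, mg L^-1 per hour (default 0).
#' @param background_rate Microbial depletion rate, mg O2 L^-1 min^-1.
#' @param o2_saturation Saturation O2, mg L^-1; `NULL` computes a freshwater
#'   value from the test temperature.
#' @param sample_interval_s Logger sampling interval, s.
#' @param seed Integer seed; fixes all randomness downstream.
#' @param survival_m50 Temperature of 50 % predicted mortality, deg C.
#' @param survival_slope Log-logistic slope (dimensionless).
#' @param n_per_temperature Fish per temperature group.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(respirometer_volume = 98, flush_minutes = 9,
                       measure_minutes = 6, cycle_count = 68,
                       test_temperature = 12, noise_sd = 0.02, drift = 0,
                       background_rate = 0, o2_saturation = NULL,
                       sample_interval_s = 5, seed = 1,
                       survival_m50 = 21, survival_slope = 25,
                       n_per_temperature = 10) {
  assert_scalar_num(respirometer_volume, "respirometer_volume", positive = TRUE)
  assert_scalar_num(flush_minutes, "flush_minutes", positive = TRUE)
  assert_scalar_num(measure_minutes, "measure_minutes", positive = TRUE)
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  if (is.null(o2_saturation)) o2_saturation <- o2_saturation_mgl(test_temperature)
  structure(list(respirometer_volume = respirometer_volume,
                 flush_minutes = flush_minutes,
                 measure_minutes = measure_minutes,
                 cycle_count = cycle_count,
                 test_temperature = test_temperature,
                 noise_sd = noise_sd, drift = drift,
                 background_rate = background_rate,
                 o2_saturation = o2_saturation,
                 sample_interval_s = sample_interval_s, seed = seed,
                 survival_m50 = survival_m50,
                 survival_slope = survival_slope,
                 n_per_temperature = n_per_temperature),
            class = "sim_config")
}

#' Freshwater oxygen saturation
#'
#' Benson-Krause fit for air-saturated fresh water at standard pressure; used
#' only to give the simulator a realistic flush ceiling.
#'
#' @param temp_c Temperature, deg C.
#' @return Saturation concentration, mg O2 L^-1.
#' @export
o2_saturation_mgl <- function(temp_c) {
  tk <- temp_c + 273.15
  exp(-139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
        1.2438e10 / tk^3 - 8.621949e11 / tk^4)
}

#' True post-chase MO2 trajectory
#'
#' The generative recovery model: MO2(t) = RMR(T) + (MMR - RMR(T)) *
#' exp(-k t), with RMR(T) = rmr12 * q10^((T - 12)/10). Mono-exponential decay
#' is the simplest kinetic model with a closed-form oxygen debt,
#' EPOC = (MMR - RMR)/k, which anchors the integration tests downstream.
#' Optional rectangular burst excursions (spontaneous activity) may be
#' superimposed.
#'
#' @param phenotype A [fish_phenotype()].
#' @param temperature Test temperature, deg C (0-30).
#' @param t_grid Times in minutes since the chase, increasing.
#' @param bursts Optional data frame with columns `start`, `duration`
#'   (minutes) and `mo2` (absolute level during the excursion).
#' @return Numeric vector of true MO2 (mg O2 kg^-1 min^-1) on `t_grid`.
#' @export
simulate_mo2_trajectory <- function(phenotype, temperature, t_grid,
                                    bursts = NULL) {
  if (any(diff(t_grid) <= 0)) stop_input("t_grid must be strictly increasing")
  if (temperature < 0 || temperature > 30) {
    stop_input("temperature outside the supported range [0, 30]")
  }
  rmr_t <- phenotype$rmr12 * phenotype$q10_true^((temperature - 12) / 10)
  mo2 <- rmr_t + (phenotype$mmr_true - rmr_t) * exp(-phenotype$epoc_rate_k * t_grid)
  if (!is.null(bursts) && nrow(bursts)) {
    for (i in seq_len(nrow(bursts))) {
      sel <- t_grid >= bursts$start[i] &
        t_grid < bursts$start[i] + bursts$duration[i]
      mo2[sel] <- pmax(mo2[sel], bursts$mo2[i])
    }
  }
  mo2
}

# closed/flush phase schedule for one recording; cycle 0 is closed at t = 0
cycle_schedule <- function(config) {
  meas_s <- config$measure_minutes * 60
  flush_s <- config$flush_minutes * 60
  period <- meas_s + flush_s
  starts <- c(0, meas_s + flush_s + (seq_len(config$cycle_count) - 1L) * period)
  data.frame(cycle = seq_along(starts) - 1L, t_start = starts,
             t_end = starts + meas_s)
}

#' Simulate a raw oxygen trace from a true MO2 trajectory
#'
#' Inverts the MO2 equation: during closed phases dO2/dt =
#' -(MO2 * m)/(v_R - v_F) - background, with i.i.d. Gaussian probe noise
#' (and optional linear drift) added to the readings; during flush phases O2
#' relaxes exponentially toward saturation. Within each closed window the
#' generative MO2 is held at the trajectory's value at the window midpoint,
#' so a noise-free trace is exactly linear within the window and the slope
#' equals -MO2 * m / (v_R - v_F) exactly; the per-cycle values are returned
#' as the ground-truth ledger.
#'
#' @param phenotype A [fish_phenotype()].
#' @param config A [sim_config()].
#' @param bursts Optional burst table, as in [simulate_mo2_trajectory()].
#' @param seed Optional integer; defaults to `config$seed`. The same seed,
#'   phenotype and config yield an identical trace.
#' @param stage Label stored on the result (`"post-MMR1h"` etc.).
#' @return A list with `trace` (an [o2_trace()] with phase labels) and
#'   `truth` (data frame `cycle`, `t_mid_min`, `mo2_true`).
#' @export
simulate_o2_trace <- function(phenotype, config, bursts = NULL, seed = NULL,
                              stage = "post-MMR1h") {
  m <- phenotype$body_mass
  v_r <- config$respirometer_volume
  v_f <- m # 1 kg displaces 1 L
  if (v_r / m < 1) stop_input("fish too large for chamber")
  if (v_r <= v_f) stop_input("fish too large for chamber")
  sched <- cycle_schedule(config)
  t_mid_min <- (sched$t_start + sched$t_end) / 2 / 60
  mo2_cycle <- simulate_mo2_trajectory(phenotype, config$test_temperature,
                                       t_mid_min, bursts = bursts)
  truth <- data.frame(cycle = sched$cycle, t_mid_min = t_mid_min,
                      mo2_true = mo2_cycle)

  dt <- config$sample_interval_s
  t_total <- sched$t_end[nrow(sched)]
  time_s <- seq(0, t_total, by = dt)
  phase <- rep("flush", length(time_s))
  o2 <- numeric(length(time_s))
  sat <- config$o2_saturation
  tau_flush <- 60 # s; flush pump restores the chamber quickly
  rates <- mo2_cycle * m / (v_r - v_f) + config$background_rate # mg/L per min
  n_cyc <- nrow(sched)
  o2_start <- sat # chamber sealed at saturation at t = 0
  for (cyc in seq_len(n_cyc)) {
    t0 <- sched$t_start[cyc]; t1 <- sched$t_end[cyc]
    sel <- time_s >= t0 & time_s <= t1
    phase[sel] <- "measure"
    o2[sel] <- o2_start - rates[cyc] * (time_s[sel] - t0) / 60
    o2_end <- o2_start - rates[cyc] * (t1 - t0) / 60
    # flush phase between this window and the next (or trailing samples)
    t_next <- if (cyc < n_cyc) sched$t_start[cyc + 1L] else Inf
    fsel <- time_s > t1 & time_s < t_next
    o2[fsel] <- sat + (o2_end - sat) * exp(-(time_s[fsel] - t1) / tau_flush)
    o2_start <- sat + (o2_end - sat) * exp(-(t_next - t1) / tau_flush)
  }
  o2 <- pmax(o2, 0)
  seed <- seed %||% config$seed
  if (config$noise_sd > 0 || config$drift != 0) {
    noise <- withr::with_seed(seed, stats::rnorm(length(o2), 0, config$noise_sd))
    o2 <- pmax(o2 + noise + config$drift * time_s / 3600, 0)
  }
  trace <- o2_trace(time_s = time_s, o2 = o2,
                    temp_c = config$test_temperature, phase = phase,
                    fish_id = phenotype$fish_id, volume_l = v_r,
                    mass_kg = m, fish_volume_l = v_f)
  attr(trace, "stage") <- stage
  list(trace = trace, truth = truth)
}

#' Log-logistic survival probability
#'
#' P(survive | T) = 1 / (1 + exp(b * (ln T - ln M50))): the two-parameter
#' log-logistic dose-response curve with temperature as the dose. At T = M50
#' the survival probability is exactly 0.5.
#'
#' @param temperature Temperature(s), deg C.
#' @param m50 Temperature of 50 % predicted mortality, deg C (> 0).
#' @param slope Slope parameter b (> 0 for survival decreasing in T).
#' @return Survival probabilities.
#' @export
survival_probability <- function(temperature, m50, slope) {
  assert_scalar_num(m50, "m50", positive = TRUE)
  1 / (1 + exp(slope * (log(temperature) - log(m50))))
}

#' Simulate per-fish survival outcomes
#'
#' Bernoulli draws from the log-logistic survival curve, seed-reproducible.
#'
#' @param temperatures Temperature of each group, deg C.
#' @param n_per_temperature Group size(s); recycled against `temperatures`.
#' @param m50,slope Curve parameters, as in [survival_probability()].
#' @param seed Integer seed.
#' @return Data frame `temperature`, `survived` (logical), one row per fish.
#' @export
simulate_survival_outcomes <- function(temperatures, n_per_temperature, m50,
                                       slope, seed = 1) {
  if (any(n_per_temperature < 1)) stop_input("n_per_temperature must be >= 1")
  n <- rep(n_per_temperature, length.out = length(temperatures))
  temp <- rep(temperatures, times = n)
  p <- survival_probability(temp, m50, slope)
  survived <- withr::with_seed(seed, stats::runif(length(temp)) < p)
  data.frame(temperature = temp, survived = survived)
}

# draw one phenotype; study-condition defaults are documented in the vignette
draw_phenotype <- function(id, population, m50_unused = NULL) {
  mass <- min(max(stats::rlnorm(1, log(3.4), 0.22), 1.4), 7.2)
  sex <- sample(c("M", "F"), 1, prob = c(0.8, 0.2))
  rmr12 <- 2.4 * (mass / 3.5)^(-0.33) * stats::rlnorm(1, 0, 0.10)
  mmr <- 11.3 * (mass / 3.5)^(-0.42) * stats::rlnorm(1, 0, 0.12)
  mmr <- max(mmr, 1.5 * rmr12)
  gsi_pct <- if (sex == "F") stats::rnorm(1, 21, 2) else stats::rnorm(1, 6.5, 1)
  hct <- if (stats::runif(1) < 0.04) stats::runif(1, 10, 19) else
    stats::rnorm(1, 57, 7)
  fish_phenotype(
    fish_id = id, population = population, sex = sex, body_mass = mass,
    fork_length = 650 * (mass / 3.5)^(1 / 3) * stats::rlnorm(1, 0, 0.03),
    rmr12 = rmr12, q10_true = max(stats::rnorm(1, 1.7, 0.15), 1.05),
    mmr_true = mmr, epoc_rate_k = stats::rlnorm(1, log(0.045), 0.2),
    burst_prob = 0.08,
    organ_masses = c(
      gonads = max(gsi_pct, 0.5) / 100 * mass * 1000,
      ventricle = max(stats::rnorm(1, 0.19, 0.02), 0.05) / 100 * mass * 1000,
      spleen = max(stats::rnorm(1, 0.18, 0.04), 0.02) / 100 * mass * 1000,
      liver = max(stats::rnorm(1, 1.65, 0.3), 0.3) / 100 * mass * 1000),
    hematocrit = hct)
}

#' Simulate a full study cohort
#'
#' Emulates the study design the pipeline targets: two populations, each
#' acclimated to 12 deg C and acutely tested at 12, 18, 21 and 24 deg C, with
#' per-fish post-chase recovery traces recorded overnight (first chase) and
#' for a short second recording after an 18 h exposure (second chase).
#' Mortality is drawn from a population-specific log-logistic survival curve;
#' fish that die do so during recovery from the first chase, so they
#' contribute a truncated first-stage trace and no second-stage trace.
#' Spontaneous overnight bursts (rectangular excursions above the recovery
#' curve) occur per cycle with the phenotype's `burst_prob`, so the overall
#' maximum MO2 may exceed the chase value, as in real recordings.
#'
#' @param config A [sim_config()]; `test_temperature` is ignored in favour of
#'   `temperatures`.
#' @param populations Named list mapping population label to a list with
#'   elements `m50` and `slope` for its survival curve.
#' @param temperatures Test temperatures, deg C.
#' @param n_per_temperature Fish per population x temperature group.
#' @param seed Integer seed fixing phenotypes, survival and noise.
#' @param stage2_cycles Number of cycles in the second-stage recording.
#' @return A list of class `cohort_sim` with `cohort` (per-fish table),
#'   `traces` (named list; per fish a list of `stage1`/`stage2` trace
#'   objects) and `truth` (ground-truth ledger: per-fish true RMR at test
#'   temperature, true chase-cycle MO2, true overall maximum, closed-form
#'   EPOC, and the per-cycle MO2 truth tables).
#' @export
simulate_cohort <- function(config = sim_config(),
                            populations = list(
                              coastal = list(m50 = 21, slope = 25),
                              interior = list(m50 = 23.6, slope = 25)),
                            temperatures = c(12, 18, 21, 24),
                            n_per_temperature = config$n_per_temperature,
                            seed = config$seed,
                            stage2_cycles = 4) {
  if (!length(temperatures)) stop_input("at least one temperature group required")
  n_rep <- rep(n_per_temperature, length.out = length(temperatures))
  if (all(n_rep == 0)) {
    return(structure(list(cohort = data.frame(), traces = list(),
                          truth = list()), class = "cohort_sim"))
  }
  withr::with_seed(seed, {
    cohort <- list(); traces <- list(); truth <- list()
    fish_no <- 0L
    for (pop in names(populations)) {
      pp <- populations[[pop]]
      for (ti in seq_along(temperatures)) {
        tt <- temperatures[ti]
        for (j in seq_len(n_rep[ti])) {
          fish_no <- fish_no + 1L
          id <- sprintf("%s_%02.0f_%03d", pop, tt, fish_no)
          ph <- draw_phenotype(id, pop)
          p_surv <- survival_probability(tt, pp$m50, pp$slope)
          survived <- stats::runif(1) < p_surv
          rmr_t <- ph$rmr12 * ph$q10_true^((tt - 12) / 10)
          cfg1 <- config
          cfg1$test_temperature <- tt
          cfg1$cycle_count <- if (survived) config$cycle_count else
            min(3L, config$cycle_count)
          # overnight bursts: per-cycle coin flips, late in recovery only
          sched <- cycle_schedule(cfg1)
          t_mid <- (sched$t_start + sched$t_end) / 2 / 60
          burstable <- which(t_mid > 60)
          hit <- burstable[stats::runif(length(burstable)) < ph$burst_prob]
          bursts <- if (length(hit)) data.frame(
            start = sched$t_start[hit] / 60,
            duration = (sched$t_end[hit] - sched$t_start[hit]) / 60,
            mo2 = rmr_t + stats::runif(length(hit), 0.7, 1.15) *
              (ph$mmr_true - rmr_t)) else NULL
          s1_seed <- sample.int(.Machine$integer.max, 1)
          s1 <- simulate_o2_trace(ph, cfg1, bursts = bursts, seed = s1_seed,
                                  stage = "post-MMR1h")
          fish_traces <- list(stage1 = s1$trace)
          truth_cycles <- list(stage1 = s1$truth)
          mmr18_true <- NA_real_
          if (survived) {
            cfg2 <- cfg1
            cfg2$cycle_count <- stage2_cycles
            s2_seed <- sample.int(.Machine$integer.max, 1)
            s2 <- simulate_o2_trace(ph, cfg2, seed = s2_seed,
                                    stage = "post-MMR18h")
            fish_traces$stage2 <- s2$trace
            truth_cycles$stage2 <- s2$truth
            mmr18_true <- s2$truth$mo2_true[1L]
          }
          mmr1_true <- s1$truth$mo2_true[1L]
          mmr_overall_true <- max(c(s1$truth$mo2_true,
                                    truth_cycles$stage2$mo2_true))
          cohort[[length(cohort) + 1L]] <- data.frame(
            fish_id = id, population = pop, sex = ph$sex,
            body_mass = ph$body_mass, fork_length = ph$fork_length,
            test_temperature = tt, survived = survived,
            gonads_g = unname(ph$organ_masses["gonads"]),
            ventricle_g = unname(ph$organ_masses["ventricle"]),
            spleen_g = unname(ph$organ_masses["spleen"]),
            liver_g = unname(ph$organ_masses["liver"]),
            hematocrit = ph$hematocrit)
          traces[[id]] <- fish_traces
          truth[[id]] <- list(
            rmr_true = rmr_t, mmr_instant_true = ph$mmr_true,
            mmr1h_true = mmr1_true, mmr18h_true = mmr18_true,
            mmr_overall_true = mmr_overall_true,
            epoc_true = (ph$mmr_true - rmr_t) / ph$epoc_rate_k,
            k_true = ph$epoc_rate_k, q10_true = ph$q10_true,
            cycles = truth_cycles, phenotype = ph)
        }
      }
    }
    structure(list(cohort = do.call(rbind, cohort), traces = traces,
                   truth = truth), class = "cohort_sim")
  })
}

#' Write a simulated cohort to delimited text files
#'
#' Emits one trace file per fish and stage (tab-separated, the canonical
#' [write_trace()] dialect), the cohort table, and the ground-truth ledger as
#' JSON, so a simulated study can be re-analyzed from files alone.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sim$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tr_dir <- file.path(dir, "traces")
  dir.create(tr_dir, showWarnings = FALSE)
  for (id in names(sim$traces)) {
    for (stg in names(sim$traces[[id]])) {
      write_trace(sim$traces[[id]][[stg]],
                  file.path(tr_dir, sprintf("%s_%s.tsv", id, stg)))
    }
  }
  truth_flat <- lapply(sim$truth, function(x) {
    x$phenotype <- NULL
    x$cycles <- lapply(x$cycles, function(d) as.list(d))
    x
  })
  jsonlite::write_json(truth_flat, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
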