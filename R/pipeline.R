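#' Default run configuration
#'
#' All analysis thresholds with their standard values: sliding-window minimum
#' 90 s with r-squared > 0.9 for chase MMR, r-squared >= 0.85 validation and
#' the 0.10 quantile for RMR, 60-measurement eligibility, the 48-52 percent
#' band for half-recovery time, the 80 percent pejus threshold, scaling
#' exponents 0.67 (RMR) / 0.58 (MMR) with a 3.5 kg reference mass.
#'
#' @param ... Overrides for any configuration entry.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1,
    output_dir = NULL,
    # analysis thresholds
    mmr_r2_min = 0.9, rmr_r2_min = 0.85, rmr_quantile = 0.10,
    min_measurements = 60, min_window_s = 90,
    recovery_band = c(0.48, 0.52), pejus_threshold = 0.80,
    exponent_rmr = 0.67, exponent_mmr = 0.58, reference_mass = 3.5,
    hematocrit_min = 20, epoc_horizon_min = 1080, tpc_n_boot = 200,
    # simulation block (used when no input paths are given)
    simulate = list(temperatures = c(12, 18, 21, 24), n_per_temperature = 6,
                    cycle_count = 68,
                    populations = list(coastal = list(m50 = 21, slope = 25),
                                       interior = list(m50 = 23.6, slope = 25))),
    input_dir = NULL, log_level = "info")
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys mirror [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> trace processing -> per-fish metabolic
#' summaries -> recovery and EPOC -> per-population thermal performance
#' curves -> survival fits, writing delimited tables and a JSON run summary
#' to `cfg$output_dir` when set. The run is deterministic given the
#' configuration and seed. Exclusion accounting conserves fish: every fish in
#' the input cohort is either analyzed or counted under an exclusion reason.
#'
#' @param cfg A [run_config()].
#' @param sim Optionally a pre-built `cohort_sim` (for example from
#'   [simulate_cohort()]); otherwise one is simulated from `cfg$simulate`.
#' @return List of class `pipeline_result` with elements `cohort`,
#'   `summaries`, `group_summaries`, `recovery`, `epoc`, `tpc`, `survival`,
#'   `morphometrics`, `exclusions` and `summary` (the machine-readable run
#'   record).
#' @export
run_pipeline <- function(cfg = run_config(), sim = NULL) {
  if (is.null(sim)) {
    sc <- sim_config(seed = cfg$seed,
                     cycle_count = cfg$simulate$cycle_count %||% 68,
                     n_per_temperature = cfg$simulate$n_per_temperature)
    log_msg(cfg, "simulating cohort (seed ", cfg$seed, ")")
    sim <- simulate_cohort(sc, populations = cfg$simulate$populations,
                           temperatures = cfg$simulate$temperatures,
                           seed = cfg$seed)
  }
  cohort <- sim$cohort
  if (!nrow(cohort)) {
    res <- structure(list(cohort = cohort, summaries = NULL,
                          summary = list(n_input = 0L,
                                         note = "no eligible fish")),
                     class = "pipeline_result")
    log_msg(cfg, "no eligible fish; nothing to analyze")
    return(res)
  }
  morpho <- cbind(cohort["fish_id"],
                  organ_indices(cohort$gonads_g, cohort$ventricle_g,
                                cohort$spleen_g, cohort$liver_g,
                                cohort$body_mass, cohort$hematocrit,
                                hematocrit_min = cfg$hematocrit_min))
  excl <- list(hematocrit = sum(!morpho$eligible))
  eligible <- cohort[morpho$eligible, ]
  log_msg(cfg, nrow(cohort), " fish in cohort; ", excl$hematocrit,
          " excluded for low hematocrit")

  summaries <- list(); recovery <- list(); epoc_tab <- list()
  for (i in seq_len(nrow(eligible))) {
    id <- eligible$fish_id[i]
    tr <- sim$traces[[id]]
    s1 <- process_trace(tr$stage1, r2_min = cfg$rmr_r2_min)
    s2 <- if (!is.null(tr$stage2)) process_trace(tr$stage2,
                                                 r2_min = cfg$rmr_r2_min)
    ms <- metabolic_summary(
      s1, s2, tr$stage1, tr$stage2, survived = eligible$survived[i],
      rmr_r2_min = cfg$rmr_r2_min, mmr_r2_min = cfg$mmr_r2_min,
      min_measurements = cfg$min_measurements,
      exponents = c(rmr = cfg$exponent_rmr, mmr = cfg$exponent_mmr),
      reference_mass = cfg$reference_mass)
    ms <- cbind(data.frame(fish_id = id, population = eligible$population[i],
                           test_temperature = eligible$test_temperature[i],
                           body_mass = eligible$body_mass[i]), ms)
    summaries[[id]] <- ms
    if (!is.na(ms$aas) && ms$aas > 0 && !is.na(ms$mmr_1h)) {
      rt <- recovery_timecourse(s1, ms$rmr, ms$aas, ms$mmr_1h, ms$mmr_overall)
      if (is.data.frame(rt)) {
        recovery[[id]] <- cbind(data.frame(fish_id = id, stage = "MMR_1h"), rt)
      }
      r50 <- rec_mmr50(s1, ms$mmr_1h, band = cfg$recovery_band)
      ep <- compute_epoc(s1, ms$rmr, horizon_min = cfg$epoc_horizon_min,
                         min_measurements = cfg$min_measurements)
      if (is.list(ep)) {
        epoc_tab[[id]] <- data.frame(
          fish_id = id, rec_mmr50_min = as.numeric(r50),
          epoc_cumulative = ep$epoc_cumulative,
          epoc_h1 = ep$epoc_hourly[1L], epoc_h2 = ep$epoc_hourly[2L],
          epoc_h3 = ep$epoc_hourly[3L], epoc_h4 = ep$epoc_hourly[4L],
          epoc_h5 = ep$epoc_hourly[5L], epoc_complete = ep$epoc_complete)
      }
    }
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  excl$no_rmr <- sum(summaries$survived & is.na(summaries$rmr))
  excl$no_mmr_overall <- sum(summaries$survived & is.na(summaries$mmr_overall))

  # thermal performance per population (mortalities as zero scope)
  tpc <- list()
  for (pop in unique(summaries$population)) {
    d <- summaries[summaries$population == pop, ]
    d <- d[!is.na(d$aas_adj), ]
    tpc[[pop]] <- tryCatch(
      fit_tpc(d$test_temperature, d$aas_adj, threshold = cfg$pejus_threshold,
              n_boot = cfg$tpc_n_boot, seed = cfg$seed),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "tpc_fit"))
  }

  # survival per population and pooled
  surv <- list()
  agg <- stats::aggregate(cbind(dead = !cohort$survived, n = 1L),
                          by = list(population = cohort$population,
                                    temperature = cohort$test_temperature),
                          FUN = sum)
  for (pop in unique(agg$population)) {
    a <- agg[agg$population == pop, ]
    surv[[pop]] <- fit_survival_loglogistic(a$dead, a$n, a$temperature)
  }
  pooled_agg <- stats::aggregate(cbind(dead = !cohort$survived, n = 1L),
                                 by = list(temperature = cohort$test_temperature),
                                 FUN = sum)
  pooled <- fit_survival_loglogistic(pooled_agg$dead, pooled_agg$n,
                                     pooled_agg$temperature)
  lrt <- if (length(surv) > 1L && !any(vapply(surv, function(f) f$boundary,
                                              logical(1))) && !pooled$boundary) {
    lrt_population(pooled, surv)
  } else NULL

  n_analyzed <- nrow(summaries)
  run_summary <- list(
    package_version = as.character(utils::packageVersion("thermalscope")),
    seed = cfg$seed,
    n_input = nrow(cohort),
    n_eligible = n_analyzed,
    exclusions = excl,
    n_recovery_profiles = length(recovery),
    n_epoc = length(epoc_tab),
    m50 = lapply(surv, function(f) as.numeric(f$m50)),
    topt = lapply(tpc, function(f) f$topt %||% NA_real_),
    t_pejus_upper = lapply(tpc, function(f) f$t_pejus_upper %||% NA_real_))

  res <- structure(list(
    cohort = cohort, morphometrics = morpho, summaries = summaries,
    group_summaries = group_summary(summaries),
    recovery = if (length(recovery)) do.call(rbind, recovery),
    epoc = if (length(epoc_tab)) do.call(rbind, epoc_tab),
    tpc = tpc, survival = surv, survival_pooled = pooled, lrt = lrt,
    exclusions = excl, summary = run_summary), class = "pipeline_result")

  if (!is.null(cfg$output_dir)) write_pipeline_result(res, cfg$output_dir)
  log_msg(cfg, "analyzed ", n_analyzed, " fish")
  res
}

#' Write pipeline outputs as delimited tables and a JSON summary
#'
#' @param res A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, nm) {
    if (!is.null(x) && is.data.frame(x) && nrow(x)) {
      utils::write.table(x, file.path(dir, nm), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  wt(res$summaries, "metabolic_summaries.tsv")
  wt(res$group_summaries, "group_summaries.tsv")
  wt(res$recovery, "recovery_blocks.tsv")
  wt(res$epoc, "epoc.tsv")
  wt(res$morphometrics, "morphometrics.tsv")
  jsonlite::write_json(res$summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
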