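#' Chase MMR by sliding-window regression
#'
#' Maximum metabolic rate after an exhaustive chase is estimated within the
#' first closed measurement window after the fish enters the chamber: every
#' window of at least `min_window_s` seconds, at every start offset (the
#' sample resolution sets the step), is fit by least squares, and the steepest
#' depletion slope with r-squared above `r2_min` is converted to MO2. The
#' search runs over all window lengths >= the minimum as well as all starts,
#' so "steepest qualifying slope" has an explicit, testable search space.
#'
#' @param time_s,o2 Samples of the first post-chase closed window.
#' @param volume_l,fish_volume_l,mass_kg Chamber/fish geometry for
#'   [compute_mo2()].
#' @param min_window_s Minimum window length in seconds (default 90).
#' @param r2_min r-squared a window must exceed to qualify (default 0.9).
#' @return MMR in mg O2 kg^-1 min^-1, with attributes `window_start_s` and
#'   `window_length_s` of the winning window; or `NA` with a `reason`
#'   attribute when the cycle is shorter than the minimum window or no window
#'   qualifies (see [missing_reason()]).
#' @export
estimate_mmr_chase <- function(time_s, o2, volume_l, fish_volume_l, mass_kg,
                               min_window_s = 90, r2_min = 0.9) {
  n <- length(time_s)
  if (n < 5L || (time_s[n] - time_s[1L]) < min_window_s) {
    return(missing_with_reason("cycle shorter than minimum sliding window"))
  }
  # O(1) per-window OLS via cumulative sums
  t0 <- time_s - time_s[1L]
  cs_t <- cumsum(t0); cs_t2 <- cumsum(t0^2)
  cs_y <- cumsum(o2); cs_y2 <- cumsum(o2^2); cs_ty <- cumsum(t0 * o2)
  rng <- function(cs, i, j) cs[j] - if (i > 1L) cs[i - 1L] else 0
  best <- -Inf; best_win <- c(NA_real_, NA_real_)
  for (i in seq_len(n - 4L)) {
    js <- which(t0 - t0[i] >= min_window_s)
    js <- js[js > i + 3L]
    if (!length(js)) next
    nn <- js - i + 1
    st <- rng(cs_t, i, js); st2 <- rng(cs_t2, i, js)
    sy <- rng(cs_y, i, js); sy2 <- rng(cs_y2, i, js); sty <- rng(cs_ty, i, js)
    sxx <- st2 - st^2 / nn
    sxy <- sty - st * sy / nn
    syy <- sy2 - sy^2 / nn
    slope <- sxy / sxx
    r2 <- ifelse(syy > 0, sxy^2 / (sxx * syy), 1)
    ok <- slope < 0 & r2 > r2_min
    if (any(ok)) {
      mag <- abs(slope)
      mag[!ok] <- -Inf
      k <- which.max(mag)
      if (mag[k] > best) {
        best <- mag[k]
        best_win <- c(time_s[i], t0[js[k]] - t0[i])
      }
    }
  }
  if (!is.finite(best)) {
    return(missing_with_reason(
      sprintf("no window of >= %g s with r-squared > %g and a negative slope",
              min_window_s, r2_min)))
  }
  mmr <- compute_mo2(-best * 60, volume_l, fish_volume_l, mass_kg)
  structure(mmr, window_start_s = best_win[1L], window_length_s = best_win[2L])
}

#' Overall MMR across the whole record
#'
#' Exhaustive chases do not always elicit the highest oxygen uptake; some fish
#' peak spontaneously during overnight recovery. The overall MMR is the
#' maximum over the chase estimates and every validated overnight MO2 value,
#' computed only for fish with more than `min_measurements` overnight values.
#'
#' @param overnight_mo2 Validated overnight MO2 values (mg O2 kg^-1 min^-1).
#' @param mmr_1h,mmr_18h Chase MMR estimates (either may be `NA`).
#' @param min_measurements Required overnight count, exclusive (default 60:
#'   more than 60 values are required).
#' @return Overall MMR, or `NA` with a `reason` attribute.
#' @export
estimate_mmr_overall <- function(overnight_mo2, mmr_1h = NA, mmr_18h = NA,
                                 min_measurements = 60) {
  overnight_mo2 <- overnight_mo2[!is.na(overnight_mo2)]
  if (length(overnight_mo2) <= min_measurements) {
    return(missing_with_reason(sprintf(
      "only %d overnight MO2 values (need more than %d)",
      length(overnight_mo2), min_measurements)))
  }
  cand <- c(as.numeric(mmr_1h), as.numeric(mmr_18h), overnight_mo2)
  max(cand, na.rm = TRUE)
}

#' Resting metabolic rate as a low quantile of validated MO2
#'
#' RMR is the `quantile` (default 0.10) quantile of all validated MO2
#' measurements, computed only for fish with at least `min_measurements`
#' validated values. The quantile uses linear interpolation between order
#' statistics (R type 7); `method = "lowest_decile_mean"` instead averages
#' the values at or below that quantile.
#'
#' @param mo2 Validated MO2 values (mg O2 kg^-1 min^-1); validation (r-squared
#'   above 0.85 by default) happens upstream in [process_trace()].
#' @param quantile Quantile level (default 0.10).
#' @param min_measurements Minimum validated count, inclusive (default 60).
#' @param method `"quantile"` (default) or `"lowest_decile_mean"`.
#' @return RMR, or `NA` with a `reason` attribute.
#' @export
estimate_rmr <- function(mo2, quantile = 0.10, min_measurements = 60,
                         method = c("quantile", "lowest_decile_mean")) {
  method <- match.arg(method)
  mo2 <- mo2[!is.na(mo2)]
  if (length(mo2) < min_measurements) {
    return(missing_with_reason(sprintf(
      "only %d validated MO2 values (need at least %d)",
      length(mo2), min_measurements)))
  }
  q <- unname(stats::quantile(mo2, quantile, type = 7))
  if (method == "quantile") q else mean(mo2[mo2 <= q])
}

#' Absolute and factorial aerobic scope
#'
#' For survivors, AAS = MMR_overall - RMR and FAS = MMR_overall / RMR. Fish
#' that died during the experiment are assigned AAS = 0 and FAS = 0 whatever
#' their recorded rates: a dead fish has no aerobic scope, and dropping
#' mortalities would overstate the aerobic capacity of the population.
#'
#' @param mmr_overall,rmr Per-fish rates (mg O2 kg^-1 min^-1).
#' @param survived Logical.
#' @return List with `aas`, `fas` and a logical `flagged` that is set when a
#'   survivor's RMR is at or above its MMR (values computed but suspect).
#' @export
aerobic_scope <- function(mmr_overall, rmr, survived) {
  if (!isTRUE(survived)) {
    return(list(aas = 0, fas = 0, flagged = FALSE))
  }
  if (is.na(mmr_overall) || is.na(rmr)) {
    return(list(aas = NA_real_, fas = NA_real_, flagged = FALSE))
  }
  list(aas = as.numeric(mmr_overall) - as.numeric(rmr),
       fas = as.numeric(mmr_overall) / as.numeric(rmr),
       flagged = rmr >= mmr_overall)
}

#' Allometric adjustment of mass-specific MO2 to a reference mass
#'
#' Whole-animal metabolic rate scales as mass^b, so mass-specific rate scales
#' as mass^(b - 1). A measurement on a fish of mass `mass` is adjusted to the
#' rate a `reference_mass` fish would show:
#' adjusted = mo2 * (mass / reference_mass)^(1 - b).
#' Typical exponents for large salmonids are b = 0.67 for RMR and b = 0.58
#' for MMR.
#'
#' @param mo2 Mass-specific rate (mg O2 kg^-1 min^-1).
#' @param mass Fish mass, kg.
#' @param exponent_b Scaling exponent b (0 < b < 1.5).
#' @param reference_mass Reference mass, kg (default 3.5).
#' @return Adjusted mass-specific rate.
#' @export
mass_adjust <- function(mo2, mass, exponent_b, reference_mass = 3.5) {
  if (any(mass <= 0)) stop_input("mass must be > 0")
  if (exponent_b <= 0 || exponent_b >= 1.5) {
    stop_input("exponent_b outside the supported range (0, 1.5)")
  }
  mo2 * (mass / reference_mass)^(1 - exponent_b)
}

#' Temperature coefficient (Q10)
#'
#' Q10 = (RX / R12)^(10 / (TX - T12)): the factor by which a rate would
#' change over a 10 deg C interval, computed from rates at two temperatures.
#'
#' @param r_low Rate at the lower reference temperature.
#' @param t_low Lower reference temperature, deg C.
#' @param r_high Rate at the comparison temperature.
#' @param t_high Comparison temperature, deg C (must differ from `t_low`).
#' @return Q10, dimensionless.
#' @export
compute_q10 <- function(r_low, t_low, r_high, t_high) {
  if (any(r_low <= 0) || any(r_high <= 0)) stop_input("rates must be > 0")
  if (any(t_high == t_low)) stop_input("temperatures must differ")
  (r_high / r_low)^(10 / (t_high - t_low))
}

#' Estimate the allometric scaling exponent
#'
#' Ordinary least squares of log10(whole-animal MO2) on log10(body mass),
#' optionally with separate intercepts per group (population, temperature)
#' and a shared slope. The slope is the scaling exponent b.
#'
#' @param whole_mo2 Whole-animal rates (mg O2 min^-1).
#' @param mass Body masses, kg.
#' @param group Optional grouping factor for group-specific intercepts.
#' @return List with `b` (the common slope), `se` and the `lm` fit.
#' @export
estimate_scaling_exponent <- function(whole_mo2, mass, group = NULL) {
  if (length(whole_mo2) < 3L) stop_input("need at least 3 fish")
  if (stats::var(mass) == 0) stop_input("no variation in body mass")
  lx <- log10(mass); ly <- log10(whole_mo2)
  fit <- if (is.null(group)) stats::lm(ly ~ lx) else
    stats::lm(ly ~ lx + factor(group))
  co <- suppressWarnings(summary(fit)$coefficients) # exact fits are fine here
  list(b = unname(co["lx", "Estimate"]), se = unname(co["lx", "Std. Error"]),
       fit = fit)
}

#' Per-fish metabolic summary
#'
#' Combines the processed MO2 series of both post-chase recordings into the
#' standard per-fish metabolic phenotype: RMR, the three MMR variants, AAS and
#' FAS (with the mortality-as-zero rule), and mass-adjusted counterparts at
#' the reference mass.
#'
#' @param series_1h Processed series ([process_trace()]) of the first
#'   (overnight) recording; cycle 0 is the chase window.
#' @param series_18h Processed series of the second recording, or `NULL`.
#' @param trace_1h,trace_18h The corresponding [o2_trace()] objects (needed
#'   for the within-cycle sliding-window MMR search).
#' @param survived Logical.
#' @param mass_kg,volume_l,fish_volume_l Geometry; defaults read from
#'   `trace_1h`.
#' @param rmr_r2_min Validation threshold for RMR entries (default 0.85).
#' @param mmr_r2_min Sliding-window threshold (default 0.9).
#' @param min_measurements Eligibility count for RMR (at least) and overall
#'   MMR (more than); default 60.
#' @param exponents Named vector of scaling exponents, `rmr` and `mmr`.
#' @param reference_mass Reference mass for adjustment, kg.
#' @return One-row data frame with columns `rmr`, `mmr_1h`, `mmr_18h`,
#'   `mmr_overall`, `aas`, `fas`, `survived`, `n_validated_mo2`, adjusted
#'   variants (`rmr_adj`, `mmr_overall_adj`, `aas_adj`, `fas_adj`) and
#'   exclusion reasons.
#' @export
metabolic_summary <- function(series_1h, series_18h = NULL, trace_1h,
                              trace_18h = NULL, survived = TRUE,
                              mass_kg = attr(trace_1h, "mass_kg"),
                              volume_l = attr(trace_1h, "volume_l"),
                              fish_volume_l = attr(trace_1h, "fish_volume_l"),
                              rmr_r2_min = 0.85, mmr_r2_min = 0.9,
                              min_measurements = 60,
                              exponents = c(rmr = 0.67, mmr = 0.58),
                              reference_mass = 3.5) {
  chase_window <- function(trace, series) {
    sel <- trace$time_s >= series$t_start[1L] & trace$time_s <= series$t_end[1L]
    estimate_mmr_chase(trace$time_s[sel], trace$o2[sel], volume_l,
                       fish_volume_l, mass_kg, r2_min = mmr_r2_min)
  }
  mmr_1h <- chase_window(trace_1h, series_1h)
  mmr_18h <- if (!is.null(series_18h)) chase_window(trace_18h, series_18h)
    else missing_with_reason("no second-chase recording")
  overnight <- series_1h[series_1h$cycle > 0 & series_1h$validated, ]
  valid_all <- series_1h[series_1h$validated & series_1h$r_squared >= rmr_r2_min, ]
  rmr <- estimate_rmr(valid_all$mo2, min_measurements = min_measurements)
  mmr_overall <- estimate_mmr_overall(overnight$mo2, mmr_1h, mmr_18h,
                                      min_measurements = min_measurements)
  sc <- aerobic_scope(mmr_overall, rmr, survived)
  adj <- function(x, b) if (is.na(x)) NA_real_ else
    mass_adjust(as.numeric(x), mass_kg, b, reference_mass)
  rmr_adj <- adj(rmr, exponents[["rmr"]])
  mmr_adj <- adj(mmr_overall, exponents[["mmr"]])
  aas_adj <- if (!isTRUE(survived)) 0 else mmr_adj - rmr_adj
  fas_adj <- if (!isTRUE(survived)) 0 else mmr_adj / rmr_adj
  data.frame(
    rmr = as.numeric(rmr), mmr_1h = as.numeric(mmr_1h),
    mmr_18h = as.numeric(mmr_18h), mmr_overall = as.numeric(mmr_overall),
    aas = sc$aas, fas = sc$fas, scope_flagged = sc$flagged,
    survived = survived, n_validated_mo2 = nrow(valid_all),
    rmr_adj = rmr_adj, mmr_overall_adj = mmr_adj,
    aas_adj = aas_adj, fas_adj = fas_adj,
    rmr_reason = missing_reason(rmr) %||% NA_character_,
    mmr_overall_reason = missing_reason(mmr_overall) %||% NA_character_,
    stringsAsFactors = FALSE)
}

#' Group summaries of per-fish metabolic phenotypes
#'
#' Means and standard errors by population and test temperature, computed
#' per individual and then averaged (so the group FAS is the mean of
#' individual ratios, not the ratio of group means).
#'
#' @param summaries Data frame of per-fish summaries with columns
#'   `population`, `test_temperature` and the metric columns.
#' @param metrics Character vector of columns to summarize.
#' @return Long data frame: `population`, `test_temperature`, `metric`,
#'   `mean`, `sem`, `n`.
#' @export
group_summary <- function(summaries,
                          metrics = c("rmr", "mmr_overall", "aas", "fas")) {
  out <- list()
  for (metric in metrics) {
    agg <- stats::aggregate(
      summaries[[metric]],
      by = list(population = summaries$population,
                test_temperature = summaries$test_temperature),
      FUN = function(x) {
        x <- x[!is.na(x)]
        c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
          n = length(x))
      })
    out[[metric]] <- data.frame(population = agg$population,
                                test_temperature = agg$test_temperature,
                                metric = metric,
                                mean = agg$x[, "mean"], sem = agg$x[, "sem"],
                                n = agg$x[, "n"])
  }
  do.call(rbind, out)
}
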