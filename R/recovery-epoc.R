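#' Short-term recovery time course as percent of scope and of MMR
#'
#' Two complementary recovery metrics over the first 50 minutes after an
#' exhaustive chase, pooled into 10-minute blocks by measurement-window
#' midpoint:
#' \itemize{
#'   \item \%AAS(t) = 100 * (MMR_overall - MO2(t)) / AAS — the fraction of the
#'     absolute aerobic scope recovered. Because the reference is the overall
#'     maximum rather than the chase maximum, \%AAS at time 0 need not be 0.
#'   \item \%MMR(t) = 100 * MO2(t) / MMR_ref — oxygen uptake relative to the
#'     chase maximum of that stage (MMR_1h or MMR_18h).
#' }
#'
#' @param mo2_series Processed series ([process_trace()]) starting at the
#'   chase; `t_mid_min` and `mo2` are used, invalid entries dropped.
#' @param rmr,aas,mmr_overall Per-fish rates from [metabolic_summary()].
#' @param mmr_ref The stage's chase MMR (MMR_1h or MMR_18h).
#' @param blocks Block left edges in minutes (default `seq(0, 50, 10)`).
#' @return Data frame `block_min`, `pct_aas`, `pct_mmr`, `n`; or `NA` with a
#'   `reason` attribute when `aas` is not positive (mortality or missing
#'   scope).
#' @export
recovery_timecourse <- function(mo2_series, rmr, aas, mmr_ref, mmr_overall,
                                blocks = seq(0, 50, 10)) {
  if (is.na(aas) || aas <= 0) {
    return(missing_with_reason("no positive aerobic scope (mortality)"))
  }
  s <- mo2_series[mo2_series$validated | mo2_series$cycle == 0, ]
  s <- s[!is.na(s$mo2), ]
  width <- if (length(blocks) > 1) diff(blocks)[1] else 10
  idx <- findInterval(s$t_mid_min, c(blocks, max(blocks) + width))
  keep <- idx >= 1 & idx <= length(blocks)
  s <- s[keep, ]; idx <- idx[keep]
  pct_aas <- 100 * (mmr_overall - s$mo2) / aas
  pct_mmr <- 100 * s$mo2 / mmr_ref
  out <- data.frame(
    block_min = blocks,
    pct_aas = as.numeric(tapply(pct_aas, factor(idx, seq_along(blocks)), mean)),
    pct_mmr = as.numeric(tapply(pct_mmr, factor(idx, seq_along(blocks)), mean)),
    n = as.integer(table(factor(idx, seq_along(blocks)))))
  out
}

#' Time to recover to 50 percent of chase MMR
#'
#' The time since the chase of the first MO2 measurement lying between 48 and
#' 52 percent of the stage's chase MMR. Fish whose series jumps across the
#' band without a measurement inside it are excluded (missing with reason)
#' rather than interpolated.
#'
#' @param mo2_series Processed series starting at the chase.
#' @param mmr_ref Chase MMR of the stage.
#' @param band Acceptance band as fractions of `mmr_ref` (default
#'   `c(0.48, 0.52)`).
#' @return Time in minutes, or `NA` with a `reason` attribute.
#' @export
rec_mmr50 <- function(mo2_series, mmr_ref, band = c(0.48, 0.52)) {
  s <- mo2_series[(mo2_series$validated | mo2_series$cycle == 0) &
                    !is.na(mo2_series$mo2), ]
  frac <- s$mo2 / mmr_ref
  hit <- which(frac >= band[1L] & frac <= band[2L])
  if (!length(hit)) {
    return(missing_with_reason(sprintf(
      "no measurement between %g%% and %g%% of chase MMR",
      100 * band[1L], 100 * band[2L])))
  }
  s$t_mid_min[hit[1L]]
}

#' Excess post-exercise oxygen consumption by spline integration
#'
#' MO2 measurements of the overnight recovery (starting at the first chase)
#' are smoothed with a cubic smoothing spline (generalized cross-validation
#' chooses the smoothing parameter unless `spar` is given) and the area
#' between the spline and RMR is integrated from the chase until the spline
#' first returns to RMR (within `return_tol`, default 2 percent) or until
#' `horizon_min`. The area is reported cumulatively and in the first five
#' hourly blocks. Fish with 60 or fewer measurements, or that never return to
#' RMR within the horizon, are flagged for exclusion.
#'
#' @param mo2_series Processed series of the overnight recording.
#' @param rmr Resting metabolic rate of the fish.
#' @param horizon_min Integration horizon in minutes (default 1080 = 18 h).
#' @param min_measurements Required measurement count, exclusive (default 60).
#' @param return_tol Relative tolerance for "returned to RMR" (default 0.02).
#' @param spar Optional smoothing parameter forwarded to
#'   [stats::smooth.spline()].
#' @param grid_step_min Integration grid step, minutes (default 0.1).
#' @return List with `epoc_cumulative` (mg O2 kg^-1), `epoc_hourly` (hours
#'   1..5), `epoc_complete` (did MO2 return to RMR inside the horizon),
#'   `t_return_min`; or a missing-with-reason `NA` when ineligible.
#' @export
compute_epoc <- function(mo2_series, rmr, horizon_min = 1080,
                         min_measurements = 60, return_tol = 0.02,
                         spar = NULL, grid_step_min = 0.1) {
  s <- mo2_series[(mo2_series$validated | mo2_series$cycle == 0) &
                    !is.na(mo2_series$mo2), ]
  if (nrow(s) <= min_measurements) {
    return(missing_with_reason(sprintf(
      "only %d MO2 measurements (need more than %d)", nrow(s),
      min_measurements)))
  }
  if (is.na(rmr)) return(missing_with_reason("no RMR estimate"))
  rmr <- as.numeric(rmr)
  fit <- if (is.null(spar)) {
    stats::smooth.spline(s$t_mid_min, s$mo2, cv = FALSE)
  } else {
    stats::smooth.spline(s$t_mid_min, s$mo2, spar = spar)
  }
  t_max <- min(horizon_min, max(s$t_mid_min))
  grid <- seq(min(s$t_mid_min), t_max, by = grid_step_min)
  mo2_hat <- stats::predict(fit, grid)$y
  returned <- which(mo2_hat <= rmr * (1 + return_tol))
  if (length(returned)) {
    t_return <- grid[returned[1L]]
    complete <- TRUE
  } else {
    t_return <- t_max
    complete <- FALSE
  }
  excess <- pmax(mo2_hat - rmr, 0)
  excess[grid > t_return] <- 0
  trap <- function(sel) {
    if (sum(sel) < 2L) return(0)
    x <- grid[sel]; y <- excess[sel]
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  cumulative <- trap(rep(TRUE, length(grid)))
  hourly <- vapply(1:5, function(h) {
    trap(grid >= (h - 1) * 60 & grid <= h * 60)
  }, numeric(1))
  list(epoc_cumulative = cumulative, epoc_hourly = hourly,
       epoc_complete = complete, t_return_min = t_return)
}
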