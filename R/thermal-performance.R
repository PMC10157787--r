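#' Fit a quadratic thermal performance curve to aerobic scope
#'
#' Least-squares fit of AAS = c0 + c1*T + c2*T^2 over per-fish (temperature,
#' scope) pairs, with mortalities entered as zeros. Peak diagnostics (optimal
#' temperature, maximum scope, upper pejus temperature) are populated only
#' when the curvature is negative and the vertex falls within the observed
#' temperature range plus `margin` deg C; otherwise they are missing with a
#' reason. Uncertainty for the peak summaries comes from a bootstrap over
#' fish.
#'
#' @param temperature Per-fish test temperatures, deg C.
#' @param aas Per-fish absolute aerobic scope (zeros for mortalities).
#' @param threshold Fraction of maximum scope defining the pejus limit
#'   (default 0.80).
#' @param margin Allowed vertex extrapolation beyond the data range, deg C
#'   (default 3).
#' @param n_boot Bootstrap draws for the SD of the peak summaries (0 to
#'   skip; default 0).
#' @param seed Seed for the bootstrap.
#' @return Object of class `tpc_fit`: coefficients `c0`, `c1`, `c2`,
#'   `topt`, `aas_max`, `t_pejus_upper`, `threshold`, `peak_valid`,
#'   `peak_reason`, bootstrap SDs (`topt_sd`, `t_pejus_sd`) when requested,
#'   and the underlying `lm` fit.
#' @export
fit_tpc <- function(temperature, aas, threshold = 0.80, margin = 3,
                    n_boot = 0, seed = 1) {
  keep <- !is.na(temperature) & !is.na(aas)
  temperature <- temperature[keep]; aas <- aas[keep]
  if (length(unique(temperature)) < 3L) {
    stop_input("need at least 3 distinct temperatures to fit a quadratic")
  }
  fit <- stats::lm(aas ~ temperature + I(temperature^2))
  co <- unname(stats::coef(fit))
  out <- list(c0 = co[1L], c1 = co[2L], c2 = co[3L], threshold = threshold,
              t_range = range(temperature), fit = fit,
              data = data.frame(temperature = temperature, aas = aas))
  th <- tpc_peak(co, threshold, out$t_range, margin)
  out <- c(out, th)
  if (n_boot > 0 && isTRUE(th$peak_valid)) {
    n <- length(aas)
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(temperature[idx])) < 3L) return(c(NA_real_, NA_real_))
        cb <- unname(stats::coef(stats::lm(aas[idx] ~ temperature[idx] +
                                             I(temperature[idx]^2))))
        pb <- tpc_peak(cb, threshold, out$t_range, margin)
        if (!isTRUE(pb$peak_valid)) return(c(NA_real_, NA_real_))
        c(pb$topt, pb$t_pejus_upper)
      }, numeric(2))
    })
    out$topt_sd <- stats::sd(boots[1L, ], na.rm = TRUE)
    out$t_pejus_sd <- stats::sd(boots[2L, ], na.rm = TRUE)
    out$n_boot_valid <- sum(!is.na(boots[1L, ]))
  }
  structure(out, class = "tpc_fit")
}

# closed-form peak summaries for a quadratic curve
tpc_peak <- function(co, threshold, t_range, margin) {
  c0 <- co[1L]; c1 <- co[2L]; c2 <- co[3L]
  if (is.na(c2) || c2 >= 0) {
    return(list(topt = NA_real_, aas_max = NA_real_, t_pejus_upper = NA_real_,
                peak_valid = FALSE, peak_reason = "no concave peak (c2 >= 0)"))
  }
  topt <- -c1 / (2 * c2)
  if (topt < t_range[1L] - margin || topt > t_range[2L] + margin) {
    return(list(topt = NA_real_, aas_max = NA_real_, t_pejus_upper = NA_real_,
                peak_valid = FALSE,
                peak_reason = "vertex outside the observed temperature range"))
  }
  aas_max <- c0 + c1 * topt + c2 * topt^2
  list(topt = topt, aas_max = aas_max,
       t_pejus_upper = topt + sqrt((1 - threshold) * aas_max / (-c2)),
       peak_valid = TRUE, peak_reason = NA_character_)
}

#' Peak summaries of a fitted thermal performance curve
#'
#' For the quadratic AAS(T) = c0 + c1*T + c2*T^2 with c2 < 0:
#' Topt = -c1 / (2 c2); AAS_max = AAS(Topt); and the upper pejus temperature,
#' the highest temperature at which scope stays above `threshold` of its
#' maximum, Tpejus = Topt + sqrt((1 - threshold) * AAS_max / (-c2)).
#'
#' @param fit A `tpc_fit` from [fit_tpc()].
#' @param threshold Fraction in (0, 1]; default the fit's own.
#' @return List `topt`, `aas_max`, `t_pejus_upper`.
#' @export
thermal_thresholds <- function(fit, threshold = fit$threshold) {
  if (threshold <= 0 || threshold > 1) stop_input("threshold must lie in (0, 1]")
  if (!isTRUE(fit$peak_valid)) {
    return(list(topt = missing_with_reason(fit$peak_reason),
                aas_max = NA_real_, t_pejus_upper = NA_real_))
  }
  pk <- tpc_peak(c(fit$c0, fit$c1, fit$c2), threshold, fit$t_range, Inf)
  list(topt = pk$topt, aas_max = pk$aas_max,
       t_pejus_upper = pk$t_pejus_upper)
}

#' Percent-of-maximum scope across temperature
#'
#' 100 * AAS(T) / AAS_max on a temperature grid, clipped below at 0. This is
#' the form in which river temperature thresholds are usually displayed, with
#' a horizontal line at the pejus threshold.
#'
#' @param fit A `tpc_fit` with a valid peak.
#' @param temperature Temperature grid, deg C.
#' @return Data frame `temperature`, `pct_max`.
#' @export
percent_max_curve <- function(fit, temperature) {
  if (!isTRUE(fit$peak_valid)) stop_input("fit has no valid peak")
  aas <- fit$c0 + fit$c1 * temperature + fit$c2 * temperature^2
  data.frame(temperature = temperature,
             pct_max = pmax(100 * aas / fit$aas_max, 0))
}

#' Functional warming tolerance
#'
#' The margin between the maximum environmental temperature a population
#' currently encounters and its upper pejus temperature. Negative values mean
#' the environment already exceeds the temperature range of near-optimal
#' aerobic performance.
#'
#' @param max_env_temperature Current maximum environmental temperature,
#'   deg C.
#' @param t_pejus_upper Upper pejus temperature, deg C.
#' @return Warming tolerance, deg C.
#' @export
warming_tolerance <- function(max_env_temperature, t_pejus_upper) {
  max_env_temperature - t_pejus_upper
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat("Quadratic thermal performance curve\n")
  cat(sprintf("  AAS(T) = %.4g + %.4g T + %.4g T^2\n", x$c0, x$c1, x$c2))
  if (isTRUE(x$peak_valid)) {
    cat(sprintf("  Topt = %.2f C, AAS_max = %.3f, upper T_pejus(%.0f%%) = %.2f C\n",
                x$topt, x$aas_max, 100 * x$threshold, x$t_pejus_upper))
    if (!is.null(x$topt_sd)) {
      cat(sprintf("  bootstrap SD: Topt %.2f, T_pejus %.2f (n = %d)\n",
                  x$topt_sd, x$t_pejus_sd, x$n_boot_valid))
    }
  } else {
    cat("  no valid peak:", x$peak_reason, "\n")
  }
  invisible(x)
}
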