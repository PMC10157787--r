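loglogistic_loglik <- function(log_m50, log_b, deaths, n, temperature) {
  p <- 1 / (1 + exp(exp(log_b) * (log(temperature) - log_m50)))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum((n - deaths) * log(p) + deaths * log(1 - p))
}

#' Fit a two-parameter log-logistic survival curve
#'
#' Binomial maximum likelihood for P(survive | T) = 1 / (1 + exp(b * (ln T -
#' ln M50))), with per-temperature death counts as the data. M50 is the
#' temperature at which 50 percent mortality is predicted. The 95 percent
#' confidence interval for M50 comes from the profile likelihood (the
#' temperatures at which the profiled deviance rises by the 0.95 chi-squared
#' quantile on 1 df); a Wald interval is available as an option.
#'
#' @param deaths Deaths per temperature group.
#' @param n Fish per temperature group.
#' @param temperature Group temperatures, deg C.
#' @param ci `"profile"` (default), `"wald"`, or `"none"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `survival_fit`: `m50`, `slope_b`, `ci95_m50`,
#'   `loglik`, `boundary` (TRUE when the data carry no interior information,
#'   e.g. all fish survive), and the inputs.
#' @export
fit_survival_loglogistic <- function(deaths, n, temperature,
                                     ci = c("profile", "wald", "none"),
                                     conf_level = 0.95) {
  ci <- match.arg(ci)
  if (length(unique(temperature)) < 2L) {
    stop_input("need at least 2 temperature levels")
  }
  if (any(deaths > n) || any(deaths < 0)) stop_input("deaths must lie in [0, n]")
  boundary <- all(deaths == 0) || all(deaths == n)
  if (boundary) {
    out <- list(m50 = missing_with_reason(
      "no mortality gradient: all fish survived or all died"),
      slope_b = NA_real_, ci95_m50 = c(NA_real_, NA_real_),
      loglik = 0, boundary = TRUE,
      deaths = deaths, n = n, temperature = temperature)
    return(structure(out, class = "survival_fit"))
  }
  nll <- function(par) {
    -loglogistic_loglik(par[1L], par[2L], deaths, n, temperature)
  }
  # start at the temperature bracketing 50 % observed mortality
  frac <- deaths / n
  start_m50 <- tryCatch(
    stats::approx(frac, temperature, xout = 0.5, ties = mean, rule = 2)$y,
    error = function(e) mean(temperature))
  opt <- stats::optim(c(log(start_m50), log(10)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt <- stats::optim(opt$par, nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  m50 <- exp(opt$par[1L]); b <- exp(opt$par[2L])
  ll_hat <- -opt$value
  ci95 <- c(NA_real_, NA_real_)
  if (ci == "profile") {
    crit <- stats::qchisq(conf_level, df = 1)
    prof_dev <- function(m50_fixed) {
      o <- stats::optimize(function(lb) {
        -loglogistic_loglik(log(m50_fixed), lb, deaths, n, temperature)
      }, interval = c(log(1e-2), log(1e3)))
      2 * (ll_hat + o$objective)
    }
    f <- function(m) prof_dev(m) - crit
    lo <- tryCatch(stats::uniroot(f, c(max(min(temperature) - 10, 0.1), m50),
                                  tol = 1e-6)$root, error = function(e) NA_real_)
    hi <- tryCatch(stats::uniroot(f, c(m50, max(temperature) + 15),
                                  tol = 1e-6)$root, error = function(e) NA_real_)
    ci95 <- c(lo, hi)
  } else if (ci == "wald") {
    h <- stats::optimHess(opt$par, nll)
    v <- tryCatch(solve(h)[1L, 1L], error = function(e) NA_real_)
    if (is.finite(v) && v > 0) {
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      ci95 <- exp(opt$par[1L] + c(-1, 1) * z * sqrt(v))
    }
  }
  structure(list(m50 = m50, slope_b = b, ci95_m50 = ci95, loglik = ll_hat,
                 boundary = FALSE, deaths = deaths, n = n,
                 temperature = temperature),
            class = "survival_fit")
}

#' Likelihood ratio test for a population effect on survival
#'
#' Compares a pooled log-logistic fit against separate per-population fits of
#' the same data: statistic = 2 * (sum of population log-likelihoods - pooled
#' log-likelihood), df = number of added parameters (2 per extra
#' two-parameter curve), chi-squared p-value.
#'
#' @param pooled_fit `survival_fit` on the combined data.
#' @param population_fits List of `survival_fit`s, one per population, whose
#'   group sizes partition the pooled data.
#' @return List `statistic`, `df`, `p_value`.
#' @export
lrt_population <- function(pooled_fit, population_fits) {
  n_pooled <- sum(pooled_fit$n)
  n_pops <- sum(vapply(population_fits, function(f) sum(f$n), numeric(1)))
  if (n_pooled != n_pops) {
    stop_input("population fits do not partition the pooled data")
  }
  ll_pops <- sum(vapply(population_fits, function(f) f$loglik, numeric(1)))
  stat <- 2 * (ll_pops - pooled_fit$loglik)
  df <- 2L * (length(population_fits) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Predicted survival from a fitted curve
#'
#' @param fit A `survival_fit`.
#' @param temperature Temperatures, deg C.
#' @return Survival probabilities.
#' @export
predict_survival <- function(fit, temperature) {
  survival_probability(temperature, as.numeric(fit$m50), fit$slope_b)
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Two-parameter log-logistic survival fit\n")
  if (isTRUE(x$boundary)) {
    cat("  boundary case:", missing_reason(x$m50), "\n")
  } else {
    cat(sprintf("  M50 = %.2f C (95%% CI %.2f-%.2f), slope b = %.2f, logLik = %.3f\n",
                x$m50, x$ci95_m50[1L], x$ci95_m50[2L], x$slope_b, x$loglik))
  }
  invisible(x)
}

#' Organ-mass indices and eligibility
#'
#' Gonadosomatic (GSI), relative ventricular (RVM), splenosomatic (SSI) and
#' hepatosomatic (HSI) indices: organ mass divided by total body mass, times
#' 100. Fish with hematocrit below 20 percent are flagged ineligible for the
#' physiological analyses.
#'
#' @param gonads_g,ventricle_g,spleen_g,liver_g Organ masses, g.
#' @param body_mass_kg Body mass, kg.
#' @param hematocrit Hematocrit, percent.
#' @param hematocrit_min Eligibility threshold (default 20).
#' @return Data frame `gsi`, `rvm`, `ssi`, `hsi` (percent of body mass),
#'   `hematocrit`, `eligible`.
#' @export
organ_indices <- function(gonads_g, ventricle_g, spleen_g, liver_g,
                          body_mass_kg, hematocrit, hematocrit_min = 20) {
  if (any(body_mass_kg <= 0)) stop_input("body mass must be > 0")
  body_g <- body_mass_kg * 1000
  organs <- cbind(gonads_g, ventricle_g, spleen_g, liver_g)
  if (any(organs > body_g)) stop_input("organ mass exceeds body mass")
  if (any(organs < 0)) stop_input("organ masses must be >= 0")
  data.frame(gsi = 100 * gonads_g / body_g, rvm = 100 * ventricle_g / body_g,
             ssi = 100 * spleen_g / body_g, hsi = 100 * liver_g / body_g,
             hematocrit = hematocrit, eligible = hematocrit >= hematocrit_min)
}

#' Enzyme activity from kinetic absorbance readings
#'
#' Beer-Lambert conversion of a kinetic plate-reader slope to a catalytic
#' rate: the concentration rate is (dA/min) / (epsilon * pathlength) in
#' mmol L^-1 min^-1 (epsilon in mmol^-1 cm^-1, i.e. mM^-1 cm^-1; 6.22 for
#' NADH at 340 nm as in LDH assays, 13.6 for TNB at 412 nm as in CS assays).
#' The activity per gram of tissue scales the concentration rate by the
#' assay/homogenate volume ratio and divides by the tissue mass represented
#' in the homogenate aliquot.
#'
#' @param delta_abs_per_min Absorbance change per minute.
#' @param extinction_coeff Extinction coefficient, mmol^-1 cm^-1.
#' @param pathlength_cm Optical path length, cm.
#' @param assay_volume Total reaction volume (same unit as
#'   `homogenate_volume`).
#' @param homogenate_volume Homogenate volume added to the reaction.
#' @param tissue_mass_g Tissue mass represented by the homogenate aliquot, g.
#' @return List with `concentration_rate` (mmol L^-1 min^-1) and `activity`
#'   (umol min^-1 g^-1 when volumes are in mL and tissue mass in g).
#' @export
enzyme_activity <- function(delta_abs_per_min, extinction_coeff, pathlength_cm,
                            assay_volume = 1, homogenate_volume = 1,
                            tissue_mass_g = 1) {
  assert_scalar_num(extinction_coeff, "extinction_coeff", positive = TRUE)
  assert_scalar_num(pathlength_cm, "pathlength_cm", positive = TRUE)
  rate <- delta_abs_per_min / (extinction_coeff * pathlength_cm)
  list(concentration_rate = rate,
       activity = rate * (assay_volume / homogenate_volume) / tissue_mass_g)
}
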