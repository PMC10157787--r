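#' Construct an oxygen trace object
#'
#' An `o2_trace` couples a dissolved-oxygen/temperature time series recorded in
#' a sealed-and-flushed respirometer with the physical quantities needed to
#' convert oxygen depletion slopes into mass-specific oxygen uptake: the
#' respirometer volume `v_R`, the fish mass `m` and the fish volume `v_F`
#' (litres; a 1 kg fish is assumed to displace 1 L, so `v_F` defaults to the
#' numeric value of the mass).
#'
#' @param time_s Sample times in seconds, strictly increasing.
#' @param o2 Dissolved oxygen in mg L^-1, non-negative.
#' @param temp_c Water temperature in deg C (scalar or per-sample).
#' @param phase Optional per-sample phase label, `"measure"` or `"flush"`.
#' @param fish_id Identifier for the fish.
#' @param volume_l Respirometer volume in litres.
#' @param mass_kg Fish mass in kg.
#' @param fish_volume_l Fish volume in litres; defaults to `mass_kg`.
#' @return A data frame of class `o2_trace` with columns `time_s`, `o2`,
#'   `temp_c` and (if given) `phase`, and attributes `fish_id`, `volume_l`,
#'   `mass_kg`, `fish_volume_l`.
#' @export
o2_trace <- function(time_s, o2, temp_c, phase = NULL, fish_id = "fish",
                     volume_l, mass_kg, fish_volume_l = mass_kg) {
  if (length(time_s) != length(o2)) {
    stop_input("`time_s` and `o2` must have equal length")
  }
  bad <- which(diff(time_s) <= 0)
  if (length(bad)) {
    stop_input(sprintf("time must be strictly increasing; violation at row %d",
                       bad[1L] + 1L))
  }
  if (any(o2 < 0, na.rm = TRUE)) {
    stop_input(sprintf("negative O2 reading at row %d", which(o2 < 0)[1L]))
  }
  assert_scalar_num(volume_l, "volume_l", positive = TRUE)
  assert_scalar_num(mass_kg, "mass_kg", positive = TRUE)
  assert_scalar_num(fish_volume_l, "fish_volume_l", positive = TRUE)
  if (volume_l <= fish_volume_l) {
    stop_input("fish too large for chamber: respirometer volume must exceed fish volume")
  }
  if (length(temp_c) == 1L) temp_c <- rep(temp_c, length(time_s))
  df <- data.frame(time_s = as.numeric(time_s), o2 = as.numeric(o2),
                   temp_c = as.numeric(temp_c))
  if (!is.null(phase)) {
    phase <- as.character(phase)
    stopifnot(length(phase) == nrow(df))
    df$phase <- phase
  }
  structure(df,
            fish_id = fish_id, volume_l = volume_l, mass_kg = mass_kg,
            fish_volume_l = fish_volume_l,
            class = c("o2_trace", "data.frame"))
}

#' Read an oxygen trace from a delimited logger export
#'
#' Reads a FireSting-style delimited export with columns for time (s),
#' dissolved oxygen (mg L^-1) and temperature (deg C), plus an optional phase
#' column, and validates it into an [o2_trace()].
#'
#' @param path Path to the delimited text file (header row required).
#' @param volume_l,mass_kg,fish_volume_l Chamber and fish geometry, as in
#'   [o2_trace()].
#' @param fish_id Fish identifier; defaults to the file name.
#' @param sep Field separator (default tab).
#' @param columns Named character vector mapping the canonical names
#'   `time_s`, `o2`, `temp_c`, `phase` to the column names in the file.
#' @return An [o2_trace()].
#' @export
read_trace <- function(path, volume_l, mass_kg, fish_volume_l = mass_kg,
                       fish_id = NULL, sep = "\t",
                       columns = c(time_s = "time_s", o2 = "o2_mg_per_l",
                                   temp_c = "temp_c", phase = "phase")) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time_s", "o2", "temp_c")
  for (nm in need) {
    col <- columns[[nm]] %||% nm
    if (!col %in% names(raw)) {
      stop_input(sprintf("missing column `%s` (expected as `%s`) in %s",
                         nm, col, path))
    }
  }
  num <- function(nm) {
    col <- columns[[nm]]
    v <- raw[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad)) {
      stop_input(sprintf("unparseable value in column `%s` at row %d", col, bad[1L]))
    }
    out
  }
  phase_col <- columns[["phase"]] %||% "phase"
  phase <- if (phase_col %in% names(raw)) as.character(raw[[phase_col]]) else NULL
  o2_trace(time_s = num("time_s"), o2 = num("o2"), temp_c = num("temp_c"),
           phase = phase,
           fish_id = fish_id %||% sub("\\.[^.]+$", "", basename(path)),
           volume_l = volume_l, mass_kg = mass_kg,
           fish_volume_l = fish_volume_l)
}

#' Write an oxygen trace to delimited text
#'
#' Canonical dialect: tab-separated, header
#' `time_s  o2_mg_per_l  temp_c  phase`. [read_trace()] of a written file
#' reproduces the samples exactly.
#'
#' @param trace An [o2_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  out <- data.frame(time_s = trace$time_s, o2_mg_per_l = trace$o2,
                    temp_c = trace$temp_c)
  out$phase <- if (!is.null(trace$phase)) trace$phase else "measure"
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment a trace into closed measurement windows
#'
#' Intermittent-flow respirometry alternates flush phases (chamber open,
#' oxygen restored toward saturation) with closed measurement phases during
#' which the fish depletes oxygen. MO2 is estimated only from closed windows.
#' Segmentation uses, in order of precedence: the per-sample `phase` labels if
#' present; an explicit schedule (`flush_min`, `measure_min`, and the phase at
#' t = 0); or automatic detection of flush phases as sustained O2 increases.
#'
#' Trailing truncated measurement windows shorter than `min_fraction` of the
#' nominal measurement length are discarded (slope stability).
#'
#' @param trace An [o2_trace()].
#' @param flush_min,measure_min Schedule in minutes (ignored when labels are
#'   present).
#' @param first_phase Phase at the start of the trace, `"measure"` or
#'   `"flush"`. The post-chase protocol seals the chamber immediately, so the
#'   first closed window of a recovery trace is cycle 0.
#' @param auto Set `TRUE` to detect phases from the trace itself when neither
#'   labels nor a schedule are available.
#' @param min_fraction Minimum fraction of the nominal measurement length a
#'   truncated final window must reach to be kept (default 0.6).
#' @return Data frame with one row per closed window: `cycle`, `t_start`,
#'   `t_end` (seconds), `n_points`.
#' @export
segment_cycles <- function(trace, flush_min = NULL, measure_min = NULL,
                           first_phase = c("measure", "flush"),
                           auto = FALSE, min_fraction = 0.6) {
  t <- trace$time_s
  if (!is.null(trace$phase)) {
    lab <- trace$phase
    runs <- rle(lab == "measure")
    ends <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    keep <- which(runs$values)
    win <- data.frame(t_start = t[starts[keep]], t_end = t[ends[keep]],
                      n_points = runs$lengths[keep])
  } else if (!is.null(flush_min) && !is.null(measure_min)) {
    first_phase <- match.arg(first_phase)
    flush_s <- flush_min * 60; meas_s <- measure_min * 60
    period <- flush_s + meas_s
    t0 <- t[1L]; t_last <- t[length(t)]
    if (t_last - t0 < 0) stop_input("empty trace")
    offs <- if (first_phase == "measure") 0 else flush_s
    if (t0 + offs >= t_last) {
      stop_input("schedule longer than trace: no usable measurement window")
    }
    starts_s <- seq(t0 + offs, t_last, by = period)
    win <- data.frame(t_start = starts_s, t_end = starts_s + meas_s)
    win <- win[win$t_start <= t_last, , drop = FALSE]
    # clip final window to the trace, then apply the truncation policy
    win$t_end <- pmin(win$t_end, t_last)
    win <- win[(win$t_end - win$t_start) >= min_fraction * meas_s, , drop = FALSE]
    if (!nrow(win)) stop_input("schedule longer than trace: no usable measurement window")
    win$n_points <- vapply(seq_len(nrow(win)), function(i) {
      sum(t >= win$t_start[i] & t <= win$t_end[i])
    }, integer(1))
  } else if (isTRUE(auto)) {
    # flush = sustained O2 increase; classify by smoothed forward difference
    d <- diff(trace$o2)
    k <- max(5L, min(25L, length(d) %/% 20L))
    sm <- stats::filter(d, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- d[is.na(sm)]
    lab <- ifelse(sm > 0, "flush", "measure")
    lab <- c(lab[1L], lab)
    runs <- rle(lab == "measure")
    ends <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    keep <- which(runs$values & runs$lengths >= 5L)
    if (!length(keep) || all(runs$values)) {
      stop_input("auto-detection found no measurement cycles")
    }
    win <- data.frame(t_start = t[starts[keep]], t_end = t[ends[keep]],
                      n_points = runs$lengths[keep])
  } else {
    stop_input("provide phase labels, a flush/measure schedule, or auto = TRUE")
  }
  win$cycle <- seq_len(nrow(win)) - 1L
  win[, c("cycle", "t_start", "t_end", "n_points")]
}

#' Fit the oxygen depletion slope within one closed window
#'
#' Ordinary least squares of O2 on time. The regression is fit on seconds and
#' the slope reported per minute, matching logger sampling and the reporting
#' convention of the field. Three quality flags operationalize visual slope
#' screening: `negative` (slope < 0, i.e. the fish is consuming oxygen),
#' `linear` (r-squared at or above `r2_min`), and `artifact_free` (no
#' single-sample jump exceeding `jump_mult` residual (robust) SDs and an
#' absolute floor of `jump_min` mg L^-1).
#'
#' @param time_s,o2 Samples within the window.
#' @param r2_min Linearity threshold on r-squared (default 0.85).
#' @param jump_mult Multiple of the robust residual SD a one-sample jump must
#'   exceed to be called an artifact (default 6).
#' @param jump_min Absolute jump floor in mg L^-1 (default 0.1).
#' @return List with `slope` (mg L^-1 min^-1, signed), `r_squared`,
#'   `n_points`, and logical flags `valid`, `negative`, `linear`,
#'   `artifact_free`. Windows with fewer than 5 samples are marked invalid
#'   rather than raising an error.
#' @export
fit_slope <- function(time_s, o2, r2_min = 0.85, jump_mult = 6, jump_min = 0.1) {
  n <- length(time_s)
  if (n < 5L) {
    return(list(slope = NA_real_, r_squared = NA_real_, n_points = n,
                valid = FALSE, negative = NA, linear = NA, artifact_free = NA))
  }
  tt <- time_s - time_s[1L]
  fit <- stats::.lm.fit(cbind(1, tt), o2)
  slope_s <- fit$coefficients[2L]
  res <- fit$residuals
  ss_tot <- sum((o2 - mean(o2))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  r2 <- min(max(r2, 0), 1)
  sd_r <- stats::mad(res)
  if (!is.finite(sd_r) || sd_r == 0) sd_r <- stats::sd(res)
  jumps <- abs(diff(res))
  artifact <- any(jumps > pmax(jump_mult * sd_r, jump_min))
  slope_min <- slope_s * 60
  # below ~1e-10 mg/L/min a "slope" is numerical noise, not respiration
  list(slope = slope_min, r_squared = r2, n_points = n, valid = TRUE,
       negative = slope_min < -1e-10, linear = r2 >= r2_min,
       artifact_free = !artifact)
}

#' Convert a depletion slope to mass-specific oxygen uptake
#'
#' MO2 = |slope| * (v_R - v_F) / m, where the slope is the fitted oxygen
#' depletion rate (mg L^-1 min^-1, negative for a respiring fish), v_R the
#' respirometer volume (L), v_F the fish volume (L, 1 kg = 1 L), and m the
#' fish mass (kg). The result is in mg O2 kg^-1 min^-1. A positive
#' (increasing-O2) slope has no metabolic interpretation and yields `NA`.
#'
#' @param slope Fitted slope in mg L^-1 min^-1 (signed; magnitude used).
#' @param volume_l Respirometer volume v_R in L.
#' @param fish_volume_l Fish volume v_F in L.
#' @param mass_kg Fish mass m in kg.
#' @return MO2 in mg O2 kg^-1 min^-1.
#' @export
compute_mo2 <- function(slope, volume_l, fish_volume_l, mass_kg) {
  assert_scalar_num(volume_l, "volume_l", positive = TRUE)
  assert_scalar_num(fish_volume_l, "fish_volume_l", positive = TRUE)
  assert_scalar_num(mass_kg, "mass_kg", positive = TRUE)
  if (volume_l <= fish_volume_l) stop_input("v_R must exceed v_F")
  out <- abs(slope) * (volume_l - fish_volume_l) / mass_kg
  out[!is.na(slope) & slope > 0] <- NA_real_
  out
}

#' Process a trace into a validated MO2 series
#'
#' Runs segmentation, per-cycle slope fitting and the MO2 conversion, and
#' stamps each entry with its window midpoint in minutes since the start of
#' the trace (minutes since the chase, for post-exercise recordings).
#'
#' @param trace An [o2_trace()].
#' @param r2_min Linearity threshold passed to [fit_slope()].
#' @param ... Segmentation arguments passed to [segment_cycles()].
#' @return Data frame (one row per closed window): `cycle`, `t_start`,
#'   `t_end`, `t_mid_min`, `slope`, `r_squared`, `n_points`, `negative`,
#'   `linear`, `artifact_free`, `validated`, `mo2`.
#' @export
process_trace <- function(trace, r2_min = 0.85, ...) {
  win <- segment_cycles(trace, ...)
  v_r <- attr(trace, "volume_l"); v_f <- attr(trace, "fish_volume_l")
  m <- attr(trace, "mass_kg")
  rows <- lapply(seq_len(nrow(win)), function(i) {
    sel <- trace$time_s >= win$t_start[i] & trace$time_s <= win$t_end[i]
    f <- fit_slope(trace$time_s[sel], trace$o2[sel], r2_min = r2_min)
    validated <- isTRUE(f$valid) && isTRUE(f$negative) && isTRUE(f$linear) &&
      isTRUE(f$artifact_free)
    mo2 <- if (isTRUE(f$valid) && isTRUE(f$negative)) {
      compute_mo2(f$slope, v_r, v_f, m)
    } else NA_real_
    data.frame(cycle = win$cycle[i], t_start = win$t_start[i],
               t_end = win$t_end[i],
               t_mid_min = (win$t_start[i] + win$t_end[i]) / 2 / 60,
               slope = f$slope, r_squared = f$r_squared,
               n_points = f$n_points,
               negative = isTRUE(f$negative), linear = isTRUE(f$linear),
               artifact_free = isTRUE(f$artifact_free),
               validated = validated, mo2 = mo2)
  })
  out <- do.call(rbind, rows)
  attr(out, "fish_id") <- attr(trace, "fish_id")
  out
}

#' Background respiration correction
#'
#' Microbial respiration in the chamber adds to the measured depletion. Blank
#' runs before and after the trial give background depletion rates (mg O2
#' L^-1 min^-1); the correction interpolates between the two in time, converts
#' through the same volume term as the fish measurement, and subtracts. The
#' default rates of zero reproduce the common finding that background
#' respiration is negligible and leave the series untouched.
#'
#' @param mo2_series Data frame from [process_trace()] (needs `t_mid_min`,
#'   `mo2`).
#' @param pre_rate,post_rate Background depletion rates (mg O2 L^-1 min^-1)
#'   measured before and after the trial.
#' @param volume_l,fish_volume_l,mass_kg Geometry used for the conversion.
#' @return The series with `mo2` adjusted; entries driven below zero are
#'   clipped to 0 and flagged in a logical `background_clipped` column.
#' @export
correct_background <- function(mo2_series, pre_rate = 0, post_rate = 0,
                               volume_l, fish_volume_l, mass_kg) {
  if (pre_rate == 0 && post_rate == 0) {
    mo2_series$background_clipped <- FALSE
    return(mo2_series)
  }
  t <- mo2_series$t_mid_min
  w <- if (length(t) > 1L) (t - min(t)) / (max(t) - min(t)) else 0
  bg <- (pre_rate * (1 - w) + post_rate * w) *
    (volume_l - fish_volume_l) / mass_kg
  adj <- mo2_series$mo2 - bg
  clipped <- !is.na(adj) & adj < 0
  adj[clipped] <- 0
  mo2_series$mo2 <- adj
  mo2_series$background_clipped <- clipped
  if (any(clipped)) {
    warning("background correction drove ", sum(clipped),
            " MO2 value(s) below zero; clipped to 0", call. = FALSE)
  }
  mo2_series
}
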