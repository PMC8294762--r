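#' Configuration for the kinetic-series generator
#'
#' Saturating-exponential curves `plateau * (1 - exp(-initial_rate * t /
#' plateau))`, whose derivative at t = 0 equals `initial_rate`, with additive
#' Gaussian noise. Sampling mirrors the plate-reader protocols: turbidity is
#' read every 35 s for 20 min starting at t = 0; translation luminescence is
#' read at 10-min end points from 10 to 50 min (the reaction pre-incubates
#' before the first reading, so there is no t = 0 point).
#'
#' @param assay `"turbidity"` or `"luminescence"`.
#' @param initial_rate early-phase rate per minute (delta-absorbance/min for
#'   turbidity, BLU/min for luminescence).
#' @param plateau saturation level (same units as the signal).
#' @param sampling_interval_min sampling interval; defaults 35/60 (turbidity)
#'   or 10 (luminescence).
#' @param duration_min total duration; defaults 20 or 50.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return a list of class `sim_kinetic_config`.
#' @export
sim_kinetic_config <- function(assay = c("turbidity", "luminescence"),
                               initial_rate = NULL, plateau = NULL,
                               sampling_interval_min = NULL,
                               duration_min = NULL, noise_sd = NULL,
                               seed = 1L) {
  assay <- match.arg(assay)
  defaults <- if (assay == "turbidity")
    list(initial_rate = 0.01, plateau = 1.0,
         sampling_interval_min = 35 / 60, duration_min = 20, noise_sd = 0.002)
  else
    list(initial_rate = 2000, plateau = 2e5,
         sampling_interval_min = 10, duration_min = 50, noise_sd = 200)
  initial_rate <- initial_rate %||% defaults$initial_rate
  plateau <- plateau %||% defaults$plateau
  sampling_interval_min <- sampling_interval_min %||% defaults$sampling_interval_min
  duration_min <- duration_min %||% defaults$duration_min
  noise_sd <- noise_sd %||% defaults$noise_sd
  check_scalar(initial_rate, "initial_rate")
  check_scalar(plateau, "plateau", positive = TRUE)
  check_scalar(sampling_interval_min, "sampling_interval_min", positive = TRUE)
  check_scalar(duration_min, "duration_min", positive = TRUE)
  if (duration_min < sampling_interval_min)
    stop("invalid configuration field 'duration_min': ",
         "duration must cover at least one sampling interval", call. = FALSE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(assay = assay, initial_rate = initial_rate, plateau = plateau,
                 sampling_interval_min = sampling_interval_min,
                 duration_min = duration_min, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_kinetic_config")
}

#' Simulate a turbidity or luminescence time series
#'
#' @param cfg a [sim_kinetic_config()].
#' @param condition optional condition label attached to the series.
#' @return a [kinetic_series()]; the generating `initial_rate` and `plateau`
#'   are attached as attribute `truth`.
#' @export
simulate_kinetics <- function(cfg, condition = NA_character_) {
  if (!inherits(cfg, "sim_kinetic_config")) cfg <- do.call(sim_kinetic_config, cfg)
  set.seed(cfg$seed)
  t0 <- if (cfg$assay == "turbidity") 0 else cfg$sampling_interval_min
  time <- seq(t0, cfg$duration_min, by = cfg$sampling_interval_min)
  signal <- cfg$plateau * (1 - exp(-cfg$initial_rate * time / cfg$plateau))
  if (cfg$noise_sd > 0) signal <- signal + rnorm(length(time), 0, cfg$noise_sd)
  ser <- kinetic_series(time, signal, condition = condition, assay = cfg$assay)
  attr(ser, "truth") <- list(initial_rate = cfg$initial_rate,
                             plateau = cfg$plateau)
  ser
}

#' Kinetic time series
#'
#' @param time_min strictly increasing time vector (minutes).
#' @param signal signal vector (OD600 or luminescence units).
#' @param condition condition label.
#' @param assay `"turbidity"` or `"luminescence"`.
#' @return data frame of class `kinetic_series` with columns `time_min`,
#'   `signal` and attributes `condition`, `assay`.
#' @export
kinetic_series <- function(time_min, signal, condition = NA_character_,
                           assay = c("turbidity", "luminescence")) {
  assay <- match.arg(assay)
  if (length(time_min) != length(signal))
    stop("time and signal lengths differ", call. = FALSE)
  if (any(diff(time_min) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  structure(data.frame(time_min = time_min, signal = signal),
            condition = condition, assay = assay,
            class = c("kinetic_series", "data.frame"))
}

#' Least-squares rate over a time window
#'
#' Ordinary least squares of signal on time, restricted to points with
#' `window[1] <= t <= window[2]`. Defaults: the turbidity convention fits the
#' early phase 0-5 min (delta-absorbance/min); luminescence fits all recorded
#' end points.
#'
#' @param series a [kinetic_series()].
#' @param window_min numeric pair, or `NULL` for the assay default.
#' @return a list of class `rate_result`: `rate` (slope per minute),
#'   `intercept`, `r_squared`, `window_min`, `n_points`.
#' @examples
#' s <- kinetic_series(c(0, 5), c(0, 0.5))
#' fit_rate(s, c(0, 5))$rate  # 0.1
#' @export
fit_rate <- function(series, window_min = NULL) {
  stopifnot(inherits(series, "kinetic_series") || is.data.frame(series))
  if (is.null(window_min)) {
    window_min <- if (identical(attr(series, "assay"), "turbidity")) c(0, 5)
    else range(series$time_min)
  }
  check_pair(window_min, "window_min")
  keep <- series$time_min >= window_min[1] & series$time_min <= window_min[2]
  if (sum(keep) < 2)
    stop("fitting error: fewer than 2 points in window [", window_min[1], ", ",
         window_min[2], "]", call. = FALSE)
  t <- series$time_min[keep]; y <- series$signal[keep]
  fit <- lm(y ~ t)
  ss_res <- sum(fit$residuals^2); ss_tot <- sum((y - mean(y))^2)
  structure(list(rate = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 window_min = window_min, n_points = sum(keep)),
            class = "rate_result")
}

#' Apparent saturation concentration from rate-vs-concentration data
#'
#' Above its saturation concentration c*, phase separation turns on and the
#' turbidity rate grows approximately linearly with protein concentration.
#' The apparent Csat is estimated as the x-intercept of a linear fit to the
#' supra-threshold points (rate above the noise floor). When replicate rates
#' exist at the lowest concentration the default floor is 3 times their SD,
#' otherwise 0.
#'
#' @param concentration_um protein concentrations (uM), length >= 3.
#' @param rate non-negative rates, same length.
#' @param noise_floor rate threshold; `NULL` for the default rule.
#' @return a list of class `csat_estimate`: `csat` (uM), `slope_above`,
#'   `fit_points`, `extrapolated` (TRUE if the intercept falls outside the
#'   tested concentration range).
#' @examples
#' estimate_csat(1:5, c(0, 0, 1, 2, 3))$csat  # 2
#' @export
estimate_csat <- function(concentration_um, rate, noise_floor = NULL) {
  if (length(concentration_um) < 3)
    stop("need at least 3 concentrations", call. = FALSE)
  if (length(rate) != length(concentration_um))
    stop("concentration and rate lengths differ", call. = FALSE)
  if (any(rate < 0)) stop("rates must be non-negative", call. = FALSE)
  if (is.null(noise_floor)) {
    low <- rate[concentration_um == min(concentration_um)]
    noise_floor <- if (length(low) >= 2) 3 * sd(low) else 0
  }
  keep <- rate > noise_floor
  if (sum(keep) < 2)
    stop("no-transition error: fewer than 2 rates above the noise floor",
         call. = FALSE)
  fit <- lm(rate[keep] ~ concentration_um[keep])
  b0 <- unname(coef(fit)[1]); b1 <- unname(coef(fit)[2])
  if (!is.finite(b1) || b1 <= 0)
    stop("no-transition error: non-positive slope above the floor", call. = FALSE)
  csat <- -b0 / b1
  structure(list(csat = csat, slope_above = b1, fit_points = sum(keep),
                 extrapolated = csat < min(concentration_um) ||
                   csat > max(concentration_um)),
            class = "csat_estimate")
}

#' Normalize condition rates to a control
#'
#' Divides every rate by the mean rate of the control condition, so the
#' control normalizes to 1 (the convention of reporting translation rates
#' relative to the buffer control).
#'
#' @param rates data frame with columns `condition` and `rate` (one row per
#'   replicate).
#' @param control control condition label (default `"control"`).
#' @return the input with a `normalized` column added; per-condition
#'   mean +/- SEM summary attached as attribute `summary`.
#' @export
normalize_rates <- function(rates, control = "control") {
  stopifnot(is.data.frame(rates), all(c("condition", "rate") %in% names(rates)))
  ctl <- rates$rate[rates$condition == control]
  if (length(ctl) == 0)
    stop("normalization error: control condition '", control, "' not found",
         call. = FALSE)
  m <- mean(ctl)
  if (!is.finite(m) || m <= 0)
    stop("normalization error: control mean rate must be > 0", call. = FALSE)
  rates$normalized <- rates$rate / m
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  smry <- do.call(rbind, lapply(split(rates, rates$condition), function(d)
    data.frame(condition = d$condition[1], mean = mean(d$normalized),
               sem = sem(d$normalized), n = nrow(d))))
  rownames(smry) <- NULL
  attr(rates, "summary") <- smry
  rates
}
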