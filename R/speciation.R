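#' Low-pass FFT smoothing of a chromatographic trace
#'
#' Smooths an intensity series by discarding Fourier components above a
#' cutoff frequency of `1 / (window_points * dt)`, mirroring the
#' points-of-window parameterisation of common chromatography software.
#' The DC component and all passband frequencies are preserved exactly, so
#' constant offsets and slow baselines survive smoothing unchanged.
#'
#' @param intensity numeric intensity series on a uniform time grid.
#' @param window_points odd integer >= 3; the effective smoothing window in
#'   samples.  Default 5.
#' @param dt sampling interval in seconds (ignored when `time` is given).
#' @param time optional time vector; must be uniformly spaced.
#' @return smoothed series, same length as the input.
#' @export
fft_smooth <- function(intensity, window_points = 5L, dt = 1, time = NULL) {
  .assert_numeric_vec(intensity, "intensity", min_len = 3L)
  window_points <- .assert_count(window_points, "window_points", min = 3L)
  if (window_points %% 2L == 0L)
    stop("'window_points' must be odd", call. = FALSE)
  if (!is.null(time)) {
    .assert_numeric_vec(time, "time", min_len = length(intensity))
    d <- diff(time)
    if (any(d <= 0) || (max(d) - min(d)) > 1e-8 * mean(d))
      stop("'time' must be a strictly increasing uniform grid", call. = FALSE)
    dt <- mean(d)
  }
  .assert_number(dt, "dt", lower = .Machine$double.eps)
  n <- length(intensity)
  if (n <= 2L * window_points)
    stop("series too short: length must exceed 2 * window_points",
         call. = FALSE)

  k <- 0:(n - 1L)
  freq <- ifelse(k <= n / 2, k, k - n) / (n * dt)
  cutoff <- 1 / (window_points * dt)
  X <- stats::fft(intensity)
  X[abs(freq) > cutoff] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Construct a chromatogram object
#'
#' A chromatogram couples a uniformly sampled (time, intensity) trace with,
#' per phosphorus species, three consecutive 60-second integration windows:
#' one minute of pre-peak background, one minute containing the peak, and
#' one minute of post-peak background.
#'
#' @param time time grid in seconds (strictly increasing, uniform).
#' @param intensity intensity counts, same length as `time`.
#' @param windows named list; one entry per species, each a list with
#'   elements `pre`, `peak`, `post`, each `c(start, end)` in seconds.
#' @param sample_id identifier carried into results.
#' @return object of class `chromatogram`.
#' @export
chromatogram <- function(time, intensity, windows, sample_id = "sample") {
  .assert_numeric_vec(time, "time", min_len = 3L)
  d <- diff(time)
  if (any(d <= 0) || (max(d) - min(d)) > 1e-8 * mean(d))
    stop("'time' must be a strictly increasing uniform grid", call. = FALSE)
  if (length(intensity) != length(time))
    stop("'intensity' and 'time' lengths differ", call. = FALSE)
  if (!is.list(windows) || is.null(names(windows)) || any(names(windows) == ""))
    stop("'windows' must be a named list (one entry per species)",
         call. = FALSE)
  for (sp in names(windows)) {
    w <- windows[[sp]]
    if (!all(c("pre", "peak", "post") %in% names(w)))
      stop(sprintf("windows for '%s' need elements pre, peak, post", sp),
           call. = FALSE)
    b <- unlist(w[c("pre", "peak", "post")])
    if (any(diff(b) < 0))
      stop(sprintf("windows for '%s' must be ordered pre < peak < post ",
                   sp), call. = FALSE)
  }
  structure(list(sample_id = sample_id, time = time, intensity = intensity,
                 windows = windows),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram '%s': %d points, %.0f-%.0f s, species: %s\n",
              x$sample_id, length(x$time), min(x$time), max(x$time),
              paste(names(x$windows), collapse = ", ")))
  invisible(x)
}

.window_idx <- function(time, w) time >= w[1] & time < w[2]

#' Integrate a baseline-corrected chromatographic peak
#'
#' The baseline is estimated from the pre- and post-peak background windows
#' (mean intensity by default, median with `baseline = "median"`), and the
#' peak area is the discrete integral of the smoothed, baseline-corrected
#' intensity over the peak window.  Negative computed areas are floored at
#' zero and flagged via the `"floored"` attribute rather than propagated.
#'
#' @param chrom a [chromatogram()] object.
#' @param species name of the species window set to integrate.
#' @param smooth apply [fft_smooth()] before integration (default TRUE).
#' @param window_points smoothing window, see [fft_smooth()].
#' @param baseline `"mean"` (default) or `"median"` of the background
#'   windows.
#' @return peak area (intensity * s) with attribute `floored`.
#' @export
integrate_peak <- function(chrom, species, smooth = TRUE, window_points = 5L,
                           baseline = c("mean", "median")) {
  stopifnot(inherits(chrom, "chromatogram"))
  baseline <- match.arg(baseline)
  if (!species %in% names(chrom$windows))
    stop(sprintf("no windows defined for species '%s'", species),
         call. = FALSE)
  w <- chrom$windows[[species]]
  tr <- range(chrom$time)
  b <- unlist(w[c("pre", "peak", "post")])
  if (min(b) < tr[1] - 1e-9 || max(b) > tr[2] + diff(chrom$time[1:2]) + 1e-9)
    stop(sprintf("windows for '%s' fall outside the trace", species),
         call. = FALSE)

  dt <- mean(diff(chrom$time))
  y <- if (isTRUE(smooth))
    fft_smooth(chrom$intensity, window_points = window_points, dt = dt)
  else chrom$intensity

  bg_idx <- .window_idx(chrom$time, w$pre) | .window_idx(chrom$time, w$post)
  base <- if (baseline == "mean") mean(y[bg_idx]) else stats::median(y[bg_idx])
  area <- sum(y[.window_idx(chrom$time, w$peak)] - base) * dt
  floored <- area < 0
  structure(max(0, area), floored = floored)
}

#' Correct raw areas or intensities for instrument drift
#'
#' ICP-MS sensitivity drifts over a run; standards re-measured at intervals
#' quantify it.  Each check point yields a drift factor measured/expected;
#' factors are interpolated piecewise-linearly over run time and raw values
#' are divided by the interpolated factor.
#'
#' @param values raw areas or intensities.
#' @param sample_times run-order times of the samples (same units as the
#'   check times).
#' @param checks data.frame with columns `time`, `expected`, `measured`;
#'   at least two checks are required and they must bracket the samples.
#' @return drift-corrected values.
#' @export
drift_correct <- function(values, sample_times, checks) {
  .assert_numeric_vec(values, "values")
  .assert_numeric_vec(sample_times, "sample_times",
                      min_len = length(values))
  .assert_cols(checks, c("time", "expected", "measured"), "checks")
  if (nrow(checks) < 2L)
    stop("need at least 2 drift check points", call. = FALSE)
  if (min(sample_times) < min(checks$time) ||
      max(sample_times) > max(checks$time))
    stop("drift checks must bracket the sample run times", call. = FALSE)
  factor <- checks$measured / checks$expected
  if (any(!is.finite(factor)) || any(factor <= 0))
    stop("drift factors must be finite and > 0", call. = FALSE)
  f <- stats::approx(checks$time, factor, xout = sample_times)$y
  values / f
}

# instrument detection limits (ppb) for the IC-ICPMS phosphorus species
.DEFAULT_DETECTION_LIMITS <- c(
  hypophosphite = 0.1,
  phosphite     = 0.1,
  phosphate     = 0.1,
  pyrophosphate = 0.2
)

#' Build a calibration curve from peak areas of standards
#'
#' OLS of peak area on standard concentration with a free intercept.
#' Standards conventionally span 0.2-100 ppb.  The per-species detection
#' limit (phosphite and phosphate 0.1 ppb, hypophosphite 0.1 ppb,
#' pyrophosphate 0.2 ppb) is attached unless overridden.
#'
#' @param standards data.frame with columns `concentration` (ppb) and
#'   `area` (intensity * s); at least three distinct concentrations.
#' @param species species name; used to look up the default detection limit.
#' @param detection_limit optional override, ppb.
#' @param average_duplicates average areas at duplicate concentrations
#'   before fitting.
#' @return object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared`, `detection_limit`, plus the standards used.
#' @export
build_calibration <- function(standards, species,
                              detection_limit = NULL,
                              average_duplicates = FALSE) {
  .assert_cols(standards, c("concentration", "area"), "standards")
  std <- standards[, c("concentration", "area")]
  if (isTRUE(average_duplicates))
    std <- stats::aggregate(area ~ concentration, data = std, FUN = mean)
  if (length(unique(std$concentration)) < 3L)
    stop("need >= 3 standards with distinct concentrations", call. = FALSE)
  fit <- stats::lm(area ~ concentration, data = std)
  slope <- unname(stats::coef(fit)["concentration"])
  if (slope <= 0)
    stop("calibration slope <= 0: inverted or absent response", call. = FALSE)
  dl <- detection_limit %||%
    unname(.DEFAULT_DETECTION_LIMITS[match(species,
                                           names(.DEFAULT_DETECTION_LIMITS))])
  if (is.null(dl) || is.na(dl))
    stop(sprintf("no default detection limit for species '%s'; ",
                 species), call. = FALSE)
  structure(list(
    species = species,
    standard_concentrations = std$concentration,
    peak_areas = std$area,
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = suppressWarnings(summary(fit))$r.squared,  # exact standards

    detection_limit = dl
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration for %s: area = %.4g * ppb + %.4g (r^2 %.4f), DL %.2g ppb\n",
              x$species, x$slope, x$intercept, x$r_squared,
              x$detection_limit))
  invisible(x)
}

#' Convert a peak area to extract and rock-basis concentrations
#'
#' Inverts the calibration (`ppb = (area - intercept) / slope`), censors
#' values below the detection limit, and converts the extract concentration
#' to a rock basis using the solid:solution ratio of the leach: with
#' `ml_per_g` millilitres of extractant per gram of rock (default 10, the
#' 1:10 EDTA-NaOH leach), `ppm_rock = ppb_extract * ml_per_g / 1000`.
#'
#' @param area peak area (intensity * s).
#' @param curve a [build_calibration()] result.
#' @param ml_per_g millilitres of extraction solution per gram of rock.
#' @return list with `species`, `extract_ppb`, `rock_ppm`, `censored`,
#'   `detection_limit` and a `label` that reads `"< DL"` for censored values.
#' @export
quantify_species <- function(area, curve, ml_per_g = 10) {
  stopifnot(inherits(curve, "calibration_curve"))
  .assert_number(area, "area")
  .assert_number(ml_per_g, "ml_per_g", lower = .Machine$double.eps)
  ppb <- (area - curve$intercept) / curve$slope
  censored <- ppb < curve$detection_limit
  list(species = curve$species,
       extract_ppb = ppb,
       rock_ppm = ppb * ml_per_g / 1000,
       censored = censored,
       detection_limit = curve$detection_limit,
       label = if (censored) sprintf("< %.2g ppb", curve$detection_limit)
               else sprintf("%.4g ppb", ppb))
}

#' Extraction yield of the leach relative to bulk rock phosphorus
#'
#' Percentage of the bulk total P recovered by the extraction, computed as
#' the sum of uncensored species concentrations (rock-basis ppm P) over the
#' bulk total P.  Values below detection are excluded from the sum.  If the
#' species are reported per molecule rather than per P atom, pyrophosphate
#' carries two P atoms; set `pp_factor = 2` (and name the entry
#' `"pyrophosphate"`) to count it twice.
#'
#' @param species_ppm named or unnamed numeric vector of rock-basis species
#'   concentrations (ppm).
#' @param bulk_total_p bulk rock total P (ppm), > 0.
#' @param censored logical vector marking below-detection entries
#'   (default none).
#' @param pp_factor multiplier applied to a `"pyrophosphate"` entry
#'   (default 1: inputs already on a ppm-P basis).
#' @return yield in percent; attribute `all_censored` flags the degenerate
#'   all-censored case (yield 0).
#' @export
extraction_yield <- function(species_ppm, bulk_total_p,
                             censored = rep(FALSE, length(species_ppm)),
                             pp_factor = 1) {
  .assert_numeric_vec(species_ppm, "species_ppm", lower = 0)
  .assert_number(bulk_total_p, "bulk_total_p", lower = .Machine$double.eps)
  if (length(censored) != length(species_ppm))
    stop("'censored' must match 'species_ppm' in length", call. = FALSE)
  vals <- species_ppm
  if (pp_factor != 1 && !is.null(names(vals))) {
    i <- names(vals) == "pyrophosphate"
    vals[i] <- vals[i] * pp_factor
  }
  keep <- !censored
  if (!any(keep)) return(structure(0, all_censored = TRUE))
  structure(100 * sum(vals[keep]) / bulk_total_p, all_censored = FALSE)
}
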