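#' Sorbed-phosphorus ratios from co-precipitation experiment records
#'
#' Converts raw records of hydrous-ferric-oxide (HFO) co-precipitation
#' experiments into isotherm points.  Measured aliquot concentrations are
#' first multiplied by the dilution factor (which tracks NaOH/HCl additions
#' used for pH control) to recover in-vessel values; the sorbed amount of
#' each element is then the difference between its initial and in-vessel
#' final dissolved concentration.  "Sorption" here is total removal with the
#' precipitate, i.e. surface adsorption plus lattice incorporation.
#'
#' @param experiments data.frame with columns `p_initial`,
#'   `p_final_dissolved`, `fe_initial`, `fe_final_dissolved` (all micromolar)
#'   and `dilution_factor` (>= 1).  Additional columns (species, matrix, pH,
#'   `replicate_id`, ...) are carried through unchanged.
#' @return data.frame with one row per experiment: `x`, the in-vessel final
#'   dissolved P (uM); `y`, the sorbed-P / sorbed-Fe molar ratio; and
#'   `negative_sorbed_p`, a flag marking points whose sorbed P came out
#'   negative through measurement noise (retained, not dropped: discarding
#'   them would bias the fitted coefficient upward).
#' @seealso [fit_kads()]
#' @examples
#' exps <- data.frame(p_initial = 2, p_final_dissolved = 1.5,
#'                    fe_initial = 200, fe_final_dissolved = 2 / 1.1,
#'                    dilution_factor = 1.1)
#' compute_sorbed(exps)
#' @export
compute_sorbed <- function(experiments) {
  .assert_cols(experiments,
               c("p_initial", "p_final_dissolved", "fe_initial",
                 "fe_final_dissolved", "dilution_factor"),
               "experiments")
  with(experiments, {
    .assert_numeric_vec(p_initial, "p_initial", lower = 0)
    .assert_numeric_vec(dilution_factor, "dilution_factor", lower = 1)
    .assert_numeric_vec(fe_initial, "fe_initial")
    if (any(fe_initial <= 0))
      stop("'fe_initial' must be > 0", call. = FALSE)
  })

  p_vessel  <- experiments$p_final_dissolved * experiments$dilution_factor
  fe_vessel <- experiments$fe_final_dissolved * experiments$dilution_factor
  sorbed_p  <- experiments$p_initial - p_vessel
  sorbed_fe <- experiments$fe_initial - fe_vessel
  if (any(sorbed_fe <= 0))
    stop("sorbed Fe <= 0 in at least one experiment: no precipitate formed, ",
         "sorbed-P/sorbed-Fe ratio is undefined", call. = FALSE)

  out <- experiments
  out$x <- p_vessel
  out$y <- sorbed_p / sorbed_fe
  out$negative_sorbed_p <- sorbed_p < 0
  if (any(out$negative_sorbed_p))
    message(sum(out$negative_sorbed_p),
            " point(s) with slightly negative sorbed P retained and flagged")
  out
}

#' Fit a linear sorption isotherm to obtain the adsorption coefficient
#'
#' Ordinary least squares of the sorbed-P/sorbed-Fe molar ratio (`y`) on the
#' equilibrium dissolved P concentration (`x`, uM).  The slope is the
#' adsorption coefficient K_ads (per uM) of the linear isotherm
#' `P_ads/Fe_ads = K_ads * [P_d]`, so a dissolved concentration can later be
#' recovered as `[P_d] = (1/K_ads) * (P_ads/Fe_ads)`.  The fit is unweighted,
#' and replicate points at the same `x` are fitted raw unless
#' `average_replicates = TRUE`.
#'
#' @param points data.frame with numeric columns `x` and `y`, typically from
#'   [compute_sorbed()].
#' @param forced_origin force the line through the origin (`y = K_ads * x`)?
#'   The free-intercept fit is appropriate when comparing species whose
#'   trend lines are not assumed to pass through zero.
#' @param average_replicates average `y` over identical `x` values before
#'   fitting (default fits all raw points).
#' @return object of class `isotherm_fit`: list with `kads` (per uM),
#'   `intercept`, `stderr_kads`, `r_squared`, `n_points`, `forced_origin`.
#' @examples
#' pts <- data.frame(x = c(1, 2, 3), y = c(0.010, 0.025, 0.032))
#' fit_kads(pts)                       # free intercept
#' fit_kads(pts, forced_origin = TRUE)
#' @export
fit_kads <- function(points, forced_origin = FALSE, average_replicates = FALSE) {
  .assert_cols(points, c("x", "y"), "points")
  pts <- points[, c("x", "y")]
  if (anyNA(pts)) stop("'points' must not contain NA", call. = FALSE)
  if (isTRUE(average_replicates))
    pts <- stats::aggregate(y ~ x, data = pts, FUN = mean)

  n <- nrow(pts)
  min_n <- if (forced_origin) 1L else 2L
  if (n < min_n)
    stop(sprintf("need at least %d point(s) for this fit", min_n),
         call. = FALSE)
  if (!forced_origin && length(unique(pts$x)) < 2L)
    stop("all x values identical: free-intercept fit is singular ",
         "(use forced_origin = TRUE)", call. = FALSE)
  if (forced_origin && all(pts$x == 0))
    stop("all x values are zero: slope undefined", call. = FALSE)

  fit <- if (forced_origin) stats::lm(y ~ x + 0, data = pts)
         else              stats::lm(y ~ x, data = pts)
  # exact (noise-free) data makes summary.lm warn about a perfect fit;
  # the NA standard error that results is mapped to 0 below
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  slope_row <- if (forced_origin) 1L else 2L
  structure(list(
    kads          = unname(co[slope_row, "Estimate"]),
    intercept     = if (forced_origin) 0 else unname(co[1L, "Estimate"]),
    stderr_kads   = {
      se <- unname(co[slope_row, "Std. Error"])
      if (is.na(se)) 0 else se          # exact fits / saturated models
    },
    r_squared     = sm$r.squared,
    n_points      = n,
    forced_origin = isTRUE(forced_origin)
  ), class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("Linear sorption isotherm fit\n")
  cat(sprintf("  K_ads     : %.6g per uM (s.e. %.3g)\n", x$kads, x$stderr_kads))
  cat(sprintf("  intercept : %.6g%s\n", x$intercept,
              if (x$forced_origin) " (forced through origin)" else ""))
  cat(sprintf("  r^2 = %.4f on %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

.kads_value <- function(x, name) {
  if (inherits(x, "isotherm_fit")) return(x$kads)
  .assert_number(x, name)
  x
}

#' Fold ratio of two adsorption coefficients
#'
#' How many times more strongly one phosphorus species sorbs onto HFO than
#' another, expressed as the ratio of their adsorption coefficients.  For
#' reporting, the ratio is conventionally rendered to the nearest integer
#' (e.g. K_ads 0.039 vs 0.0011 per uM reads as "35 times stronger").
#'
#' @param fit_pv,fit_piii `isotherm_fit` objects or bare K_ads values
#'   (per uM) for the numerator (phosphate) and denominator (phosphite).
#' @return object of class `fold_ratio`: list with `ratio` (exact) and
#'   `rendered` (nearest integer).
#' @examples
#' kads_fold_ratio(0.039, 0.0011)  # renders as 35
#' @export
kads_fold_ratio <- function(fit_pv, fit_piii) {
  num <- .kads_value(fit_pv, "fit_pv")
  den <- .kads_value(fit_piii, "fit_piii")
  if (den <= 0)
    stop("denominator K_ads must be > 0", call. = FALSE)
  r <- num / den
  structure(list(ratio = r, rendered = round(r)), class = "fold_ratio")
}

#' @export
print.fold_ratio <- function(x, ...) {
  cat(sprintf("K_ads fold ratio: %.4g (rendered %d)\n",
              x$ratio, as.integer(x$rendered)))
  invisible(x)
}
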