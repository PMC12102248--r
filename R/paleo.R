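#' Pair of adsorption coefficients used for seawater reconstruction
#'
#' The defaults are the coefficients appropriate for mildly acidic
#' (pH ~6.75) silica-rich artificial seawater, the conditions closest to
#' estimated Archean surface seawater: `kads_p5 = 0.026` per uM for
#' phosphate and `kads_p3 = 0.0005` per uM for phosphite.  Both are fully
#' configurable.
#'
#' @param kads_p5 adsorption coefficient for P(V), per uM.
#' @param kads_p3 adsorption coefficient for P(III), per uM.
#' @return object of class `kads_pair`.
#' @export
kads_pair <- function(kads_p5 = 0.026, kads_p3 = 0.0005) {
  .assert_number(kads_p5, "kads_p5", lower = .Machine$double.eps)
  .assert_number(kads_p3, "kads_p3", lower = .Machine$double.eps)
  structure(list(kads_p5 = kads_p5, kads_p3 = kads_p3), class = "kads_pair")
}

#' @export
print.kads_pair <- function(x, ...) {
  cat(sprintf("K_ads pair: P(V) %.4g, P(III) %.4g per uM\n",
              x$kads_p5, x$kads_p3))
  invisible(x)
}

#' Partition bulk BIF phosphorus into phosphite and phosphate
#'
#' The EDTA-NaOH leach recovers only a few percent of the rock's total P,
#' so the measured extract speciation must be projected onto the bulk rock
#' under an explicit assumption:
#' \describe{
#'   \item{`"ratio"`}{the P-species ratio in the bulk BIF equals that of the
#'     extract: `p3_bif = total_p * extract_p3 / S` and
#'     `p5_bif = total_p * extract_p5 / S`, where `S` is the summed extract
#'     species (pyrophosphate included in the denominator by default since
#'     it is measured dissolved P, though it is never itself projected to
#'     seawater).}
#'   \item{`"complete"`}{the leach recovered all BIF-hosted phosphite (its
#'     solubility is far higher than phosphate's): `p3_bif = extract_p3`
#'     and the entire remainder `total_p - extract_p3` is phosphate.}
#' }
#'
#' @param sample one-row data.frame or list with `extract_p3`, `extract_p5`,
#'   `extract_pp` (ppm of rock) and `total_p` (bulk ppm).
#' @param assumption `"ratio"` or `"complete"`.
#' @param include_pp include pyrophosphate in the ratio denominator
#'   (default TRUE).
#' @return named numeric vector `c(p3_bif, p5_bif)` in ppm of rock.
#' @export
partition_bif_phosphorus <- function(sample,
                                     assumption = c("ratio", "complete"),
                                     include_pp = TRUE) {
  assumption <- match.arg(assumption)
  p3 <- sample$extract_p3; p5 <- sample$extract_p5
  pp <- sample$extract_pp %||% 0
  tp <- sample$total_p
  for (v in c("extract_p3" = p3, "extract_p5" = p5, "total_p" = tp))
    if (is.null(v) || !is.finite(v) || v < 0)
      stop("sample fields extract_p3, extract_p5, total_p must be ",
           "non-negative numbers", call. = FALSE)
  if (assumption == "ratio") {
    s <- p3 + p5 + if (include_pp) pp else 0
    if (s <= 0)
      stop("extract species sum is zero: 'ratio' partition undefined",
           call. = FALSE)
    c(p3_bif = tp * p3 / s, p5_bif = tp * p5 / s)
  } else {
    c(p3_bif = p3, p5_bif = tp - p3)
  }
}

#' Subtract metamorphically produced phosphite
#'
#' Post-depositional iron-redox chemistry can reduce a small fraction of
#' the coexisting phosphate pool to phosphite during diagenesis and
#' metamorphism.  The primary (depositional) phosphite is estimated as
#' `p3_bif - yield * p5_bif`, floored at zero; the floor is flagged through
#' the `"floored"` attribute, mirroring how sub-zero corrected cells are
#' reported in bracketing tables.  Experiments at 350 degC report a yield
#' of 0.075% (`yield = 0.00075`), available as the packaged constant used
#' by scenarios 2b/4b of [run_scenarios()].
#'
#' @param p3_bif,p5_bif rock-basis phosphite and phosphate, ppm.
#' @param yield fraction of the P(V) pool converted to P(III), in `[0, 1]`.
#' @return primary phosphite (ppm) with attribute `floored`.
#' @export
metamorphic_correct <- function(p3_bif, p5_bif, yield) {
  .assert_number(p3_bif, "p3_bif", lower = 0)
  .assert_number(p5_bif, "p5_bif", lower = 0)
  .assert_number(yield, "yield", lower = 0, upper = 1)
  v <- p3_bif - yield * p5_bif
  structure(max(0, v), floored = v < 0)
}

#' Dissolved seawater concentration from rock-basis P and Fe
#'
#' Inverts the linear sorption isotherm: the molar sorbed-P/sorbed-Fe ratio
#' recorded by the rock, divided by the adsorption coefficient, gives the
#' dissolved concentration of that species in the water from which the HFO
#' precipitated, `[P_d] = (1/K_ads) * (P_ads / Fe_ads)`.  The molar ratio
#' is computed from mass-basis rock analyses via atomic masses
#' (P 30.974, Fe 55.845 g/mol).
#'
#' @param p_bif species concentration in rock, ppm (ug/g).
#' @param fe_bif bulk iron, wt%.
#' @param kads adsorption coefficient, per uM.
#' @return dissolved concentration in uM.
#' @examples
#' dissolved_concentration(0.30, 40, 0.0005)  # ~2.7 nM
#' @export
dissolved_concentration <- function(p_bif, fe_bif, kads) {
  .assert_numeric_vec(p_bif, "p_bif", lower = 0)
  .assert_numeric_vec(fe_bif, "fe_bif")
  if (any(fe_bif <= 0)) stop("'fe_bif' must be > 0", call. = FALSE)
  .assert_number(kads, "kads", lower = .Machine$double.eps)
  mol_ratio <- (p_bif * 1e-6 / M_P) / (fe_bif * 1e-2 / M_FE)
  mol_ratio / kads
}

#' Phosphite share of total dissolved inorganic phosphorus
#'
#' @param p3_d,p5_d dissolved phosphite and phosphate, uM.
#' @return percentage `100 * p3 / (p3 + p5)`; `NA` with attribute
#'   `undefined = TRUE` (plus a warning) when both are zero.
#' @export
phosphite_fraction <- function(p3_d, p5_d) {
  .assert_number(p3_d, "p3_d", lower = 0)
  .assert_number(p5_d, "p5_d", lower = 0)
  if (p3_d + p5_d == 0) {
    warning("both concentrations are zero: fraction undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  structure(100 * p3_d / (p3_d + p5_d), undefined = FALSE)
}

# Scenario definitions bracketing the reconstruction.  Extraction: was the
# leached species ratio representative ("ratio") or was phosphite leached
# completely ("complete")?  Metamorphic phosphite: none, an experimental
# yield supplied by the user ("a" variants), the packaged 350-degC yield of
# 0.075% ("b" variants), or all of it (scenario 5, under which no primary
# phosphite estimate is possible).
.SCENARIO_TABLE <- data.frame(
  id         = c("1", "2a", "2b", "3", "4a", "4b", "5"),
  extraction = c("ratio", "ratio", "ratio", "complete", "complete",
                 "complete", "ratio"),
  yield_kind = c("none", "user", "packaged", "none", "user", "packaged",
                 "all"),
  stringsAsFactors = FALSE
)

#' Scenario identifiers for the seawater reconstruction
#'
#' @return character vector of valid scenario ids.
#' @export
scenario_ids <- function() .SCENARIO_TABLE$id

.resolve_scenarios <- function(scenarios, experimental_yield) {
  scenarios <- as.character(scenarios)
  unknown <- setdiff(scenarios, .SCENARIO_TABLE$id)
  if (length(unknown))
    stop("unknown scenario id(s): ", paste(unknown, collapse = ", "),
         " (valid: ", paste(.SCENARIO_TABLE$id, collapse = ", "), ")",
         call. = FALSE)
  defs <- .SCENARIO_TABLE[match(scenarios, .SCENARIO_TABLE$id), ]
  defs$yield <- vapply(defs$yield_kind, function(kind) switch(
    kind,
    none     = 0,
    packaged = METAMORPHIC_YIELD_350C,
    all      = NA_real_,   # scenario 5: estimation not possible
    user     = {
      if (is.null(experimental_yield))
        stop("scenarios 2a/4a need 'experimental_yield' (a published ",
             "metamorphic P(V)->P(III) yield, fraction in [0,1])",
             call. = FALSE)
      .assert_number(experimental_yield, "experimental_yield",
                     lower = 0, upper = 1)
      experimental_yield
    }), numeric(1))
  defs
}

#' Scenario-based reconstruction of dissolved phosphite and phosphate
#'
#' Chains [partition_bif_phosphorus()], [metamorphic_correct()] and
#' [dissolved_concentration()] for every sample under every requested
#' scenario, then brackets each formation by the (min, max) over its
#' samples.  Scenario 5 (all phosphite metamorphic) yields a dissolved
#' phosphite of exactly zero, flagged "estimation not possible"; its
#' phosphate estimate uses the ratio partition with no correction.
#'
#' Rendered tables print concentrations to three decimals in uM; cells
#' below 0.0005 uM (0.5 nM) print as `0.000*`, and scenario-5 phosphite
#' cells print as `ENP`.
#'
#' @param samples data.frame of BIF samples with columns `sample_id`,
#'   `formation`, `extract_p3`, `extract_p5`, `extract_pp` (ppm of rock),
#'   `total_p` (ppm), `total_fe` (wt%), e.g. from [gen_bif_table()].
#' @param kads a [kads_pair()].
#' @param scenarios scenario ids to run (subset of
#'   `c("1","2a","2b","3","4a","4b","5")`).  Defaults to the ids that need
#'   no external yield.
#' @param experimental_yield metamorphic yield (fraction) for scenarios
#'   2a/4a; required when those ids are requested, no default.
#' @param include_pp include pyrophosphate in the ratio denominator.
#' @param render_threshold uM threshold below which table cells render as
#'   `0.000*` (default 0.0005).
#' @return object of class `seawater_scenarios`: list with `per_sample`
#'   (tidy data.frame of estimates), `formation_table` (min/max brackets)
#'   and `rendered` (formatted character table).
#' @export
run_scenarios <- function(samples, kads = kads_pair(),
                          scenarios = c("1", "2b", "3", "4b", "5"),
                          experimental_yield = NULL,
                          include_pp = TRUE,
                          render_threshold = 0.0005) {
  .assert_cols(samples, c("sample_id", "formation", "extract_p3",
                          "extract_p5", "total_p", "total_fe"), "samples")
  stopifnot(inherits(kads, "kads_pair"))
  if (nrow(samples) < 1L) stop("'samples' is empty", call. = FALSE)
  defs <- .resolve_scenarios(scenarios, experimental_yield)

  rows <- vector("list", nrow(samples) * nrow(defs))
  k <- 0L
  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    for (j in seq_len(nrow(defs))) {
      def <- defs[j, ]
      part <- partition_bif_phosphorus(smp, assumption = def$extraction,
                                       include_pp = include_pp)
      if (def$yield_kind == "all") {
        p3_d <- 0
        floored <- FALSE
        not_possible <- TRUE
      } else {
        p3_prim <- metamorphic_correct(part[["p3_bif"]], part[["p5_bif"]],
                                       def$yield)
        floored <- attr(p3_prim, "floored")
        not_possible <- FALSE
        p3_d <- dissolved_concentration(as.numeric(p3_prim), smp$total_fe,
                                        kads$kads_p3)
      }
      p5_d <- dissolved_concentration(part[["p5_bif"]], smp$total_fe,
                                      kads$kads_p5)
      frac <- if (p3_d + p5_d > 0) 100 * p3_d / (p3_d + p5_d) else NA_real_
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample_id = smp$sample_id, formation = smp$formation,
        scenario = def$id,
        p3_dissolved_uM = p3_d, p5_dissolved_uM = p5_d,
        p3_fraction_pct = frac,
        p3_floored = floored, p3_not_possible = not_possible,
        stringsAsFactors = FALSE)
    }
  }
  per_sample <- do.call(rbind, rows)
  per_sample <- per_sample[order(per_sample$formation, per_sample$scenario,
                                 per_sample$sample_id), ]
  rownames(per_sample) <- NULL

  agg <- function(v, f) stats::aggregate(
    v, by = list(formation = per_sample$formation,
                 scenario = per_sample$scenario), FUN = f)$x
  key <- stats::aggregate(per_sample$p3_dissolved_uM,
                          by = list(formation = per_sample$formation,
                                    scenario = per_sample$scenario),
                          FUN = min)[, 1:2]
  formation_table <- data.frame(
    key,
    p3_min = agg(per_sample$p3_dissolved_uM, min),
    p3_max = agg(per_sample$p3_dissolved_uM, max),
    p5_min = agg(per_sample$p5_dissolved_uM, min),
    p5_max = agg(per_sample$p5_dissolved_uM, max),
    n_floored = agg(per_sample$p3_floored, sum),
    stringsAsFactors = FALSE)

  fmt <- function(v) ifelse(v < render_threshold,
                            "0.000*", sprintf("%.3f", v))
  enp <- formation_table$scenario %in%
    .SCENARIO_TABLE$id[.SCENARIO_TABLE$yield_kind == "all"]
  rendered <- data.frame(
    formation = formation_table$formation,
    scenario  = formation_table$scenario,
    p3 = ifelse(enp, "ENP",
                paste0(fmt(formation_table$p3_min), "-",
                       fmt(formation_table$p3_max))),
    p5 = paste0(fmt(formation_table$p5_min), "-",
                fmt(formation_table$p5_max)),
    stringsAsFactors = FALSE)

  structure(list(per_sample = per_sample,
                 formation_table = formation_table,
                 rendered = rendered,
                 kads = kads,
                 render_threshold = render_threshold),
            class = "seawater_scenarios")
}

#' @export
print.seawater_scenarios <- function(x, ...) {
  cat("Estimated dissolved P(III) and P(V) in surface seawater (uM)\n")
  cat(sprintf("  K_ads: P(V) %.4g, P(III) %.4g per uM; '0.000*' < %.4g uM;",
              x$kads$kads_p5, x$kads$kads_p3, x$render_threshold))
  cat(" ENP = estimation not possible\n\n")
  print(x$rendered, row.names = FALSE)
  invisible(x)
}
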