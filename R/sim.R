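# Seeded generators for every input the reconstruction consumes: sorption
# experiment tables, chromatograms, BIF sample tables and labeled gene
# trees.  Defaults reproduce the study conditions the analysis assumes
# (0.2 mM initial Fe(II), a 0-28 uM dissolved-P grid, triplicate runs,
# 3-minute per-species chromatograph windows, formation-level concentration
# ranges, a monophyletic DPO clade).

#' Simulate a co-precipitation sorption experiment table
#'
#' Emits one experiment record per grid value and replicate.  The
#' noise-free sorbed-P/sorbed-Fe molar ratio at dissolved concentration `x`
#' is `true_kads * x` (a linear isotherm); noise is multiplicative
#' lognormal (concentrations are positive and ICP-MS error is relative),
#' applied to the sorbed ratio.  About 99% of the initial Fe(II) is
#' reported as precipitated, matching the near-complete HFO precipitation
#' seen experimentally.  A per-record dilution factor in `[1, 1.1]`
#' emulates the NaOH/HCl additions tracked for pH control; measured aliquot
#' concentrations are the in-vessel values divided by it, so
#' [compute_sorbed()] inverts the bookkeeping exactly.
#'
#' @param true_kads adsorption coefficient generating the data, per uM.
#' @param dissolved_grid equilibrium dissolved P concentrations, uM
#'   (default a 0-28 uM grid).
#' @param fe_initial initial Fe(II), uM (default 200, i.e. 0.2 mM).
#' @param noise_sd relative (lognormal sigma) noise on the sorbed ratio.
#' @param replicates runs per grid value.
#' @param seed integer seed; same spec and seed give identical output.
#' @param species,matrix,pH,duration_h metadata carried into the records.
#' @param fe_sorbed_fraction fraction of Fe reported precipitated.
#' @return data.frame of experiment records (one per grid value and
#'   replicate) with attributes `true_kads` and `seed`.
#' @export
gen_sorption_dataset <- function(true_kads,
                                 dissolved_grid = c(0, 2, 5, 10, 15, 20, 28),
                                 fe_initial = 200,
                                 noise_sd = 0.05,
                                 replicates = 3L,
                                 seed = 1L,
                                 species = "PIII",
                                 matrix = "SeaSi",
                                 pH = 8,
                                 duration_h = 0.5,
                                 fe_sorbed_fraction = 0.99) {
  .assert_number(true_kads, "true_kads", lower = 0)
  .assert_numeric_vec(dissolved_grid, "dissolved_grid", lower = 0)
  .assert_number(fe_initial, "fe_initial", lower = .Machine$double.eps)
  .assert_number(noise_sd, "noise_sd", lower = 0)
  replicates <- .assert_count(replicates, "replicates", min = 1L)
  seed <- .assert_count(seed, "seed", min = 0L)
  .assert_number(fe_sorbed_fraction, "fe_sorbed_fraction",
                 lower = .Machine$double.eps, upper = 1)

  set.seed(seed)
  grid <- rep(dissolved_grid, each = replicates)
  rep_id <- rep(seq_len(replicates), times = length(dissolved_grid))
  n <- length(grid)
  noise <- if (noise_sd > 0) exp(stats::rnorm(n, 0, noise_sd)) else rep(1, n)
  dilution <- stats::runif(n, 1, 1.1)

  y <- true_kads * grid * noise
  fe_sorbed <- fe_sorbed_fraction * fe_initial
  p_sorbed <- y * fe_sorbed
  out <- data.frame(
    species = species, matrix = matrix, pH = pH, duration_h = duration_h,
    replicate_id = rep_id,
    p_initial = grid + p_sorbed,
    p_final_dissolved = grid / dilution,
    fe_initial = fe_initial,
    fe_final_dissolved = (fe_initial - fe_sorbed) / dilution,
    dilution_factor = dilution,
    stringsAsFactors = FALSE)
  attr(out, "true_kads") <- true_kads
  attr(out, "seed") <- seed
  out
}

#' Simulate an IC-ICPMS chromatogram with known species concentrations
#'
#' The trace is a drifting baseline plus one Gaussian peak per species plus
#' Gaussian noise.  Each peak's amplitude is chosen so that its integrated
#' area equals `response_factor * true_concentration`
#' (`A = area / (sigma * sqrt(2*pi))`), so peak integration and calibration
#' can be validated against the generating truth.  Each species receives
#' the conventional three 60-s windows (pre-peak background, peak,
#' post-peak background) centred on its retention time.
#'
#' @param species_table data.frame with columns `name`, `retention_time`
#'   (s, >= 90 so the pre-window fits), `true_concentration` (ppb) and
#'   `response_factor` (area per ppb).  Retention times must be distinct;
#'   peaks closer than `6 * peak_sigma` trigger a warning since their
#'   integration windows may overlap.
#' @param peak_sigma Gaussian peak width, s.
#' @param baseline_level,drift_slope baseline intercept (counts) and linear
#'   drift (counts/s).
#' @param noise_sd additive noise sd, counts.
#' @param sampling_interval s per point.
#' @param seed integer seed.
#' @param sample_id identifier for the chromatogram.
#' @return a [chromatogram()] with attributes `truth` (the species table)
#'   and `seed`.
#' @export
gen_chromatogram <- function(species_table,
                             peak_sigma = 5,
                             baseline_level = 50,
                             drift_slope = 0.02,
                             noise_sd = 1,
                             sampling_interval = 1,
                             seed = 1L,
                             sample_id = "synthetic") {
  .assert_cols(species_table,
               c("name", "retention_time", "true_concentration",
                 "response_factor"), "species_table")
  rt <- species_table$retention_time
  .assert_numeric_vec(rt, "retention_time", lower = 90)
  if (anyDuplicated(rt))
    stop("'retention_time' values must be distinct", call. = FALSE)
  .assert_number(peak_sigma, "peak_sigma", lower = .Machine$double.eps)
  .assert_number(sampling_interval, "sampling_interval",
                 lower = .Machine$double.eps)
  .assert_number(noise_sd, "noise_sd", lower = 0)
  .assert_numeric_vec(species_table$true_concentration, "true_concentration",
                      lower = 0)
  .assert_numeric_vec(species_table$response_factor, "response_factor",
                      lower = 0)
  seed <- .assert_count(seed, "seed", min = 0L)
  if (length(rt) > 1L && min(diff(sort(rt))) < 6 * peak_sigma)
    warning("peaks closer than 6 * peak_sigma: integration windows may overlap")

  set.seed(seed)
  time <- seq(0, max(rt) + 90, by = sampling_interval)
  signal <- baseline_level + drift_slope * time
  for (i in seq_len(nrow(species_table))) {
    area <- species_table$response_factor[i] *
      species_table$true_concentration[i]
    amp <- area / (peak_sigma * sqrt(2 * pi))
    signal <- signal + amp * exp(-(time - rt[i])^2 / (2 * peak_sigma^2))
  }
  if (noise_sd > 0) signal <- signal + stats::rnorm(length(time), 0, noise_sd)

  windows <- lapply(seq_len(nrow(species_table)), function(i) list(
    pre  = c(rt[i] - 90, rt[i] - 30),
    peak = c(rt[i] - 30, rt[i] + 30),
    post = c(rt[i] + 30, rt[i] + 90)))
  names(windows) <- species_table$name
  out <- chromatogram(time, signal, windows, sample_id = sample_id)
  attr(out, "truth") <- species_table
  attr(out, "seed") <- seed
  out
}

#' Formation-level concentration ranges for the studied BIFs
#'
#' Summary ranges (per formation) of EDTA-NaOH-extractable phosphite and
#' phosphate, bulk total P, bulk Fe, and the number of samples analysed,
#' for the four Neoarchean-Paleoproterozoic iron formations studied
#' (Kuruman-Gamohaan and three Hamersley units).  Useful as realistic
#' envelopes for [gen_bif_table()].
#'
#' @return data.frame with one row per formation.
#' @export
bif_formation_ranges <- function() {
  data.frame(
    formation = c("Kuruman-Gamohaan", "Joffre", "Dales Gorge",
                  "Marra Mamba"),
    n_samples = c(7L, 4L, 6L, 4L),
    p3_min = c(0.22, 0.02, 0.15, 0.23),
    p3_max = c(0.37, 0.05, 0.56, 0.34),
    p5_min = c(1.59, 2.21, 1.59, 3.32),
    p5_max = c(28.4, 15.4, 60.6, 11.6),
    total_p_min = c(70, 20, 20, 160),
    total_p_max = c(950, 110, 3720, 1090),
    fe_min = c(26.8, 27.4, 29.6, 30.4),
    fe_max = c(44.8, 34.7, 50, 50),
    stringsAsFactors = FALSE)
}

#' Simulate a table of BIF sample analyses
#'
#' Draws `n_samples` records uniformly within the given ranges, enforcing
#' the two features the analysis relies on: extractable phosphite below
#' extractable phosphate in every sample, and extract species summing to no
#' more than the bulk total P.  Draws violating either constraint are
#' rejected and redrawn.
#'
#' @param n_samples number of samples.
#' @param p3_range,p5_range,pp_range ranges (ppm of rock) for extractable
#'   phosphite, phosphate and pyrophosphate.
#' @param total_p_range bulk total P range, ppm.
#' @param fe_range bulk Fe range, wt% (<= 70).
#' @param formation label carried into the records.
#' @param seed integer seed.
#' @param sample_prefix prefix for sample ids.
#' @return data.frame with columns `sample_id`, `formation`, `extract_p3`,
#'   `extract_p5`, `extract_pp`, `total_p`, `total_fe`.
#' @export
gen_bif_table <- function(n_samples = 7L,
                          p3_range = c(0.22, 0.37),
                          p5_range = c(1.59, 28.4),
                          pp_range = c(0, 0.5),
                          total_p_range = c(70, 950),
                          fe_range = c(26.8, 44.8),
                          formation = "Kuruman-Gamohaan",
                          seed = 1L,
                          sample_prefix = formation) {
  n_samples <- .assert_count(n_samples, "n_samples", min = 1L)
  .assert_range(p3_range, "p3_range", lower = 0)
  .assert_range(p5_range, "p5_range", lower = 0)
  .assert_range(pp_range, "pp_range", lower = 0)
  .assert_range(total_p_range, "total_p_range", lower = 0)
  .assert_range(fe_range, "fe_range", lower = 0, upper = 70)
  seed <- .assert_count(seed, "seed", min = 0L)

  set.seed(seed)
  draw <- function() c(stats::runif(1, p3_range[1], p3_range[2]),
                       stats::runif(1, p5_range[1], p5_range[2]),
                       stats::runif(1, pp_range[1], pp_range[2]),
                       stats::runif(1, total_p_range[1], total_p_range[2]),
                       stats::runif(1, fe_range[1], fe_range[2]))
  rows <- matrix(NA_real_, n_samples, 5L)
  for (i in seq_len(n_samples)) {
    for (try in seq_len(1000L)) {
      d <- draw()
      ok <- (d[1] < d[2] || (p3_range[1] == p3_range[2] &&
                             p5_range[1] == p5_range[2])) &&
        d[1] + d[2] + d[3] <= d[4]
      if (ok) break
      if (try == 1000L)
        stop("ranges incompatible with extract_p3 < extract_p5 and ",
             "extract sum <= total_p", call. = FALSE)
    }
    rows[i, ] <- d
  }
  data.frame(
    sample_id = sprintf("%s-%02d", sample_prefix, seq_len(n_samples)),
    formation = formation,
    extract_p3 = rows[, 1], extract_p5 = rows[, 2], extract_pp = rows[, 3],
    total_p = rows[, 4], total_fe = rows[, 5],
    stringsAsFactors = FALSE)
}

#' Simulate BIF tables for all four studied formations
#'
#' Convenience wrapper calling [gen_bif_table()] once per row of
#' [bif_formation_ranges()], with per-formation sub-seeds derived from
#' `seed`.
#'
#' @param seed integer seed.
#' @param n_per_formation optional count overriding each formation's
#'   sample number.
#' @return combined data.frame of samples.
#' @export
gen_bif_multiformation <- function(seed = 1L, n_per_formation = NULL) {
  seed <- .assert_count(seed, "seed", min = 0L)
  rg <- bif_formation_ranges()
  out <- lapply(seq_len(nrow(rg)), function(i) {
    r <- rg[i, ]
    gen_bif_table(
      n_samples = n_per_formation %||% r$n_samples,
      p3_range = c(r$p3_min, r$p3_max),
      p5_range = c(r$p5_min, r$p5_max),
      pp_range = c(0, 0.5),
      total_p_range = c(r$total_p_min, r$total_p_max),
      fe_range = c(r$fe_min, r$fe_max),
      formation = r$formation,
      seed = (seed * 13L + i) %% .Machine$integer.max)
  })
  do.call(rbind, out)
}

# random rooted binary topology by sequential attachment: start from a
# two-tip tree and repeatedly split a uniformly chosen edge with the next
# tip.  Returns an edge matrix (parent, child) over ids 1..n (tips) and
# n+1.. (internals, root = n+1 after renumbering is not guaranteed; the
# newick writer below works from the recorded root id).
.rand_topology <- function(n) {
  if (n == 1L) return(list(edges = NULL, root = 1L))
  root <- n + 1L
  next_id <- n + 2L
  edges <- matrix(c(root, 1L, root, 2L), ncol = 2L, byrow = TRUE)
  for (tip in seq_len(n)[-(1:2)]) {
    e <- sample.int(nrow(edges), 1L)
    w <- next_id; next_id <- next_id + 1L
    child <- edges[e, 2L]
    edges[e, 2L] <- w
    edges <- rbind(edges, c(w, child), c(w, tip))
  }
  list(edges = edges, root = root)
}

# newick text for a topology with exponential branch lengths;
# tip_text[i] supplies the (possibly nested) newick fragment for tip i
.topology_newick <- function(topo, tip_text, scale) {
  if (is.null(topo$edges)) return(tip_text[1L])
  lens <- stats::rexp(nrow(topo$edges), rate = 1 / scale)
  kids <- split(seq_len(nrow(topo$edges)), topo$edges[, 1L])
  rec <- function(node) {
    if (node <= length(tip_text)) return(tip_text[node])
    parts <- vapply(kids[[as.character(node)]], function(e) {
      paste0(rec(topo$edges[e, 2L]), ":",
             format(lens[e], digits = 10))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(topo$root)
}

#' Simulate a rooted gene tree with a monophyletic DPO clade
#'
#' Generates a random rooted binary topology by sequential random
#' attachment with exponential branch lengths (mean
#' `branch_length_scale`).  When both states are present, the tree is
#' built as an APO backbone in which one tip slot is replaced by a random
#' subtree of `dpo_clade_size` DPO tips, so the DPO tips form exactly one
#' clade; the slot is chosen away from the root whenever the backbone
#' allows, so the clade's stem is never a root child and the rooted
#' parsimony argument (one switch under a free or APO root, two under a
#' DPO root) is well posed for every seed.
#'
#' @param n_tips total tips (>= 2).
#' @param dpo_clade_size tips labeled DPO, `0 <= dpo_clade_size <= n_tips`.
#' @param branch_length_scale mean branch length, substitutions/site.
#' @param seed integer seed; identical seeds give identical Newick.
#' @return a rooted [labeled_tree()] with attribute `seed`.
#' @export
gen_labeled_tree <- function(n_tips, dpo_clade_size,
                             branch_length_scale = 0.1, seed = 1L) {
  n_tips <- .assert_count(n_tips, "n_tips", min = 2L)
  dpo_clade_size <- .assert_count(dpo_clade_size, "dpo_clade_size", min = 0L)
  if (dpo_clade_size > n_tips)
    stop("'dpo_clade_size' must be <= n_tips", call. = FALSE)
  .assert_number(branch_length_scale, "branch_length_scale",
                 lower = .Machine$double.eps)
  seed <- .assert_count(seed, "seed", min = 0L)
  set.seed(seed)

  n_apo <- n_tips - dpo_clade_size
  if (dpo_clade_size == 0L || n_apo == 0L) {
    lab <- if (dpo_clade_size == 0L) "apo" else "dpo"
    topo <- .rand_topology(n_tips)
    nwk <- paste0(.topology_newick(topo, sprintf("%s%02d", lab,
                                                 seq_len(n_tips)),
                                   branch_length_scale), ";")
  } else {
    # DPO subtree first, then the backbone with a placeholder slot
    dpo_nwk <- if (dpo_clade_size == 1L) "dpo01" else
      .topology_newick(.rand_topology(dpo_clade_size),
                       sprintf("dpo%02d", seq_len(dpo_clade_size)),
                       branch_length_scale)
    m <- n_apo + 1L
    topo <- .rand_topology(m)
    # slots not adjacent to the root, when any exist
    root_kids <- if (is.null(topo$edges)) integer(0) else
      topo$edges[topo$edges[, 1L] == topo$root, 2L]
    candidates <- setdiff(seq_len(m), root_kids[root_kids <= m])
    slot <- if (length(candidates)) candidates[sample.int(length(candidates),
                                                          1L)]
            else sample.int(m, 1L)
    tip_text <- character(m)
    tip_text[slot] <- dpo_nwk
    tip_text[-slot] <- sprintf("apo%02d", seq_len(n_apo))
    nwk <- paste0(.topology_newick(topo, tip_text, branch_length_scale), ";")
  }
  tree <- ape::read.tree(text = nwk)
  states <- stats::setNames(
    ifelse(startsWith(tree$tip.label, "dpo"), "DPO", "APO"),
    tree$tip.label)
  out <- labeled_tree(tree, states)
  attr(out, "seed") <- seed
  attr(out, "newick") <- nwk
  out
}
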