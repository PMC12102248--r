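---
title: "Methods: reconstructing seawater phosphite and phosphate from banded iron formations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing seawater phosphite and phosphate from banded iron formations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosbif)
```

## The model

Banded iron formations (BIFs) are treated as chemical archives of the
photic-zone water column: their iron precipitated as hydrous ferric oxide
(HFO), and dissolved phosphorus species partitioned onto the precipitate
according to a linear sorption isotherm,

$$\frac{P_\mathrm{ads}}{Fe_\mathrm{ads}} = K_\mathrm{ads}\,[P_d],$$

where the sorbed-P/precipitated-Fe ratio is molar, $[P_d]$ is the
dissolved concentration in µM, and $K_\mathrm{ads}$ (µM⁻¹) is a
species- and matrix-specific adsorption coefficient.  "Sorption" means
total removal with the precipitate — surface adsorption plus lattice
incorporation; the two are not separated, and they need not be, because
the same lumped coefficient is used in both directions of the inference.
Inverting the isotherm per species turns a rock's P/Fe record into a
seawater concentration.  The essential empirical fact driving the
analysis is the contrast between species: phosphate coefficients are of
order $10^{-2}$ µM⁻¹, phosphite coefficients of order $10^{-4}$, so HFO
precipitation strips phosphate from surface seawater while leaving
phosphite largely behind.

The model's assumptions, and hence the domain of validity of every
number downstream, are: (i) the BIF precursor was HFO formed in shallow
water (the reconstruction says nothing about deep-water settings with
Fe(II) precursors such as greenalite); (ii) the isotherm is linear over
the relevant concentration range (no Langmuir saturation term is fitted,
and none is warranted by the 0–28 µM experimental range); (iii)
equilibrium was reached (supported by the insensitivity of fitted
coefficients to 0.5 h vs 24 h experiment duration).

## Sorption experiments to coefficients

`compute_sorbed()` reconstructs in-vessel concentrations from measured
aliquots.  pH control adds NaOH/HCl volumes during an experiment, so the
final aliquot is diluted relative to the vessel; the recorded
`dilution_factor` ≥ 1 multiplies the measured concentrations — the
standard mass-balance reading of tracked titrant additions.  Sorbed P
and Fe are then initial minus in-vessel final; the isotherm point is
$(x, y) = ([P_d], P_\mathrm{sorbed}/Fe_\mathrm{sorbed})$.

Noise can push a sorbed-P difference slightly negative when sorption is
weak.  Such points are **retained and flagged**, never dropped: deleting
them would censor the low tail and bias $K_\mathrm{ads}$ upward.
A zero or negative sorbed-Fe, by contrast, is an error — with no
precipitate the ratio is undefined.

`fit_kads()` is unweighted OLS (no weighting scheme is defensible
without replicate-level variance estimates, and the measurement error is
approximately relative anyway).  Both a free-intercept fit (used when
comparing species trend lines) and a forced-origin fit (used when a
coefficient feeds the seawater inversion, since the isotherm has no
constant term) are provided, as is optional pre-averaging of replicate
points at the same $x$ — raw-point fitting is the default because it
preserves the replicate weights.  `kads_fold_ratio()` reports how many
times more strongly phosphate sorbs than phosphite; the report view
rounds to the nearest integer, which is how such preferences are quoted
(e.g. 0.039/0.0011 → 35, 0.021/0.0008 → 26).  One rounding caveat is
deliberately left visible: the DI-water pair 0.011/0.0003 rounds to 37,
not the conventionally quoted 36, indicating the quoted figure came from
unrounded fits; the package reports what it computes.

## Chromatograms to speciation

The IC-ICPMS produces, per species, a three-minute trace: one minute of
pre-peak background, one of peak, one of post-peak background.
`fft_smooth()` implements the "points-of-window 5" smoothing convention
as an ideal low-pass filter with cutoff $1/(5\,\Delta t)$: the original
software's transfer function is proprietary, only the relative
stabilisation of peak areas matters, and an ideal low-pass is exactly
characterisable (DC and passband preserved to machine precision — tested
properties).  `integrate_peak()` takes the baseline as the mean of the
two background windows (a robust-median variant is a flag) and sums the
baseline-corrected smoothed intensity over the peak window.  Negative
areas are floored at zero and flagged.  Because the baseline is
estimated from the trace itself, peak area is invariant under adding any
constant to the whole trace — a tested invariant.

`build_calibration()` fits area on concentration (0.2–100 ppb
standards) with a free intercept, and attaches per-species detection
limits (0.1 ppb for phosphite, phosphate and hypophosphite, 0.2 ppb for
pyrophosphate).  `quantify_species()` inverts the curve, censors
below-detection values (reported as "< DL" and excluded from sums), and
converts extract ppb to rock-basis ppm through the 1:10 solid:solution
ratio of the EDTA-NaOH leach: ppm = ppb × (mL/g)/1000.
`extraction_yield()` sums uncensored species against bulk total P.
Pyrophosphate is assumed to be reported on a ppm-P basis by default; a
`pp_factor = 2` switch counts it per molecule instead.  The choice only
rescales yields, never the seawater estimates.

## Scenario-based seawater estimates

The leach recovers only ~1–38 % of bulk P, and post-depositional
iron-redox chemistry can generate phosphite from phosphate in the rock.
Neither effect is measurable per sample, so the reconstruction brackets
them with explicit scenarios — two extraction assumptions crossed with
three metamorphic assumptions:

| id | extraction | metamorphic phosphite |
|----|------------|-----------------------|
| 1  | ratio preserved | none |
| 2a / 2b | ratio preserved | user-supplied yield / 0.075 % |
| 3  | complete phosphite extraction | none |
| 4a / 4b | complete | user-supplied yield / 0.075 % |
| 5  | — | all phosphite metamorphic |

The 0.075 % yield (fraction of the coexisting P(V) pool reduced to
P(III)) comes from 350 °C experiments on ferruginous sediments — close
to the maximum burial temperature of the Hamersley units — and ships as
a packaged constant.  The yield behind the "a" variants is a published
experimental value that is cited but not printed in the sources this
package encodes, so it is a **required input with no default**.
Scenario 5 makes a primary-phosphite estimate impossible by definition:
the package returns exactly zero, flagged "estimation not possible",
rather than omitting the row.

Design choices worth recording:

* Under "complete" extraction, all of `total_p − extract_p3` is assigned
  to phosphate.  This follows from the bracketing logic (it maximises
  the phosphate pool consistent with the phosphite assumption) and
  matches the observation that complete-extraction phosphate ranges sit
  at or slightly above the ratio-based ones.
* Pyrophosphate enters the ratio denominator (it is genuinely measured
  dissolved P in the extract) but is never itself projected to seawater.
  Hypophosphite, which never quantifies above detection, is excluded.
* Formation ranges are min/max over **per-sample** estimates, not
  combinations of per-variable range endpoints: the extremes of
  different variables occur in different samples, and combining them
  would manufacture unphysical corner cases.
* The metamorphic correction is floored at zero and the floor flagged;
  rendered tables print `0.000*` for any cell below 0.5 nM (the
  rendering threshold is configurable), so a floored zero and a merely
  tiny value are distinguishable in the per-sample output.
* The default coefficient pair for the inversion is
  $K_\mathrm{ads}^{P(V)} = 0.026$, $K_\mathrm{ads}^{P(III)} = 0.0005$
  µM⁻¹ — the pH ≈ 6.75 silica-seawater values, pH-appropriate for
  Archean seawater.  The exact pair behind published tables is not
  printed as a pair anywhere, so this default is an explicit, fully
  configurable assumption.
* Unit handling runs through atomic masses ($M_P = 30.974$,
  $M_{Fe} = 55.845$ g/mol): ppm and wt% are converted to a molar ratio
  before the isotherm inversion, and a dimensional-cancellation test
  guards the conversion.

## The gene-tree argument

Whether early phosphite use was assimilatory (APO, phosphite as P
source) or dissimilatory (DPO, phosphite as electron donor) is read off
a rooted *ptxD* gene tree whose tips are labeled by the presence of
dissimilatory-pathway genes in the same genome.  States are a side
table, not label suffixes, keeping Newick files standard.

`fitch_min_changes()` implements Fitch small parsimony with unit cost.
The constrained-root variant is defined by the zero-length pseudo-tip
reduction: a pseudo-observation of the forced state at the root adds one
change exactly when that state is outside the free-root optimal set, so
the constrained count always exceeds the free count by 0 or 1.  (On
degenerate inputs — a uniform-state tree forced to the opposite root
state — this statistic differs from the conditional minimum over
histories with that root state, which would be 2; the pseudo-tip
statistic is the documented and tested definition, and the two coincide
on the nested-clade trees the argument actually concerns.)
Multifurcations are resolved arbitrarily with zero-length branches,
logged, since Bayesian consensus trees may contain polytomies.  The
implementation is verified against exhaustive enumeration of internal
labelings on trees up to 12 tips and cross-checked against an
independent parsimony implementation.

`mad_root()` implements minimal-ancestor-deviation rooting: for every
branch and continuous position on it, the root-mean-square of
$|2\,d(\mathrm{root},b)/d(b,c) - 1|$ over all tip pairs $(b,c)$
spanning the candidate root is minimised.  The per-branch optimum is
closed-form (each deviation is affine in the root position), ties
between branches go to the first branch in edge-matrix order (logged),
and the result is verified against a numeric grid-plus-optimiser oracle.
A perfectly clocklike tree roots at its symmetric midpoint with
deviation zero.

On any tree where the DPO tips form a clade not adjacent to the root,
the counts reproduce the one-vs-two-switch comparison: free root 1, APO
root 1, DPO root 2 — an APO-associated origin is the more parsimonious
history.

## What the synthetic data emulate — and what they do not

The generators produce inputs with the statistical structure the
analysis assumes, under the study conditions:

* `gen_sorption_dataset()`: 0.2 mM initial Fe(II), a 0–28 µM dissolved-P
  grid, triplicates, ~99 % Fe precipitation, multiplicative lognormal
  noise (default σ = 0.05) on the sorbed ratio — chosen multiplicative
  because concentrations are positive and ICP-MS error is relative —
  and a per-record dilution factor in [1, 1.1].
* `gen_chromatogram()`: Gaussian peaks over a linearly drifting
  baseline with additive noise; amplitudes are set so integrated area
  equals response factor × concentration, making round-trip recovery
  exactly checkable.  Peaks closer than 6σ warn, since their windows
  would overlap.
* `gen_bif_table()`: uniform draws within formation-level ranges
  (shipped in `bif_formation_ranges()`), constrained so extractable
  phosphite is below phosphate and extract sums stay below bulk total P.
* `gen_labeled_tree()`: topology by sequential random attachment,
  exponential branch lengths, and a DPO clade grafted in place of a
  backbone tip chosen away from the root, so the clade is nested for
  every seed.

Two limitations matter for interpreting green tests.  First, the BIF
generator draws each variable independently within its range; real
samples correlate bulk P, extract speciation and Fe, so synthetic
formation-level extremes (e.g. the scenario-1 maximum phosphite) are
systematically wider than those computed from the real per-sample data,
which live in an external archive.  Passing tests therefore demonstrate
the correctness of the chain, not the published per-sample numbers; the
archive-dependent values are reproducible only with those files
supplied, through the same file-based interface the tests exercise with
generated stand-ins.  Second, chromatographic noise is white and
Gaussian; real traces have correlated baseline wander, which the
pre/post-window baseline absorbs only to first order.

## Numerical choices and problem sizes

Zero-noise recovery tests demand machine-precision agreement (≤ 1e-10
relative) because every stage is algebraically exact in that limit.
Stochastic checks use fixed seed loops: 50 seeds for the ≤ 2 %
median-bias bound on coefficient recovery at 5 % noise, 100 seeds for
the noise-propagation bound on chromatographic recovery, 101-point
grids refined by golden-section optimisation in the MAD oracle.  The
pipeline's simulated tree defaults to 24 tips with an 8-tip DPO clade —
large enough that root-adjacency accidents cannot arise, small enough
that exhaustive-enumeration cross-checks stay instant.  Sub-seeds are
derived linearly from the master seed and kept below 2³¹.  All tests
and the acceptance script complete in seconds.
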