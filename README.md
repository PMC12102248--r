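# phosbif

Reconstruction of dissolved phosphite (P(III)) and phosphate (P(V)) in
Neoarchean–Paleoproterozoic surface seawater from the chemistry of banded
iron formations (BIFs), for geochemists and astrobiologists studying the
early-Earth phosphorus cycle.

Banded iron formations precipitated as hydrous ferric oxide (HFO) in the
photic zone, scavenging dissolved phosphorus on the way down.  For a
species with a linear sorption isotherm, the molar ratio of sorbed P to
precipitated Fe recorded by the rock ties back to the water column
through the adsorption coefficient *K*<sub>ads</sub> (µM⁻¹):

    P_ads / Fe_ads = K_ads · [P_d]        ⇒        [P_d] = (1/K_ads) · (P_ads / Fe_ads)

Because HFO sorbs phosphate far more strongly than phosphite
(*K*<sub>ads</sub> differing by factors of ~26–36 depending on the
matrix), the same rock record implies very different seawater inventories
for the two species.  The package implements the full inference chain:

* **sorption** — turn co-precipitation experiment records (with dilution
  bookkeeping) into isotherm points and fit *K*<sub>ads</sub> by OLS,
  free-intercept or through the origin (`compute_sorbed()`, `fit_kads()`,
  `kads_fold_ratio()`);
* **speciation** — quantify hypophosphite, phosphite, phosphate and
  pyrophosphate in EDTA-NaOH rock extracts from IC-ICPMS chromatograms:
  FFT low-pass smoothing, windowed peak integration over a pre/post-peak
  baseline, drift correction, calibration over 0.2–100 ppb with
  per-species detection limits, and conversion to rock-basis ppm via the
  1:10 solid:solution ratio (`fft_smooth()`, `integrate_peak()`,
  `build_calibration()`, `quantify_species()`, `extraction_yield()`);
* **paleo-seawater** — project extract speciation onto bulk rock under
  bracketing assumptions (species ratio preserved vs complete phosphite
  extraction), subtract metamorphically produced phosphite, and invert the
  isotherm per sample under five scenarios, aggregated into
  formation-level ranges (`partition_bif_phosphorus()`,
  `metamorphic_correct()`, `dissolved_concentration()`,
  `run_scenarios()`);
* **phylo** — analyse a phosphite-dehydrogenase (*ptxD*) gene tree whose
  tips are labeled by assimilatory (APO) vs dissimilatory (DPO) phosphite
  oxidation: monophyly, Fitch parsimony with free or constrained root
  state, and minimal-ancestor-deviation rooting (`fitch_min_changes()`,
  `mad_root()`);
* **synthetic data** — seeded generators for all of the above
  (`gen_sorption_dataset()`, `gen_chromatogram()`, `gen_bif_table()`,
  `gen_labeled_tree()`), so the chain is testable end to end;
* **pipeline** — `run_pipeline()` chains everything with provenance
  headers and a run log; a thin CLI lives at
  `inst/scripts/phosbif-pipeline.R`.

## Worked example

```r
library(phosbif)
out <- run_pipeline(pipeline_config("runs/demo", seed = 1))
out$fits$PIII
#> Linear sorption isotherm fit
#>   K_ads     : 0.000503937 per uM (s.e. 7.05e-06)
#>   intercept : 0 (forced through origin)
#>   r^2 = 0.9961 on 21 points
```

The phosphite isotherm fitted from the simulated silica-seawater
experiments (21 points, 5 % relative noise) recovers the generating
coefficient of 0.0005 µM⁻¹ — the weak sorption that lets phosphite stay
in seawater while phosphate is stripped.  The scenario table brackets the
seawater inventory per formation (µM; `0.000*` marks cells below 0.5 nM,
`ENP` marks scenario 5, where all phosphite is assumed metamorphic and no
primary estimate is possible):

```r
out$scenarios
#>         formation scenario            p3          p5
#>       Dales Gorge        1   0.146-1.494 0.120-0.611
#>            Joffre        1   0.002-0.007 0.006-0.016
#>  Kuruman-Gamohaan        1   0.058-0.373 0.082-0.155
#>       Marra Mamba        1   0.172-0.495 0.107-0.163
#>  ...
#>       Dales Gorge        5           ENP 0.120-0.611
```

Scenario 1 (extract ratio representative, no metamorphic phosphite) gives
the upper envelope of dissolved phosphite; scenario 4b (complete
extraction plus a 0.075 % metamorphic yield) drives most cells below the
0.5 nM rendering threshold.  The parsimony block reproduces the
evolutionary argument — with the DPO-associated genes monophyletic and
nested, an APO-associated origin needs one switch and a DPO origin two:

```r
out$phylo
#>           quantity     value
#> 1 dpo_monophyletic 1.0000000
#> 2 min_changes_free 1.0000000
#> 3  min_changes_apo 1.0000000
#> 4  min_changes_dpo 2.0000000
#> 5        mad_score 0.2996059
```

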