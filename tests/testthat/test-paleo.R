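kuruman_extreme <- list(extract_p3 = 0.37, extract_p5 = 28.4,
                        extract_pp = 0, total_p = 950, total_fe = 40)

test_that("bulk-P partition under both extraction assumptions", {
  r <- partition_bif_phosphorus(kuruman_extreme, "ratio")
  expect_equal(r[["p3_bif"]], 950 * 0.37 / 28.77, tolerance = 1e-12)
  expect_equal(r[["p3_bif"]], 12.218, tolerance = 1e-4)
  expect_equal(r[["p5_bif"]], 937.78, tolerance = 1e-4)

  cmp <- partition_bif_phosphorus(kuruman_extreme, "complete")
  expect_equal(cmp[["p3_bif"]], 0.37)
  expect_equal(cmp[["p5_bif"]], 949.63)

  # no extractable phosphite -> zero under both assumptions
  none <- list(extract_p3 = 0, extract_p5 = 10, extract_pp = 0,
               total_p = 500)
  expect_equal(partition_bif_phosphorus(none, "ratio")[["p3_bif"]], 0)
  expect_equal(partition_bif_phosphorus(none, "complete")[["p3_bif"]], 0)

  # pyrophosphate enters the ratio denominator when included
  pp <- list(extract_p3 = 1, extract_p5 = 3, extract_pp = 1, total_p = 100)
  expect_equal(partition_bif_phosphorus(pp, "ratio")[["p3_bif"]], 20)
  expect_equal(partition_bif_phosphorus(pp, "ratio",
                                        include_pp = FALSE)[["p3_bif"]], 25)

  zero <- list(extract_p3 = 0, extract_p5 = 0, extract_pp = 0, total_p = 10)
  expect_error(partition_bif_phosphorus(zero, "ratio"), "zero")
})

test_that("metamorphic correction subtracts a yield of the P(V) pool", {
  expect_equal(as.numeric(metamorphic_correct(12.218, 937.78, 0)), 12.218)
  v <- metamorphic_correct(12.218, 937.78, 0.00075)
  expect_equal(as.numeric(v), 11.515, tolerance = 1e-4)
  expect_false(attr(v, "floored"))

  fl <- metamorphic_correct(0.3, 1000, 0.00075)
  expect_equal(as.numeric(fl), 0)
  expect_true(attr(fl, "floored"))

  expect_error(metamorphic_correct(1, 1, 1.5), "yield")
})

test_that("isotherm inversion converts rock P/Fe to dissolved uM", {
  expect_equal(dissolved_concentration(0.30, 40, 0.0005),
               2.7045e-3, tolerance = 1e-4)
  expect_equal(dissolved_concentration(0, 40, 0.0005), 0)
  # inverse proportionality in K_ads
  expect_equal(dissolved_concentration(0.30, 40, 0.001) * 2,
               dissolved_concentration(0.30, 40, 0.0005))
  expect_error(dissolved_concentration(1, 0, 0.001), "fe_bif")

  # dimensional audit: the atomic masses must cancel against a pure
  # molar-basis computation
  p_ppm <- 2.5; fe_wt <- 35; kads <- 0.002
  mol_p <- p_ppm * 1e-6 / 30.974
  mol_fe <- fe_wt * 1e-2 / 55.845
  expect_equal(dissolved_concentration(p_ppm, fe_wt, kads),
               (mol_p / mol_fe) / kads, tolerance = 1e-14)
})

test_that("phosphite fraction of total dissolved inorganic P", {
  expect_equal(as.numeric(phosphite_fraction(1, 1)), 50)
  expect_equal(as.numeric(phosphite_fraction(0, 2)), 0)
  expect_equal(as.numeric(phosphite_fraction(0.15, 0.05)), 75)
  expect_warning(f <- phosphite_fraction(0, 0), "undefined")
  expect_true(is.na(f))
  expect_true(attr(f, "undefined"))
})

test_that("run_scenarios composes the three sub-operations per cell", {
  samples <- gen_bif_table(n_samples = 3, seed = 7)
  kp <- kads_pair()
  res <- run_scenarios(samples, kads = kp,
                       scenarios = c("1", "2b", "3", "4b", "5"))

  # manual composition oracle on a single sample x scenario
  smp <- samples[2, ]
  for (sc in list(list(id = "1", assum = "ratio", yield = 0),
                  list(id = "2b", assum = "ratio", yield = 0.00075),
                  list(id = "3", assum = "complete", yield = 0),
                  list(id = "4b", assum = "complete", yield = 0.00075))) {
    part <- partition_bif_phosphorus(smp, sc$assum)
    p3p <- metamorphic_correct(part[["p3_bif"]], part[["p5_bif"]], sc$yield)
    want_p3 <- dissolved_concentration(as.numeric(p3p), smp$total_fe,
                                       kp$kads_p3)
    want_p5 <- dissolved_concentration(part[["p5_bif"]], smp$total_fe,
                                       kp$kads_p5)
    row <- res$per_sample[res$per_sample$sample_id == smp$sample_id &
                            res$per_sample$scenario == sc$id, ]
    expect_equal(row$p3_dissolved_uM, want_p3, tolerance = 1e-12)
    expect_equal(row$p5_dissolved_uM, want_p5, tolerance = 1e-12)
  }

  expect_error(run_scenarios(samples, scenarios = "6"), "unknown scenario")
  expect_error(run_scenarios(samples, scenarios = "2a"),
               "experimental_yield")
})

test_that("scenario 5 always yields zero phosphite, flagged", {
  for (s in c(1, 5, 9)) {
    samples <- gen_bif_table(n_samples = 4, seed = s)
    res <- run_scenarios(samples, scenarios = "5")
    expect_true(all(res$per_sample$p3_dissolved_uM == 0))
    expect_true(all(res$per_sample$p3_not_possible))
    expect_true(all(res$rendered$p3 == "ENP"))
  }
})

test_that("scenario identities, monotonicity and ordering invariance", {
  samples <- gen_bif_multiformation(seed = 4)
  res <- run_scenarios(samples, scenarios = c("1", "2a", "2b", "3", "4b"),
                       experimental_yield = 0)
  ps <- res$per_sample

  # scenario 2 with yield forced to 0 equals scenario 1
  s1 <- ps[ps$scenario == "1", "p3_dissolved_uM"]
  s2 <- ps[ps$scenario == "2a", "p3_dissolved_uM"]
  expect_equal(s1, s2, tolerance = 1e-14)

  # metamorphic correction can only lower phosphite: 2b <= 1, 4b <= 3
  s2b <- ps[ps$scenario == "2b", "p3_dissolved_uM"]
  s3 <- ps[ps$scenario == "3", "p3_dissolved_uM"]
  s4b <- ps[ps$scenario == "4b", "p3_dissolved_uM"]
  expect_true(all(s2b <= s1 + 1e-14))
  expect_true(all(s4b <= s3 + 1e-14))

  # complete extraction <= ratio scaling whenever extract_p3 <= ratio p3_bif
  idx <- order(samples$formation, samples$sample_id)
  ord <- samples[idx, ]
  ratio_p3 <- mapply(function(i) {
    partition_bif_phosphorus(ord[i, ], "ratio")[["p3_bif"]]
  }, seq_len(nrow(ord)))
  stopifnot(all(ord$extract_p3 <= ratio_p3))  # true for Table-1-like draws
  expect_true(all(s3 <= s1 + 1e-14))

  # formation brackets contain every per-sample value
  for (r in seq_len(nrow(res$formation_table))) {
    ft <- res$formation_table[r, ]
    sub <- ps[ps$formation == ft$formation & ps$scenario == ft$scenario, ]
    expect_true(all(sub$p3_dissolved_uM >= ft$p3_min - 1e-15 &
                      sub$p3_dissolved_uM <= ft$p3_max + 1e-15))
    expect_true(all(sub$p5_dissolved_uM >= ft$p5_min - 1e-15 &
                      sub$p5_dissolved_uM <= ft$p5_max + 1e-15))
  }

  # sample order must not matter
  shuffled <- samples[rev(seq_len(nrow(samples))), ]
  res2 <- run_scenarios(shuffled, scenarios = c("1", "2a", "2b", "3", "4b"),
                        experimental_yield = 0)
  expect_equal(res$per_sample, res2$per_sample, tolerance = 1e-14)
  expect_equal(res$formation_table, res2$formation_table, tolerance = 1e-14)
})

test_that("rendering rounds to 3 decimals and stars sub-0.5 nM cells", {
  samples <- data.frame(
    sample_id = c("a", "b"), formation = "F",
    extract_p3 = c(0.0001, 0.3), extract_p5 = c(10, 10),
    extract_pp = 0, total_p = c(100, 100), total_fe = c(40, 40))
  res <- run_scenarios(samples, scenarios = "1")
  low <- res$per_sample$p3_dissolved_uM[1]
  expect_lt(low, 0.0005)
  expect_match(res$rendered$p3[1], "^0\\.000\\*")
})
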