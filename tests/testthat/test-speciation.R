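test_that("fft_smooth passes DC and passband, attenuates noise", {
  n <- 512
  expect_equal(fft_smooth(rep(7, n)), rep(7, n), tolerance = 1e-10)

  # integer-cycle sinusoid below the cutoff survives unchanged
  t <- 0:(n - 1)
  slow <- sin(2 * pi * 8 * t / n)            # 8/512 Hz << 0.2 Hz cutoff
  expect_equal(fft_smooth(slow, dt = 1), slow, tolerance = 1e-6)

  # white noise loses variance; matches a direct frequency-domain filter
  set.seed(99)
  x <- rnorm(n)
  sm <- fft_smooth(x, window_points = 5, dt = 1)
  expect_lt(var(sm), var(x))
  keep <- abs(ifelse(0:(n - 1) <= n / 2, 0:(n - 1), 0:(n - 1) - n) / n) <= 1 / 5
  direct <- Re(fft(fft(x) * keep, inverse = TRUE)) / n
  expect_equal(sm, direct, tolerance = 1e-10)

  expect_error(fft_smooth(rnorm(50), window_points = 4), "odd")
  expect_error(fft_smooth(rnorm(8), window_points = 5), "too short")
  expect_error(fft_smooth(rnorm(50), time = c(1:49, 51)), "uniform")
})

test_that("integrate_peak recovers Gaussian areas over a baseline", {
  tm <- seq(0, 180, by = 1)
  wins <- list(g = list(pre = c(0, 60), peak = c(60, 120),
                        post = c(120, 180)))

  # flat trace at any level integrates to zero
  flat <- chromatogram(tm, rep(123.4, length(tm)), wins)
  expect_equal(as.numeric(integrate_peak(flat, "g")), 0, tolerance = 1e-8)

  # amplitude 100, sigma 5 -> closed-form area 100 * 5 * sqrt(2*pi)
  g <- 100 * exp(-(tm - 90)^2 / (2 * 5^2))
  ch <- chromatogram(tm, g, wins)
  expect_equal(as.numeric(integrate_peak(ch, "g")),
               100 * 5 * sqrt(2 * pi), tolerance = 0.5 / 1253)

  # invariance under adding a constant to the whole trace
  ch2 <- chromatogram(tm, g + 300, wins)
  expect_equal(as.numeric(integrate_peak(ch2, "g")),
               as.numeric(integrate_peak(ch, "g")), tolerance = 1e-8)

  # negative area floored and flagged
  dip <- chromatogram(tm, 100 - g, wins)
  a <- integrate_peak(dip, "g")
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "floored"))

  expect_error(integrate_peak(ch, "missing"), "no windows")
  bad <- chromatogram(tm, g, list(g = list(pre = c(-60, 0), peak = c(0, 60),
                                           post = c(60, 120))))
  expect_error(integrate_peak(bad, "g"), "outside")
})

test_that("generator round trip: area equals response_factor * concentration", {
  sp <- data.frame(name = "phosphite", retention_time = 270,
                   true_concentration = 3, response_factor = 500)
  ch <- gen_chromatogram(sp, noise_sd = 0, seed = 1)
  area <- as.numeric(integrate_peak(ch, "phosphite"))
  expect_equal(area, 500 * 3, tolerance = 0.005)
})

test_that("drift correction interpolates run-order sensitivity factors", {
  checks <- data.frame(time = c(0, 10), expected = c(100, 100),
                       measured = c(100, 100))
  expect_equal(drift_correct(c(5, 7), c(2, 8), checks), c(5, 7))

  drift <- data.frame(time = c(0, 10), expected = c(100, 100),
                      measured = c(100, 80))
  expect_equal(drift_correct(90, 5, drift), 100)

  half <- data.frame(time = c(0, 10), expected = c(100, 100),
                     measured = c(50, 50))
  expect_equal(drift_correct(c(10, 20), c(1, 9), half), c(20, 40))

  expect_error(drift_correct(1, 11, checks), "bracket")
  neg <- data.frame(time = c(0, 10), expected = c(100, 100),
                    measured = c(100, -1))
  expect_error(drift_correct(1, 5, neg), "> 0")
})

test_that("calibration fitting and inversion follow the standards", {
  stds <- data.frame(concentration = c(0.2, 1, 5, 20, 100))
  stds$area <- 50 * stds$concentration
  cal <- build_calibration(stds, "phosphate")
  expect_equal(cal$slope, 50, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1)

  # per-species default detection limits
  expect_equal(build_calibration(stds, "phosphite")$detection_limit, 0.1)
  expect_equal(build_calibration(stds, "pyrophosphate")$detection_limit, 0.2)

  # duplicate standards averaged when requested
  dup <- rbind(stds, data.frame(concentration = 5, area = 260))
  avg <- build_calibration(dup, "phosphate", average_duplicates = TRUE)
  expect_equal(length(avg$standard_concentrations), 5L)

  inv <- data.frame(concentration = c(1, 2, 3), area = c(30, 20, 10))
  expect_error(build_calibration(inv, "phosphate"), "slope")
  expect_error(build_calibration(stds[1:2, ], "phosphate"), ">= 3")

  q <- quantify_species(1500, cal, ml_per_g = 10)
  expect_equal(q$extract_ppb, 30)
  expect_equal(q$rock_ppm, 0.30)
  expect_false(q$censored)

  q0 <- quantify_species(cal$intercept, cal)
  expect_equal(q0$extract_ppb, 0)
  expect_true(q0$censored)
  qc <- quantify_species(0.05 * cal$slope, cal)   # 0.05 ppb < DL 0.1
  expect_true(qc$censored)
  expect_match(qc$label, "^< ")
})

test_that("extraction yield sums uncensored species against bulk P", {
  expect_equal(as.numeric(extraction_yield(c(1, 1.5, 0.5), 100)), 3.0)
  expect_equal(as.numeric(extraction_yield(c(5, 2.52), 20)), 37.6)

  cen <- extraction_yield(c(1, 2), 100, censored = c(TRUE, TRUE))
  expect_equal(as.numeric(cen), 0)
  expect_true(attr(cen, "all_censored"))

  # scale invariance
  y1 <- extraction_yield(c(1, 2, 0.3), 50)
  y2 <- extraction_yield(2 * c(1, 2, 0.3), 100)
  expect_equal(as.numeric(y1), as.numeric(y2))

  # molecular pyrophosphate counted as two P when configured
  v <- c(phosphite = 1, pyrophosphate = 2)
  expect_equal(as.numeric(extraction_yield(v, 100, pp_factor = 2)), 5)
})

test_that("chromatogram pipeline recovers true concentrations", {
  sp <- data.frame(
    name = c("phosphite", "phosphate"),
    retention_time = c(270, 450),
    true_concentration = c(3, 40),
    response_factor = c(500, 480))
  stds_conc <- c(0.2, 1, 5, 20, 100)

  # zero noise: within 1%
  ch <- gen_chromatogram(sp, noise_sd = 0, seed = 1)
  for (i in 1:2) {
    stds <- data.frame(concentration = stds_conc,
                       area = sp$response_factor[i] * stds_conc)
    cal <- build_calibration(stds, sp$name[i])
    q <- quantify_species(as.numeric(integrate_peak(ch, sp$name[i])), cal)
    expect_equal(q$extract_ppb, sp$true_concentration[i],
                 tolerance = 0.01)
  }

  # with noise: recovered concentration within 3 noise-propagated sd.
  # area noise sd ~ noise_sd * sqrt(n_peak + n_peak^2/n_bg) * dt
  noise_sd <- 2
  n_peak <- 60; n_bg <- 120
  area_sd <- noise_sd * sqrt(n_peak + n_peak^2 / n_bg)
  errs <- vapply(1:100, function(s) {
    chn <- gen_chromatogram(sp[2, ], noise_sd = noise_sd, seed = s)
    stds <- data.frame(concentration = stds_conc,
                       area = sp$response_factor[2] * stds_conc)
    cal <- build_calibration(stds, "phosphate")
    q <- quantify_species(as.numeric(integrate_peak(chn, "phosphate")), cal)
    q$extract_ppb - 40
  }, numeric(1))
  conc_sd <- area_sd / sp$response_factor[2]
  expect_lt(max(abs(errs)), 3 * conc_sd * 1.5)  # headroom for smoothing
  expect_lt(abs(mean(errs)), 3 * conc_sd / sqrt(100) * 2)
})
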