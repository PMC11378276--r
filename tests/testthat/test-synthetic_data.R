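test_that("the standard panel matches the published anion masses", {
  panel <- standard_panel()
  expect_equal(nrow(panel), 10L)
  printed <- c("cyclopentanecarboxylic acid" = 113.06,
               "benzoic acid" = 121.03,
               "cyclohexanebutyric acid" = 169.12,
               "1-naphthoic acid" = 171.05,
               "9-anthracenecarboxylic acid" = 221.06,
               "pentadecanoic acid" = 241.22,
               "decanoic acid" = 171.14,
               "3,5-dimethyladamantane-1-carboxylic acid" = 207.14,
               "3,5-dimethyladamantane-1-acetic acid" = 221.15,
               "2-methyloctadecanoic acid" = 297.28)
  expect_equal(round(panel$mz_anion, 2), unname(printed[panel$name]))
  expect_true(all(panel$response_factor > 0))
  # all ten are O2 acids with even hydrogen counts
  expect_true(all(panel$o == 2))
  expect_true(all(panel$h %% 2 == 0))
})

test_that("make_design builds the concentration design", {
  d <- make_design()
  expect_equal(nrow(d), 36L)
  expect_equal(range(d$concentration), c(0.50, 40.00))
  expect_equal(length(unique(d$concentration)), 12L)
  expect_equal(make_design(5, 2)$concentration, c(5, 5))
  expect_error(make_design(replicates = 0), class = "naquant_domain_error")
  expect_error(make_design(c(5, -1)), class = "naquant_domain_error")
  expect_error(simulation_params(sigma_ppm = -1, seed = 1),
               class = "naquant_domain_error")
  expect_error(simulation_params(), class = "naquant_domain_error")
})

test_that("noise-free spectra are exact and proportional to concentration", {
  p0 <- simulation_params(sigma_ppm = 0, intensity_cv = 0,
                          n_baseline_peaks = 0, seed = 1)
  panel <- standard_panel()
  s <- simulate_spectrum(10, p0)
  expect_equal(length(s$mz), 10L)
  expect_equal(s$mz, sort(panel$mz_anion))
  expect_equal(s$intensity,
               panel$response_factor[order(panel$mz_anion)])
  # doubling concentration doubles every peak exactly
  s2 <- simulate_spectrum(20, p0)
  expect_equal(s2$intensity, 2 * s$intensity)
  # zero concentration, zero baseline -> empty (no zero-intensity peaks kept)
  expect_equal(length(simulate_spectrum(0, p0)$mz), 0L)
  expect_error(simulate_spectrum(-1, p0), class = "naquant_domain_error")
})

test_that("equimolar sharing gives equal moles and conserves total mass", {
  p0 <- simulation_params(sigma_ppm = 0, intensity_cv = 0,
                          n_baseline_peaks = 0, seed = 1)
  panel <- standard_panel()
  s <- simulate_spectrum(10, p0, share = "equimolar")
  ord <- order(panel$mz_anion)
  conc_i <- s$intensity / panel$response_factor[ord]
  expect_equal(sum(conc_i), 10)
  moles <- conc_i / panel$neutral_mass[ord]
  expect_equal(max(moles) / min(moles), 1, tolerance = 1e-9)
})

test_that("simulation is seed-deterministic", {
  p <- simulation_params(seed = 77)
  s1 <- simulate_spectrum(10, p)
  s2 <- simulate_spectrum(10, p)
  expect_identical(s1, s2)
  ds1 <- simulate_dataset(make_design(c(1, 20), 2), p)
  ds2 <- simulate_dataset(make_design(c(1, 20), 2), p)
  expect_identical(ds1, ds2)
  # different sub-streams per sample: replicates differ
  expect_false(identical(ds1$spectra[[1]]$intensity,
                         ds1$spectra[[2]]$intensity))
})

test_that("dataset-level structure: shared background, matching y", {
  p <- simulation_params(seed = 5, n_baseline_peaks = 20)
  ds <- simulate_dataset(make_design(), p)
  expect_equal(length(ds$spectra), 36L)
  expect_equal(range(ds$y), c(0.50, 40.00))
  # background ions are a shared panel: occupied bins far fewer than if each
  # spectrum drew its own 20 positions
  am <- align_spectra(ds$spectra)
  expect_lt(ncol(am$X), 36 * 20 / 2)
})

test_that("real-sample mode adds interferents away from standard masses", {
  p <- simulation_params(seed = 9, n_baseline_peaks = 0, n_interferents = 50)
  s <- simulate_spectrum(10, p, mode = "real_sample")
  expect_gt(length(s$mz), 10 + 40)
  panel <- standard_panel()
  extra <- s$mz[vapply(s$mz, function(m)
    min(abs(m - panel$mz_anion)) > 1e-3, logical(1))]
  # every interferent stays > 0.005 Th from every standard mass (up to the
  # 1 ppm jitter, far below 0.005 at m/z < 400)
  expect_true(all(vapply(extra, function(m)
    min(abs(m - panel$mz_anion)) > 0.004, logical(1))))
})

test_that("standard-peak mass errors stay within +/-4 sigma", {
  p <- simulation_params(sigma_ppm = 2, intensity_cv = 0,
                         n_baseline_peaks = 0, seed = 123)
  panel <- standard_panel()
  theo <- sort(panel$mz_anion)
  errs <- unlist(lapply(1:1000, function(i) {
    pi <- p; pi$seed <- i
    s <- simulate_spectrum(10, pi)
    (s$mz - theo) / theo * 1e6
  }))
  expect_equal(length(errs), 10000L)
  expect_lt(max(abs(errs)), 4 * 2)
  expect_equal(sd(errs), 2, tolerance = 0.05)
})
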