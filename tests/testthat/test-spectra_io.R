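test_that("peak-list CSV parsing: direct parse, sorting, validation", {
  p <- write_peaklist(c(121.0295, 241.2173), c(1000, 500))
  s <- read_spectrum(p)
  expect_s3_class(s, "spectrum")
  expect_equal(s$mz, c(121.0295, 241.2173))
  expect_equal(s$intensity, c(1000, 500))

  # out-of-order rows come back sorted ascending
  p2 <- write_peaklist(c(300.2, 150.1, 210.7), c(1, 2, 3))
  expect_equal(read_spectrum(p2)$mz, c(150.1, 210.7, 300.2))

  # header row is tolerated
  p3 <- write_peaklist(c(100.5, 200.5), c(10, 20), header = TRUE)
  expect_equal(read_spectrum(p3)$intensity, c(10, 20))

  # invariant violations
  expect_error(read_spectrum(write_peaklist(150.1, -5)), class = "naquant_format_error")
  p4 <- tempfile(fileext = ".csv"); writeLines("a,b\nx,y", p4)
  expect_error(read_spectrum(p4), class = "naquant_format_error")

  # zero-intensity peaks are dropped
  s5 <- read_spectrum(write_peaklist(c(100.5, 101.5), c(0, 7)))
  expect_equal(s5$mz, 101.5)
})

test_that("mzML reading: centroided scans, multi-scan averaging, profile refusal", {
  mz <- c(113.0608, 241.2173); it <- c(250, 1000)
  s <- read_spectrum(write_mzml(list(list(mz = mz, intensity = it))))
  expect_equal(s$mz, round(mz, 6))
  expect_equal(s$intensity, it)

  # two scans are summed peak-wise then divided by scan count
  s2 <- read_spectrum(write_mzml(list(
    list(mz = mz, intensity = it),
    list(mz = mz, intensity = c(350, 800)))))
  expect_equal(s2$intensity, c((250 + 350) / 2, (1000 + 800) / 2))

  expect_error(
    read_spectrum(write_mzml(list(list(mz = mz, intensity = it)),
                             centroided = FALSE)),
    class = "naquant_unsupported_mode_error")
})

test_that("bin_spectrum: floor indexing, bin sharing, half-open boundary", {
  s <- spectrum(c(150.0004, 150.0006), c(10, 20))
  b <- bin_spectrum(s, 100, 400, 0.001)
  expect_equal(b$bin, 50000L)
  expect_equal(b$intensity, 30)

  # a peak exactly at mz_max is discarded (half-open interval)
  s2 <- spectrum(c(399.9995, 400), c(5, 7))
  b2 <- bin_spectrum(s2, 100, 400, 0.001)
  expect_equal(b2$bin, 299999L)
  expect_equal(b2$intensity, 5)

  # empty input -> empty map
  expect_equal(nrow(bin_spectrum(spectrum(500.1, 3), 100, 400, 0.001)), 0L)

  # decimal-safe arithmetic: printed 3-decimal values land in their own bin
  s3 <- spectrum(c(121.029, 121.030), c(1, 1))
  expect_equal(bin_spectrum(s3, 100, 400, 0.001)$bin, c(21029L, 21030L))
})

test_that("binning conserves total in-range intensity and is idempotent", {
  set.seed(5)
  for (i in 1:20) {
    s <- spectrum(runif(50, 90, 420), rexp(50, 1 / 100))
    b <- bin_spectrum(s, 100, 400, 0.001)
    in_range <- s$mz >= 100 & s$mz < 400
    expect_equal(sum(b$intensity), sum(s$intensity[in_range]))
  }
  # re-binning a bin-centered spectrum at the same grid is the identity
  s <- spectrum(runif(30, 100, 400), rexp(30, 1 / 10))
  b <- bin_spectrum(s, 100, 400, 0.001)
  centered <- spectrum(100 + (b$bin + 0.5) * 0.001, b$intensity)
  b2 <- bin_spectrum(centered, 100, 400, 0.001)
  expect_equal(b2, b)
})

test_that("align_spectra builds the occupied-bin union matrix", {
  s1 <- spectrum(150.5004, 10, sample_id = "a")
  s2 <- spectrum(250.2504, 20, sample_id = "b")
  am <- align_spectra(list(s1, s2))
  expect_equal(dim(am$X), c(2L, 2L))
  expect_equal(unname(am$X), matrix(c(10, 0, 0, 20), 2, byrow = TRUE))
  expect_equal(am$sample_ids, c("a", "b"))
  # bin centers: mz_min + (index + 0.5) * resolution
  expect_equal(am$bin_centers,
               100 + (am$grid$occupied_bins + 0.5) * 0.001)

  # identical spectra -> identical rows
  am3 <- align_spectra(list(s1, s1, s1))
  expect_equal(dim(am3$X), c(3L, 1L))
  expect_true(all(am3$X == 10))

  expect_error(align_spectra(list(spectrum(500.2, 5))),
               class = "naquant_empty_matrix_error")

  # row totals equal each spectrum's in-range intensity
  ds <- quiet_dataset(seed = 3, n_baseline = 5, intensity_cv = 0.1)
  am4 <- align_spectra(ds$spectra)
  totals <- vapply(ds$spectra, function(s)
    sum(s$intensity[s$mz >= 100 & s$mz < 400]), numeric(1))
  expect_equal(unname(rowSums(am4$X)), totals)
  # never more columns than the grid allows
  expect_lte(ncol(am4$X), floor((400 - 100) / 0.001) + 1)
})

test_that("36 noise-free standard spectra occupy exactly 10 bins", {
  ds <- quiet_dataset(seed = 2)
  am <- align_spectra(ds$spectra)
  expect_equal(ncol(am$X), 10L)
})

test_that("aligned CSV export and manifest reading round-trip", {
  ds <- quiet_dataset(seed = 4, levels = c(1, 10), replicates = 1)
  am <- align_spectra(ds$spectra)
  out <- tempfile(fileext = ".csv")
  write_aligned_csv(am, out)
  back <- utils::read.csv(out, check.names = FALSE)
  expect_equal(dim(back), c(2L, 11L))
  expect_equal(back$sample_id, am$sample_ids)

  d <- tempfile(); dir.create(d)
  p1 <- file.path(d, "s1.csv")
  utils::write.table(data.frame(150.5, 10), p1, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  man <- data.frame(sample_id = "s1", path = "s1.csv", role = "unknown")
  mf <- file.path(d, "manifest.csv")
  utils::write.csv(man, mf, row.names = FALSE)
  got <- read_manifest(mf)
  expect_true(file.exists(got$path[1]))
  expect_equal(got$dilution_factor, 1)
  man$role <- "mystery"
  utils::write.csv(man, mf, row.names = FALSE)
  expect_error(read_manifest(mf), class = "naquant_manifest_error")
})
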