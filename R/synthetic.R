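# Monoisotopic masses (u) and the electron mass; shared with the formula
# assignment module.
.MASS_C <- 12
.MASS_H <- 1.00782503
.MASS_O <- 15.9949146
.MASS_E <- 0.00054858

neutral_mass <- function(c, h, o) c * .MASS_C + h * .MASS_H + o * .MASS_O

# [M-H]-: lose a proton but keep its electron; the 0.55 mDa electron term
# matters at 3 ppm below m/z 200.
anion_mass <- function(c, h, o) c * .MASS_C + (h - 1) * .MASS_H + o * .MASS_O + .MASS_E

#' The ten-acid calibration standard panel
#'
#' The carboxylic-acid standards used to prepare simulated produced water,
#' with neutral CHO formulas, theoretical deprotonated ([M-H]-) masses, and
#' fixed compound-specific ESI(-) response factors (counts per mg/L of that
#' compound). Response factors differ by compound because electrospray
#' ionization efficiency does; the values are arbitrary but fixed.
#'
#' @return data.frame with columns `name`, `c`, `h`, `o`, `formula`,
#'   `neutral_mass`, `mz_anion`, `response_factor`.
#' @export
standard_panel <- function() {
  df <- data.frame(
    name = c("cyclopentanecarboxylic acid", "benzoic acid",
             "cyclohexanebutyric acid", "1-naphthoic acid",
             "9-anthracenecarboxylic acid", "pentadecanoic acid",
             "decanoic acid", "3,5-dimethyladamantane-1-carboxylic acid",
             "3,5-dimethyladamantane-1-acetic acid",
             "2-methyloctadecanoic acid"),
    c = c(6L, 7L, 10L, 11L, 15L, 15L, 10L, 13L, 14L, 19L),
    h = c(10L, 6L, 18L, 8L, 10L, 30L, 20L, 20L, 22L, 38L),
    o = rep(2L, 10),
    response_factor = c(1.6, 0.7, 1.3, 0.9, 0.8, 1.8, 1.5, 1.1, 1.0, 2.0) * 1e6,
    stringsAsFactors = FALSE)
  df$formula <- sprintf("C%dH%dO%d", df$c, df$h, df$o)
  df$neutral_mass <- neutral_mass(df$c, df$h, df$o)
  df$mz_anion <- anion_mass(df$c, df$h, df$o)
  df[, c("name", "c", "h", "o", "formula", "neutral_mass", "mz_anion",
         "response_factor")]
}

#' Simulation parameters
#'
#' @param sigma_ppm SD of the per-peak mass error (ppm).
#' @param intensity_cv relative SD of per-peak multiplicative intensity noise.
#' @param n_baseline_peaks number of chemical-background ions.
#' @param baseline_intensity_scale mean background-ion intensity (counts).
#' @param n_interferents extra matrix ions added in `real_sample` mode.
#' @param interferent_intensity_scale mean interferent intensity (counts).
#' @param seed mandatory integer seed for every stochastic call.
#' @return list of class `"simulation_params"`.
#' @export
simulation_params <- function(sigma_ppm = 1, intensity_cv = 0.05,
                              n_baseline_peaks = 100,
                              baseline_intensity_scale = 1e6,
                              n_interferents = 150,
                              interferent_intensity_scale = 5e5,
                              seed) {
  if (missing(seed) || is.null(seed))
    stop_naquant("seed is mandatory", class = "naquant_domain_error")
  vals <- c(sigma_ppm, intensity_cv, n_baseline_peaks,
            baseline_intensity_scale, n_interferents,
            interferent_intensity_scale)
  if (any(vals < 0))
    stop_naquant("simulation parameters must be nonnegative",
                 class = "naquant_domain_error")
  structure(list(sigma_ppm = sigma_ppm, intensity_cv = intensity_cv,
                 n_baseline_peaks = as.integer(n_baseline_peaks),
                 baseline_intensity_scale = baseline_intensity_scale,
                 n_interferents = as.integer(n_interferents),
                 interferent_intensity_scale = interferent_intensity_scale,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Calibration design
#'
#' Default levels are the twelve standard-mixture concentrations
#' 0.50-40.00 mg/L with three replicates each (36 samples).
#'
#' @param levels total NA concentrations (mg/L), each >= 0.
#' @param replicates replicates per level, >= 1.
#' @return data.frame with `sample_id`, `level`, `replicate`,
#'   `concentration`.
#' @export
make_design <- function(levels = c(0.50, 4.10, 7.68, 11.27, 14.86, 18.45,
                                   22.05, 25.63, 29.23, 32.82, 36.41, 40.00),
                        replicates = 3) {
  if (!length(levels) || any(levels < 0))
    stop_naquant("levels must be nonempty and nonnegative",
                 class = "naquant_domain_error")
  if (replicates < 1)
    stop_naquant("replicates must be >= 1", class = "naquant_domain_error")
  lev <- rep(seq_along(levels), each = replicates)
  rep_i <- rep(seq_len(replicates), times = length(levels))
  data.frame(
    sample_id = sprintf("L%02d_r%d", lev, rep_i),
    level = lev, replicate = rep_i,
    concentration = levels[lev],
    stringsAsFactors = FALSE)
}

# Draw a shared background panel (contaminant ion m/z + base intensities).
# In real direct-infusion spectra the chemical background is a reproducible
# set of ions, so a dataset shares one panel; per-sample variation is applied
# in simulate_spectrum.
draw_background_panel <- function(n, scale, mz_min, mz_max,
                                  exclude_mz = numeric(0), exclude_width = 0.005) {
  if (n == 0) return(data.frame(mz = numeric(0), base = numeric(0)))
  mz <- numeric(0)
  while (length(mz) < n) {
    cand <- stats::runif(n, mz_min, mz_max)
    if (length(exclude_mz)) {
      ok <- vapply(cand, function(m) all(abs(m - exclude_mz) > exclude_width),
                   logical(1))
      cand <- cand[ok]
    }
    mz <- c(mz, cand)
  }
  mz <- mz[seq_len(n)]
  data.frame(mz = mz, base = stats::rexp(n, rate = 1 / scale))
}

#' Simulate one direct-infusion ESI(-) spectrum
#'
#' Each standard contributes one [M-H]- peak at `mz_anion * (1 + e/1e6)`,
#' `e ~ N(0, sigma_ppm)`, with intensity `response_factor * per-compound
#' concentration * max(0, 1 + N(0, intensity_cv))`. The total concentration is
#' shared across the ten standards either by equal mass (default) or
#' equimolarly. Background ions (and, in `real_sample` mode, abundant
#' interferent ions kept at least 0.005 Th away from any standard mass) are
#' added on top; their m/z panel can be supplied via `background` /
#' `interferents` so that a dataset shares one reproducible background.
#'
#' @param concentration total NA concentration (mg/L), >= 0.
#' @param params a [simulation_params()].
#' @param mode `"standard_mix"` or `"real_sample"`.
#' @param share `"equal_mass"`: each compound at `concentration/10`;
#'   `"equimolar"`: equal moles, mass share proportional to molar mass.
#' @param panel standard panel (default [standard_panel()]).
#' @param mz_min,mz_max simulated m/z range.
#' @param sample_id sample identifier.
#' @param dilution_factor carried into the spectrum metadata.
#' @param background,interferents optional pre-drawn panels
#'   (data.frame `mz`, `base`); drawn from `params$seed` when `NULL`.
#' @return A [spectrum()].
#' @export
simulate_spectrum <- function(concentration, params,
                              mode = c("standard_mix", "real_sample"),
                              share = c("equal_mass", "equimolar"),
                              panel = standard_panel(),
                              mz_min = 100, mz_max = 400,
                              sample_id = "sim", dilution_factor = 1,
                              background = NULL, interferents = NULL) {
  mode <- match.arg(mode)
  share <- match.arg(share)
  stopifnot(inherits(params, "simulation_params"))
  if (concentration < 0)
    stop_naquant("concentration must be >= 0", class = "naquant_domain_error")
  with_seed(params$seed, {
    if (is.null(background))
      background <- draw_background_panel(params$n_baseline_peaks,
                                          params$baseline_intensity_scale,
                                          mz_min, mz_max)
    if (mode == "real_sample" && is.null(interferents))
      interferents <- draw_background_panel(params$n_interferents,
                                            params$interferent_intensity_scale,
                                            mz_min, mz_max,
                                            exclude_mz = panel$mz_anion)
    conc_i <- switch(share,
      equal_mass = rep(concentration / nrow(panel), nrow(panel)),
      equimolar  = concentration * panel$neutral_mass / sum(panel$neutral_mass))
    e <- stats::rnorm(nrow(panel), 0, params$sigma_ppm)
    mz_std <- panel$mz_anion * (1 + e / 1e6)
    it_std <- panel$response_factor * conc_i *
      pmax(0, 1 + stats::rnorm(nrow(panel), 0, params$intensity_cv))
    noise_fac <- function(n) pmax(0, 1 + stats::rnorm(n, 0, params$intensity_cv))
    mz_bg <- background$mz * (1 + stats::rnorm(nrow(background), 0,
                                               params$sigma_ppm) / 1e6)
    it_bg <- background$base * noise_fac(nrow(background))
    mz <- c(mz_std, mz_bg); it <- c(it_std, it_bg)
    if (mode == "real_sample") {
      mz_if <- interferents$mz * (1 + stats::rnorm(nrow(interferents), 0,
                                                   params$sigma_ppm) / 1e6)
      it_if <- interferents$base * noise_fac(nrow(interferents))
      mz <- c(mz, mz_if); it <- c(it, it_if)
    }
    keep <- mz >= mz_min & mz < mz_max
    spectrum(mz[keep], it[keep], sample_id = sample_id,
             dilution_factor = dilution_factor)
  })
}

#' Simulate a complete calibration dataset
#'
#' One spectrum per design row, each drawn from a deterministic per-sample
#' sub-stream of `params$seed`; the background (and interferent) ion panel is
#' drawn once from the master seed and shared across samples.
#'
#' Spectra measured in one session share their chemical background, so pass
#' a calibration dataset's `background` when simulating unknowns that the
#' calibrated model will predict.
#'
#' @param design a [make_design()] data.frame.
#' @param params a [simulation_params()].
#' @inheritParams simulate_spectrum
#' @return list with `spectra` (list of [spectrum()]), `y` (concentration
#'   vector, mg/L), `design`, and the `background` / `interferents` panels
#'   used (reusable in later calls).
#' @export
simulate_dataset <- function(design = make_design(), params,
                             mode = c("standard_mix", "real_sample"),
                             share = c("equal_mass", "equimolar"),
                             panel = standard_panel(),
                             mz_min = 100, mz_max = 400,
                             background = NULL, interferents = NULL) {
  mode <- match.arg(mode)
  share <- match.arg(share)
  stopifnot(inherits(params, "simulation_params"))
  bg <- background %||% with_seed(params$seed,
    draw_background_panel(params$n_baseline_peaks,
                          params$baseline_intensity_scale, mz_min, mz_max))
  intf <- if (!is.null(interferents)) interferents
  else if (mode == "real_sample")
    with_seed(derive_seed(params$seed, 999983L),
      draw_background_panel(params$n_interferents,
                            params$interferent_intensity_scale,
                            mz_min, mz_max, exclude_mz = panel$mz_anion))
  else NULL
  spectra <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    p_i <- params
    p_i$seed <- derive_seed(params$seed, i)
    spectra[[i]] <- simulate_spectrum(
      design$concentration[i], p_i, mode = mode, share = share, panel = panel,
      mz_min = mz_min, mz_max = mz_max, sample_id = design$sample_id[i],
      background = bg, interferents = intf)
  }
  list(spectra = spectra, y = design$concentration, design = design,
       background = bg, interferents = intf)
}
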