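#' Default pipeline configuration
#'
#' Binning range m/z 100-400 at 0.001 Th, sum normalization with autoscaling,
#' latent variables 1-10 chosen by Monte-Carlo leave-3-out CV (200 splits),
#' OPS window 20 / increment 5 / 100 percent scanned, 24 + 12 calibration /
#' prediction split.
#'
#' @param ... named overrides of any default.
#' @return Named list of settings.
#' @export
default_config <- function(...) {
  cfg <- list(mz_min = 100, mz_max = 400, resolution = 0.001,
              normalization = "sum", scaling = "autoscale",
              lv_grid = 1:10, leave_out = 3, n_splits = 200,
              ops_window = 20, ops_increment = 5, ops_percent = 100,
              ops_kind = "regression",
              n_cal = 24, n_pred = 12, seed = 1)
  utils::modifyList(cfg, list(...))
}

#' Split samples into calibration and prediction sets
#'
#' Random split stratified on concentration level so both sets span the
#' modeled range: samples are grouped by level, calibration quotas are
#' allocated proportionally (largest-remainder rounding), and the lowest and
#' highest levels are guaranteed at least one calibration sample (and one
#' prediction sample when they have replicates to spare). With fewer than two
#' distinct levels a plain random split is drawn with a warning.
#'
#' @param y concentration vector.
#' @param n_cal,n_pred set sizes; must sum to `length(y)`.
#' @param seed RNG seed.
#' @return list with integer index vectors `calibration` and `prediction`.
#' @export
split_samples <- function(y, n_cal = 24, n_pred = 12, seed = 1) {
  n <- length(y)
  if (n_cal + n_pred != n)
    stop_naquant("n_cal + n_pred must equal the number of samples",
                 class = "naquant_domain_error")
  with_seed(seed, {
    levels <- sort(unique(y))
    if (length(levels) < 2) {
      warning("fewer than 2 concentration levels; plain random split")
      cal <- sort(sample.int(n, n_cal))
      return(list(calibration = cal, prediction = setdiff(seq_len(n), cal)))
    }
    groups <- lapply(levels, function(l) which(y == l))
    m <- lengths(groups)
    f <- n_cal / n
    a <- floor(m * f)
    rem <- m * f - a
    short <- n_cal - sum(a)
    if (short > 0) {
      pick <- order(rem + stats::runif(length(rem)) * 1e-9,
                    decreasing = TRUE)
      pick <- pick[a[pick] < m[pick]][seq_len(short)]
      a[pick] <- a[pick] + 1L
    }
    L <- length(levels)
    for (lv in c(1L, L)) {        # extremes must calibrate
      if (a[lv] == 0) {
        donor <- which(a > ifelse(seq_len(L) %in% c(1L, L), 1L, 0L))[1]
        a[donor] <- a[donor] - 1L; a[lv] <- a[lv] + 1L
      }
      if (a[lv] == m[lv] && m[lv] >= 2) {  # and predict, replicates permitting
        taker <- which(a < m & !(seq_len(L) %in% c(1L, L)))[1]
        if (is.na(taker)) taker <- setdiff(which(a < m), lv)[1]
        if (!is.na(taker)) { a[lv] <- a[lv] - 1L; a[taker] <- a[taker] + 1L }
      }
    }
    cal <- unlist(lapply(seq_along(groups), function(i) {
      g <- sample(groups[[i]])
      g[seq_len(a[i])]
    }))
    cal <- sort(cal)
    list(calibration = cal, prediction = setdiff(seq_len(n), cal))
  })
}

#' Run the full calibration pipeline
#'
#' Align -> row-normalize -> split -> calibration-fitted scaling -> OPS-PLS
#' on the calibration set -> report RMSEC/Rc (calibration fit), RMSECV/Rcv
#' (Monte-Carlo CV of the selected subset) and RMSEP/Rp (held-out prediction
#' set). Input is either a list of spectra plus `y`, or a manifest
#' data.frame/CSV naming peak-list files with roles and concentrations.
#'
#' @param spectra list of [spectrum()] objects.
#' @param y concentrations (mg/L), one per spectrum.
#' @param config a [default_config()] list.
#' @param manifest optional manifest (path or data.frame, see
#'   [read_manifest()]); overrides `spectra`/`y`, and its
#'   calibration/prediction roles override the random split.
#' @return An object of class `"na_calibration"`: `report` (the Table-1-style
#'   metrics), `model` (selected PLS model), `ops`, `split`, `grid`,
#'   `normalization`, `selected_columns`, `y_range`, `aligned`.
#' @export
run_calibration <- function(spectra = NULL, y = NULL, config = default_config(),
                            manifest = NULL) {
  config <- utils::modifyList(default_config(), config)
  roles <- NULL
  if (!is.null(manifest)) {
    if (is.character(manifest)) manifest <- read_manifest(manifest)
    use <- manifest$role %in% c("calibration", "prediction")
    manifest <- manifest[use, , drop = FALSE]
    if (any(is.na(manifest$concentration_mg_per_L)))
      stop_naquant("manifest calibration/prediction rows need concentrations",
                   class = "naquant_manifest_error")
    spectra <- lapply(seq_len(nrow(manifest)), function(i)
      read_spectrum(manifest$path[i], sample_id = manifest$sample_id[i],
                    dilution_factor = manifest$dilution_factor[i]))
    y <- manifest$concentration_mg_per_L
    if (all(c("calibration", "prediction") %in% manifest$role))
      roles <- manifest$role
  }
  stopifnot(length(spectra) == length(y))
  if (length(unique(y)) < 2)
    stop_naquant("need at least 2 calibration levels",
                 class = "naquant_manifest_error")

  am <- align_spectra(spectra, config$mz_min, config$mz_max, config$resolution)
  Xn <- normalize_rows(am, config$normalization)$X
  if (!is.null(roles)) {
    split <- list(calibration = which(roles == "calibration"),
                  prediction = which(roles == "prediction"))
  } else {
    n <- length(y)
    n_cal <- if (config$n_cal + config$n_pred == n) config$n_cal
             else round(n * config$n_cal / (config$n_cal + config$n_pred))
    split <- split_samples(y, n_cal, n - n_cal, seed = derive_seed(config$seed, 1L))
  }
  cal <- split$calibration; prd <- split$prediction

  ops <- ops_select(Xn[cal, , drop = FALSE], y[cal],
                    window = config$ops_window,
                    increment = config$ops_increment,
                    percent = config$ops_percent,
                    lv_grid = config$lv_grid, kind = config$ops_kind,
                    cv = list(leave_out = config$leave_out,
                              n_splits = config$n_splits,
                              seed = derive_seed(config$seed, 2L),
                              scaling = config$scaling))

  report <- list(
    pretreatment = paste0(config$scaling, " normalization by ",
                          config$normalization),
    n_lv = ops$selected_lv,
    rmsec = ops$rmsec, rc = ops$rc,
    rmsecv = ops$rmsecv, rcv = ops$rcv,
    rmsep = NA_real_, rp = NA_real_,
    n_variables_selected = length(ops$selected_columns),
    n_variables_total = ncol(Xn),
    seed = config$seed)
  if (length(prd)) {
    yhat_p <- predict(ops$selected_model,
                      Xn[prd, ops$selected_columns, drop = FALSE])
    report$rmsep <- rmse(y[prd], yhat_p)
    report$rp <- pearson_r(y[prd], yhat_p)
  }
  structure(list(report = report, model = ops$selected_model, ops = ops,
                 split = split, grid = am$grid,
                 bin_centers = am$bin_centers,
                 normalization = config$normalization,
                 selected_columns = ops$selected_columns,
                 y_range = range(y[cal]), config = config, y = y),
            class = "na_calibration")
}

#' @export
print.na_calibration <- function(x, ...) {
  r <- x$report
  cat("<na_calibration>\n")
  cat(sprintf("  pretreatment : %s\n", r$pretreatment))
  cat(sprintf("  variables    : %d selected of %d\n",
              r$n_variables_selected, r$n_variables_total))
  cat(sprintf("  LV           : %d\n", r$n_lv))
  cat(sprintf("  RMSEC  %.4f   Rc  %.4f\n", r$rmsec, r$rc))
  cat(sprintf("  RMSECV %.4f   Rcv %.4f\n", r$rmsecv, r$rcv))
  if (!is.na(r$rmsep))
    cat(sprintf("  RMSEP  %.4f   Rp  %.4f\n", r$rmsep, r$rp))
  invisible(x)
}

# Project a new spectrum onto a fitted model's bin grid. Normalization
# statistics come from the spectrum's full in-range binned vector, so
# intensity landing outside the training bins still counts toward the row
# total -- the aligned training matrix behaves identically because its
# occupied-bin union covers all its own peaks.
project_spectrum <- function(fit, s) {
  g <- fit$grid
  b <- bin_spectrum(s, g$mz_min, g$mz_max, g$resolution)
  if (!nrow(b))
    stop_naquant("spectrum ", s$sample_id, " has no peaks in the model range",
                 class = "naquant_alignment_error")
  denom <- switch(fit$normalization,
    none = 1,
    sum = sum(b$intensity),
    max = max(b$intensity),
    vector = sqrt(sum(b$intensity^2)))
  v <- numeric(length(g$occupied_bins))
  hit <- match(b$bin, g$occupied_bins)
  ok <- !is.na(hit)
  v[hit[ok]] <- b$intensity[ok]
  v / denom
}

#' Multiply instrument-level predictions by the dilution factor
#'
#' @param pred1 predicted concentration at instrument level (mg/L).
#' @param dilution_factor dilution applied before infusion, > 0.
#' @return Corrected concentrations `pred1 * dilution_factor`.
#' @export
dilution_correct <- function(pred1, dilution_factor) {
  if (any(dilution_factor <= 0))
    stop_naquant("dilution_factor must be > 0", class = "naquant_domain_error")
  pred1 * dilution_factor
}

#' Predict unknown samples with dilution correction
#'
#' Projects each spectrum onto the model's bin grid, predicts the
#' instrument-level concentration (PRED1), and multiplies by the dilution
#' factor (PRED2 = PRED1 x factor). Predictions below zero or above the
#' calibrated range are flagged, never clipped. When reference values are
#' supplied the summary reports the mean difference (PRED2 - reference) and
#' the Pearson correlation between PRED2 and the reference.
#'
#' @param fit a [run_calibration()] result.
#' @param spectra list of [spectrum()] objects.
#' @param dilution_factor dilution factor applied to every sample
#'   (default 20); `NULL` uses each spectrum's own `dilution_factor`.
#' @param reference optional reference concentrations (mg/L), same order.
#' @return An object of class `"prediction_report"`: `records` (data.frame
#'   with `sample_id`, `pred1`, `dilution_factor`, `pred2`, `reference`,
#'   `difference`, `flag`), `mean_difference`, `pearson_r`.
#' @export
predict_unknowns <- function(fit, spectra, dilution_factor = 20,
                             reference = NULL) {
  stopifnot(inherits(fit, "na_calibration"))
  if (!is.null(dilution_factor) && any(dilution_factor <= 0))
    stop_naquant("dilution_factor must be > 0", class = "naquant_domain_error")
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    v <- project_spectrum(fit, s)
    pred1 <- predict(fit$model, v[fit$selected_columns])
    df <- if (is.null(dilution_factor)) s$dilution_factor
          else if (length(dilution_factor) > 1) dilution_factor[i]
          else dilution_factor
    flag <- if (pred1 < 0) "below calibration range"
            else if (pred1 > fit$y_range[2]) "above calibration range"
            else ""
    data.frame(sample_id = s$sample_id, pred1 = pred1, dilution_factor = df,
               pred2 = dilution_correct(pred1, df), flag = flag,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec$reference <- if (is.null(reference)) NA_real_ else reference
  rec$difference <- rec$pred2 - rec$reference
  mean_diff <- r <- NA_real_
  if (!is.null(reference) && sum(!is.na(reference)) >= 2) {
    ok <- !is.na(rec$reference)
    mean_diff <- mean(rec$difference[ok])
    r <- pearson_r(rec$reference[ok], rec$pred2[ok])
  }
  rec <- rec[, c("sample_id", "pred1", "dilution_factor", "pred2",
                 "reference", "difference", "flag")]
  structure(list(records = rec, mean_difference = mean_diff, pearson_r = r),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report>\n")
  print(x$records, row.names = FALSE, digits = 4)
  if (!is.na(x$mean_difference))
    cat(sprintf("mean difference = %.2f mg/L, Pearson r = %.4f\n",
                x$mean_difference, x$pearson_r))
  invisible(x)
}

#' Published reference comparison for twelve produced-water samples
#'
#' The packaged comparison table for twelve real produced-water samples:
#' instrument-level predictions (`pred1`, mg/L), their 20-fold
#' dilution-corrected values (`pred2`), the LC-MS reference concentrations
#' (`lcms`), and the printed difference column.
#'
#' @return data.frame with columns `sample`, `pred1`, `pred2`, `lcms`,
#'   `difference`.
#' @export
reference_comparison <- function() {
  path <- system.file("extdata", "produced_water_reference.csv",
                      package = "naquant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize / restore a calibration to JSON
#'
#' Stores the bin grid, normalization, scaler statistics, selected columns
#' and PLS matrices in a documented JSON container.
#' @param fit a [run_calibration()] result.
#' @param path JSON file path.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "na_calibration"))
  m <- fit$model
  obj <- list(
    container = "naquant_model", version = 1L,
    grid = fit$grid, normalization = fit$normalization,
    selected_columns = fit$selected_columns,
    y_range = fit$y_range,
    report = fit$report,
    scaler = unclass(m$scaler),
    pls = list(n_lv = m$n_lv, weights = m$weights, x_loadings = m$x_loadings,
               y_loadings = m$y_loadings, B = m$B))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns a reduced `"na_calibration"` usable by
#'   [predict_unknowns()].
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "naquant_model"))
    stop_naquant("not a naquant model file", class = "naquant_format_error")
  sc <- obj$scaler
  sc$fitted <- TRUE
  class(sc) <- "scaler"
  model <- structure(list(
    n_lv = obj$pls$n_lv,
    weights = as.matrix(obj$pls$weights),
    x_loadings = as.matrix(obj$pls$x_loadings),
    y_loadings = obj$pls$y_loadings,
    B = as.matrix(obj$pls$B),
    regression_vector = as.matrix(obj$pls$B)[, obj$pls$n_lv],
    scaler = sc), class = "pls_model")
  structure(list(report = obj$report, model = model,
                 grid = obj$grid, normalization = obj$normalization,
                 selected_columns = obj$selected_columns,
                 y_range = obj$y_range),
            class = "na_calibration")
}
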