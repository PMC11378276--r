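#' Row normalization of an intensity matrix
#'
#' Removes between-sample differences in overall ion current. `"sum"` divides
#' each row by its total (rows then sum to 1), `"max"` by its largest entry,
#' `"vector"` by its Euclidean norm, `"none"` leaves the matrix untouched.
#'
#' @param X an [align_spectra()] result or a plain numeric matrix.
#' @param method `"sum"`, `"max"`, `"vector"` or `"none"`.
#' @return Same type as the input, with normalized rows.
#' @export
normalize_rows <- function(X, method = c("sum", "max", "vector", "none")) {
  method <- match.arg(method)
  am <- NULL
  if (inherits(X, "aligned_matrix")) { am <- X; X <- am$X }
  X <- as.matrix(X)
  if (method != "none") {
    denom <- switch(method,
      sum = rowSums(X),
      max = apply(X, 1, max),
      vector = sqrt(rowSums(X^2)))
    bad <- which(denom <= 0)
    if (length(bad)) {
      ids <- rownames(X)[bad] %||% as.character(bad)
      stop_naquant("degenerate (all-zero) row for sample(s): ",
                   paste(ids, collapse = ", "),
                   class = "naquant_degenerate_row_error")
    }
    X <- X / denom
  }
  if (is.null(am)) return(X)
  am$X <- X
  am
}

#' Fit a column scaler on calibration data
#'
#' Computes per-column means (and, for autoscaling, sample standard
#' deviations, n-1 denominator) plus the response mean/SD on the calibration
#' rows only. Zero-variance calibration columns are dropped and recorded in
#' `dropped_columns`.
#'
#' @param X_cal calibration matrix (already row-normalized).
#' @param y_cal calibration response (mg/L); optional.
#' @param method `"autoscale"` (center and scale) or `"center"`.
#' @return An object of class `"scaler"`.
#' @export
fit_scaler <- function(X_cal, y_cal = NULL, method = c("autoscale", "center")) {
  method <- match.arg(method)
  X_cal <- as.matrix(X_cal)
  mu <- colMeans(X_cal)
  sds <- apply(X_cal, 2, stats::sd)
  if (method == "autoscale") {
    retained <- which(sds > 0)
    dropped <- which(sds == 0)
  } else {
    retained <- seq_len(ncol(X_cal))
    dropped <- integer(0)
  }
  if (!length(retained))
    stop_naquant("all calibration columns have zero variance",
                 class = "naquant_degenerate_row_error")
  s <- list(method = method,
            column_means = mu[retained],
            column_sds = if (method == "autoscale") sds[retained] else NULL,
            retained_columns = retained,
            dropped_columns = dropped,
            y_mean = if (!is.null(y_cal)) mean(y_cal) else NA_real_,
            y_sd = if (!is.null(y_cal) && method == "autoscale")
                     stats::sd(y_cal) else 1,
            fitted = TRUE)
  class(s) <- "scaler"
  s
}

#' Apply a fitted scaler
#'
#' Uses calibration statistics only; on unseen data the scaled column means
#' are in general nonzero.
#' @param scaler a [fit_scaler()] result.
#' @param X matrix with the same columns the scaler was fitted on.
#' @return Scaled matrix restricted to the retained columns.
#' @export
apply_scaler <- function(scaler, X) {
  check_scaler(scaler)
  X <- as.matrix(X)
  if (ncol(X) < max(scaler$retained_columns))
    stop_naquant("matrix has fewer columns than the scaler was fitted on",
                 class = "naquant_alignment_error")
  X <- X[, scaler$retained_columns, drop = FALSE]
  X <- sweep(X, 2, scaler$column_means, "-")
  if (scaler$method == "autoscale")
    X <- sweep(X, 2, scaler$column_sds, "/")
  X
}

#' Scale / back-transform the response
#'
#' `scale_y` maps concentrations to the preprocessed response scale;
#' `inverse_y` is its exact inverse.
#' @param scaler a [fit_scaler()] result fitted with `y_cal`.
#' @param y,y_scaled numeric vectors.
#' @return Numeric vector.
#' @export
scale_y <- function(scaler, y) {
  check_scaler(scaler)
  if (is.na(scaler$y_mean))
    stop_naquant("scaler was fitted without a response", class = "naquant_state_error")
  (y - scaler$y_mean) / scaler$y_sd
}

#' @rdname scale_y
#' @export
inverse_y <- function(scaler, y_scaled) {
  check_scaler(scaler)
  if (is.na(scaler$y_mean))
    stop_naquant("scaler was fitted without a response", class = "naquant_state_error")
  y_scaled * scaler$y_sd + scaler$y_mean
}

check_scaler <- function(scaler) {
  if (!inherits(scaler, "scaler") || !isTRUE(scaler$fitted))
    stop_naquant("scaler has not been fitted", class = "naquant_state_error")
  invisible(scaler)
}
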