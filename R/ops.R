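#' Informative vector for ordered predictor selection
#'
#' Per-variable importance used to order predictors: `"regression"` is the
#' absolute PLS regression vector, `"correlation"` the absolute per-column
#' Pearson correlation with the response, `"product"` their elementwise
#' product; each is rescaled to unit maximum. Columns the model's scaler
#' dropped (zero calibration variance) score 0, as do zero-variance columns
#' under the correlation kind.
#'
#' @param X row-normalized predictor matrix the model was built from.
#' @param y response vector.
#' @param model a [fit_pls()] model fitted on (X, y) (with its scaler).
#' @param kind `"regression"`, `"correlation"` or `"product"`.
#' @return Numeric vector of length `ncol(X)` in [0, 1].
#' @export
informative_vector <- function(X, y, model,
                               kind = c("regression", "correlation", "product")) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  p <- ncol(X)
  retained <- if (!is.null(model$scaler)) model$scaler$retained_columns else seq_len(p)
  reg <- numeric(p)
  reg[retained] <- abs(model$regression_vector)
  if (kind != "regression") {
    sds <- apply(X, 2, stats::sd)
    corr <- numeric(p)
    ok <- sds > 0
    if (any(ok)) corr[ok] <- abs(stats::cor(X[, ok, drop = FALSE], y))
  }
  v <- switch(kind,
    regression = reg,
    correlation = corr,
    product = reg * corr)
  mx <- max(v)
  if (mx > 0) v <- v / mx
  v
}

#' Ordered predictor selection (OPS) for PLS calibration
#'
#' Ranks variables by an informative vector computed from a pilot PLS model
#' (order chosen by cross-validation on all variables), then evaluates nested
#' prefixes of the ranking -- sizes `window`, `window + increment`,
#' `window + 2*increment`, ... up to `ceil(percent/100 * p)` (the full set is
#' always included when `percent = 100`) -- by the same Monte-Carlo
#' cross-validation. The prefix (and latent-variable count) with minimal
#' pooled RMSECV wins; ties go to fewer variables, then fewer latent
#' variables. The returned model is refitted on all calibration rows
#' restricted to the selected columns.
#'
#' All prefix evaluations reuse one CV seed, so every candidate sees the same
#' random splits and the full-variable model is directly comparable.
#'
#' @param X row-normalized calibration matrix.
#' @param y calibration concentrations (mg/L).
#' @param window first prefix size (default 20).
#' @param increment prefix growth step (default 5).
#' @param percent percentage of variables to scan (default 100).
#' @param lv_grid candidate latent-variable counts.
#' @param kind informative-vector kind, see [informative_vector()].
#' @param cv list of cross-validation settings: `leave_out`, `n_splits`,
#'   `seed`, `scaling` (defaults 3, 200, 1, autoscale).
#' @return An object of class `"ops_result"`: `ordering`, `window_trace`
#'   (data.frame size/lv/rmsecv), `selected_columns`, `selected_model`,
#'   `selected_lv`, `rmsecv`, `rcv`, `pilot_lv`, `informative_kind`.
#' @export
ops_select <- function(X, y, window = 20, increment = 5, percent = 100,
                       lv_grid = 1:10,
                       kind = c("regression", "correlation", "product"),
                       cv = list()) {
  kind <- match.arg(kind)
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(window >= 1, increment >= 1, percent > 0, percent <= 100)
  cv <- utils::modifyList(list(leave_out = 3, n_splits = 200, seed = 1,
                               scaling = "autoscale"), cv)
  p <- ncol(X)
  run_cv <- function(Xsub) cross_validate(
    Xsub, y, lv_grid = lv_grid, leave_out = cv$leave_out,
    n_splits = cv$n_splits, seed = cv$seed, scaling = cv$scaling)

  # pilot model on all variables, order by CV
  pilot_cv <- run_cv(X)
  sc0 <- fit_scaler(X, y, method = cv$scaling)
  pilot <- fit_pls(apply_scaler(sc0, X), scale_y(sc0, y), pilot_cv$chosen_lv,
                   scaler = sc0)
  iv <- informative_vector(X, y, pilot, kind = kind)
  ordering <- order(iv, decreasing = TRUE)

  p_target <- as.integer(ceiling(percent / 100 * p))
  if (window >= p_target) sizes <- p_target
  else sizes <- seq(as.integer(window), p_target, by = as.integer(increment))
  if (percent == 100 && sizes[length(sizes)] != p) sizes <- c(sizes, p)
  else if (sizes[length(sizes)] != p_target) sizes <- c(sizes, p_target)

  trace <- data.frame(size = sizes, lv = NA_integer_, rmsecv = NA_real_)
  cvs <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    cols <- ordering[seq_len(sizes[i])]
    cr <- run_cv(X[, cols, drop = FALSE])
    cvs[[i]] <- cr
    trace$lv[i] <- cr$chosen_lv
    trace$rmsecv[i] <- cr$rmsecv
  }
  # minimum RMSECV; ties -> fewer variables then fewer LV (trace is sorted by
  # increasing size, and chosen_lv already breaks LV ties downward)
  best <- which.min(trace$rmsecv)
  selected <- ordering[seq_len(trace$size[best])]

  sc <- fit_scaler(X[, selected, drop = FALSE], y, method = cv$scaling)
  model <- fit_pls(apply_scaler(sc, X[, selected, drop = FALSE]),
                   scale_y(sc, y), trace$lv[best], scaler = sc)
  fitted_y <- predict(model, X[, selected, drop = FALSE])
  structure(list(
    informative_kind = kind,
    ordering = ordering,
    informative_values = iv,
    window_trace = trace,
    selected_columns = selected,
    selected_model = model,
    selected_lv = trace$lv[best],
    rmsecv = trace$rmsecv[best],
    rcv = cvs[[best]]$rcv,
    rmsec = rmse(y, fitted_y),
    rc = pearson_r(y, fitted_y),
    pilot_lv = pilot_cv$chosen_lv,
    cv_settings = cv),
    class = "ops_result")
}

#' @export
print.ops_result <- function(x, ...) {
  cat(sprintf(paste0("<ops_result> kind = %s: %d/%d variables, %d LV, ",
                     "RMSECV = %.4f (full-set RMSECV = %.4f)\n"),
              x$informative_kind, length(x$selected_columns),
              length(x$ordering), x$selected_lv, x$rmsecv,
              x$window_trace$rmsecv[nrow(x$window_trace)]))
  invisible(x)
}
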