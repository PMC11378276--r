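#' Fit a PLS1 regression by NIPALS
#'
#' Single-response partial least squares. Per component the weight is the
#' closed-form `w = X'y / ||X'y||`, scores `t = Xw`, x-loading
#' `p = X't / t't`, y-loading `q = y't / t't`, followed by deflation of both
#' `X` and `y`. The regression vector for `a` components is
#' `b_a = W_a (P_a' W_a)^{-1} q_a`; all cumulative vectors are stored so a
#' single fit yields predictions for every model order up to `n_lv`.
#'
#' `X` and `y` are expected on the preprocessed scale (see [fit_scaler()]);
#' pass the scaler so [predict.pls_model()] can map raw data in and
#' concentrations out.
#'
#' @param X preprocessed predictor matrix (n x p).
#' @param y preprocessed response vector.
#' @param n_lv number of latent variables, `<= min(n - 1, p)`.
#' @param scaler optional [fit_scaler()] result stored with the model.
#' @param allow_truncation if TRUE, stop quietly at the numerical rank when a
#'   weight vector collapses instead of raising the degenerate-response
#'   error; the returned model then has fewer than `n_lv` components.
#'   Cross-validation uses this to skip infeasible model orders per split.
#' @return An object of class `"pls_model"` with `weights` (W), `x_loadings`
#'   (P), `y_loadings` (q), `scores` (T), `B` (p x n_lv cumulative regression
#'   vectors), `regression_vector` (= `B[, n_lv]`), `n_lv`, `scaler`.
#' @export
fit_pls <- function(X, y, n_lv, scaler = NULL, allow_truncation = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  n_lv <- as.integer(n_lv)
  max_lv <- min(n - 1L, p)
  if (n_lv < 1L || n_lv > max_lv)
    stop_naquant("n_lv must be between 1 and min(n-1, p) = ", max_lv,
                 class = "naquant_rank_error")
  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  Xd <- X; yd <- y
  achieved <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      if (allow_truncation && a > 1L) break
      stop_naquant("zero-norm weight vector at component ", a,
                   " (degenerate response)", class = "naquant_degenerate_response_error")
    }
    w <- w / nw
    tt <- Xd %*% w
    t2 <- sum(tt^2)
    pl <- crossprod(Xd, tt) / t2
    qa <- sum(yd * tt) / t2
    Xd <- Xd - tcrossprod(tt, pl)
    yd <- yd - qa * tt
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- tt; q[a] <- qa
    achieved <- a
  }
  if (achieved < n_lv) {
    n_lv <- achieved
    W <- W[, 1:n_lv, drop = FALSE]; P <- P[, 1:n_lv, drop = FALSE]
    Tm <- Tm[, 1:n_lv, drop = FALSE]; q <- q[1:n_lv]
  }
  PtW <- crossprod(P, W)
  B <- matrix(0, p, n_lv)
  for (a in seq_len(n_lv)) {
    Ra <- W[, 1:a, drop = FALSE] %*% solve(PtW[1:a, 1:a, drop = FALSE])
    B[, a] <- Ra %*% q[1:a]
  }
  structure(list(n_lv = n_lv, weights = W, x_loadings = P, y_loadings = q,
                 scores = Tm, B = B, regression_vector = B[, n_lv],
                 scaler = scaler),
            class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' When the model carries a scaler, `newdata` is taken on the raw
#' (row-normalized) scale: it is column-scaled with the stored calibration
#' statistics, projected onto the regression vector, and the response is
#' back-transformed to concentration units. Without a scaler both input and
#' output stay on the preprocessed scale.
#'
#' @param object a [fit_pls()] model.
#' @param newdata matrix (or vector, treated as one row).
#' @param n_lv model order to use (default: the fitted order).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > object$n_lv)
    stop_naquant("n_lv outside the fitted range", class = "naquant_rank_error")
  if (!is.null(object$scaler)) {
    Xs <- apply_scaler(object$scaler, newdata)
    if (ncol(Xs) != nrow(object$B))
      stop_naquant("column mismatch between model and new data",
                   class = "naquant_alignment_error")
    inverse_y(object$scaler, drop(Xs %*% object$B[, n_lv]))
  } else {
    if (ncol(newdata) != nrow(object$B))
      stop_naquant("column mismatch between model and new data",
                   class = "naquant_alignment_error")
    drop(newdata %*% object$B[, n_lv])
  }
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d predictors%s\n",
              x$n_lv, nrow(x$B),
              if (!is.null(x$scaler)) sprintf(", %s preprocessing", x$scaler$method)
              else ""))
  invisible(x)
}

#' Root-mean-square error
#'
#' `sqrt(sum((y - yhat)^2) / n)` in the units of `y`; reported as RMSEC,
#' RMSECV or RMSEP depending on which sample set it is computed on.
#' @param y,yhat measured and predicted values (equal length, n >= 1).
#' @return Nonnegative scalar.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation between measured and predicted values
#'
#' The product-moment correlation about the means of each vector (Rc, Rcv or
#' Rp depending on the sample set).
#' @param y,yhat equal-length vectors, n >= 2.
#' @return Scalar in [-1, 1].
#' @export
pearson_r <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop_naquant("correlation undefined: zero variance",
                 class = "naquant_undefined_correlation_error")
  stats::cor(y, yhat)
}

#' Monte-Carlo cross-validation for PLS model-order selection
#'
#' Repeatedly holds out `leave_out` samples drawn without replacement, refits
#' the column scaler and the PLS model on the remainder for every order in
#' `lv_grid`, and predicts the held-out samples in concentration units.
#' RMSECV per order pools all held-out residuals across splits; the chosen
#' order is the pooled-RMSECV minimum with ties broken toward fewer latent
#' variables. Orders exceeding the rank bound of a split are skipped for that
#' split and counted in `skipped`.
#'
#' With `exhaustive = TRUE` every sample is held out exactly once
#' (`leave_out = 1`, `n_splits = n`): classical leave-one-out CV.
#'
#' @param X row-normalized predictor matrix.
#' @param y concentrations (mg/L).
#' @param lv_grid candidate latent-variable counts.
#' @param leave_out samples held out per split (default 3).
#' @param n_splits number of random splits (default 200).
#' @param seed RNG seed for the split draws (mandatory).
#' @param scaling `"autoscale"` or `"center"`, refitted inside every split.
#' @param exhaustive if TRUE, run leave-one-out instead of random splits.
#' @return An object of class `"cv_result"`: `rmsecv_by_lv`, `rcv_by_lv`,
#'   `chosen_lv`, `rmsecv`, `rcv`, `n_splits`, `leave_out`, `seed`,
#'   `skipped`.
#' @export
cross_validate <- function(X, y, lv_grid = 1:10, leave_out = 3,
                           n_splits = 200, seed = 1,
                           scaling = c("autoscale", "center"),
                           exhaustive = FALSE) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n, n_splits >= 1)
  if (exhaustive) {
    leave_out <- 1L
    holdouts <- as.list(seq_len(n))
  } else {
    if (leave_out >= n)
      stop_naquant("leave_out must be < n_samples", class = "naquant_domain_error")
    holdouts <- with_seed(seed, lapply(seq_len(n_splits), function(i)
      sample.int(n, leave_out)))
  }
  lv_grid <- sort(unique(as.integer(lv_grid)))
  res <- lapply(lv_grid, function(a) list(y = numeric(0), yhat = numeric(0)))
  names(res) <- as.character(lv_grid)
  skipped <- stats::setNames(integer(length(lv_grid)), as.character(lv_grid))
  for (out in holdouts) {
    tr <- setdiff(seq_len(n), out)
    sc <- fit_scaler(X[tr, , drop = FALSE], y[tr], method = scaling)
    Xtr <- apply_scaler(sc, X[tr, , drop = FALSE])
    ytr <- scale_y(sc, y[tr])
    a_max <- min(max(lv_grid), length(tr) - 1L, ncol(Xtr))
    fit <- fit_pls(Xtr, ytr, a_max, allow_truncation = TRUE)
    a_max <- fit$n_lv  # numerical rank may truncate further
    Xte <- apply_scaler(sc, X[out, , drop = FALSE])
    for (a in lv_grid) {
      if (a > a_max) { skipped[as.character(a)] <- skipped[as.character(a)] + 1L; next }
      yhat <- inverse_y(sc, drop(Xte %*% fit$B[, a]))
      k <- as.character(a)
      res[[k]]$y <- c(res[[k]]$y, y[out])
      res[[k]]$yhat <- c(res[[k]]$yhat, yhat)
    }
  }
  evaluated <- vapply(res, function(r) length(r$y) > 0, logical(1))
  if (!any(evaluated))
    stop_naquant("no latent-variable count in lv_grid was feasible",
                 class = "naquant_rank_error")
  rmsecv_by_lv <- vapply(res[evaluated], function(r) rmse(r$y, r$yhat), numeric(1))
  rcv_by_lv <- vapply(res[evaluated], function(r)
    if (length(r$y) >= 2 && stats::sd(r$y) > 0 && stats::sd(r$yhat) > 0)
      stats::cor(r$y, r$yhat) else NA_real_, numeric(1))
  chosen <- as.integer(names(which.min(rmsecv_by_lv)))  # ties: first = smallest
  structure(list(rmsecv_by_lv = rmsecv_by_lv, rcv_by_lv = rcv_by_lv,
                 chosen_lv = chosen,
                 rmsecv = unname(rmsecv_by_lv[as.character(chosen)]),
                 rcv = unname(rcv_by_lv[as.character(chosen)]),
                 n_splits = if (exhaustive) n else as.integer(n_splits),
                 leave_out = as.integer(leave_out),
                 seed = if (exhaustive) NA_integer_ else as.integer(seed),
                 exhaustive = exhaustive, skipped = skipped),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d split(s) leaving out %d: chosen LV = %d, RMSECV = %.4f, Rcv = %.4f\n",
              if (x$exhaustive) "leave-one-out" else "Monte-Carlo",
              x$n_splits, x$leave_out, x$chosen_lv, x$rmsecv, x$rcv))
  invisible(x)
}
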