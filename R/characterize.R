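#' Assign CHO molecular formulas to an ESI(-) peak
#'
#' Enumerates neutral formulas CcHhOo over the carbon and oxygen ranges,
#' solving the hydrogen count from the observed deprotonated mass ([M-H]-:
#' neutral minus a proton, i.e. the electron stays with the anion). Hydrogen
#' is restricted to even values so the double-bond-equivalent count
#' `DBE = c - h/2 + 1` of the neutral is an integer; candidates must fall
#' within `tolerance_ppm` and `dbe_range`. Results are ranked by absolute
#' ppm error.
#'
#' @param mz observed m/z (Th), in (0, 2000).
#' @param tolerance_ppm mass tolerance (ppm), > 0.
#' @param c_range,o_range inclusive element count ranges (defaults 1-40 C,
#'   1-6 O).
#' @param dbe_range inclusive DBE range (default 0-15).
#' @return data.frame ranked by `abs(ppm_error)` with columns `observed_mz`,
#'   `c`, `h`, `o`, `formula`, `theoretical_mz`, `ppm_error`, `dbe`,
#'   `class_label`, `z`. Zero rows when nothing matches.
#' @export
assign_formula <- function(mz, tolerance_ppm = 3, c_range = c(1, 40),
                           o_range = c(1, 6), dbe_range = c(0, 15)) {
  stopifnot(mz > 0, mz < 2000, tolerance_ppm > 0)
  grid <- expand.grid(c = seq(c_range[1], c_range[2]),
                      o = seq(o_range[1], o_range[2]))
  h_exact <- (mz - grid$c * .MASS_C - grid$o * .MASS_O - .MASS_E) / .MASS_H + 1
  h <- 2 * round(h_exact / 2)  # nearest even hydrogen count
  ok <- h >= 2
  grid <- grid[ok, , drop = FALSE]; h <- h[ok]
  theo <- anion_mass(grid$c, h, grid$o)
  ppm <- (mz - theo) / theo * 1e6
  dbe <- grid$c - h / 2 + 1
  keep <- abs(ppm) <= tolerance_ppm & dbe >= dbe_range[1] & dbe <= dbe_range[2]
  out <- data.frame(observed_mz = rep(mz, sum(keep)), c = grid$c[keep], h = h[keep],
                    o = grid$o[keep], theoretical_mz = theo[keep],
                    ppm_error = ppm[keep], dbe = dbe[keep])
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  out$formula <- sprintf("C%dH%dO%d", out$c, out$h, out$o)
  out$class_label <- sprintf("O%d", out$o)
  out$z <- 2 * (1 - out$dbe)
  rownames(out) <- NULL
  out[, c("observed_mz", "c", "h", "o", "formula", "theoretical_mz",
          "ppm_error", "dbe", "class_label", "z")]
}

#' Assign formulas to every peak of a spectrum
#'
#' Keeps the top-ranked CHO candidate per peak; peaks with no candidate
#' within tolerance are omitted.
#' @param s a [spectrum()].
#' @inheritParams assign_formula
#' @return data.frame of top-hit assignments with an extra `intensity`
#'   column.
#' @export
assign_peaks <- function(s, tolerance_ppm = 3, c_range = c(1, 40),
                         o_range = c(1, 6), dbe_range = c(0, 15)) {
  stopifnot(inherits(s, "spectrum"))
  hits <- lapply(seq_along(s$mz), function(i) {
    a <- assign_formula(s$mz[i], tolerance_ppm, c_range, o_range, dbe_range)
    if (!nrow(a)) return(NULL)
    a <- a[1, , drop = FALSE]
    a$intensity <- s$intensity[i]
    a
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits))
    return(cbind(assign_formula(100.5, 1e-9)[0, ], intensity = numeric(0)))
  do.call(rbind, hits)
}

#' Heteroatom-class distribution
#'
#' Relative abundance per oxygen class (O2, O4, ...) as percent of the summed
#' assigned intensity.
#' @param assignments data.frame with `class_label` (e.g. from
#'   [assign_peaks()]).
#' @param intensities per-assignment intensities; taken from
#'   `assignments$intensity` when omitted.
#' @return data.frame with `class_label` and `percent` (sums to 100).
#' @export
class_distribution <- function(assignments, intensities = assignments$intensity) {
  stopifnot(nrow(assignments) >= 1, length(intensities) == nrow(assignments))
  tot <- tapply(intensities, assignments$class_label, sum)
  out <- data.frame(class_label = names(tot),
                    percent = 100 * as.numeric(tot) / sum(tot))
  out[order(out$class_label), , drop = FALSE]
}

#' DBE versus carbon-number abundance matrix
#'
#' Summed intensity per (DBE, carbon) cell, optionally restricted to one
#' heteroatom class and normalized to percent -- the numeric content of a
#' DBE-carbon contour plot.
#' @inheritParams class_distribution
#' @param class_filter keep only this class label (e.g. `"O2"`); NULL keeps
#'   all.
#' @param percent normalize cells to percent of the retained intensity.
#' @return Numeric matrix, rows = DBE values, columns = carbon numbers.
#' @export
dbe_carbon_matrix <- function(assignments, intensities = assignments$intensity,
                              class_filter = NULL, percent = TRUE) {
  stopifnot(nrow(assignments) >= 1, length(intensities) == nrow(assignments))
  keep <- if (is.null(class_filter)) rep(TRUE, nrow(assignments))
          else assignments$class_label == class_filter
  if (!any(keep))
    stop_naquant("no assignments in class ", class_filter,
                 class = "naquant_domain_error")
  a <- assignments[keep, , drop = FALSE]
  it <- intensities[keep]
  dbe_lev <- sort(unique(a$dbe)); c_lev <- sort(unique(a$c))
  m <- matrix(0, length(dbe_lev), length(c_lev),
              dimnames = list(dbe = dbe_lev, carbon = c_lev))
  for (i in seq_len(nrow(a)))
    m[as.character(a$dbe[i]), as.character(a$c[i])] <-
      m[as.character(a$dbe[i]), as.character(a$c[i])] + it[i]
  if (percent) m <- 100 * m / sum(m)
  m
}
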