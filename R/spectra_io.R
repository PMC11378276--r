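#' Construct a centroided spectrum
#'
#' A spectrum is one sample's centroided peak list from direct-infusion
#' ESI(-) analysis: strictly increasing m/z (thomson), non-negative
#' intensities (arbitrary counts). Duplicate m/z values are merged by summing
#' their intensities (ion-current conservation) and zero-intensity peaks are
#' dropped.
#'
#' @param mz numeric vector of m/z values, all > 0.
#' @param intensity numeric vector of intensities, all >= 0.
#' @param sample_id sample identifier.
#' @param polarity ionization polarity; only `"negative"` is supported.
#' @param dilution_factor dilution applied before infusion (>= 1); carried as
#'   metadata and used by [predict_unknowns()].
#' @return An object of class `"spectrum"` with fields `sample_id`, `mz`,
#'   `intensity`, `polarity`, `dilution_factor`.
#' @export
spectrum <- function(mz, intensity, sample_id = "sample",
                     polarity = "negative", dilution_factor = 1) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop_naquant("mz and intensity lengths differ", class = "naquant_format_error")
  if (anyNA(mz) || anyNA(intensity))
    stop_naquant("NA values in peak list", class = "naquant_format_error")
  if (any(mz <= 0))
    stop_naquant("all m/z must be > 0", class = "naquant_format_error")
  if (any(intensity < 0))
    stop_naquant("negative intensity in peak list", class = "naquant_format_error")
  polarity <- match.arg(polarity, "negative")
  if (!is.numeric(dilution_factor) || length(dilution_factor) != 1 || dilution_factor < 1)
    stop_naquant("dilution_factor must be a single number >= 1",
                 class = "naquant_format_error")
  keep <- intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(
    list(sample_id = as.character(sample_id), mz = mz, intensity = intensity,
         polarity = polarity, dilution_factor = dilution_factor),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d peaks", x$sample_id, length(x$mz)))
  if (length(x$mz))
    cat(sprintf(", m/z %.4f-%.4f, TIC %.4g", min(x$mz), max(x$mz), sum(x$intensity)))
  cat(sprintf(", dilution %gx\n", x$dilution_factor))
  invisible(x)
}

#' Read a centroided spectrum from disk
#'
#' Supports two-column peak-list CSV (m/z, intensity; optional header) and
#' centroided mzML. Multiple mzML scans are averaged: peaks are pooled at the
#' reader's native precision (m/z rounded to 1e-6 Th), summed, and divided by
#' the scan count.
#'
#' @param path path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"mzml"`.
#' @inheritParams spectrum
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "mzml"),
                          sample_id = NULL, dilution_factor = 1) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_naquant("file not found: ", path, class = "naquant_format_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("mzml", "xml")) "mzml" else "csv"
  }
  sample_id <- sample_id %||% tools::file_path_sans_ext(basename(path))
  if (format == "csv") read_spectrum_csv(path, sample_id, dilution_factor)
  else read_spectrum_mzml(path, sample_id, dilution_factor)
}

read_spectrum_csv <- function(path, sample_id, dilution_factor) {
  first <- readLines(path, n = 1L)
  has_header <- {
    toks <- strsplit(first, ",", fixed = TRUE)[[1]]
    any(is.na(suppressWarnings(as.numeric(toks))))
  }
  df <- tryCatch(
    utils::read.csv(path, header = has_header, stringsAsFactors = FALSE),
    error = function(e) stop_naquant("unparseable CSV: ", conditionMessage(e),
                                     class = "naquant_format_error"))
  if (ncol(df) < 2)
    stop_naquant("peak-list CSV needs two columns (mz, intensity)",
                 class = "naquant_format_error")
  mz <- suppressWarnings(as.numeric(df[[1]]))
  it <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(mz) || anyNA(it))
    stop_naquant("non-numeric values in peak-list CSV: ", path,
                 class = "naquant_format_error")
  spectrum(mz, it, sample_id = sample_id, dilution_factor = dilution_factor)
}

# Minimal centroided-mzML reader (no mzR/pyteomics equivalent is available in
# the target library): base64 binary arrays, 32/64-bit floats, zlib or no
# compression. Profile-mode scans are refused.
read_spectrum_mzml <- function(path, sample_id, dilution_factor) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_naquant("unparseable mzML: ",
                                                   conditionMessage(e),
                                                   class = "naquant_format_error"))
  xml2::xml_ns_strip(doc)
  scans <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (!length(scans))
    stop_naquant("no spectra in mzML file: ", path, class = "naquant_format_error")
  pool_mz <- numeric(0); pool_it <- numeric(0)
  for (sc in scans) {
    accs <- xml2::xml_attr(xml2::xml_find_all(sc, "./cvParam"), "accession")
    if ("MS:1000128" %in% accs)
      stop_naquant("profile-mode mzML scan; centroided data required",
                   class = "naquant_unsupported_mode_error")
    if (!("MS:1000127" %in% accs))
      stop_naquant("mzML scan does not declare centroid mode",
                   class = "naquant_unsupported_mode_error")
    arrs <- xml2::xml_find_all(sc, ".//binaryDataArray")
    mzv <- itv <- NULL
    for (arr in arrs) {
      a <- xml2::xml_attr(xml2::xml_find_all(arr, "./cvParam"), "accession")
      vals <- decode_binary_array(
        xml2::xml_text(xml2::xml_find_first(arr, "./binary")),
        size = if ("MS:1000521" %in% a) 4L else 8L,
        zlib = "MS:1000574" %in% a)
      if ("MS:1000514" %in% a) mzv <- vals
      if ("MS:1000515" %in% a) itv <- vals
    }
    if (is.null(mzv) || is.null(itv) || length(mzv) != length(itv))
      stop_naquant("mzML scan lacks matching m/z and intensity arrays",
                   class = "naquant_format_error")
    pool_mz <- c(pool_mz, mzv); pool_it <- c(pool_it, itv)
  }
  # average scans: pool at native precision (1e-6 Th), sum, divide by count
  key <- round(pool_mz, 6)
  agg <- tapply(pool_it, factor(key, levels = unique(key)), sum)
  mz <- unique(key)
  spectrum(mz, as.numeric(agg) / length(scans),
           sample_id = sample_id, dilution_factor = dilution_factor)
}

decode_binary_array <- function(b64, size, zlib) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  if (zlib) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, what = "double", n = length(raw) %/% size, size = size,
          endian = "little")
}

#' Bin a spectrum onto a fixed-width m/z grid
#'
#' Peaks are assigned to half-open bins `[mz_min + i*resolution,
#' mz_min + (i+1)*resolution)` by floor indexing with decimal-safe arithmetic;
#' peaks outside `[mz_min, mz_max)` are discarded and peaks sharing a bin are
#' summed.
#'
#' @param s a [spectrum()].
#' @param mz_min,mz_max grid limits (Th), `mz_min < mz_max`.
#' @param resolution bin width (Th), > 0.
#' @return A data.frame with integer `bin` (ascending) and summed `intensity`.
#' @export
bin_spectrum <- function(s, mz_min = 100, mz_max = 400, resolution = 0.001) {
  stopifnot(inherits(s, "spectrum"), resolution > 0, mz_min < mz_max)
  keep <- s$mz >= mz_min & s$mz < mz_max
  mz <- s$mz[keep]; it <- s$intensity[keep]
  if (!length(mz)) return(data.frame(bin = integer(0), intensity = numeric(0)))
  idx <- decimal_floor_index(mz, mz_min, resolution)
  agg <- tapply(it, factor(idx, levels = sort(unique(idx))), sum)
  data.frame(bin = as.integer(names(agg)), intensity = as.numeric(agg),
             row.names = NULL)
}

#' Align spectra into the calibration X matrix
#'
#' Columns are the union of occupied bins across all spectra (not the full
#' grid); each row holds one sample's binned intensities, zero where that
#' sample has no peak. Bin centers are `mz_min + (index + 0.5) * resolution`.
#'
#' @param spectra list of [spectrum()] objects.
#' @inheritParams bin_spectrum
#' @return An object of class `"aligned_matrix"`: `X` (samples x bins),
#'   `bin_centers`, `sample_ids`, and `grid` (`mz_min`, `mz_max`,
#'   `resolution`, `occupied_bins`).
#' @export
align_spectra <- function(spectra, mz_min = 100, mz_max = 400,
                          resolution = 0.001) {
  stopifnot(length(spectra) >= 1)
  binned <- lapply(spectra, bin_spectrum, mz_min = mz_min, mz_max = mz_max,
                   resolution = resolution)
  occupied <- sort(unique(unlist(lapply(binned, `[[`, "bin"))))
  if (!length(occupied))
    stop_naquant("no peaks fall inside [", mz_min, ", ", mz_max,
                 ") in any spectrum", class = "naquant_empty_matrix_error")
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  X <- matrix(0, nrow = length(spectra), ncol = length(occupied),
              dimnames = list(ids, NULL))
  for (i in seq_along(binned)) {
    b <- binned[[i]]
    X[i, match(b$bin, occupied)] <- b$intensity
  }
  structure(
    list(X = X,
         bin_centers = mz_min + (occupied + 0.5) * resolution,
         sample_ids = ids,
         grid = list(mz_min = mz_min, mz_max = mz_max,
                     resolution = resolution, occupied_bins = occupied)),
    class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("<aligned_matrix> %d samples x %d occupied bins (m/z %g-%g, width %g)\n",
              nrow(x$X), ncol(x$X), x$grid$mz_min, x$grid$mz_max,
              x$grid$resolution))
  invisible(x)
}

#' Export an aligned matrix as wide CSV
#'
#' One row per sample; column headers are bin-center m/z values.
#' @param am an [align_spectra()] result.
#' @param path output path.
#' @export
write_aligned_csv <- function(am, path) {
  stopifnot(inherits(am, "aligned_matrix"))
  df <- as.data.frame(am$X)
  names(df) <- sprintf("%.*f", max(0, -floor(log10(am$grid$resolution))) + 1,
                       am$bin_centers)
  df <- cbind(sample_id = am$sample_ids, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Expected columns: `sample_id`, `path`, `role` (one of calibration,
#' prediction, unknown), `concentration_mg_per_L` (NA allowed for unknowns),
#' `dilution_factor` (defaults to 1 when absent).
#'
#' @param path manifest CSV path.
#' @param base_dir directory relative paths are resolved against (default:
#'   the manifest's own directory).
#' @return A data.frame with validated columns.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "path", "role")
  if (!all(need %in% names(df)))
    stop_naquant("manifest must have columns: ", paste(need, collapse = ", "),
                 class = "naquant_manifest_error")
  if (!all(df$role %in% c("calibration", "prediction", "unknown")))
    stop_naquant("manifest role must be calibration/prediction/unknown",
                 class = "naquant_manifest_error")
  if (is.null(df$concentration_mg_per_L)) df$concentration_mg_per_L <- NA_real_
  if (is.null(df$dilution_factor)) df$dilution_factor <- 1
  abs <- file.path(base_dir, df$path)
  df$path <- ifelse(file.exists(df$path), df$path, abs)
  df
}
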