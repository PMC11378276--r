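# Fixture builders: everything is generated in code at test time.

write_peaklist <- function(mz, intensity, path = tempfile(fileext = ".csv"),
                           header = FALSE) {
  df <- data.frame(mz = mz, intensity = intensity)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = header)
  path
}

# Minimal centroided mzML writer (uncompressed, 64-bit little-endian),
# enough to exercise the reader.
write_mzml <- function(scans, path = tempfile(fileext = ".mzML"),
                       centroided = TRUE) {
  enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8, endian = "little"))
  mode_acc <- if (centroided) "MS:1000127" else "MS:1000128"
  mode_name <- if (centroided) "centroid spectrum" else "profile spectrum"
  spec <- vapply(seq_along(scans), function(i) {
    sc <- scans[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="%s" name="%s"/>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, length(sc$mz), mode_acc, mode_name,
      enc(sc$mz), enc(sc$intensity))
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="r1"><spectrumList count="', length(scans), '">',
    paste(spec, collapse = ""), '</spectrumList></run></mzML>')
  writeLines(xml, path)
  path
}

# A small noise-free standard-mix dataset for fast pipeline tests.
quiet_dataset <- function(seed = 11, n_baseline = 0, intensity_cv = 0,
                          sigma_ppm = 0, levels = NULL, replicates = 3) {
  params <- simulation_params(sigma_ppm = sigma_ppm,
                              intensity_cv = intensity_cv,
                              n_baseline_peaks = n_baseline, seed = seed)
  design <- if (is.null(levels)) make_design(replicates = replicates)
            else make_design(levels, replicates)
  simulate_dataset(design, params)
}
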