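# Fixture builders shared across the suite. Everything is generated in code;
# no binary assets.

# Deterministic acquisition: `ratios[k]` is the exact S/N (and ion-count)
# heavy/light ratio of every scan in block k of an n_scan block.
make_acq <- function(n_scan = 5, ratio = 0.11, rt_start = 0, rt_step = 0.1,
                     it_ms = 10, microscans = 2, resolution = 60000,
                     agc_target = 1e6, light_intensity = 1e6, noise = 1e3,
                     mz_light = 175.0765, mz_heavy = 176.0798,
                     role = NA_character_, t0 = NA_real_,
                     extra_peaks = NULL) {
  idx <- seq_len(n_scan)
  meta <- data.frame(scan_index = idx,
                     rt_min = rt_start + (idx - 1) * rt_step,
                     it_ms = it_ms, tic = light_intensity * (1 + ratio),
                     microscans = microscans, resolution = resolution,
                     agc_target = agc_target)
  peaks <- rbind(
    data.frame(scan_index = idx, mz = mz_light,
               intensity = light_intensity, noise = noise),
    data.frame(scan_index = idx, mz = mz_heavy,
               intensity = light_intensity * ratio, noise = noise))
  if (!is.null(extra_peaks)) {
    extra <- do.call(rbind, lapply(idx, function(i) {
      cbind(scan_index = i, extra_peaks)
    }))
    peaks <- rbind(peaks, extra)
  }
  acquisition(meta, peaks, source_id = "fixture", role = role, t0 = t0)
}

thn_pair <- function() target_pair("C11H12O2", label_prefix = "THN")

# Minimal centroided mzML writer (64-bit little-endian floats, optional
# zlib), independent of the package reader: used as the round-trip oracle.
write_test_mzml <- function(path, scans, compress = FALSE, profile = FALSE) {
  enc <- function(x) {
    raw <- writeBin(as.numeric(x), raw(), size = 8, endian = "little")
    if (compress) raw <- memCompress(raw, type = "gzip")
    jsonlite::base64_enc(raw)
  }
  comp_cv <- if (compress) {
    '<cvParam accession="MS:1000574" name="zlib compression" value=""/>'
  } else {
    '<cvParam accession="MS:1000576" name="no compression" value=""/>'
  }
  mode_cv <- if (profile) {
    '<cvParam accession="MS:1000128" name="profile spectrum" value=""/>'
  } else {
    '<cvParam accession="MS:1000127" name="centroid spectrum" value=""/>'
  }
  sp <- vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      mode_cv,
      '<cvParam accession="MS:1000285" name="total ion current" value="%g"/>',
      '<scanList count="1"><scan>',
      '<cvParam accession="MS:1000016" name="scan start time" value="%g" unitAccession="UO:0000031"/>',
      '<cvParam accession="MS:1000927" name="ion injection time" value="%g"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray><cvParam accession="MS:1000523" name="64-bit float" value=""/>',
      comp_cv,
      '<cvParam accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray><cvParam accession="MS:1000523" name="64-bit float" value=""/>',
      comp_cv,
      '<cvParam accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, length(s$mz), s$tic, s$rt_min, s$it_ms,
      enc(s$mz), enc(s$intensity))
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="run1"><spectrumList count="', length(scans), '">',
    paste(sp, collapse = ""), '</spectrumList></run></mzML>')
  writeLines(xml, path)
  invisible(path)
}
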