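# Portable scan-table I/O, centroided mzML reading, time-window culling.
#
# The scan table is the canonical interchange format: UTF-8 CSV, one row per
# (scan, peak), scan metadata repeated on each row, mandatory header with
# columns scan_index, rt_min, it_ms, tic, microscans, resolution, agc_target,
# mz, intensity, noise. Flat, diff-able, language-neutral; vendor RAW decoding
# is out of scope.

.SCAN_COLS <- c("scan_index", "rt_min", "it_ms", "tic", "microscans",
                "resolution", "agc_target")
.PEAK_COLS <- c("mz", "intensity", "noise")

#' Construct an acquisition object
#'
#' An acquisition is one injection/run: ordered scans (strictly increasing
#' retention time) each carrying instrument metadata and a centroid peak list
#' with per-peak signal and baseline noise.
#'
#' @param meta data.frame with one row per scan and columns `scan_index`,
#'   `rt_min`, `it_ms`, `tic`, `microscans`, `resolution`, `agc_target`.
#' @param peaks data.frame with columns `scan_index`, `mz`, `intensity`,
#'   `noise`; zero rows for a scan means an empty peak list.
#' @param source_id Text identifier of the source file/run.
#' @param role `"standard"`, `"sample"`, or `NA`.
#' @param block_index 1-based block position in a bracketed sequence, or `NA`.
#' @param t0 Acquisition start time in minutes on the sequence clock (used as
#'   the drift regressor offset); `NA` when unknown.
#' @return Object of class `"orbiso_acquisition"`.
#' @export
acquisition <- function(meta, peaks, source_id = "<memory>",
                        role = NA_character_, block_index = NA_integer_,
                        t0 = NA_real_) {
  missing_cols <- setdiff(.SCAN_COLS, names(meta))
  if (length(missing_cols)) {
    stop("scan metadata missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  missing_p <- setdiff(c("scan_index", .PEAK_COLS), names(peaks))
  if (length(missing_p)) {
    stop("peak table missing mandatory column(s): ",
         paste(missing_p, collapse = ", "))
  }
  meta <- meta[order(meta$scan_index), c(.SCAN_COLS), drop = FALSE]
  if (anyDuplicated(meta$scan_index)) stop("duplicated scan_index")
  if (is.unsorted(meta$rt_min, strictly = TRUE)) {
    stop("retention time must be strictly increasing across scans")
  }
  if (any(meta$it_ms <= 0)) stop("injection time must be > 0")
  if (any(meta$tic < 0)) stop("tic must be >= 0")
  if (any(meta$resolution <= 0)) stop("resolution must be > 0")
  if (any(meta$microscans < 1)) stop("microscans must be >= 1")
  bad <- !peaks$scan_index %in% meta$scan_index
  if (any(bad)) stop("peaks reference unknown scan_index: ",
                     paste(unique(peaks$scan_index[bad]), collapse = ", "))
  if (nrow(peaks) && any(peaks$mz <= 0)) stop("peak mz must be > 0")
  if (nrow(peaks) && any(peaks$noise <= 0)) stop("peak noise must be > 0")
  if (length(unique(meta$microscans)) > 1L ||
      length(unique(meta$resolution)) > 1L) {
    warning("scans do not share a single microscans/resolution setting")
  }
  peaks <- peaks[order(peaks$scan_index, peaks$mz),
                 c("scan_index", .PEAK_COLS), drop = FALSE]
  rownames(meta) <- NULL
  rownames(peaks) <- NULL
  structure(list(meta = meta, peaks = peaks,
                 source_id = source_id, role = role,
                 block_index = block_index, t0 = t0),
            class = "orbiso_acquisition")
}

#' @export
print.orbiso_acquisition <- function(x, ...) {
  cat(sprintf("<orbiso_acquisition> %s: %d scans, %d peaks, rt %.3f-%.3f min%s\n",
              x$source_id, nrow(x$meta), nrow(x$peaks),
              min(x$meta$rt_min), max(x$meta$rt_min),
              if (!is.na(x$role)) paste0(" [", x$role, "]") else ""))
  invisible(x)
}

#' Number of scans in an acquisition
#' @param acq An `orbiso_acquisition`.
#' @export
n_scans <- function(acq) nrow(acq$meta)

#' Read a scan-table CSV
#'
#' @param path Path to a scan-table CSV (format documented in
#'   [write_scan_table()]).
#' @param source_id Identifier stored on the result; defaults to the file
#'   name.
#' @return An `orbiso_acquisition`.
#' @export
read_scan_table <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(.SCAN_COLS, .PEAK_COLS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("scan table ", path, " missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num_bad <- which(!stats::complete.cases(df[.SCAN_COLS]))
  if (length(num_bad)) {
    stop("malformed scan metadata at data row(s): ",
         paste(utils::head(num_bad, 10L), collapse = ", "))
  }
  meta <- unique(df[.SCAN_COLS])
  if (anyDuplicated(meta$scan_index)) {
    stop("inconsistent scan metadata: scan_index repeated with different values")
  }
  # rows with NA mz encode a scan with an empty peak list
  pk <- df[!is.na(df$mz), c("scan_index", .PEAK_COLS), drop = FALSE]
  acquisition(meta, pk, source_id = source_id)
}

#' Write a scan-table CSV
#'
#' One row per (scan, peak); scans with empty peak lists are written as a
#' single row with empty peak fields so they round-trip.
#'
#' @param acq An `orbiso_acquisition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(acq, path) {
  stopifnot(inherits(acq, "orbiso_acquisition"))
  pk <- acq$peaks
  empty <- setdiff(acq$meta$scan_index, pk$scan_index)
  if (length(empty)) {
    pk <- rbind(pk, data.frame(scan_index = empty, mz = NA_real_,
                               intensity = NA_real_, noise = NA_real_))
  }
  df <- merge(acq$meta, pk, by = "scan_index", sort = TRUE)
  df <- df[order(df$scan_index, df$mz), c(.SCAN_COLS, .PEAK_COLS)]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a centroided mzML file
#'
#' Supports 32/64-bit float m/z and intensity arrays, with or without zlib
#' compression. mzML carries no standard per-peak noise array, so noise is
#' filled by `noise_strategy` and the result is flagged approximate: the
#' ion-count model presumes the vendor noise estimate.
#'
#' @param path Path to an mzML file with centroided MS1 spectra.
#' @param noise_strategy `"percentile"` (default: the `percentile`-th
#'   percentile of in-scan intensities) or `"constant"`.
#' @param noise_value Noise value used when `noise_strategy = "constant"`.
#' @param percentile Percentile (0-100) for the percentile strategy.
#' @param agc_target AGC target to record (mzML rarely stores it); default NA.
#' @return An `orbiso_acquisition` with attribute `noise_approximate = TRUE`.
#' @export
read_mzml <- function(path, noise_strategy = c("percentile", "constant"),
                      noise_value = NULL, percentile = 10,
                      agc_target = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  noise_strategy <- match.arg(noise_strategy)
  if (noise_strategy == "constant" &&
      (is.null(noise_value) || noise_value <= 0)) {
    stop("constant noise strategy requires noise_value > 0")
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  if (!length(spectra)) stop("no spectra in ", path)
  meta_rows <- vector("list", length(spectra))
  peak_rows <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    cv <- xml2::xml_find_all(sp, "./cvParam")
    acc <- xml2::xml_attr(cv, "accession")
    if ("MS:1000128" %in% acc) {
      stop("profile-mode spectrum found (index ", i,
           "); centroid the data before import")
    }
    scan_cv <- xml2::xml_find_all(sp, ".//scanList/scan/cvParam")
    sacc <- xml2::xml_attr(scan_cv, "accession")
    sval <- xml2::xml_attr(scan_cv, "value")
    rt <- .cv_value(sacc, sval, "MS:1000016")
    unit <- xml2::xml_attr(scan_cv, "unitAccession")[match("MS:1000016", sacc)]
    if (!is.na(unit) && identical(unit, "UO:0000010")) rt <- rt / 60  # s -> min
    it_ms <- .cv_value(sacc, sval, "MS:1000927")
    tic <- .cv_value(acc, xml2::xml_attr(cv, "value"), "MS:1000285")
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- inten <- numeric(0)
    for (arr in arrays) {
      acv <- xml2::xml_find_all(arr, "./cvParam")
      aacc <- xml2::xml_attr(acv, "accession")
      vals <- .decode_binary(xml2::xml_text(xml2::xml_find_first(arr, "./binary")),
                             size = if ("MS:1000521" %in% aacc) 4L else 8L,
                             zlib = "MS:1000574" %in% aacc)
      if ("MS:1000514" %in% aacc) mz <- vals
      if ("MS:1000515" %in% aacc) inten <- vals
    }
    if (length(mz) != length(inten)) {
      stop("spectrum ", i, ": m/z and intensity arrays differ in length")
    }
    noise <- if (!length(mz)) numeric(0)
    else if (noise_strategy == "constant") rep(noise_value, length(mz))
    else rep(max(stats::quantile(inten, percentile / 100, names = FALSE),
                 .Machine$double.eps), length(mz))
    meta_rows[[i]] <- data.frame(
      scan_index = i, rt_min = rt,
      it_ms = if (is.na(it_ms)) 1 else it_ms,
      tic = if (is.na(tic)) sum(inten) else tic,
      microscans = 1, resolution = NA_real_, agc_target = agc_target)
    peak_rows[[i]] <- data.frame(scan_index = rep(i, length(mz)),
                                 mz = mz, intensity = inten, noise = noise)
  }
  meta <- do.call(rbind, meta_rows)
  if (all(is.na(meta$resolution))) meta$resolution <- 60000  # setting not in file
  out <- acquisition(meta, do.call(rbind, peak_rows),
                     source_id = basename(path))
  attr(out, "noise_approximate") <- TRUE
  out
}

.cv_value <- function(accessions, values, want) {
  i <- match(want, accessions)
  if (is.na(i)) NA_real_ else as.numeric(values[i])
}

.decode_binary <- function(b64, size, zlib) {
  b64 <- gsub("[[:space:]]", "", b64)
  if (!nzchar(b64)) return(numeric(0))
  raw <- jsonlite::base64_dec(b64)
  if (zlib) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, what = "double", n = length(raw) / size, size = size,
          endian = "little")
}

#' Cull an acquisition to a retention-time window
#'
#' Direct-infusion runs include a solvent front and a final wash; only a
#' central time segment is used for ratio work. The default window of
#' 2 to 8 minutes keeps the interval between the first and final 2 minutes of
#' a 10-minute acquisition. Closed on both ends; idempotent.
#'
#' @param acq An `orbiso_acquisition`.
#' @param t_start,t_end Window bounds in minutes (defaults 2 and 8).
#' @return The culled `orbiso_acquisition`.
#' @export
cull_time_window <- function(acq, t_start = 2, t_end = 8) {
  stopifnot(inherits(acq, "orbiso_acquisition"))
  if (t_start >= t_end) stop("t_start must be < t_end")
  keep <- acq$meta$rt_min >= t_start & acq$meta$rt_min <= t_end
  if (!any(keep)) {
    stop("no scans inside window [", t_start, ", ", t_end,
         "] min: empty acquisition")
  }
  out <- acq
  out$meta <- acq$meta[keep, , drop = FALSE]
  out$peaks <- acq$peaks[acq$peaks$scan_index %in% out$meta$scan_index, ,
                         drop = FALSE]
  out
}
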