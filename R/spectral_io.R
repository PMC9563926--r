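#' Construct a single mass spectrum
#'
#' The atomic data unit of the pipeline: one full-scan positive-mode spectrum
#' as acquired by the instrument, held as paired m/z and intensity vectors.
#' Intensities are in counts per second (cps), the unit in which the
#' downstream peak height filter is expressed; no unit conversion is ever
#' applied.
#'
#' @param mz Numeric vector of m/z values in Da, strictly increasing.
#' @param intensity Numeric vector of non-negative intensities (cps), same
#'   length as `mz`.
#' @param scan_time Seconds from session start (acquisition time stamp).
#' @param ms_level Integer MS level; the pipeline only uses MS1 scans.
#' @param centroided Logical; `FALSE` for profile-mode data (the default
#'   working mode, since peak picking happens downstream).
#' @param acquisition_range Length-2 numeric, the instrument's configured
#'   m/z acquisition window in Da. Points outside it are retained but
#'   flagged with a warning: the range is an instrument setting, not a
#'   processing rule.
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, scan_time = 0, ms_level = 1L,
                          centroided = FALSE, acquisition_range = c(50, 500)) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("mz must be strictly increasing")
  if (any(!is.finite(intensity)) || any(!is.finite(mz)))
    stop("mz and intensity must be finite (no NaN/Inf)")
  if (any(intensity < 0))
    stop("intensities must be non-negative")
  out_of_range <- length(mz) > 0L &&
    (min(mz) < acquisition_range[1] || max(mz) > acquisition_range[2])
  if (out_of_range)
    warning("spectrum contains points outside the acquisition range ",
            acquisition_range[1], "-", acquisition_range[2],
            " Da; retained and flagged")
  structure(
    list(mz = mz, intensity = intensity, scan_time = as.numeric(scan_time),
         ms_level = as.integer(ms_level), centroided = isTRUE(centroided),
         acquisition_range = acquisition_range, out_of_range = out_of_range),
    class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %d points, m/z %.4f-%.4f, t=%.2fs, TIC=%.1f%s\n",
              length(x$mz),
              if (length(x$mz)) min(x$mz) else NA, if (length(x$mz)) max(x$mz) else NA,
              x$scan_time, sum(x$intensity),
              if (x$centroided) " (centroid)" else " (profile)"))
  invisible(x)
}

#' Total ion current of a spectrum
#'
#' @param spectrum A `mass_spectrum`.
#' @return Sum of all intensities (cps).
#' @export
spectrum_tic <- function(spectrum) sum(spectrum$intensity)

#' Construct a breath measurement session
#'
#' One subject's complete measurement: an ordered stream of full scans
#' covering (by protocol) six consecutive exhalations interleaved with
#' ambient air, plus the subject's clinical metadata.
#'
#' @param subject_id Opaque subject identifier string.
#' @param scans List of [mass_spectrum] objects in acquisition order.
#' @param metadata Optional one-row data.frame of subject metadata (see
#'   [subject_records()]).
#' @return An object of class `breath_session`.
#' @export
breath_session <- function(subject_id, scans, metadata = NULL) {
  if (length(scans) < 1L) stop("a breath session needs at least one scan")
  if (!all(vapply(scans, inherits, logical(1), "mass_spectrum")))
    stop("scans must all be mass_spectrum objects")
  st <- vapply(scans, function(s) s$scan_time, numeric(1))
  if (any(diff(st) < 0)) stop("scan_time must be non-decreasing across scans")
  structure(list(subject_id = as.character(subject_id), scans = scans,
                 metadata = metadata),
            class = "breath_session")
}

#' @export
print.breath_session <- function(x, ...) {
  cat(sprintf("<breath_session> subject '%s': %d scans, %.1f-%.1f s\n",
              x$subject_id, length(x$scans),
              x$scans[[1]]$scan_time, x$scans[[length(x$scans)]]$scan_time))
  invisible(x)
}

#' Number of scans in a session
#' @param session A `breath_session`.
#' @return Integer scan count.
#' @export
n_scans <- function(session) length(session$scans)

#' Per-scan total ion current
#' @param session A `breath_session`.
#' @return Numeric vector of TICs, one per scan, in acquisition order.
#' @export
session_tics <- function(session)
  vapply(session$scans, spectrum_tic, numeric(1))

#' Read a breath session from an mzXML file
#'
#' Parses an mzXML file (the format MSConvert emits from the vendor raw
#' files) into a [breath_session]. Only MS1 scans are kept; scans are
#' returned in acquisition order and never reordered. Profile and centroid
#' data are both accepted and flagged as such.
#'
#' @param path Path to an mzXML file.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param metadata Optional subject metadata attached to the session.
#' @param acquisition_range Instrument m/z window, see [mass_spectrum()].
#' @return A [breath_session].
#' @export
read_mzxml <- function(path, subject_id = NULL, metadata = NULL,
                       acquisition_range = c(50, 500)) {
  if (!file.exists(path)) stop("mzXML file not found: ", path)
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("failed to parse mzXML file '",
                                          path, "': ", conditionMessage(e)))
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0L)
    stop("no MS1 scans in '", path, "': empty session")
  scans <- vector("list", length(ms1))
  for (i in seq_along(ms1)) {
    pk <- mzR::peaks(ms, ms1[i])
    row <- hdr[ms1[i], ]
    cent <- if ("centroided" %in% names(hdr)) isTRUE(row$centroided) else FALSE
    scans[[i]] <- tryCatch(
      mass_spectrum(pk[, 1], pk[, 2], scan_time = row$retentionTime,
                    ms_level = 1L, centroided = cent,
                    acquisition_range = acquisition_range),
      error = function(e) stop("malformed scan ", ms1[i], " in '", path,
                               "': ", conditionMessage(e)))
  }
  breath_session(subject_id, scans, metadata = metadata)
}

#' Write a breath session to an mzXML file
#'
#' Emits a session to disk in mzXML so that synthetic cohorts travel through
#' exactly the same on-disk format the pipeline reads. Round-tripping
#' through [read_mzxml()] reproduces (mz, intensity, scan_time) to within
#' floating-point read precision.
#'
#' @param session A valid [breath_session] with at least one scan.
#' @param path Output file path (extension `.mzXML` recommended).
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(session, path) {
  if (!inherits(session, "breath_session"))
    stop("session must be a breath_session")
  if (length(session$scans) == 0L)
    stop("refusing to write a session without scans")
  n <- length(session$scans)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(session$scans, function(s) s$ms_level, integer(1)),
    polarity = rep(1L, n),
    peaksCount = vapply(session$scans, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(session$scans, spectrum_tic, numeric(1)),
    retentionTime = vapply(session$scans, function(s) s$scan_time, numeric(1)),
    basePeakMZ = vapply(session$scans, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(session$scans, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(session$scans, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(session$scans, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = "",
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = vapply(session$scans, function(s) s$centroided, logical(1)),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = session$scans[[1]]$acquisition_range[1],
    scanWindowUpperLimit = session$scans[[1]]$acquisition_range[2],
    stringsAsFactors = FALSE)
  pks <- lapply(session$scans, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  # mzXML has no slot for the filter string; mzR warns, harmlessly
  suppressWarnings(
    mzR::writeMSData(object = pks, file = path, header = hdr,
                     outformat = "mzxml"))
  invisible(path)
}
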