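#' Default calibrant list: the protonated water cluster series
#'
#' Breath spectra always carry the protonated water clusters, which makes
#' them natural calibrants for session-to-session mass recalibration:
#' `[(H2O)2+H]+` 37.0284, `[(H2O)3+H]+` 55.0390, `[(H2O)4+H]+` 73.0495 Da.
#'
#' @return Numeric vector of calibrant m/z values in Da.
#' @export
water_cluster_mzs <- function() {
  c(dimer = 37.0284, trimer = 55.0390, tetramer = 73.0495)
}

# Locate a calibrant's observed centroid in one spectrum: apex within
# +/- window, then intensity-weighted mean over the contiguous region
# above half the apex. Returns NA when the apex is below min_height.
locate_calibrant <- function(spectrum, calibrant_mz, window = 0.02,
                             min_height = 5) {
  sel <- which(spectrum$mz >= calibrant_mz - window &
               spectrum$mz <= calibrant_mz + window)
  if (length(sel) == 0L) return(NA_real_)
  ints <- spectrum$intensity[sel]
  apex <- which.max(ints)
  if (ints[apex] < min_height) return(NA_real_)
  half <- ints[apex] / 2
  lo <- apex; while (lo > 1L && ints[lo - 1L] >= half) lo <- lo - 1L
  hi <- apex; while (hi < length(ints) && ints[hi + 1L] >= half) hi <- hi + 1L
  idx <- sel[lo:hi]
  sum(spectrum$mz[idx] * spectrum$intensity[idx]) / sum(spectrum$intensity[idx])
}

# The session's most intense scan (max TIC): a breath scan in practice,
# used as the spectrum on which calibrants are located.
most_intense_scan <- function(session) {
  session$scans[[which.max(session_tics(session))]]
}

#' Fit a linear mass recalibration onto a reference breath spectrum
#'
#' All sessions are recalibrated onto one reference breath spectrum so that
#' the same molecular feature lands on the same m/z across subjects despite
#' per-session instrument drift. The correction is a two-parameter linear
#' map `mz_corrected = slope * mz + offset`, least-squares fitted on the
#' observed positions of calibrant ions (by default the protonated water
#' cluster series, always present in breath). TOF drifts are locally linear
#' over 50-500 Da; higher polynomial orders are not identifiable from a
#' handful of calibrants.
#'
#' @param session The [breath_session] to calibrate.
#' @param reference A [mass_spectrum]: the common reference breath spectrum.
#' @param calibrant_mzs Numeric vector of calibrant m/z (Da); default
#'   [water_cluster_mzs()].
#' @param window Coarse search window around each calibrant, Da.
#' @param min_height Minimum apex height (cps) for a calibrant to count as
#'   detected.
#' @return An object of class `calibration_model` with fields `slope`,
#'   `offset`, `reference_id`, `calibrant_mzs`, `residuals` (Da, per matched
#'   calibrant, after the fit) and `accepted` (sanity bounds
#'   slope in \[0.999, 1.001\], |offset| <= 0.05 Da).
#' @export
fit_recalibration <- function(session, reference,
                              calibrant_mzs = water_cluster_mzs(),
                              window = 0.02, min_height = 5) {
  spec <- most_intense_scan(session)
  obs <- vapply(calibrant_mzs, function(m)
    locate_calibrant(spec, m, window, min_height), numeric(1))
  ref <- vapply(calibrant_mzs, function(m)
    locate_calibrant(reference, m, window, min_height), numeric(1))
  ok <- is.finite(obs) & is.finite(ref)
  if (sum(ok) < 2L) {
    missing <- calibrant_mzs[!ok]
    stop("calibration failure: fewer than 2 calibrants matched; missing ",
         paste(sprintf("%.4f", missing), collapse = ", "))
  }
  fit <- stats::lm.fit(cbind(1, obs[ok]), ref[ok])
  offset <- unname(fit$coefficients[1])
  slope <- unname(fit$coefficients[2])
  res <- ref[ok] - (slope * obs[ok] + offset)
  accepted <- slope >= 0.999 && slope <= 1.001 && abs(offset) <= 0.05
  if (!accepted)
    warning("calibration fit outside sanity bounds (slope ", signif(slope, 8),
            ", offset ", signif(offset, 4), " Da); flagged as not accepted")
  structure(list(slope = slope, offset = offset,
                 reference_id = session$subject_id,
                 calibrant_mzs = calibrant_mzs[ok], residuals = res,
                 accepted = accepted),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> slope=%.8f offset=%+.5f Da (max |resid| %.2e Da)%s\n",
              x$slope, x$offset, max(abs(x$residuals)),
              if (x$accepted) "" else " [NOT ACCEPTED]"))
  invisible(x)
}

#' Invert a calibration model
#' @param model A `calibration_model`.
#' @return The algebraic inverse model.
#' @export
invert_calibration <- function(model) {
  structure(list(slope = 1 / model$slope, offset = -model$offset / model$slope,
                 reference_id = model$reference_id,
                 calibrant_mzs = model$calibrant_mzs,
                 residuals = model$residuals, accepted = model$accepted),
            class = "calibration_model")
}

#' Apply a mass recalibration to a session
#'
#' Pure m/z transform (`slope * mz + offset`) on every scan; intensities are
#' untouched and the operation is invertible via [invert_calibration()].
#'
#' @param session A [breath_session].
#' @param model A `calibration_model` from [fit_recalibration()].
#' @return The recalibrated [breath_session].
#' @export
apply_recalibration <- function(session, model) {
  session$scans <- lapply(session$scans, function(s) {
    s$mz <- model$slope * s$mz + model$offset
    s
  })
  session
}

#' Define a common m/z feature grid
#'
#' The uniform axis onto which all spectra are interpolated so that signal
#' intensities are aligned across scans and subjects. Default spacing is
#' 0.001 Da, well under half the width of the narrowest peak a TOF with
#' resolving power ~30,000 produces in 50-500 Da.
#'
#' @param mz_min,mz_max Grid range in Da.
#' @param step Uniform grid spacing in Da.
#' @return An object of class `feature_grid` with field `mz`.
#' @export
feature_grid <- function(mz_min = 50, mz_max = 500, step = 0.001) {
  if (step <= 0) stop("grid step must be positive")
  if (mz_max <= mz_min) stop("mz_max must exceed mz_min")
  structure(list(mz = seq(mz_min, mz_max, by = step), step = step),
            class = "feature_grid")
}

#' Interpolate a spectrum onto a feature grid
#'
#' Linear interpolation of the intensity trace onto the common axis; grid
#' points outside the spectrum's support get zero.
#'
#' @param spectrum A [mass_spectrum].
#' @param grid A [feature_grid()].
#' @return Numeric intensity vector, one value per grid point.
#' @export
interpolate_to_grid <- function(spectrum, grid) {
  if (length(spectrum$mz) == 0L) stop("cannot interpolate an empty spectrum")
  if (max(spectrum$mz) < grid$mz[1] || min(spectrum$mz) > grid$mz[length(grid$mz)])
    stop("spectrum m/z range does not overlap the grid")
  if (length(spectrum$mz) == 1L) {
    out <- numeric(length(grid$mz))
    i <- which.min(abs(grid$mz - spectrum$mz))
    out[i] <- spectrum$intensity
    return(out)
  }
  stats::approx(spectrum$mz, spectrum$intensity, xout = grid$mz,
                yleft = 0, yright = 0)$y
}

#' Select exhalation-phase scans via the water-cluster gate ion
#'
#' A breath session alternates ambient and exhalation phases; only scans
#' acquired during exhalation carry breath signal. Exhalation scans are
#' recognised by the presence of the protonated water trimer
#' `[(H2O)3+H]+` at m/z 55.039: a scan is selected iff its maximum
#' intensity within `gate_mz` +/- `gate_tolerance` strictly exceeds
#' `gate_fraction` times the session-wide maximum of that window. The
#' fractional threshold makes the gate robust to inter-subject intensity
#' scale and reduces to a simple threshold for clean data.
#'
#' @param session A recalibrated [breath_session].
#' @param gate_mz Gate ion m/z, Da (default the water trimer, 55.0390).
#' @param gate_tolerance Half-window around the gate ion, Da.
#' @param gate_fraction Fraction of the session-wide window maximum a scan
#'   must exceed to count as exhalation.
#' @return Integer vector of selected scan indices, in acquisition order.
#' @export
select_breath_scans <- function(session, gate_mz = 55.0390,
                                gate_tolerance = 0.005, gate_fraction = 0.1) {
  win_max <- vapply(session$scans, function(s) {
    sel <- s$mz >= gate_mz - gate_tolerance & s$mz <= gate_mz + gate_tolerance
    if (any(sel)) max(s$intensity[sel]) else 0
  }, numeric(1))
  m <- max(win_max)
  idx <- which(win_max > gate_fraction * m)
  if (m <= 0 || length(idx) == 0L)
    stop("no breath scans detected: water-cluster gate ion absent ",
         "(failed measurement?)")
  idx
}

#' Pick peaks from a gridded intensity trace
#'
#' Detects local maxima (strictly greater than both neighbours; plateaus
#' are resolved to the plateau midpoint) with apex height at or above
#' `min_height` (default 5 cps, the pipeline's height filter). Each peak's
#' centroid is the intensity-weighted mean m/z over the contiguous region
#' above half the apex.
#'
#' @param mz Numeric grid m/z vector (ascending), or a [mass_spectrum].
#' @param intensity Numeric intensity vector (ignored when `mz` is a
#'   spectrum).
#' @param min_height Apex height filter in cps.
#' @return A `peak_list`: data.frame with columns `mz` (centroids,
#'   ascending) and `height` (apex, cps). Empty when nothing passes.
#' @export
pick_peaks <- function(mz, intensity = NULL, min_height = 5) {
  if (inherits(mz, "mass_spectrum")) {
    intensity <- mz$intensity
    mz <- mz$mz
  }
  n <- length(mz)
  empty <- structure(data.frame(mz = numeric(0), height = numeric(0)),
                     class = c("peak_list", "data.frame"))
  if (n < 3L) return(empty)
  # plateau-aware local maxima via run-length encoding of the trace
  r <- rle(intensity)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  apex_idx <- integer(0)
  for (j in seq_len(k)) {
    if (j == 1L || j == k) next          # runs touching the edges are not apexes
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
      mid <- starts[j] + (r$lengths[j] - 1L) %/% 2L   # plateau midpoint
      apex_idx <- c(apex_idx, mid)
    }
  }
  if (length(apex_idx) == 0L) return(empty)
  heights <- intensity[apex_idx]
  keep <- heights >= min_height
  apex_idx <- apex_idx[keep]
  heights <- heights[keep]
  if (length(apex_idx) == 0L) return(empty)
  cent <- vapply(seq_along(apex_idx), function(i) {
    a <- apex_idx[i]
    half <- intensity[a] / 2
    lo <- a; while (lo > 1L && intensity[lo - 1L] >= half) lo <- lo - 1L
    hi <- a; while (hi < n && intensity[hi + 1L] >= half) hi <- hi + 1L
    sum(mz[lo:hi] * intensity[lo:hi]) / sum(intensity[lo:hi])
  }, numeric(1))
  ord <- order(cent)
  structure(data.frame(mz = cent[ord], height = heights[ord]),
            class = c("peak_list", "data.frame"))
}

#' Average a subject's breath scans into a feature profile
#'
#' Interpolates each selected exhalation scan onto the common grid, takes
#' the arithmetic mean per grid point, and peak-picks the averaged trace to
#' obtain the subject's feature list. Averaging before picking (rather than
#' picking per scan and averaging centroids) is the default; the
#' alternative order is available via `per_scan = TRUE`.
#'
#' @param session A recalibrated [breath_session].
#' @param indices Integer scan indices from [select_breath_scans()].
#' @param grid A [feature_grid()].
#' @param min_height Peak height filter, cps.
#' @param per_scan If `TRUE`, pick peaks on each scan separately and average
#'   matched peak heights instead (alignment at `0.005` Da).
#' @return A `subject_profile`: list with `subject_id`, `feature_mz`,
#'   `feature_intensity`, `tic` (sum of feature intensities) and `n_scans`.
#' @export
average_breath_scans <- function(session, indices, grid, min_height = 5,
                                 per_scan = FALSE) {
  if (length(indices) == 0L) stop("empty breath-scan index set")
  if (any(indices < 1L | indices > length(session$scans)))
    stop("scan index out of range")
  if (per_scan) {
    pls <- lapply(indices, function(i)
      pick_peaks(interp_spectrum(session$scans[[i]], grid), min_height = 0))
    pooled <- do.call(rbind, pls)
    if (nrow(pooled) == 0L) {
      pk <- data.frame(mz = numeric(0), height = numeric(0))
    } else {
      cl <- cluster_mz(pooled$mz, 0.005)
      pk <- do.call(rbind, lapply(split(pooled, cl), function(d)
        data.frame(mz = stats::weighted.mean(d$mz, pmax(d$height, 1e-12)),
                   height = sum(d$height) / length(indices))))
      pk <- pk[pk$height >= min_height, , drop = FALSE]
      pk <- pk[order(pk$mz), , drop = FALSE]
    }
  } else {
    acc <- numeric(length(grid$mz))
    for (i in indices)
      acc <- acc + interpolate_to_grid(session$scans[[i]], grid)
    avg <- acc / length(indices)
    pk <- pick_peaks(grid$mz, avg, min_height = min_height)
  }
  structure(list(subject_id = session$subject_id,
                 feature_mz = pk$mz, feature_intensity = pk$height,
                 tic = sum(pk$height), n_scans = length(indices)),
            class = "subject_profile")
}

# wrap a gridded trace back into a spectrum (per-scan picking path)
interp_spectrum <- function(spectrum, grid) {
  y <- interpolate_to_grid(spectrum, grid)
  structure(list(mz = grid$mz, intensity = y, scan_time = spectrum$scan_time,
                 ms_level = 1L, centroided = FALSE,
                 acquisition_range = spectrum$acquisition_range,
                 out_of_range = FALSE),
            class = "mass_spectrum")
}

# single-linkage clustering of sorted 1-D positions: cut where the gap
# between neighbours exceeds the tolerance (equivalent to hclust single
# linkage cut at that height). Returns integer cluster ids per input value.
cluster_mz <- function(mz, tolerance) {
  ord <- order(mz)
  sorted <- mz[ord]
  breaks <- c(FALSE, diff(sorted) > tolerance)
  ids_sorted <- cumsum(breaks) + 1L
  ids <- integer(length(mz))
  ids[ord] <- ids_sorted
  ids
}

#' Align subject profiles into a subject-by-feature intensity matrix
#'
#' Features from all subjects are pooled and single-linkage clustered along
#' m/z with cluster link distance at most `align_tolerance` (0.005 Da, the
#' same tolerance later used for marker matching). Each cluster becomes one
#' matrix column; its representative m/z is the intensity-weighted mean of
#' its members. Subjects lacking a feature in a cluster get intensity 0 —
#' absent signal, not a missing value, matching TIC semantics.
#'
#' @param profiles List of `subject_profile` objects (>= 2).
#' @param align_tolerance Cluster link tolerance in Da.
#' @return An `intensity_matrix` in state `"raw"`: list with `values`
#'   (subjects x features), `subject_ids`, `feature_mz`, `tics` (per-subject
#'   raw TIC) and `state`.
#' @export
build_feature_matrix <- function(profiles, align_tolerance = 0.005) {
  if (length(profiles) < 2L) stop("need at least two subject profiles")
  subj <- vapply(profiles, function(p) p$subject_id, character(1))
  if (anyDuplicated(subj)) stop("duplicate subject ids among profiles")
  pooled <- do.call(rbind, lapply(seq_along(profiles), function(i)
    data.frame(subject = i, mz = profiles[[i]]$feature_mz,
               intensity = profiles[[i]]$feature_intensity)))
  if (nrow(pooled) == 0L)
    stop("no features in any profile")
  cl <- cluster_mz(pooled$mz, align_tolerance)
  ncl <- max(cl)
  rep_mz <- numeric(ncl)
  values <- matrix(0, nrow = length(profiles), ncol = ncl,
                   dimnames = list(subj, NULL))
  for (j in seq_len(ncl)) {
    d <- pooled[cl == j, , drop = FALSE]
    w <- d$intensity
    rep_mz[j] <- if (sum(w) > 0) sum(d$mz * w) / sum(w) else mean(d$mz)
    agg <- tapply(d$intensity, d$subject, sum)
    values[as.integer(names(agg)), j] <- agg
  }
  ord <- order(rep_mz)
  structure(list(values = values[, ord, drop = FALSE], subject_ids = subj,
                 feature_mz = rep_mz[ord],
                 tics = vapply(profiles, function(p) p$tic, numeric(1)),
                 state = "raw"),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d subjects x %d features [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' Normalization cascade: TIC, median-TIC scaling, auto-scaling
#'
#' Advances an intensity matrix through the fixed normalization order
#' `raw -> tic_normalized -> median_scaled -> autoscaled`:
#' 1. divide each subject row by its total ion current (rows then sum to 1);
#' 2. multiply all rows by the median TIC across included subjects (restores
#'    an interpretable cps scale);
#' 3. auto-scale: per-feature z-score (column mean 0, SD 1). The SD uses the
#'    population (n) convention by default, configurable to sample (n-1).
#' Columns with zero variance are dropped at the auto-scaling step with a
#' warning. The `tic_normalized` values are retained alongside the final
#' matrix (field `tic_values`) because z-scores destroy the ratios needed
#' for fold changes.
#'
#' @param matrix An `intensity_matrix` in state `"raw"`.
#' @param to Target state, one of `"tic_normalized"`, `"median_scaled"`,
#'   `"autoscaled"` (default).
#' @param sd_type `"population"` (divide by n) or `"sample"` (n-1).
#' @return The matrix advanced to the requested state; when the cascade has
#'   passed `tic_normalized`, field `tic_values` holds the TIC-normalized
#'   rows for all retained features.
#' @export
normalize_cascade <- function(matrix, to = "autoscaled",
                              sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  to <- match.arg(to, c("tic_normalized", "median_scaled", "autoscaled"))
  if (matrix$state != "raw")
    stop("normalize_cascade expects a matrix in state 'raw', got '",
         matrix$state, "'")
  tics <- matrix$tics
  if (any(tics <= 0)) {
    bad <- matrix$subject_ids[tics <= 0]
    stop("zero TIC for subject(s): ", paste(bad, collapse = ", "))
  }
  v <- sweep(matrix$values, 1, tics, "/")
  matrix$values <- v
  matrix$state <- "tic_normalized"
  if (to == "tic_normalized") return(matrix)

  med <- stats::median(tics)
  matrix$tic_values <- v
  matrix$values <- v * med
  matrix$state <- "median_scaled"
  if (to == "median_scaled") return(matrix)

  m <- matrix$values
  mu <- colMeans(m)
  n <- nrow(m)
  sdv <- sqrt(colSums(sweep(m, 2, mu)^2) /
              (if (sd_type == "population") n else n - 1L))
  keep <- sdv > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance feature(s) dropped at auto-scaling")
  matrix$values <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]),
                         2, sdv[keep], "/")
  matrix$tic_values <- matrix$tic_values[, keep, drop = FALSE]
  matrix$feature_mz <- matrix$feature_mz[keep]
  matrix$state <- "autoscaled"
  matrix
}

#' Write an intensity matrix to CSV (with a JSON sidecar)
#'
#' Columns are named by representative m/z to 4 decimals; the sidecar
#' records the normalization state and per-subject TICs.
#'
#' @param matrix An `intensity_matrix`.
#' @param path Output CSV path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(matrix, path) {
  df <- as.data.frame(matrix$values)
  names(df) <- sprintf("%.4f", matrix$feature_mz)
  df <- cbind(subject_id = matrix$subject_ids, df)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(state = matrix$state, n_subjects = nrow(matrix$values),
               n_features = ncol(matrix$values),
               tics = as.list(stats::setNames(matrix$tics, matrix$subject_ids)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
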