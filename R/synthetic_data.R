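#' Configuration for a synthetic breath cohort
#'
#' Defines the study conditions a generated cohort emulates: group sizes as
#' in the validation cohort (43 untreated OSA, 43 CPAP-treated OSA, 32
#' controls), six exhalations per measurement at 0.5 s scan accumulation,
#' marker intensities log-normal across subjects (breath intensities are
#' right-skewed, which is what motivates the nonparametric testing), a
#' per-subject linear mass drift, TOF-like Gaussian peak shapes at
#' resolving power ~30,000, and a trapezoidal water-cluster burst marking
#' each exhalation.
#'
#' The default planted effect raises the nine significant markers'
#' untreated-group log-intensity by 0.73 between-subject log-SD units,
#' which with `sigma_log = 0.5` corresponds to a median fold change of
#' about 1.44 (the reported 2-butylfuran fold change).
#'
#' @param n_untreated,n_treated,n_control Group sizes.
#' @param marker_mz Panel feature m/z values the generator emits; default
#'   the 42 detectable features of [osa_panel()].
#' @param effect_table Named numeric vector (names = `sprintf("%.4f", mz)`)
#'   of per-marker untreated-vs-rest median shifts in units of
#'   `sigma_log`; markers not named get 0. Default: 0.73 for the nine
#'   significant markers, 0 elsewhere.
#' @param sigma_log Between-subject SD of log intensity.
#' @param log_height_range Range of per-feature baseline log mean height
#'   (cps) from which feature abundances are drawn.
#' @param baseline_n Number of non-panel background features.
#' @param noise_sd Per-point additive intensity noise SD, cps.
#' @param mass_drift_range Per-subject mass-axis offset range, Da
#'   (|drift| <= 0.01).
#' @param n_exhalations Exhalations per session.
#' @param ambient_scans,exhalation_scans Scans per ambient / exhalation
#'   block.
#' @param scan_period Scan accumulation time, s.
#' @param gate_height Water-trimer plateau intensity, cps.
#' @param resolution Mass resolving power m/dm (FWHM) for peak widths.
#' @param mz_range Acquisition m/z window of the synthetic instrument, Da.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_untreated = 43, n_treated = 43, n_control = 32,
                          marker_mz = NULL, effect_table = NULL,
                          sigma_log = 0.5, log_height_range = log(c(20, 400)),
                          baseline_n = 30, noise_sd = 2,
                          mass_drift_range = c(-0.003, 0.003),
                          n_exhalations = 6, ambient_scans = 4,
                          exhalation_scans = 8, scan_period = 0.5,
                          gate_height = 1000, resolution = 30000,
                          mz_range = c(50, 210)) {
  if (is.null(marker_mz)) {
    p <- osa_panel()
    marker_mz <- p$mz[attr(p, "detectable")]
  }
  if (is.null(effect_table)) {
    sig9 <- intersect(sprintf("%.4f", table2_panel()$mz),
                      sprintf("%.4f", marker_mz))
    effect_table <- stats::setNames(rep(0.73, length(sig9)), sig9)
  }
  stopifnot(n_untreated > 0, n_treated >= 0, n_control >= 0,
            noise_sd >= 0, max(abs(mass_drift_range)) <= 0.01,
            n_exhalations >= 1, exhalation_scans >= 1, ambient_scans >= 1)
  effects <- stats::setNames(rep(0, length(marker_mz)),
                             sprintf("%.4f", marker_mz))
  known <- intersect(names(effect_table), names(effects))
  effects[known] <- effect_table[known]
  structure(list(n_untreated = n_untreated, n_treated = n_treated,
                 n_control = n_control, marker_mz = sort(marker_mz),
                 effects = effects[sprintf("%.4f", sort(marker_mz))],
                 sigma_log = sigma_log, log_height_range = log_height_range,
                 baseline_n = baseline_n, noise_sd = noise_sd,
                 mass_drift_range = mass_drift_range,
                 n_exhalations = n_exhalations,
                 ambient_scans = ambient_scans,
                 exhalation_scans = exhalation_scans,
                 scan_period = scan_period, gate_height = gate_height,
                 resolution = resolution, mz_range = mz_range),
            class = "cohort_config")
}

# clinical metadata sampled per group from log-normal / clipped-normal
# approximations of the cohort's baseline characteristics (AHI untreated
# median ~28, treated at visit ~1.3 but ~35 at diagnosis; ESS medians 5-8;
# CPAP usage centred near 5.8 h/night so roughly two thirds meet the
# 5 h/night stratification bar).
simulate_metadata <- function(config) {
  rln <- function(n, med, slog) stats::rlnorm(n, log(med), slog)
  ess_draw <- function(n, med) pmin(24, round(rln(n, med, 0.55)))
  n_u <- config$n_untreated; n_t <- config$n_treated; n_c <- config$n_control
  df <- data.frame(
    subject_id = c(sprintf("U%03d", seq_len(n_u)),
                   sprintf("T%03d", seq_len(n_t)),
                   sprintf("C%03d", seq_len(n_c))),
    group = rep(c("osa_untreated", "osa_treated", "control"),
                c(n_u, n_t, n_c)),
    stringsAsFactors = FALSE)
  df$ahi_visit <- c(rln(n_u, 28.0, 0.56), rln(n_t, 1.3, 0.80),
                    rep(NA_real_, n_c))
  df$ahi_diagnosis <- c(rln(n_u, 30.2, 0.47), rln(n_t, 35.5, 0.46),
                        rln(n_c, 3.0, 0.50))
  df$odi <- c(rln(n_u, 29.9, 0.60), rep(NA_real_, n_t), rln(n_c, 4.5, 0.60))
  df$ess <- c(ess_draw(n_u, 5), ess_draw(n_t, 6), ess_draw(n_c, 7.5))
  df$cpap_hours <- c(rep(NA_real_, n_u),
                     pmin(10, pmax(0, stats::rnorm(n_t, 5.8, 1.6))),
                     rep(NA_real_, n_c))
  subject_records(df)
}

#' Simulate a cohort at the intensity-matrix level
#'
#' Draws the per-subject true averaged peak heights (cps) that
#' parameterise full scan-stream synthesis: for each feature a baseline
#' log-mean abundance, log-normal between-subject variation
#' (`sigma_log`), and for panel markers with a planted effect an upward
#' shift of the untreated group's log intensity by `effect x sigma_log`.
#' Background (non-panel) features carry no group effect. This is the
#' fast layer used for large simulation studies (null calibration, power),
#' and the exact height table [generate_session()] plants into scans.
#'
#' @param config A [cohort_config()].
#' @param seed Integer RNG seed.
#' @return List with `heights` (subjects x features, cps), `feature_mz`,
#'   `is_marker`, `metadata` ([subject_records()]), `effects` (per marker,
#'   in `sigma_log` units) and `config`.
#' @export
simulate_intensity_cohort <- function(config = cohort_config(), seed = 1L) {
  set.seed(seed)
  meta <- simulate_metadata(config)
  n_sub <- nrow(meta)
  # background features: kept well clear of panel masses so alignment and
  # matching stay unambiguous
  base_mz <- numeric(0)
  guard <- sort(config$marker_mz)
  lo <- config$mz_range[1] + 1; hi <- config$mz_range[2] - 1
  while (length(base_mz) < config$baseline_n) {
    cand <- round(stats::runif(1, lo, hi), 4)
    if (all(abs(cand - c(guard, base_mz,
                         water_cluster_mzs())) > 0.05))
      base_mz <- c(base_mz, cand)
  }
  feature_mz <- c(config$marker_mz, sort(base_mz))
  is_marker <- c(rep(TRUE, length(config$marker_mz)),
                 rep(FALSE, length(base_mz)))
  n_feat <- length(feature_mz)
  meanlog <- stats::runif(n_feat, config$log_height_range[1],
                          config$log_height_range[2])
  eff <- c(config$effects, rep(0, length(base_mz)))
  shift <- outer(meta$group == "osa_untreated", eff * config$sigma_log)
  z <- matrix(stats::rnorm(n_sub * n_feat), n_sub, n_feat)
  heights <- exp(sweep(z * config$sigma_log + shift, 2, meanlog, "+"))
  rownames(heights) <- meta$subject_id
  list(heights = heights, feature_mz = feature_mz, is_marker = is_marker,
       metadata = meta, effects = config$effects, config = config)
}

#' Turn a simulated cohort into a raw intensity matrix
#'
#' Packages the true height table of [simulate_intensity_cohort()] as an
#' `intensity_matrix` in state `"raw"`, ready for [normalize_cascade()] —
#' the entry point for matrix-level simulation studies that skip spectral
#' synthesis.
#'
#' @param sim Output of [simulate_intensity_cohort()].
#' @return An `intensity_matrix` (state `"raw"`).
#' @export
as_intensity_matrix <- function(sim) {
  structure(list(values = sim$heights, subject_ids = rownames(sim$heights),
                 feature_mz = sim$feature_mz, tics = rowSums(sim$heights),
                 state = "raw"),
            class = "intensity_matrix")
}

# union of per-peak sampling windows plus a sparse 1-Da baseline comb;
# returns sorted unique native m/z axis and, per peak, the index window
build_native_axis <- function(peak_mz, resolution, mz_range) {
  sig <- peak_mz / (resolution * 2 * sqrt(2 * log(2)))
  pts <- lapply(seq_along(peak_mz), function(i)
    peak_mz[i] + seq(-3, 3, by = 0.5) * sig[i])
  comb <- seq(mz_range[1], mz_range[2], by = 1.0)
  axis <- sort(unique(round(c(unlist(pts), comb), 7)))
  axis <- axis[axis >= mz_range[1] & axis <= mz_range[2]]
  axis <- axis[c(TRUE, diff(axis) > 1e-7)]
  idx <- lapply(seq_along(peak_mz), function(i) {
    which(axis >= peak_mz[i] - 3.5 * sig[i] & axis <= peak_mz[i] + 3.5 * sig[i])
  })
  list(axis = axis, sigma = sig, window = idx)
}

#' Generate one synthetic breath session
#'
#' Emits a scan stream alternating ambient blocks (low background, no
#' water-cluster burst) and exhalation blocks in which the water-cluster
#' series bursts on (trapezoidal ramp on the gate trimer) and breath
#' features appear as Gaussian profiles of constant height on the m/z
#' axis, plus additive noise. A subject-specific linear mass drift is
#' applied to the whole axis. Deterministic given the seed.
#'
#' @param subject_id Subject identifier.
#' @param feature_heights Named numeric vector: true averaged peak heights
#'   (cps) per feature, names `sprintf("%.4f", mz)`.
#' @param feature_mz Numeric vector of true feature m/z (Da), matching
#'   `feature_heights` order.
#' @param config A [cohort_config()].
#' @param seed Integer RNG seed.
#' @param drift Optional list(slope, offset); when `NULL`, drawn from
#'   `config$mass_drift_range`.
#' @return List with `session` (a [breath_session]) and `truth` (exhalation
#'   windows, drift, feature table).
#' @export
generate_session <- function(subject_id, feature_heights, feature_mz,
                             config = cohort_config(), seed = 1L,
                             drift = NULL) {
  set.seed(seed)
  if (is.null(drift))
    drift <- list(slope = 1 + stats::runif(1, -5e-6, 5e-6),
                  offset = stats::runif(1, config$mass_drift_range[1],
                                        config$mass_drift_range[2]))
  gate <- water_cluster_mzs()
  gate_height <- config$gate_height * c(dimer = 0.6, trimer = 1, tetramer = 0.3)
  true_mz <- c(unname(gate), feature_mz)
  heights <- c(unname(gate_height), unname(feature_heights))
  obs_mz <- drift$slope * true_mz + drift$offset
  ax <- build_native_axis(obs_mz, config$resolution, config$mz_range)
  n_peaks <- length(obs_mz)
  # per-peak Gaussian profile evaluated once on its axis window
  shapes <- lapply(seq_len(n_peaks), function(i) {
    w <- ax$window[[i]]
    list(idx = w, y = exp(-(ax$axis[w] - obs_mz[i])^2 / (2 * ax$sigma[i]^2)))
  })
  # trapezoidal gate ramp across an exhalation block; plateau for features
  ramp <- rep(1, config$exhalation_scans)
  if (config$exhalation_scans >= 2) ramp[c(1, config$exhalation_scans)] <- 0.5
  blocks <- c(rep(list(c("ambient", "exhale")), config$n_exhalations),
              list("ambient"))
  phases <- unlist(blocks)
  n_total <- sum(ifelse(phases == "ambient", config$ambient_scans,
                        config$exhalation_scans))
  scans <- vector("list", n_total)
  windows <- list()
  t0 <- 0; k <- 0L
  for (ph in phases) {
    len <- if (ph == "ambient") config$ambient_scans else config$exhalation_scans
    if (ph == "exhale") windows[[length(windows) + 1L]] <- (k + 1L):(k + len)
    for (s in seq_len(len)) {
      k <- k + 1L
      y <- numeric(length(ax$axis))
      if (ph == "exhale") {
        for (i in seq_len(n_peaks)) {
          amp <- heights[i] * if (i <= 3L) ramp[s] else 1  # gate ions ramp
          y[shapes[[i]]$idx] <- y[shapes[[i]]$idx] + amp * shapes[[i]]$y
        }
      }
      if (config$noise_sd > 0)
        y <- pmax(0, y + stats::rnorm(length(y), 0, config$noise_sd))
      scans[[k]] <- mass_spectrum(ax$axis, y,
                                  scan_time = (k - 1L) * config$scan_period,
                                  acquisition_range = config$mz_range)
      t0 <- t0 + config$scan_period
    }
  }
  list(session = breath_session(subject_id, scans),
       truth = list(windows = windows, drift = drift,
                    feature_mz = feature_mz,
                    feature_height = unname(feature_heights)))
}

#' Generate a full synthetic breath cohort
#'
#' Draws the cohort's true intensity table and clinical metadata via
#' [simulate_intensity_cohort()], then synthesises one breath session per
#' subject with [generate_session()]. When `out_dir` is given, each
#' session is written as mzXML alongside `subjects.csv` (metadata) and
#' `ground_truth.json` — the same artifact layout the pipeline consumes.
#' Fully reproducible from the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer RNG seed.
#' @param out_dir Optional output directory (created if needed).
#' @return List with `sessions` (list of [breath_session]), `truth`
#'   (per-subject windows/drift plus the cohort simulation), `metadata`,
#'   and `files` (paths, when written).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            out_dir = NULL) {
  sim <- simulate_intensity_cohort(config, seed)
  n_sub <- nrow(sim$heights)
  sessions <- vector("list", n_sub)
  truth <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    g <- generate_session(
      sim$metadata$subject_id[i],
      stats::setNames(sim$heights[i, ], sprintf("%.4f", sim$feature_mz)),
      sim$feature_mz, config, seed = seed + 1000L + i)
    sessions[[i]] <- g$session
    truth[[i]] <- g$truth
  }
  names(sessions) <- names(truth) <- sim$metadata$subject_id
  files <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
    files <- character(n_sub)
    for (i in seq_len(n_sub)) {
      files[i] <- file.path(out_dir,
                            paste0(sim$metadata$subject_id[i], ".mzXML"))
      write_mzxml(sessions[[i]], files[i])
    }
    utils::write.csv(as.data.frame(sim$metadata),
                     file.path(out_dir, "subjects.csv"), row.names = FALSE)
    gt <- list(seed = seed,
               effects = as.list(sim$effects),
               feature_mz = sim$feature_mz,
               is_marker = sim$is_marker,
               subjects = lapply(truth, function(t)
                 list(windows = t$windows,
                      drift = t$drift,
                      feature_height = t$feature_height)))
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(sessions = sessions, truth = truth, metadata = sim$metadata,
       sim = sim, files = files)
}
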