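# Shared in-code fixtures: every spectral object is built programmatically.

# profile-mode Gaussian peak(s) on a uniform axis
gaussian_spectrum <- function(centers, heights, sigma = 0.0015,
                              mz_range = range(centers) + c(-0.5, 0.5),
                              step = 0.0005, scan_time = 0,
                              acquisition_range = c(50, 500)) {
  mz <- seq(mz_range[1], mz_range[2], by = step)
  y <- numeric(length(mz))
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-(mz - centers[i])^2 / (2 * sigma^2))
  mass_spectrum(mz, y, scan_time = scan_time,
                acquisition_range = acquisition_range)
}

# minimal session: gate trimer + one marker peak in every scan
tiny_session <- function(subject_id = "S1", n = 3, marker_mz = 125.0958,
                         marker_height = 50, gate_height = 1000,
                         mz_shift = 0) {
  scans <- lapply(seq_len(n), function(i)
    gaussian_spectrum(c(37.0284, 55.0390, 73.0495, marker_mz) + mz_shift,
                      c(0.6, 1, 0.3, marker_height / gate_height) * gate_height,
                      mz_range = c(36, marker_mz + 1),
                      scan_time = (i - 1) * 0.5,
                      acquisition_range = c(30, 500)))
  breath_session(subject_id, scans)
}

# small fast cohort configuration for spectral-path tests
small_cohort_config <- function(...) {
  cohort_config(n_untreated = 3, n_treated = 3, n_control = 0,
                baseline_n = 5, mz_range = c(50, 210), ...)
}

# metadata row builder for stratification tests
meta_row <- function(id, group, ahi_visit = NA, ahi_diagnosis = NA,
                     odi = NA, ess = 0, cpap_hours = NA) {
  data.frame(subject_id = id, group = group,
             ahi_visit = as.numeric(ahi_visit),
             ahi_diagnosis = as.numeric(ahi_diagnosis),
             odi = as.numeric(odi), ess = as.numeric(ess),
             cpap_hours = as.numeric(cpap_hours),
             stringsAsFactors = FALSE)
}

# brute-force two-sided Mann-Whitney permutation p over all labelings
brute_force_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  combs <- utils::combn(n, n1)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_all <- apply(combs, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  u_min <- min(u_obs, n1 * (n - n1) - u_obs)
  min(1, 2 * mean(u_all <= u_min))
}
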