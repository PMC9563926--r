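test_that("recalibration is exact for identity and planted shifts", {
  ses <- tiny_session()
  ref <- most_intense <- ses$scans[[1]]
  m0 <- fit_recalibration(ses, ref)
  expect_equal(m0$slope, 1, tolerance = 1e-9)
  expect_equal(m0$offset, 0, tolerance = 1e-9)

  shifted <- tiny_session(mz_shift = +0.002)
  m <- fit_recalibration(shifted, ref)
  expect_equal(m$offset, -0.002, tolerance = 5e-4)
  expect_lt(max(abs(m$residuals)), 5e-4)
  # water trimer maps back onto its reference position
  corr <- apply_recalibration(shifted, m)
  apex <- corr$scans[[1]]$mz[which.max(
    corr$scans[[1]]$intensity * (abs(corr$scans[[1]]$mz - 55.039) < 0.02))]
  expect_lt(abs(apex - 55.0390), 5e-4)
})

test_that("recalibration recovers random linear drifts below 5e-4 Da", {
  ref <- tiny_session()$scans[[1]]
  for (seed in 1:8) {
    set.seed(seed)
    off <- runif(1, -0.01, 0.01)
    sl <- 1 + runif(1, -2e-5, 2e-5)
    scans <- lapply(tiny_session()$scans, function(s) {
      s$mz <- sl * s$mz + off
      s
    })
    drifted <- breath_session("d", scans)
    m <- fit_recalibration(drifted, ref)
    expect_lt(max(abs(m$residuals)), 5e-4)
    expect_true(m$accepted)
  }
})

test_that("apply_recalibration is pure, invertible, and identity-stable", {
  ses <- tiny_session()
  ident <- structure(list(slope = 1, offset = 0, reference_id = "r",
                          calibrant_mzs = 55.039, residuals = 0,
                          accepted = TRUE), class = "calibration_model")
  expect_equal(apply_recalibration(ses, ident), ses)
  mod <- structure(list(slope = 1.00001, offset = -0.004, reference_id = "r",
                        calibrant_mzs = 55.039, residuals = 0,
                        accepted = TRUE), class = "calibration_model")
  fwd <- apply_recalibration(ses, mod)
  expect_equal(fwd$scans[[1]]$intensity, ses$scans[[1]]$intensity)  # untouched
  back <- apply_recalibration(fwd, invert_calibration(mod))
  expect_equal(back$scans[[1]]$mz, ses$scans[[1]]$mz, tolerance = 1e-12)
})

test_that("fit_recalibration fails with fewer than two matched calibrants", {
  # a session with only the marker peak, no water-cluster series
  scans <- lapply(1:2, function(i)
    gaussian_spectrum(125.0958, 50, mz_range = c(120, 130),
                      scan_time = i - 1))
  bare <- breath_session("b", scans)
  expect_error(fit_recalibration(bare, tiny_session()$scans[[1]]),
               "calibration failure")
})

test_that("grid interpolation is linear, support-limited, area-preserving", {
  g <- feature_grid(100, 101, 0.001)
  sp <- mass_spectrum(c(100.000, 100.002), c(0, 10))
  y <- interpolate_to_grid(sp, g)
  expect_equal(y[g$mz == 100.001], 5)             # linear midpoint
  expect_equal(y[g$mz == 100.5], 0)               # outside support -> 0

  onto_itself <- mass_spectrum(g$mz, seq_along(g$mz))
  expect_equal(interpolate_to_grid(onto_itself, g), as.numeric(seq_along(g$mz)))

  # Gaussian resampled to a 2x finer grid preserves area within 1%
  sigma <- 0.004
  native <- seq(99.9, 100.1, by = 0.002)
  peak <- mass_spectrum(native, 10 * exp(-(native - 100)^2 / (2 * sigma^2)))
  fine <- feature_grid(99.9, 100.1, 0.001)
  area_native <- sum(peak$intensity) * 0.002      # quadrature oracle
  area_fine <- sum(interpolate_to_grid(peak, fine)) * 0.001
  expect_lt(abs(area_fine - area_native) / area_native, 0.01)

  expect_error(interpolate_to_grid(mass_spectrum(numeric(0), numeric(0)), g),
               "empty")
  expect_error(interpolate_to_grid(mass_spectrum(200, 5), g),
               "does not overlap")
})

test_that("breath-scan gate selects planted exhalation windows exactly", {
  cfg <- small_cohort_config(noise_sd = 2)
  g <- generate_session("G1", setNames(80, "120.0500"), 120.05, cfg, seed = 3)
  sel <- select_breath_scans(g$session)
  expect_identical(sel, unlist(g$truth$windows))
})

test_that("gate threshold is monotone and handles edge cases", {
  ses <- tiny_session(n = 5)                       # identical scans: all gate
  expect_identical(select_breath_scans(ses), 1:5)
  # zero signal near the trimer -> no-breath error
  scans <- lapply(1:3, function(i)
    gaussian_spectrum(125.0958, 50, mz_range = c(54, 126),
                      scan_time = i - 1))
  expect_error(select_breath_scans(breath_session("n", scans)),
               "no breath scans")
  # raising gate_fraction never adds a scan
  cfg <- small_cohort_config(noise_sd = 2)
  g <- generate_session("G2", setNames(80, "120.0500"), 120.05, cfg, seed = 9)
  prev <- select_breath_scans(g$session, gate_fraction = 0.05)
  for (f in c(0.1, 0.3, 0.6, 0.9)) {
    cur <- select_breath_scans(g$session, gate_fraction = f)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("peak picking centroids Gaussians and applies the height filter", {
  expect_equal(nrow(pick_peaks(seq(100, 101, 0.001),
                               rep(0, 1001))), 0)   # flat zero
  g <- seq(99.9, 100.1, by = 0.001)
  y <- 10 * exp(-(g - 100.0000)^2 / (2 * 0.0015^2))
  pk <- pick_peaks(g, y)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - 100.0000), 0.001)
  expect_equal(pk$height, 10, tolerance = 1e-6)
  # filter boundary: 4.9 cps excluded, 5.0 cps included
  expect_equal(nrow(pick_peaks(g, y * 0.49)), 0)
  expect_equal(nrow(pick_peaks(g, y * 0.50)), 1)
  # plateau resolved to its midpoint
  yy <- c(0, 1, 6, 6, 6, 1, 0)
  pp <- pick_peaks(seq_along(yy), yy, min_height = 5)
  expect_equal(nrow(pp), 1)
  expect_equal(pp$height, 6)
  expect_equal(pp$mz, sum(c(3, 4, 5) * 6) / 18)     # half-apex region = plateau
})

test_that("raising the height filter never adds a peak", {
  set.seed(11)
  g <- seq(50, 52, by = 0.001)
  for (rep in 1:5) {
    y <- pmax(0, stats::filter(rnorm(length(g), 2, 4), rep(1 / 5, 5),
                               circular = TRUE))
    prev <- nrow(pick_peaks(g, as.numeric(y), min_height = 0))
    for (h in c(2, 5, 10, 20)) {
      cur <- nrow(pick_peaks(g, as.numeric(y), min_height = h))
      expect_lte(cur, prev)
      prev <- cur
    }
  }
})

test_that("breath-scan averaging is the arithmetic mean of scans", {
  grid <- feature_grid(54, 126, 0.001)
  ses <- tiny_session(n = 1, marker_height = 50)
  prof1 <- average_breath_scans(ses, 1L, grid)
  direct <- pick_peaks(grid$mz, interpolate_to_grid(ses$scans[[1]], grid))
  expect_equal(prof1$feature_mz, direct$mz)
  expect_equal(prof1$feature_intensity, direct$height)
  expect_equal(prof1$tic, sum(direct$height))

  # two scans with one peak at 4 and 8 cps -> averaged height 6
  s4 <- gaussian_spectrum(c(55.039, 100.05), c(1000, 4), mz_range = c(54, 101))
  s8 <- gaussian_spectrum(c(55.039, 100.05), c(1000, 8), mz_range = c(54, 101),
                          scan_time = 0.5)
  ses2 <- breath_session("avg", list(s4, s8))
  prof <- average_breath_scans(ses2, 1:2, feature_grid(54, 101, 0.001))
  near <- which.min(abs(prof$feature_mz - 100.05))
  expect_equal(prof$feature_intensity[near], 6, tolerance = 0.02)

  expect_error(average_breath_scans(ses, integer(0), grid), "empty")
  expect_error(average_breath_scans(ses, 99L, grid), "out of range")
})

test_that("feature alignment merges within tolerance, splits beyond it", {
  mk_prof <- function(id, mz, int) structure(
    list(subject_id = id, feature_mz = mz, feature_intensity = int,
         tic = sum(int), n_scans = 1L), class = "subject_profile")
  p1 <- mk_prof("a", c(100.0, 125.0958), c(10, 20))
  p2 <- mk_prof("b", c(100.0, 125.0960), c(10, 40))
  m <- build_feature_matrix(list(p1, p2))
  expect_equal(ncol(m$values), 2)                  # 0.0002 Da apart: merged
  merged <- which.min(abs(m$feature_mz - 125.0959))
  expect_equal(m$feature_mz[merged],
               (125.0958 * 20 + 125.0960 * 40) / 60)  # intensity-weighted
  expect_equal(unname(m$values[, merged]), c(20, 40))

  p3 <- mk_prof("c", c(100.0, 125.1020), c(10, 40))
  m2 <- build_feature_matrix(list(p1, p3))
  expect_equal(ncol(m2$values), 3)                 # 0.0062 Da apart: split
  expect_equal(unname(m2$values[1, ]), c(10, 20, 0))  # absent feature -> 0

  # shared feature set stacks profiles unchanged
  p4 <- mk_prof("d", c(100.0, 125.0958), c(5, 7))
  m3 <- build_feature_matrix(list(p1, p4))
  expect_equal(unname(m3$values), rbind(c(10, 20), c(5, 7)))
})

test_that("1-D alignment clustering matches single-linkage hclust", {
  set.seed(21)
  for (rep in 1:10) {
    mzs <- sort(runif(40, 100, 100.5))
    prof <- lapply(seq_along(mzs), function(i) structure(
      list(subject_id = paste0("s", i), feature_mz = mzs[i],
           feature_intensity = 10, tic = 10, n_scans = 1L),
      class = "subject_profile"))
    m <- build_feature_matrix(prof, align_tolerance = 0.01)
    oracle <- cutree(hclust(dist(mzs), method = "single"), h = 0.01)
    expect_equal(ncol(m$values), length(unique(oracle)))
  }
})

test_that("normalization cascade satisfies its stated contracts", {
  mk_prof <- function(id, int) structure(
    list(subject_id = id, feature_mz = c(100.1, 110.2, 120.3),
         feature_intensity = int, tic = sum(int), n_scans = 1L),
    class = "subject_profile")
  m <- build_feature_matrix(list(mk_prof("a", c(10, 20, 30)),
                                 mk_prof("b", c(5, 80, 15)),
                                 mk_prof("c", c(40, 10, 50))))
  tn <- normalize_cascade(m, to = "tic_normalized")
  expect_equal(unname(rowSums(tn$values)), rep(1, 3))
  expect_equal(tn$state, "tic_normalized")

  az <- normalize_cascade(m, to = "autoscaled")
  expect_equal(unname(colMeans(az$values)), rep(0, 3), tolerance = 1e-9)
  n <- nrow(az$values)
  pop_sd <- apply(az$values, 2, function(v) sqrt(sum((v - mean(v))^2) / n))
  expect_equal(unname(pop_sd), rep(1, 3), tolerance = 1e-9)
  expect_equal(az$state, "autoscaled")
  expect_false(is.null(az$tic_values))

  # scale invariance: multiplying one subject's raw row by c > 0
  m_scaled <- m
  m_scaled$values[2, ] <- m_scaled$values[2, ] * 7
  m_scaled$tics[2] <- m_scaled$tics[2] * 7
  tn2 <- normalize_cascade(m_scaled, to = "tic_normalized")
  expect_equal(tn2$values[2, ], tn$values[2, ])

  # identical subjects stay identical at every state
  m_dup <- build_feature_matrix(list(mk_prof("a", c(10, 20, 30)),
                                     mk_prof("b", c(10, 20, 30)),
                                     mk_prof("c", c(40, 10, 40))))
  az_dup <- normalize_cascade(m_dup)
  expect_equal(az_dup$values[1, ], az_dup$values[2, ])

  # state machine and degenerate inputs
  expect_error(normalize_cascade(az), "state 'raw'")
  m_zero <- m; m_zero$tics[1] <- 0
  expect_error(normalize_cascade(m_zero), "zero TIC.*a")
  # feature 1 carries a constant 1/6 of each subject's TIC: zero variance
  # after TIC normalization, so it is dropped at auto-scaling
  m_const <- build_feature_matrix(list(mk_prof("a", c(10, 20, 30)),
                                       mk_prof("b", c(20, 50, 50)),
                                       mk_prof("c", c(5, 10, 15))))
  expect_warning(az_c <- normalize_cascade(m_const), "zero-variance")
  expect_equal(ncol(az_c$values), 2)
})

test_that("the spectral pipeline is deterministic end to end", {
  cfg <- small_cohort_config(noise_sd = 2)
  run_once <- function() {
    coh <- generate_cohort(cfg, seed = 5)
    grid <- feature_grid(50, 210, 0.005)
    profs <- lapply(coh$sessions, function(s)
      average_breath_scans(s, select_breath_scans(s), grid))
    normalize_cascade(build_feature_matrix(profs))
  }
  m1 <- run_once()
  m2 <- run_once()
  expect_identical(m1$values, m2$values)
  expect_identical(m1$feature_mz, m2$feature_mz)
})
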