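test_that("stratification rules apply their thresholds at the boundaries", {
  rec <- rbind(
    meta_row("t_49", "osa_treated", ahi_visit = 2, ahi_diagnosis = 40,
             ess = 5, cpap_hours = 4.9),
    meta_row("t_50", "osa_treated", ahi_visit = 2, ahi_diagnosis = 40,
             ess = 5, cpap_hours = 5.0),
    meta_row("u_all", "osa_untreated", ahi_visit = 20, ahi_diagnosis = 25,
             ess = 3),
    meta_row("ctrl", "control", ahi_diagnosis = 2, ess = 8))
  s1 <- apply_stratification(rec, "strat1")
  expect_false("t_49" %in% s1$osa_treated)   # CPAP 4.9 h/night: excluded
  expect_true("t_50" %in% s1$osa_treated)    # boundary closed at >= 5
  expect_true("u_all" %in% s1$osa_untreated) # strat1 keeps all untreated
  expect_true("ctrl" %in% s1$control)
  expect_equal(s1$excluded$reason[s1$excluded$subject_id == "t_49"],
               "CPAP usage < 5 h/night")
})

test_that("stratification 2 combines severity and sleepiness strictly", {
  rec <- rbind(
    meta_row("u1", "osa_untreated", ahi_visit = 12, ess = 11),  # in
    meta_row("u2", "osa_untreated", ahi_visit = 12, ess = 9),   # out
    meta_row("u3", "osa_untreated", ahi_visit = 35, ess = 2),   # AHI > 30
    meta_row("u4", "osa_untreated", ahi_visit = 30, ess = 2),   # boundary: out
    meta_row("u5", "osa_untreated", ahi_visit = 10, ess = 15))  # boundary: out
  s2 <- apply_stratification(rec, "strat2")
  expect_setequal(s2$osa_untreated, c("u1", "u3"))

  # treated subjects use the pre-treatment AHI and still need CPAP >= 5
  rec_t <- rbind(
    meta_row("t1", "osa_treated", ahi_visit = 1.3, ahi_diagnosis = 35,
             ess = 2, cpap_hours = 6),
    meta_row("t2", "osa_treated", ahi_visit = 1.3, ahi_diagnosis = 35,
             ess = 2, cpap_hours = 4),
    meta_row("t3", "osa_treated", ahi_visit = 45, ahi_diagnosis = 5,
             ess = 2, cpap_hours = 6))
  s2t <- apply_stratification(rec_t, "strat2")
  expect_setequal(s2t$osa_treated, "t1")

  # legacy ODI-based variant of the earlier study
  rec_o <- rbind(
    meta_row("o1", "osa_untreated", ahi_visit = 2, odi = 35, ess = 2),
    meta_row("o2", "osa_untreated", ahi_visit = 50, odi = 5, ess = 2))
  so <- apply_stratification(rec_o, "strat2_odi")
  expect_setequal(so$osa_untreated, "o1")
})

test_that("subject records validate fields and CPAP semantics", {
  expect_error(subject_records(data.frame(subject_id = "a", group = "bad",
                                          ahi_visit = 1, ahi_diagnosis = 1,
                                          ess = 1)), "group")
  expect_error(subject_records(meta_row("a", "osa_untreated", ahi_visit = -1,
                                        ahi_diagnosis = 1)), "non-negative")
  expect_error(subject_records(meta_row("a", "control", ahi_diagnosis = 1,
                                        cpap_hours = 5)),
               "absent for non-treated")
})

test_that("Mann-Whitney U reproduces closed-form and tie cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 0.1)          # 2/20 labelings as extreme
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_two_sided, 1)
  half <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(half$U, 2)                   # n1*n2/2 with midranks
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p equals the brute-force permutation p", {
  set.seed(31)
  for (n1 in c(2, 3, 4, 5)) {
    for (rep in 1:4) {
      n2 <- sample(2:(10 - n1), 1)
      x <- round(rnorm(n1), 6); y <- round(rnorm(n2, 0.5), 6)
      r <- mann_whitney_u(x, y)
      expect_equal(r$p_two_sided, brute_force_mw_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("U statistics are complementary and rank-invariant", {
  set.seed(32)
  for (rep in 1:20) {
    x <- rnorm(7); y <- rnorm(9)
    r <- mann_whitney_u(x, y)
    u2 <- mann_whitney_u(y, x)$U1
    expect_equal(r$U1 + u2, length(x) * length(y))
    # strictly monotone transform leaves the rank test unchanged
    f <- sample(list(function(v) exp(v), function(v) atan(v) * 3,
                     function(v) v^3 + 2 * v), 1)[[1]]
    r2 <- mann_whitney_u(f(x), f(y))
    expect_equal(r2$U, r$U)
    expect_equal(r2$p_two_sided, r$p_two_sided)
  }
})

test_that("Shapiro-Wilk gate behaves under null, skew and degeneracy", {
  set.seed(33)
  p_norm <- replicate(400, shapiro_wilk(rnorm(50))$p)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_skew <- replicate(400, shapiro_wilk(exp(rnorm(50)))$p)
  expect_gte(mean(p_skew < 0.05), 0.90)
  expect_error(shapiro_wilk(rep(1, 10)), "degenerate")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("group comparison reports coherent effect directions", {
  set.seed(34)
  sim <- simulate_intensity_cohort(
    cohort_config(n_untreated = 12, n_treated = 12, n_control = 0,
                  baseline_n = 5,
                  effect_table = c("125.0958" = 3, "95.0494" = 3)),
    seed = 34)
  m <- normalize_cascade(as_intensity_matrix(sim))
  pan <- marker_panel(sim$feature_mz[sim$is_marker])
  matches <- match_markers(m, pan)
  ids_u <- sim$metadata$subject_id[sim$metadata$group == "osa_untreated"]
  ids_t <- sim$metadata$subject_id[sim$metadata$group == "osa_treated"]
  res <- compare_groups(m, matches, ids_u, ids_t)
  expect_equal(nrow(res), sum(matches$detected))
  # direction is defined by the fold change on the TIC scale
  expect_true(all((res$fold_change > 1) == (res$direction == "increased"),
                  na.rm = TRUE))
  planted <- res[res$mz %in% c(125.0958, 95.0494), ]
  expect_true(all(planted$significant))
  expect_true(all(planted$direction == "increased"))
  expect_true(all(res$U >= 0 & res$U <= length(ids_u) * length(ids_t) / 2))

  # identical groups: nothing can be significant
  res0 <- compare_groups(m, matches, ids_u, ids_u)
  expect_equal(sum(res0$significant), 0)

  expect_error(compare_groups(m, matches, ids_u[1:2], ids_t),
               "at least 3")
})

test_that("p-values agree between auto-scaled and TIC-normalized testing", {
  sim <- simulate_intensity_cohort(
    cohort_config(n_untreated = 8, n_treated = 8, n_control = 0,
                  baseline_n = 4), seed = 35)
  az <- normalize_cascade(as_intensity_matrix(sim), to = "autoscaled")
  pan <- marker_panel(sim$feature_mz[sim$is_marker][1:10])
  matches <- match_markers(az, pan)
  ids_u <- sim$metadata$subject_id[sim$metadata$group == "osa_untreated"]
  ids_t <- sim$metadata$subject_id[sim$metadata$group == "osa_treated"]
  res <- compare_groups(az, matches, ids_u, ids_t)
  # per feature, auto-scaling is a positive affine map of the TIC scale:
  # recomputing each p on the TIC-normalized values must agree exactly
  ia <- match(ids_u, az$subject_ids); ib <- match(ids_t, az$subject_ids)
  for (k in seq_len(nrow(res))) {
    j <- matches$column[k]
    p_tic <- mann_whitney_u(az$tic_values[ia, j],
                            az$tic_values[ib, j])$p_two_sided
    expect_equal(res$p[k], p_tic)
  }
})
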