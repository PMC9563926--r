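#' Validate a subject metadata table
#'
#' Columns: `subject_id`; `group` (one of `osa_untreated`, `osa_treated`,
#' `control`); `ahi_visit` and `ahi_diagnosis` (apnea/hypopnea index,
#' events/h); optional `odi` (oxygen desaturation index, events/h); `ess`
#' (Epworth Sleepiness Scale, points); optional `cpap_hours` (averaged
#' CPAP usage, h/night — treated subjects only).
#'
#' @param df A data.frame with the columns above.
#' @return The validated data.frame (class `subject_records`).
#' @export
subject_records <- function(df) {
  need <- c("subject_id", "group", "ahi_visit", "ahi_diagnosis", "ess")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing metadata column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$group %in% c("osa_untreated", "osa_treated", "control")))
    stop("group must be one of osa_untreated, osa_treated, control")
  if (!"odi" %in% names(df)) df$odi <- NA_real_
  if (!"cpap_hours" %in% names(df)) df$cpap_hours <- NA_real_
  num <- c("ahi_visit", "ahi_diagnosis", "odi", "ess", "cpap_hours")
  for (col in num) {
    v <- df[[col]]
    if (any(!is.na(v) & v < 0)) stop(col, " must be non-negative")
  }
  if (any(df$group != "osa_treated" & !is.na(df$cpap_hours)))
    stop("cpap_hours must be absent for non-treated subjects")
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id")
  structure(df, class = c("subject_records", "data.frame"))
}

#' Stratify subjects for the between-group marker comparison
#'
#' Implements the two cohort stratification rules used for the
#' untreated-vs-treated OSA contrast:
#' * `strat1`: all untreated kept; treated kept iff averaged CPAP usage
#'   >= `cpap_min` h/night (boundary closed: "minimal 5 h/night").
#' * `strat2`: a subject is kept iff AHI > `ahi_high`, or (AHI > `ahi_low`
#'   and ESS > `ess_min`) — strict inequalities as printed; treated
#'   subjects additionally require CPAP usage >= `cpap_min`.
#'
#' The AHI used reflects pre-treatment severity: `ahi_visit` for untreated
#' subjects, `ahi_diagnosis` (from the original sleep report, before CPAP)
#' for treated subjects.
#'
#' Legacy variants `strat1_odi` / `strat2_odi` substitute ODI for AHI
#' (`ODI > 30, or ODI > 10 and ESS > 10`), mirroring the earlier study's
#' criteria; they are provided for comparison only.
#'
#' Control subjects are never filtered; their ids pass through for the
#' untreated-vs-control contrast.
#'
#' @param records A [subject_records()] table.
#' @param rule `"strat1"`, `"strat2"`, `"strat1_odi"` or `"strat2_odi"`.
#' @param cpap_min,ahi_high,ahi_low,ess_min Rule thresholds.
#' @return List with `osa_untreated`, `osa_treated`, `control` (character
#'   id vectors) and `excluded` (data.frame of id + reason).
#' @export
apply_stratification <- function(records, rule = c("strat1", "strat2",
                                                   "strat1_odi", "strat2_odi"),
                                 cpap_min = 5, ahi_high = 30, ahi_low = 10,
                                 ess_min = 10) {
  rule <- match.arg(rule)
  records <- subject_records(as.data.frame(records))
  use_odi <- grepl("_odi$", rule)
  base_rule <- sub("_odi$", "", rule)
  keep <- logical(nrow(records))
  reason <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$group == "control") { keep[i] <- TRUE; next }
    severity <- if (use_odi) r$odi
                else if (r$group == "osa_untreated") r$ahi_visit
                else r$ahi_diagnosis
    cpap_ok <- r$group != "osa_treated" ||
      (!is.na(r$cpap_hours) && r$cpap_hours >= cpap_min)
    if (base_rule == "strat1") {
      keep[i] <- cpap_ok
      if (!keep[i]) reason[i] <- sprintf("CPAP usage < %g h/night", cpap_min)
    } else {
      if (is.na(severity) || is.na(r$ess)) {
        keep[i] <- FALSE
        reason[i] <- "missing severity/ESS field"
        next
      }
      sev_ok <- severity > ahi_high || (severity > ahi_low && r$ess > ess_min)
      keep[i] <- sev_ok && cpap_ok
      if (!sev_ok) reason[i] <- "below severity criteria"
      else if (!cpap_ok) reason[i] <- sprintf("CPAP usage < %g h/night", cpap_min)
    }
  }
  list(osa_untreated = records$subject_id[keep & records$group == "osa_untreated"],
       osa_treated = records$subject_id[keep & records$group == "osa_treated"],
       control = records$subject_id[keep & records$group == "control"],
       excluded = data.frame(subject_id = records$subject_id[!keep],
                             reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Mann-Whitney U test for two independent samples
#'
#' Computes the U statistic from midrank sums (reported as the smaller of
#' U1 and U2) and a two-sided p-value: exact (equivalent to full
#' permutation enumeration) when the combined sample size is at most 12 and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity corrections. The p-value computation is delegated to
#' [stats::wilcox.test()].
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List with `U` (min of U1, U2), `U1` (U for `x`), `p_two_sided`,
#'   `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2) <= 12L && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  list(U = min(u1, u2), U1 = u1, p_two_sided = min(p, 1), n1 = n1, n2 = n2)
}

#' Shapiro-Wilk normality test
#'
#' Reports the normality gate that justifies the nonparametric group
#' comparison (marker intensities are right-skewed); it never switches the
#' test silently.
#'
#' @param values Numeric sample, 3 <= n <= 5000, non-degenerate.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n)
  if (length(unique(values)) == 1L)
    stop("Shapiro-Wilk is degenerate for a constant sample")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Between-group marker comparison
#'
#' Tests every detected panel marker for an intensity difference between
#' two subject groups with the Mann-Whitney U test. P-values are computed
#' on the matrix's current (typically auto-scaled) values — per feature
#' this is a positive affine transform of the TIC-normalized intensities,
#' so the rank test gives identical p-values on either scale. Fold changes
#' are ratios of group medians on the TIC-normalized scale (z-scores
#' destroy ratios). Shapiro-Wilk normality p-values are reported per group.
#' No multiple-testing correction is applied by default (the unadjusted
#' p < alpha rule); Benjamini-Hochberg is available via
#' `p_adjust = "BH"`.
#'
#' @param matrix An `intensity_matrix` carrying `tic_values` (i.e. advanced
#'   past `tic_normalized`, see [normalize_cascade()]).
#' @param matches A `match_table` from [match_markers()].
#' @param group_a,group_b Character vectors of subject ids (group A is the
#'   reference for "increased", conventionally untreated OSA). Each must
#'   have at least 3 subjects.
#' @param alpha Significance level for the `significant` flag.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return A `marker_test_result` data.frame with one row per detected
#'   marker: `mz`, `U`, `p`, `fold_change` (median A / median B, TIC
#'   scale), `direction`, `shapiro_p_a`, `shapiro_p_b`, `significant`.
#' @export
compare_groups <- function(matrix, matches, group_a, group_b, alpha = 0.05,
                           p_adjust = "none") {
  if (is.null(matrix$tic_values))
    stop("matrix must carry tic_values; run normalize_cascade() first")
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("each group needs at least 3 subjects for a meaningful test")
  ia <- match(group_a, matrix$subject_ids)
  ib <- match(group_b, matrix$subject_ids)
  if (anyNA(ia) || anyNA(ib)) stop("group ids not all present in the matrix")
  det <- which(matches$detected)
  if (length(det) == 0L)
    stop("no detected markers to test")
  rows <- lapply(det, function(k) {
    j <- matches$column[k]
    xa <- matrix$values[ia, j]; xb <- matrix$values[ib, j]
    mw <- mann_whitney_u(xa, xb)
    ta <- matrix$tic_values[ia, j]; tb <- matrix$tic_values[ib, j]
    fc <- stats::median(ta) / stats::median(tb)
    sw <- function(v) tryCatch(shapiro_wilk(v)$p, error = function(e) NA_real_)
    data.frame(mz = matches$panel_mz[k], U = mw$U, p = mw$p_two_sided,
               fold_change = fc,
               direction = if (is.nan(fc)) NA_character_
                           else if (fc > 1) "increased" else "decreased",
               shapiro_p_a = sw(xa), shapiro_p_b = sw(xb),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p, method = p_adjust)
  res$significant <- res$p_adjusted < alpha
  structure(res, class = c("marker_test_result", "data.frame"),
            alpha = alpha, n_a = length(group_a), n_b = length(group_b))
}
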