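#' Default pipeline run configuration
#'
#' Assembles the full set of processing parameters with their standard
#' values: 0.005 Da mass tolerance for alignment and targeted matching,
#' 5 cps peak height filter, water-trimer exhalation gate at 10% of the
#' session maximum, 0.001 Da interpolation grid, stratification 1 for
#' marker testing and stratification 2 with balanced subsampling for
#' 10-fold cross-validated classification.
#'
#' @param input_dir Directory of per-subject mzXML files.
#' @param metadata Path to the subject metadata CSV (see
#'   [subject_records()]), or a data.frame.
#' @param out_dir Output run directory.
#' @param panel Path to a panel CSV, a [marker_panel()], or `NULL` for the
#'   bundled 78-feature panel.
#' @param ... Overrides for any default element (`tolerance`, `min_height`,
#'   `gate`, `grid_step`, `grid_range`, `calibrants`, `test_stratification`,
#'   `classify_stratification`, `cv`, `seed`).
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, metadata, out_dir, panel = NULL, ...) {
  cfg <- list(input_dir = input_dir, metadata = metadata, out_dir = out_dir,
              panel = panel,
              tolerance = 0.005, min_height = 5,
              gate = list(mz = 55.0390, tolerance = 0.005, fraction = 0.1),
              grid_step = 0.001, grid_range = NULL,
              calibrants = water_cluster_mzs(),
              test_stratification = "strat1",
              classify_stratification = "strat2",
              cv = list(k = 10L, cost = 1, scale = "fold", balance = TRUE),
              seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with at least `input_dir`, `metadata`, `out_dir`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("input_dir", "metadata", "out_dir")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("config missing field(s): ",
                         paste(miss, collapse = ", "))
  do.call(run_config, y)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  drop <- intersect(c("metadata"), names(cfg))
  ser <- cfg
  if (is.data.frame(ser$metadata)) ser$metadata <- "<inline data.frame>"
  jsonlite::write_json(ser, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

#' Run the full breath-marker validation pipeline
#'
#' Orchestrates the analysis end to end: read every mzXML session in the
#' input directory, recalibrate all sessions onto one reference breath
#' spectrum, select exhalation scans by the water-trimer gate, average and
#' peak-pick each subject's breath scans, align features into the
#' intensity matrix, run the TIC / median-TIC / auto-scaling cascade,
#' match the marker panel at fixed tolerance, test untreated vs treated
#' group differences, and cross-validate the marker-based classifier.
#' Each stage's output is written before the next begins
#' (`matrix.csv`, `matches.csv`, `results.csv`, `report.json`, `log.txt`);
#' any stage failure aborts with a stage-named error.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @return Invisibly, a list with `matrix`, `matches`, `results`, `report`
#'   and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- sort(list.files(config$input_dir, pattern = "\\.mzXML$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stop("pipeline stage 'input' failed: no mzXML files in ",
         config$input_dir, call. = FALSE)
  meta <- stage("metadata", {
    m <- config$metadata
    if (is.character(m)) m <- utils::read.csv(m, stringsAsFactors = FALSE)
    subject_records(m)
  })
  panel <- stage("panel", {
    p <- config$panel
    if (is.null(p)) osa_panel()
    else if (is.character(p)) read_marker_panel(p)
    else p
  })
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE))
    stop("cannot create output directory ", config$out_dir)
  log_con <- file(file.path(config$out_dir, "log.txt"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_line(log_con, "run start; ", length(files), " input file(s)")

  sessions <- stage("read", lapply(files, read_mzxml))
  names(sessions) <- vapply(sessions, function(s) s$subject_id, character(1))

  reference <- stage("reference", most_intense_scan(sessions[[1]]))
  log_line(log_con, "reference spectrum: most intense scan of '",
           sessions[[1]]$subject_id, "'")

  sessions <- stage("recalibration", lapply(sessions, function(s) {
    mod <- fit_recalibration(s, reference, calibrant_mzs = config$calibrants,
                             min_height = config$min_height)
    log_line(log_con, sprintf("recalibrated %s: slope %.8f offset %+.5f Da",
                              s$subject_id, mod$slope, mod$offset))
    apply_recalibration(s, mod)
  }))

  grid <- stage("grid", {
    rng <- config$grid_range
    if (is.null(rng)) {
      all_rng <- range(unlist(lapply(sessions, function(s)
        lapply(s$scans, function(sc) range(sc$mz)))))
      rng <- c(floor(all_rng[1]), ceiling(all_rng[2]))
    }
    feature_grid(rng[1], rng[2], config$grid_step)
  })

  profiles <- stage("breath_selection_and_averaging", lapply(sessions,
    function(s) {
      idx <- select_breath_scans(s, gate_mz = config$gate$mz,
                                 gate_tolerance = config$gate$tolerance,
                                 gate_fraction = config$gate$fraction)
      log_line(log_con, sprintf("%s: %d/%d breath scans", s$subject_id,
                                length(idx), length(s$scans)))
      average_breath_scans(s, idx, grid, min_height = config$min_height)
    }))

  mat <- stage("feature_matrix", {
    m <- build_feature_matrix(profiles, align_tolerance = config$tolerance)
    normalize_cascade(m, to = "autoscaled")
  })
  matrix_path <- file.path(config$out_dir, "matrix.csv")
  write_intensity_matrix(mat, matrix_path)
  log_line(log_con, sprintf("matrix: %d subjects x %d features",
                            nrow(mat$values), ncol(mat$values)))

  matches <- stage("marker_matching",
                   match_markers(mat, panel, tolerance = config$tolerance))
  matches_path <- file.path(config$out_dir, "matches.csv")
  utils::write.csv(as.data.frame(matches), matches_path, row.names = FALSE)
  log_line(log_con, sprintf("detected %d/%d panel markers",
                            attr(matches, "n_detected"), nrow(panel)))

  strat <- stage("stratification",
                 apply_stratification(meta, config$test_stratification))
  for (i in seq_len(nrow(strat$excluded)))
    log_line(log_con, "excluded ", strat$excluded$subject_id[i], ": ",
             strat$excluded$reason[i])
  results <- stage("group_stats",
                   compare_groups(mat, matches,
                                  group_a = strat$osa_untreated,
                                  group_b = strat$osa_treated))
  results_path <- file.path(config$out_dir, "results.csv")
  utils::write.csv(as.data.frame(results), results_path, row.names = FALSE)
  log_line(log_con, sprintf("%d/%d detected markers significant at alpha %.2f",
                            sum(results$significant), nrow(results),
                            attr(results, "alpha")))

  report <- stage("classification", {
    strat2 <- apply_stratification(meta, config$classify_stratification)
    ids <- c(strat2$osa_untreated, strat2$osa_treated)
    labels <- stats::setNames(
      meta$group[match(ids, meta$subject_id)], ids)
    if (isTRUE(config$cv$balance))
      ids <- balanced_subsample(labels[ids], seed = config$seed)
    cols <- matches$column[matches$detected]
    x <- mat$tic_values[match(ids, mat$subject_ids), cols, drop = FALSE]
    rownames(x) <- ids
    crossvalidate(x, labels[ids], positive = "osa_untreated",
                  k = config$cv$k, seed = config$seed,
                  cost = config$cv$cost, scale = config$cv$scale)
  })
  report_path <- file.path(config$out_dir, "report.json")
  report_json <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("breathflow")),
    config_hash = config_hash(config), seed = config$seed,
    n_detected = attr(matches, "n_detected"), n_panel = nrow(panel),
    n_significant = sum(results$significant),
    n_untreated_tested = attr(results, "n_a"),
    n_treated_tested = attr(results, "n_b"),
    cv = list(k = report$k, auc = report$auc, accuracy = report$accuracy,
              sensitivity = report$sensitivity,
              specificity = report$specificity,
              confusion = report$confusion))
  jsonlite::write_json(report_json, report_path, auto_unbox = TRUE,
                       digits = NA)
  log_line(log_con, sprintf("CV: AUC %.3f acc %.3f sens %.3f spec %.3f",
                            report$auc, report$accuracy, report$sensitivity,
                            report$specificity))
  log_line(log_con, "run complete")
  invisible(list(matrix = mat, matches = matches, results = results,
                 report = report, report_json = report_json,
                 paths = list(matrix = matrix_path, matches = matches_path,
                              results = results_path, report = report_path,
                              log = file.path(config$out_dir, "log.txt"))))
}
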