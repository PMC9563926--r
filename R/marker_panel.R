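#' Monoisotopic masses of the most abundant isotopes
#'
#' Atomic masses (u) of the most abundant naturally occurring isotope of
#' each supported element, plus the electron mass used for cation m/z.
#' Values follow the current IUPAC/AME evaluations to sub-ppm precision.
#'
#' @return Named numeric vector of isotope masses in u.
#' @export
isotope_masses <- function() {
  c(C = 12.0,
    H = 1.00782503224,
    N = 14.00307400446,
    O = 15.99491461960,
    S = 31.9720711744,
    P = 30.97376199842,
    Na = 22.98976928195,
    K = 38.96370648660,
    Cl = 34.968852682)
}

ELECTRON_MASS <- 0.000548579909

#' Parse an elemental composition string
#'
#' Accepts Hill-style formulas such as `"C8H13O"` or `"C6H10NO2"`: element
#' symbols (one capital letter optionally followed by a lower-case letter)
#' each followed by an optional count.
#'
#' @param formula Composition string.
#' @return Named integer vector of atom counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
    stop("formula must be a non-empty string")
  pat <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula: '", formula, "'")
  sym <- sub(pat, "\\1", toks)
  cnt <- sub(pat, "\\2", toks)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  if (any(cnt <= 0L)) stop("atom counts must be positive in '", formula, "'")
  counts <- tapply(cnt, sym, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass (or cation m/z) of an elemental composition
#'
#' Sums the masses of each element's most abundant isotope, subtracts
#' `charge` electron masses, and divides by `|charge|` to give the ion's
#' m/z. With `charge = 0` the neutral monoisotopic mass is returned with a
#' warning. Table-2-style panel compositions are cation formulas (the
#' protonated species, charge +1); e.g. `monoisotopic_mass("H7O3", 1)`
#' gives 55.0390, the water-trimer gate ion.
#'
#' @param formula Composition string, e.g. `"C8H13O"`, interpreted as the
#'   ion's full formula (protons included).
#' @param charge Integer charge of the ion (default +1).
#' @param masses Isotope mass table, see [isotope_masses()]; extensible.
#' @return m/z in Da (Thomson), full double precision.
#' @export
monoisotopic_mass <- function(formula, charge = 1L, masses = isotope_masses()) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(masses))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  neutral <- sum(masses[names(counts)] * counts)
  if (charge == 0L) {
    warning("charge 0: returning the neutral monoisotopic mass, not an m/z")
    return(neutral)
  }
  (neutral - charge * ELECTRON_MASS) / abs(charge)
}

#' Construct a marker panel
#'
#' A targeted feature list for marker detection: prior-study m/z values
#' with optional cation composition, metabolite name, prior direction of
#' change and prior significance flag.
#'
#' @param mz Numeric vector of marker m/z (Da), within 50-500, unique at
#'   4-decimal precision.
#' @param formula Optional character vector of cation compositions (`NA`
#'   where unknown).
#' @param name Optional metabolite names.
#' @param prior_direction Optional `"increased"`/`"decreased"` per marker.
#' @param prior_significant Optional logical per marker.
#' @param provenance Free-text label recording where the panel comes from.
#' @return A `marker_panel` (data.frame subclass) with a `provenance`
#'   attribute.
#' @export
marker_panel <- function(mz, formula = NA_character_, name = NA_character_,
                         prior_direction = NA_character_,
                         prior_significant = NA, provenance = "unspecified") {
  mz <- as.numeric(mz)
  blank2na <- function(x) {
    x <- as.character(x); x[!is.na(x) & !nzchar(x)] <- NA_character_; x
  }
  formula <- blank2na(formula)
  name <- blank2na(name)
  prior_direction <- blank2na(prior_direction)
  if (any(mz < 50 | mz > 500)) stop("panel m/z must lie in 50-500 Da")
  if (anyDuplicated(round(mz, 4)))
    stop("panel m/z values must be unique at 4-decimal precision")
  ok_dir <- is.na(prior_direction) |
    prior_direction %in% c("increased", "decreased")
  if (!all(ok_dir)) stop("prior_direction must be 'increased' or 'decreased'")
  df <- data.frame(mz = mz, formula = formula, name = name,
                   prior_direction = prior_direction,
                   prior_significant = prior_significant,
                   stringsAsFactors = FALSE)
  for (f in df$formula[!is.na(df$formula)]) parse_formula(f)  # must parse
  structure(df, class = c("marker_panel", "data.frame"),
            provenance = provenance)
}

#' Read a marker panel from CSV
#'
#' Expected columns: `mz` (required), `formula`, `name`, `prior_direction`,
#' `prior_significant` (optional).
#'
#' @param path CSV file path.
#' @param provenance Provenance label; defaults to the file name.
#' @return A [marker_panel()].
#' @export
read_marker_panel <- function(path, provenance = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mz" %in% names(df)) stop("panel CSV must have an 'mz' column")
  get <- function(col, default) if (col %in% names(df)) df[[col]] else default
  marker_panel(df$mz,
               formula = get("formula", NA_character_),
               name = get("name", NA_character_),
               prior_direction = get("prior_direction", NA_character_),
               prior_significant = get("prior_significant", NA),
               provenance = provenance)
}

#' The nine significant OSA markers (bundled panel)
#'
#' The nine markers found significantly increased in untreated versus
#' CPAP-treated OSA, with their suggested cation compositions and, where
#' identified, metabolite names (2-butylfuran at m/z 125.0958 and
#' 4-(hexyloxy)phenol at 195.1379).
#'
#' @return A [marker_panel()] of nine fully attributed entries.
#' @export
table2_panel <- function() {
  read_marker_panel(
    system.file("extdata", "table2_markers.csv", package = "breathflow",
                mustWork = TRUE),
    provenance = "nine significant OSA markers (validation study)")
}

#' The 78-feature prior OSA panel (synthetic stand-in)
#'
#' The targeted panel of 78 previously reported OSA-associated breath
#' features. Only the nine significant markers are published with full
#' attribution; the remaining 69 entries bundled here are synthetic
#' placeholders (plausible m/z values, no composition) so that the full
#' targeted-matching workflow can be exercised. See
#' `inst/extdata/osa_panel_synthetic.csv`.
#'
#' @return A [marker_panel()] with 78 rows; the `detectable` attribute (a
#'   logical vector) marks the 42 features the synthetic cohort generator
#'   emits by default.
#' @export
osa_panel <- function() {
  path <- system.file("extdata", "osa_panel_synthetic.csv",
                      package = "breathflow", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  p <- marker_panel(df$mz, formula = df$formula, name = df$name,
                    prior_direction = df$prior_direction,
                    prior_significant = NA,
                    provenance = "78-feature prior OSA panel (synthetic stand-in)")
  attr(p, "detectable") <- as.logical(df$detectable)
  p
}

#' Match matrix features against a marker panel at fixed mass tolerance
#'
#' For every panel marker, finds the nearest matrix feature column within
#' `tolerance` (default 0.005 Da, the targeted-matching tolerance); the
#' nearest column wins when several fall inside the window.
#'
#' @param matrix An `intensity_matrix` (any state), or a numeric vector of
#'   feature m/z values.
#' @param panel A [marker_panel()].
#' @param tolerance Mass tolerance in Da.
#' @return A `match_table` data.frame: `panel_mz`, `name`, `column`
#'   (matched column index or `NA`), `matched_mz`, `delta` (signed
#'   matched - panel, Da) and `detected`. Attribute `n_detected` gives the
#'   detection count.
#' @export
match_markers <- function(matrix, panel, tolerance = 0.005) {
  feat <- if (inherits(matrix, "intensity_matrix")) matrix$feature_mz
          else as.numeric(matrix)
  if (length(feat) < 1L) stop("matrix has no feature columns")
  res <- lapply(panel$mz, function(m) {
    d <- feat - m
    j <- which.min(abs(d))
    if (abs(d[j]) <= tolerance)
      list(column = j, matched_mz = feat[j], delta = d[j])
    else
      list(column = NA_integer_, matched_mz = NA_real_, delta = NA_real_)
  })
  out <- data.frame(panel_mz = panel$mz, name = panel$name,
                    column = vapply(res, `[[`, integer(1), "column"),
                    matched_mz = vapply(res, `[[`, numeric(1), "matched_mz"),
                    delta = vapply(res, `[[`, numeric(1), "delta"),
                    stringsAsFactors = FALSE)
  out$detected <- !is.na(out$column)
  structure(out, class = c("match_table", "data.frame"),
            n_detected = sum(out$detected), tolerance = tolerance)
}

#' Audit a panel's (m/z, composition) consistency
#'
#' For every formula-bearing marker, computes the +1 cation monoisotopic
#' m/z from first principles and checks agreement with the printed panel
#' m/z within `tolerance`. A deterministic, pure computation — the
#' mass-consistency audit of the attributed panel.
#'
#' @param panel A [marker_panel()].
#' @param tolerance Mass tolerance in Da (default 0.005).
#' @param charge Assumed ion charge for the compositions (default +1;
#'   panel compositions are cation formulas).
#' @return List with `n_formula`, `n_pass`, and `table` (per-marker
#'   computed m/z, signed delta and pass flag).
#' @export
audit_panel_masses <- function(panel, tolerance = 0.005, charge = 1L) {
  has <- !is.na(panel$formula) & nzchar(panel$formula)
  if (!any(has))
    return(list(n_formula = 0L, n_pass = 0L,
                table = data.frame(mz = numeric(0), formula = character(0),
                                   computed_mz = numeric(0), delta = numeric(0),
                                   pass = logical(0))))
  comp <- vapply(panel$formula[has], monoisotopic_mass, numeric(1),
                 charge = charge)
  delta <- comp - panel$mz[has]
  pass <- abs(delta) <= tolerance
  list(n_formula = sum(has), n_pass = sum(pass),
       table = data.frame(mz = panel$mz[has],
                          formula = panel$formula[has],
                          computed_mz = unname(comp), delta = unname(delta),
                          pass = unname(pass), stringsAsFactors = FALSE))
}
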