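# Reading, validating and curating source-apportionment records.
#
# A record is one measurement from one study: the city and its covariates,
# the overall PM2.5 concentration (ug/m^3) and the percentage contribution
# of traffic. Curation derives the traffic-related concentration and the
# model covariates (log population in millions, latitude/10, post-2005
# indicator, four-level location category).

PM_RECORD_FIELDS <- c(
  "study_id", "city", "country", "region", "pub_year", "population",
  "latitude", "longitude", "site_type", "overall_pm25", "traffic_share_pct",
  "sea_salt_reported", "method"
)

#' Default column-mapping dialect
#'
#' Maps canonical record field names to the column headers of an input CSV.
#' The default is the identity mapping, matching the headers written by
#' [simulate_dataset()] and [make_fixture()]. Supply a modified copy to
#' [read_records()] to ingest files with arbitrary headers.
#'
#' @return Named character vector: canonical field -> CSV header.
#' @export
default_dialect <- function() {
  stats::setNames(PM_RECORD_FIELDS, PM_RECORD_FIELDS)
}

#' Read source-apportionment records from CSV
#'
#' Reads one record per row, renames columns according to `dialect`,
#' coerces types and validates the record invariants (positive overall
#' concentration, latitude within \[-90, 90\], traffic share within
#' (0, 100\] when present, publication year within 1980--2030). Rows
#' violating an invariant are reported by row number in a single error;
#' nothing is silently dropped.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect Named character vector mapping canonical field names to
#'   the file's column headers; see [default_dialect()].
#' @return A data.frame with one validated record per row and canonical
#'   column names.
#' @export
read_records <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) {
    pm_stop(sprintf("records file not found: %s", path), "pm_config_error")
  }
  missing_map <- setdiff(PM_RECORD_FIELDS, names(dialect))
  if (length(missing_map)) {
    pm_stop(sprintf("dialect does not map required field(s): %s",
                    paste(missing_map, collapse = ", ")), "pm_config_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    pm_stop(sprintf("records file is empty: %s", path), "pm_data_error")
  }
  missing_cols <- dialect[!dialect %in% names(raw)]
  if (length(missing_cols)) {
    pm_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")), "pm_config_error")
  }
  df <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                   lapply(dialect, function(h) raw[[h]]))
  names(df) <- names(dialect)

  numify <- function(x) suppressWarnings(as.numeric(x))
  df$pub_year <- numify(df$pub_year)
  df$population <- numify(df$population)
  df$latitude <- numify(df$latitude)
  df$longitude <- numify(df$longitude)
  df$overall_pm25 <- numify(df$overall_pm25)
  df$traffic_share_pct <- numify(df$traffic_share_pct)
  df$sea_salt_reported <- is_flag_true(df$sea_salt_reported)
  df$site_type <- tolower(trimws(as.character(df$site_type)))

  validate_records(df)
  df
}

#' @noRd
validate_records <- function(df) {
  problems <- character(0)
  note <- function(rows, what) {
    if (any(rows, na.rm = TRUE)) {
      sprintf("%s (row %s)", what,
              paste(which(rows), collapse = ", "))
    } else character(0)
  }
  problems <- c(
    problems,
    note(is.na(df$overall_pm25) | df$overall_pm25 <= 0,
         "overall_pm25 must be a positive number"),
    note(is.na(df$latitude) | abs(df$latitude) > 90,
         "latitude must lie in [-90, 90]"),
    note(!is.na(df$traffic_share_pct) &
           (df$traffic_share_pct <= 0 | df$traffic_share_pct > 100),
         "traffic_share_pct must lie in (0, 100] when present"),
    note(is.na(df$pub_year) | df$pub_year < 1980 | df$pub_year > 2030,
         "pub_year must lie in [1980, 2030]")
  )
  if (length(problems)) {
    pm_stop(paste0("record validation failed:\n  ",
                   paste(problems, collapse = "\n  ")),
            "pm_validation_error")
  }
  invisible(df)
}

#' Restrict records to urban sites reporting a traffic share
#'
#' Applies the two inclusion rules of the meta-analysis: the site typology
#' must be urban (industrial, rural and other typologies are excluded to
#' keep the sample comparable), and the study must report the percentage
#' traffic contribution. The counts removed by each rule are attached as
#' the `"retention_log"` attribute.
#'
#' @param records Validated records from [read_records()].
#' @return The retained subset, with a `retention_log` attribute.
#' @export
filter_records <- function(records) {
  n0 <- nrow(records)
  non_urban <- records$site_type != "urban"
  no_share <- is.na(records$traffic_share_pct)
  keep <- !non_urban & !no_share
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    pm_stop("no records remain after urban/traffic-share filtering",
            "pm_data_error")
  }
  attr(out, "retention_log") <- list(
    n_input = n0,
    removed_non_urban = sum(non_urban),
    removed_missing_traffic_share = sum(no_share & !non_urban),
    n_retained = nrow(out)
  )
  out
}

#' Derive curated analysis variables
#'
#' Computes, for each retained record:
#' * `traffic_pm25` = `overall_pm25 * traffic_share_pct / 100` (ug/m^3);
#' * `ln_population` = log of population expressed in millions;
#' * `lat10` = latitude divided by 10 (signed);
#' * `post2005` = 1 if the study was published strictly after `year_cut`;
#' * `loc_cat` = four-level location category from [region_to_loc_cat()].
#'
#' Records with non-positive population raise a validation error. Records
#' with a zero traffic share, or with missing population or latitude, are
#' excluded (complete-case) and itemised in the `"curation_log"` attribute.
#'
#' @param records Filtered records from [filter_records()].
#' @param year_cut Publication-year cut point; the indicator is 1 for
#'   years strictly greater. Default 2005.
#' @return Curated data.frame with the added columns and a `curation_log`
#'   attribute.
#' @export
curate_records <- function(records, year_cut = 2005) {
  if (any(!is.na(records$population) & records$population <= 0)) {
    pm_stop(sprintf("population must be positive (row %s)",
                    paste(which(records$population <= 0), collapse = ", ")),
            "pm_validation_error")
  }
  zero_share <- !is.na(records$traffic_share_pct) & records$traffic_share_pct == 0
  incomplete <- is.na(records$population) | is.na(records$latitude)
  drop <- zero_share | incomplete
  log <- list(
    n_input = nrow(records),
    rejected_zero_traffic_share = which(zero_share),
    excluded_incomplete_covariates = which(incomplete & !zero_share),
    year_cut = year_cut
  )
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    pm_stop("no records remain after curation", "pm_data_error")
  }
  out$traffic_pm25 <- out$overall_pm25 * out$traffic_share_pct / 100
  out$ln_population <- log(out$population / 1e6)
  out$lat10 <- out$latitude / 10
  out$post2005 <- as.integer(out$pub_year > year_cut)
  out$loc_cat <- region_to_loc_cat(out$region)
  log$n_curated <- nrow(out)
  attr(out, "curation_log") <- log
  out
}

#' Default regressor sets for the two outcome equations
#'
#' The traffic equation uses log population, latitude/10, the sea-salt
#' indicator, the post-2005 indicator and the first two location dummies;
#' the overall equation replaces the post-2005 indicator with the
#' rest-of-Europe dummy. Reference groups: no sea salt reported, published
#' on or before the cut year, rest of the world.
#'
#' @return List with character vectors `traffic` and `overall`.
#' @export
default_regressors <- function() {
  list(
    traffic = c("ln_population", "lat10", "sea_salt_reported", "post2005",
                "loc_NA_Oceania_Japan", "loc_NW_W_Europe"),
    overall = c("ln_population", "lat10", "sea_salt_reported",
                "loc_NA_Oceania_Japan", "loc_NW_W_Europe", "loc_rest_of_Europe")
  )
}

# Numeric covariate frame with location dummies expanded; shared between
# design construction and city prediction so both use identical coding.
#' @noRd
expand_covariates <- function(curated) {
  loc <- curated$loc_cat
  data.frame(
    ln_population = curated$ln_population,
    lat10 = curated$lat10,
    sea_salt_reported = as.numeric(curated$sea_salt_reported),
    post2005 = as.numeric(curated$post2005),
    loc_NA_Oceania_Japan = as.numeric(loc == "NA_Oceania_Japan"),
    loc_NW_W_Europe = as.numeric(loc == "NW_W_Europe"),
    loc_rest_of_Europe = as.numeric(loc == "rest_of_Europe")
  )
}

#' Build design matrices for the joint meta-regression
#'
#' Constructs the two log-outcome vectors (`y1` = log traffic-related
#' PM2.5, `y2` = log overall PM2.5) and the per-equation regressor
#' matrices. Intercepts are handled inside the sampler and are not
#' columns of `X1`/`X2`.
#'
#' @param curated Curated records from [curate_records()].
#' @param formula_cfg List with character vectors `traffic` and `overall`
#'   naming the regressors of each equation; see [default_regressors()].
#' @return Object of class `pm_design`: list with `y1`, `y2`, `X1`, `X2`,
#'   `city_index` and `n`.
#' @export
build_design <- function(curated, formula_cfg = default_regressors()) {
  cov <- expand_covariates(curated)
  known <- names(cov)
  for (side in c("traffic", "overall")) {
    unknown <- setdiff(formula_cfg[[side]], known)
    if (length(unknown)) {
      pm_stop(sprintf("unknown regressor name(s) in %s equation: %s",
                      side, paste(unknown, collapse = ", ")),
              "pm_config_error")
    }
  }
  X1 <- as.matrix(cov[, formula_cfg$traffic, drop = FALSE])
  X2 <- as.matrix(cov[, formula_cfg$overall, drop = FALSE])
  structure(
    list(
      y1 = log(curated$traffic_pm25),
      y2 = log(curated$overall_pm25),
      X1 = X1,
      X2 = X2,
      city_index = curated$city,
      n = nrow(curated)
    ),
    class = "pm_design"
  )
}

#' @export
print.pm_design <- function(x, ...) {
  cat(sprintf("Joint meta-regression design: %d observations\n", x$n))
  cat("  traffic equation regressors:", paste(colnames(x$X1), collapse = ", "), "\n")
  cat("  overall equation regressors:", paste(colnames(x$X2), collapse = ", "), "\n")
  invisible(x)
}

#' Descriptive summary of a curated dataset
#'
#' @param curated Curated records from [curate_records()].
#' @return List of three data.frames: `covariates` (mean/sd/min/max of the
#'   model covariates), `regions` (count and percent per region) and
#'   `concentrations` (mean/sd/min/max of overall and traffic PM2.5).
#' @export
descriptive_summary <- function(curated) {
  if (nrow(curated) == 0L) pm_stop("empty input", "pm_data_error")
  cov <- expand_covariates(curated)
  cov <- cov[, c("ln_population", "lat10", "sea_salt_reported", "post2005",
                 "loc_NA_Oceania_Japan", "loc_NW_W_Europe", "loc_rest_of_Europe")]
  cov$latitude <- curated$latitude
  stat <- function(x) c(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x))
  covariates <- data.frame(
    variable = names(cov),
    t(vapply(cov, stat, numeric(4))),
    row.names = NULL
  )
  tab <- table(factor(curated$region, levels = pm_regions()))
  regions <- data.frame(
    region = names(tab),
    count = as.integer(tab),
    percent = round(100 * as.integer(tab) / nrow(curated), 2),
    row.names = NULL
  )
  conc <- rbind(
    data.frame(outcome = "overall_pm25", t(stat(curated$overall_pm25))),
    data.frame(outcome = "traffic_pm25", t(stat(curated$traffic_pm25)))
  )
  list(covariates = covariates, regions = regions, concentrations = conc)
}
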