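# Core domain tables and their readers/writers.
#
# The package works on three tidy tables:
#   * survey table  -- one row per recorded species per site per survey
#                      period (presence implied by row existence);
#   * indicator table -- per-species ordinal indicator values (1-5) for
#                      temperature, soil moisture, nutrients and light;
#   * site covariates -- per-site environmental gradients.
# Species never listed for a site-period are absent: absences are implicit
# against the per-site species universe, and every consumer materializes
# them that way.

INDICATOR_DIMENSIONS <- c("temperature", "moisture", "nutrients", "light")

SURVEY_COLS <- c("site_id", "period", "surveyor", "species_id")
INDICATOR_COLS <- c("species_id", INDICATOR_DIMENSIONS)
COVARIATE_COLS <- c("site_id", "temp_c", "precip_mm", "ndep2000",
                    "ndep2015", "inclination_deg", "elevation_m")

#' Construct and validate a survey table
#'
#' @param x data frame with columns `site_id`, `period`, `species_id`, an
#'   optional `surveyor` column (`"regular"` or `"replicate"`, defaults to
#'   `"regular"`) and an optional logical/0-1 `present` column (rows with
#'   `present == FALSE` are dropped; presence is otherwise implied by row
#'   existence).
#' @return A tibble of class `mt_survey` with columns `site_id`, `period`,
#'   `surveyor`, `species_id`, deduplicated-checked.
#' @export
survey_table <- function(x) {
  x <- tibble::as_tibble(x)
  for (col in c("site_id", "period", "species_id")) {
    if (!col %in% names(x)) {
      stop("survey table is missing required column '", col, "'")
    }
  }
  if (!"surveyor" %in% names(x)) x$surveyor <- "regular"
  if ("present" %in% names(x)) {
    x <- x[as.logical(x$present), , drop = FALSE]
    x$present <- NULL
  }
  x <- x[SURVEY_COLS]
  x$site_id <- as.character(x$site_id)
  x$species_id <- as.character(x$species_id)
  x$period <- as.integer(x$period)
  x$surveyor <- as.character(x$surveyor)
  bad <- setdiff(unique(x$surveyor), c("regular", "replicate"))
  if (length(bad)) {
    stop("unknown surveyor flag(s): ", paste(bad, collapse = ", "))
  }
  dup <- duplicated(x)
  if (any(dup)) {
    offenders <- utils::head(x[dup, ], 5)
    stop("duplicate (site, period, surveyor, species) records, e.g.: ",
         paste(sprintf("(%s, %d, %s, %s)", offenders$site_id,
                       offenders$period, offenders$surveyor,
                       offenders$species_id), collapse = "; "))
  }
  class(x) <- c("mt_survey", class(x))
  x
}

#' Construct and validate an indicator-value table
#'
#' @param x data frame with columns `species_id`, `temperature`, `moisture`,
#'   `nutrients`, `light`; values are ordinal in `[1, 5]`, `NA` = missing.
#'   Each species must carry at least one non-missing dimension.
#' @return A tibble of class `mt_indicators`.
#' @export
indicator_table <- function(x) {
  x <- tibble::as_tibble(x)
  for (col in INDICATOR_COLS) {
    if (!col %in% names(x)) {
      stop("indicator table is missing required column '", col, "'")
    }
  }
  x <- x[INDICATOR_COLS]
  x$species_id <- as.character(x$species_id)
  if (anyDuplicated(x$species_id)) {
    stop("indicator table has duplicated species_id values")
  }
  vals <- as.matrix(x[INDICATOR_DIMENSIONS])
  if (any(vals < 1 | vals > 5, na.rm = TRUE)) {
    stop("indicator values must lie in [1, 5]")
  }
  all_na <- rowSums(!is.na(vals)) == 0
  if (any(all_na)) {
    stop("species with no indicator value on any dimension: ",
         paste(utils::head(x$species_id[all_na], 5), collapse = ", "))
  }
  class(x) <- c("mt_indicators", class(x))
  x
}

#' Construct and validate a site-covariate table
#'
#' @param x data frame with columns `site_id`, `temp_c` (mean annual
#'   temperature, deg C), `precip_mm` (annual precipitation), `ndep2000` and
#'   `ndep2015` (N deposition, kg N ha-1 yr-1), `inclination_deg`,
#'   `elevation_m`. One row per site; deposition must be positive and
#'   inclination within `[0, 90]`.
#' @return A tibble of class `mt_covariates`.
#' @export
site_covariates <- function(x) {
  x <- tibble::as_tibble(x)
  for (col in COVARIATE_COLS) {
    if (!col %in% names(x)) {
      stop("covariate table is missing required column '", col, "'")
    }
  }
  x <- x[COVARIATE_COLS]
  x$site_id <- as.character(x$site_id)
  if (anyDuplicated(x$site_id)) {
    stop("covariate table must have one row per site")
  }
  if (any(x$ndep2000 <= 0 | x$ndep2015 <= 0, na.rm = TRUE)) {
    stop("N deposition values must be positive")
  }
  if (any(x$inclination_deg < 0 | x$inclination_deg > 90, na.rm = TRUE)) {
    stop("inclination must lie in [0, 90] degrees")
  }
  class(x) <- c("mt_covariates", class(x))
  x
}

#' Validate a survey/indicator/covariate triple
#'
#' Records whose species is absent from the indicator table (e.g.
#' genus-level determinations) are dropped, mirroring the pre-analysis
#' removal of records not identified to species level; records at sites
#' missing from the covariate table are likewise dropped. Both drops are
#' reported. After dropping, every regular site-period must retain at least
#' one species.
#'
#' @param survey,indicators,covariates tables as returned by
#'   [survey_table()], [indicator_table()], [site_covariates()].
#' @return A list with elements `survey`, `indicators`, `covariates`
#'   (validated, filtered) and `report` (tibble of dropped records with a
#'   `reason` column).
#' @export
validate_dataset <- function(survey, indicators, covariates) {
  survey <- survey_table(survey)
  indicators <- indicator_table(indicators)
  covariates <- site_covariates(covariates)

  unresolved <- !(survey$species_id %in% indicators$species_id)
  orphan <- !(survey$site_id %in% covariates$site_id)
  report <- dplyr::bind_rows(
    dplyr::mutate(survey[unresolved & !orphan, ],
                  reason = "species not in indicator table"),
    dplyr::mutate(survey[orphan, ], reason = "site not in covariate table")
  )
  survey <- survey[!(unresolved | orphan), ]
  class(survey) <- c("mt_survey", setdiff(class(survey), "mt_survey"))

  if (nrow(survey) == 0) stop("no survey records remain after validation")
  reg <- survey[survey$surveyor == "regular", ]
  n_by <- dplyr::count(reg, .data$site_id, .data$period)
  # emptiness can only arise through dropping: a (site, period) that lost
  # every record would silently vanish from n_by, so check against the
  # site-period grid seen before filtering
  all_sp <- unique(reg[c("site_id", "period")])
  if (nrow(all_sp) != nrow(n_by) || any(n_by$n < 1)) {
    stop("a regular site-period lost all its species during validation")
  }
  list(survey = survey, indicators = indicators, covariates = covariates,
       report = report)
}

read_table_auto <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read and validate a dataset from delimited files
#'
#' Files may be CSV or TSV (chosen by extension). Column contracts:
#' community file `site_id, period, surveyor, species_id` (optional
#' `present`); indicators file `species_id, temperature, moisture,
#' nutrients, light` (empty cell = missing); covariates file `site_id,
#' temp_c, precip_mm, ndep2000, ndep2015, inclination_deg, elevation_m`.
#'
#' @param community_path,indicators_path,covariates_path file paths.
#' @return A validated dataset list as from [validate_dataset()].
#' @export
read_dataset <- function(community_path, indicators_path, covariates_path) {
  for (p in c(community_path, indicators_path, covariates_path)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  validate_dataset(
    survey = read_table_auto(community_path),
    indicators = read_table_auto(indicators_path),
    covariates = read_table_auto(covariates_path)
  )
}

#' Write a dataset to a directory as CSV files with a metadata sidecar
#'
#' @param dataset a validated dataset list (elements `survey`, `indicators`,
#'   `covariates`).
#' @param dir output directory, created if needed.
#' @param meta optional named list merged into the JSON sidecar
#'   (e.g. run id, seed, config hash).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    community = file.path(dir, "community.csv"),
    indicators = file.path(dir, "indicators.csv"),
    covariates = file.path(dir, "covariates.csv")
  )
  readr::write_csv(dataset$survey, paths[["community"]])
  readr::write_csv(dataset$indicators, paths[["indicators"]])
  readr::write_csv(dataset$covariates, paths[["covariates"]])
  sidecar <- c(list(written = format(Sys.time(), tz = "UTC"),
                    n_records = nrow(dataset$survey)), meta)
  jsonlite::write_json(sidecar, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Species recorded at a site-period
#'
#' @param survey a survey table.
#' @param site,period site identifier and integer period.
#' @param surveyor `"regular"` (default) or `"replicate"`.
#' @return Sorted character vector of species present.
#' @export
species_set <- function(survey, site, period, surveyor = "regular") {
  keep <- survey$site_id == site & survey$period == period &
    survey$surveyor == surveyor
  if (!any(keep)) {
    stop("no survey found for site '", site, "', period ", period,
         ", surveyor '", surveyor, "'")
  }
  sort(unique(survey$species_id[keep]))
}

#' Total community of a site: union of species over all regular surveys
#'
#' @inheritParams species_set
#' @return Sorted character vector of species ever recorded at the site.
#' @export
total_community <- function(survey, site) {
  keep <- survey$site_id == site & survey$surveyor == "regular"
  if (!any(keep)) stop("unknown site: ", site)
  sort(unique(survey$species_id[keep]))
}

#' @noRd
site_periods <- function(survey, site) {
  sort(unique(survey$period[survey$site_id == site &
                              survey$surveyor == "regular"]))
}
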