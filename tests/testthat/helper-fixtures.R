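# Fixtures built in code: a 2-site, 3-period survey with one replicate
# survey, plus matching indicator and covariate tables.

fixture_paths <- function() {
  dir <- system.file("extdata", "example", package = "meadowturn")
  list(community = file.path(dir, "community.csv"),
       indicators = file.path(dir, "indicators.csv"),
       covariates = file.path(dir, "covariates.csv"))
}

# survey built from a named list of named lists: sites -> periods -> species
make_survey <- function(spec, replicates = NULL) {
  rows <- list()
  for (s in names(spec)) {
    for (p in names(spec[[s]])) {
      sp <- spec[[s]][[p]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        site_id = s, period = as.integer(p), surveyor = "regular",
        species_id = sp)
    }
  }
  if (!is.null(replicates)) {
    for (r in replicates) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        site_id = r$site, period = as.integer(r$period),
        surveyor = "replicate", species_id = r$species)
    }
  }
  survey_table(dplyr::bind_rows(rows))
}

make_indicators <- function(ids, nutrients = NULL, temperature = NULL,
                            moisture = NULL, light = NULL) {
  n <- length(ids)
  fill <- function(x) if (is.null(x)) rep(3, n) else x
  indicator_table(tibble::tibble(
    species_id = ids, temperature = fill(temperature),
    moisture = fill(moisture), nutrients = fill(nutrients),
    light = fill(light)))
}

make_covariates <- function(ids, ndep2000 = NULL, ndep2015 = NULL,
                            elevation = NULL) {
  n <- length(ids)
  # draws (not sequences) so the four gradients are not collinear
  set.seed(99 + n)
  base_ndep <- stats::runif(n, 8, 30)
  site_covariates(tibble::tibble(
    site_id = ids,
    temp_c = stats::runif(n, 3, 9),
    precip_mm = stats::runif(n, 1000, 1600),
    ndep2000 = if (is.null(ndep2000)) base_ndep else ndep2000,
    ndep2015 = if (is.null(ndep2015)) pmax(base_ndep - 2.5, 0.6) else
      ndep2015,
    inclination_deg = stats::runif(n, 2, 40),
    elevation_m = if (is.null(elevation)) stats::runif(n, 800, 2000)
      else elevation))
}
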