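#!/usr/bin/env Rscript
# Thin command-line wrapper around meadowturn::run_all(): runs the full
# analysis either on three input files or on a synthetic dataset.
#
# Examples:
#   Rscript scripts/run_pipeline.R --outdir out --seed 1
#   Rscript scripts/run_pipeline.R --outdir out \
#     --community data/community.csv --indicators data/indicators.csv \
#     --covariates data/covariates.csv

suppressPackageStartupMessages({
  library(optparse)
  library(meadowturn)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "meadowturn_out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n-draws", type = "integer", default = 1000L,
              dest = "n_draws"),
  make_option("--community", type = "character", default = NULL),
  make_option("--indicators", type = "character", default = NULL),
  make_option("--covariates", type = "character", default = NULL),
  make_option("--n-sites", type = "integer", default = 129L,
              dest = "n_sites", help = "synthetic mode only"),
  make_option("--ndep-year", type = "character", default = "midpoint",
              dest = "ndep_year"),
  make_option("--colonization-pool", type = "character", default = "site",
              dest = "colonization_pool")
)))

paths <- list(community = opt$community, indicators = opt$indicators,
              covariates = opt$covariates)
have_files <- !vapply(paths, is.null, logical(1))
if (any(have_files) && !all(have_files)) {
  stop("--community, --indicators and --covariates must be given together")
}

cfg <- run_config(
  outdir = opt$outdir,
  input_paths = if (all(have_files)) paths else NULL,
  synthetic = if (all(have_files)) NULL else
    synthetic_config(n_sites = opt$n_sites, seed = opt$seed),
  seed = opt$seed,
  n_draws = opt$n_draws,
  ndep_year = opt$ndep_year,
  colonization_pool = opt$colonization_pool
)
run_all(cfg)
cat("outputs written to", opt$outdir, "\n")
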