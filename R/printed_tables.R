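# Published Australian fur seal census data bundled with the package.
#
# These small tables carry the published range-wide census results
# (2007/2013/2017 live-pup estimates, between-census changes) and the
# published per-colony trend coefficients. They serve as worked-example
# inputs and as regression targets for the census arithmetic; the raw
# per-sub-area tallies behind them were never deposited, which is what the
# simulator in this package stands in for.

afs_file <- function(name) {
  system.file("extdata", name, package = "pupcensus", mustWork = TRUE)
}

#' Bundled Australian fur seal colony registry
#'
#' The 21 breeding colonies visited during the 2017 range-wide census, with
#' state, oceanographic region, coordinates and terrain figures.
#'
#' @return a `colony_registry` data.frame (see [load_registry()]).
#' @export
afs_colony_registry <- function() {
  load_registry(afs_file("afs_colonies.csv"))
}

#' Published census results (2007, 2013, 2017)
#'
#' Per-colony live-pup estimates (with standard errors where published) from
#' the three most recent Australian fur seal range-wide censuses, plus the
#' published between-census percent-change labels. Kanowna Island values are
#' on the CMR scale (direct counts times the site conversion factor 1.71).
#'
#' @return a data.frame with columns `colony_id`, `site`, `region`,
#'   `pups_2007`, `se_2007`, `pups_2013`, `se_2013`, `pups_2017`, `se_2017`,
#'   `change_2007_2013`, `change_2013_2017` (change columns are printed
#'   labels: signed integers, `"+>1000"` or `"Na"`).
#' @export
afs_census_results <- function() {
  utils::read.csv(afs_file("afs_census_results.csv"),
                  stringsAsFactors = FALSE,
                  colClasses = c(change_2007_2013 = "character",
                                 change_2013_2017 = "character"))
}

#' Published per-colony trend coefficients
#'
#' Negative binomial GLM results for the 18 colonies with sufficient survey
#' history (1986--2018): year slope (`beta_year`, log scale), intercept, Wald
#' z, p-value, 95% CI, percent deviance explained and dispersion `theta`.
#' The underlying multi-decade survey histories are supplementary data and
#' are not distributed; these coefficients support the growth-rate versus
#' abundance regression and the reliability-classification checks.
#'
#' @return a data.frame with one row per colony.
#' @export
afs_trend_results <- function() {
  utils::read.csv(afs_file("afs_trend_results.csv"), stringsAsFactors = FALSE)
}

#' Long-format published abundance history
#'
#' Reshapes [afs_census_results()] to one row per colony and census season
#' (the trend-input schema).
#'
#' @return data.frame with `colony_id`, `season_year`, `estimate`.
#' @export
afs_abundance_history <- function() {
  cen <- afs_census_results()
  out <- do.call(rbind, lapply(c(2007, 2013, 2017), function(y) {
    data.frame(colony_id = cen$colony_id, season_year = y,
               estimate = cen[[paste0("pups_", y)]],
               stringsAsFactors = FALSE)
  }))
  out[!is.na(out$estimate), , drop = FALSE]
}
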