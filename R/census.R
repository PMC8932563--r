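# Census assembly: per-season colony tables, mortality and population
# conversions, and between-census change statistics.

#' Conversion configuration for census assembly
#'
#' Bundles the factors that turn live-pup estimates into production and
#' total-population figures:
#' \itemize{
#'   \item `mortality_fraction` -- fraction of pups born that die before the
#'     survey (default 0.15, the long-run early-mortality estimate for
#'     Australian fur seals); live pups are divided by `1 - mortality` to get
#'     production.
#'   \item `population_multiplier` -- pups-to-total-population multiplier
#'     (default 4.5, from the female age structure and low fecundity of this
#'     sub-species).
#'   \item `population_rounding` -- total population is reported to the
#'     nearest multiple of this (default 100).
#'   \item `count_conversion_factors` -- named list mapping colony_id to a
#'     site-specific direct-count-to-CMR factor (default `Kan = 1.71`).
#'   \item `mortality_mode` -- `"divide"` (default; live/(1-q)) or
#'     `"multiply"` (live*(1+q)), kept for sensitivity analysis.
#' }
#'
#' @param mortality_fraction proportion in [0, 1).
#' @param population_multiplier positive real.
#' @param population_rounding positive count.
#' @param count_conversion_factors named list of positive factors.
#' @param mortality_mode `"divide"` or `"multiply"`.
#' @return a list with class `conversion_config`.
#' @export
conversion_config <- function(mortality_fraction = 0.15,
                              population_multiplier = 4.5,
                              population_rounding = 100,
                              count_conversion_factors = list(Kan = 1.71),
                              mortality_mode = c("divide", "multiply")) {
  if (mortality_fraction < 0 || mortality_fraction >= 1) {
    pc_stop("pc_config_error", "mortality_fraction must be in [0, 1)")
  }
  if (population_multiplier <= 0) {
    pc_stop("pc_config_error", "population_multiplier must be positive")
  }
  structure(list(mortality_fraction = mortality_fraction,
                 population_multiplier = population_multiplier,
                 population_rounding = population_rounding,
                 count_conversion_factors = count_conversion_factors,
                 mortality_mode = match.arg(mortality_mode)),
            class = "conversion_config")
}

#' Read a conversion/simulation config from YAML
#'
#' @param path YAML file; recognised keys are the arguments of
#'   [conversion_config()] (unknown keys are ignored so the same file can
#'   carry simulation blocks).
#' @return a `conversion_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  conversion_config(
    mortality_fraction = y$mortality_fraction %||% 0.15,
    population_multiplier = y$population_multiplier %||% 4.5,
    population_rounding = y$population_rounding %||% 100,
    count_conversion_factors = y$count_conversion_factors %||% list(Kan = 1.71),
    mortality_mode = y$mortality_mode %||% "divide")
}

#' Total pup production from live pups
#'
#' Adds pre-survey pup mortality back onto the live-pup estimate. With a
#' mortality fraction q, live pups are (1 - q) of production, so production
#' is live / (1 - q), truncated to a whole pup. (The alternative reading
#' live * (1 + q) is available as `mode = "multiply"` for sensitivity
#' analysis; only the division form is consistent with treating q as the
#' fraction of births that die.)
#'
#' @param total_live live pup count.
#' @param mortality_fraction proportion of births dying before survey.
#' @param mode `"divide"` (default) or `"multiply"`.
#' @return total pup production (integer).
#' @examples
#' production_from_live(16861, 0.15) # 19836
#' @export
production_from_live <- function(total_live, mortality_fraction = 0.15,
                                 mode = c("divide", "multiply")) {
  mode <- match.arg(mode)
  if (mortality_fraction < 0 || mortality_fraction >= 1) {
    pc_stop("pc_config_error", "mortality_fraction must be in [0, 1)")
  }
  raw <- if (mode == "divide") total_live / (1 - mortality_fraction)
         else total_live * (1 + mortality_fraction)
  as.integer(floor(raw))
}

#' Total population from pup production
#'
#' @param production total pup production.
#' @param multiplier pups-to-population factor (default 4.5).
#' @param rounding report to the nearest multiple of this (default 100).
#' @return total population size, rounded.
#' @examples
#' population_from_production(19836) # 89300
#' @export
population_from_production <- function(production, multiplier = 4.5,
                                       rounding = 100) {
  stopifnot(production >= 0)
  round_half_away(production * multiplier / rounding) * rounding
}

#' Percent change between two censuses
#'
#' Computes 100 (curr - prev) / prev per colony. Zero estimates are replaced
#' by `zero_floor` (default 1) before the ratio so change from or to an empty
#' colony stays finite. The display value is rounded half-away-from-zero to
#' an integer; raw values are retained. Changes beyond +1000% display as
#' `"+>1000"`.
#'
#' @param prev,curr non-negative counts (vectorised).
#' @param zero_floor replacement for zero counts (default 1).
#' @return a `data.frame` with columns `raw` (unrounded percent), `rounded`
#'   (integer, half-away-from-zero) and `label` (display string).
#' @examples
#' percent_change(5660, 4092)$rounded # -28
#' percent_change(0, 16)$raw          # 1500
#' @export
percent_change <- function(prev, curr, zero_floor = 1) {
  if (any(prev < 0, na.rm = TRUE) || any(curr < 0, na.rm = TRUE)) {
    pc_stop("pc_usage_error", "counts must be non-negative")
  }
  p <- ifelse(prev == 0, zero_floor, prev)
  q <- ifelse(curr == 0, zero_floor, curr)
  raw <- 100 * (q - p) / p
  rounded <- round_half_away(raw)
  label <- ifelse(is.na(raw), "Na",
           ifelse(raw > 1000, "+>1000",
           ifelse(rounded > 0, paste0("+", rounded), as.character(rounded))))
  data.frame(raw = raw, rounded = rounded, label = label,
             stringsAsFactors = FALSE)
}

#' Annualised percent change
#'
#' Geometric (compound) rate: 100 ((n1/n0)^(1/years) - 1).
#'
#' @param n0,n1 counts at the start and end (zero-floored to `zero_floor`).
#' @param years elapsed years (>= 1).
#' @param zero_floor replacement for zero counts.
#' @return percent per annum (real).
#' @examples
#' annualized_percent_change(100, 200, 10) # ~7.18
#' @export
annualized_percent_change <- function(n0, n1, years, zero_floor = 1) {
  if (years < 1) pc_stop("pc_usage_error", "years must be >= 1")
  n0 <- ifelse(n0 == 0, zero_floor, n0)
  n1 <- ifelse(n1 == 0, zero_floor, n1)
  100 * ((n1 / n0)^(1 / years) - 1)
}

#' Colony size category
#'
#' Categories used for stratifying change analyses by the most recent census
#' abundance: small 0--599, medium 600--1699, large 1700 and above. (The
#' stated ranges "large > 1700" and "medium 600:1699" leave 1700 itself
#' unassigned; it is classed large so the categories are exhaustive.)
#'
#' @param estimate pup abundance (vectorised, >= 0).
#' @return factor with levels small, medium, large.
#' @export
classify_size <- function(estimate) {
  if (any(estimate < 0, na.rm = TRUE)) {
    pc_stop("pc_usage_error", "estimates must be non-negative")
  }
  cut(estimate, breaks = c(-Inf, 599.5, 1699.5, Inf),
      labels = c("small", "medium", "large"))
}

#' Assemble a census table for one season
#'
#' Joins per-colony abundance estimates with the registry, classifies colony
#' sizes, computes percent change against a prior census where both seasons
#' have estimates, and derives the season totals: total live pups (sum of
#' rounded row estimates), total pup production (mortality correction) and
#' total population (multiplier, rounded).
#'
#' @param estimates a `data.frame` with columns `colony_id`, `mean` and
#'   optionally `se` (e.g. from [estimates_table()]), one row per colony;
#'   count conversions are assumed already applied.
#' @param season_year integer census season.
#' @param registry a `colony_registry` (optional; adds regions and carries
#'   colonies missing from `estimates` as NA rows).
#' @param config a [conversion_config()].
#' @param prev a previous `census_table` (optional) for the change column.
#' @return a `census_table`: list with `season_year`, `rows` (data.frame),
#'   `total_live_pups`, `total_production`, `total_population`, and
#'   `total_change` (percent vs the previous census, when given).
#' @export
assemble_census <- function(estimates, season_year, registry = NULL,
                            config = conversion_config(), prev = NULL) {
  if (is.null(estimates) || nrow(estimates) == 0L) {
    rows <- data.frame(colony_id = character(0), region = character(0),
                       estimate = numeric(0), se = numeric(0),
                       size_category = character(0),
                       stringsAsFactors = FALSE)
    return(structure(list(season_year = season_year, rows = rows,
                          total_live_pups = 0L, total_production = 0L,
                          total_population = 0, total_change = NULL),
                     class = "census_table"))
  }
  if (anyDuplicated(estimates$colony_id)) {
    pc_stop("pc_usage_error",
            "more than one estimate for a colony in one season")
  }
  rows <- data.frame(colony_id = estimates$colony_id,
                     estimate = round_half_away(estimates$mean),
                     se = if ("se" %in% names(estimates)) estimates$se else NA_real_,
                     stringsAsFactors = FALSE)
  if (!is.null(registry)) {
    rows <- merge(data.frame(colony_id = registry$colony_id,
                             region = registry$region,
                             stringsAsFactors = FALSE),
                  rows, by = "colony_id", all = TRUE)
  } else {
    rows$region <- NA_character_
    rows <- rows[, c("colony_id", "region", "estimate", "se")]
  }
  rows$size_category <- as.character(classify_size(rows$estimate))
  if (!is.null(prev)) {
    stopifnot(inherits(prev, "census_table"))
    prev_est <- prev$rows$estimate[match(rows$colony_id, prev$rows$colony_id)]
    ok <- !is.na(prev_est) & !is.na(rows$estimate)
    rows$change_pct <- NA_real_
    rows$change_label <- "Na"
    if (any(ok)) {
      ch <- percent_change(prev_est[ok], rows$estimate[ok])
      rows$change_pct[ok] <- ch$raw
      rows$change_label[ok] <- ch$label
    }
  }
  # region order, declining colonies first within region (table convention)
  ord <- order(match(rows$region, pup_regions),
               if (!is.null(prev)) rows$change_pct else -rows$estimate,
               na.last = TRUE)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  total_live <- sum(rows$estimate, na.rm = TRUE)
  total_prod <- production_from_live(total_live, config$mortality_fraction,
                                     config$mortality_mode)
  total_pop <- population_from_production(total_prod,
                                          config$population_multiplier,
                                          config$population_rounding)
  total_change <- if (!is.null(prev)) {
    percent_change(prev$total_live_pups, total_live)
  }
  structure(list(season_year = season_year, rows = rows,
                 total_live_pups = total_live,
                 total_production = total_prod,
                 total_population = total_pop,
                 total_change = total_change),
            class = "census_table")
}

#' @export
print.census_table <- function(x, ...) {
  cat(sprintf("<census_table> season %d: %d colonies\n",
              x$season_year, nrow(x$rows)))
  print(x$rows)
  cat(sprintf("TOTAL live pups: %d | production: %d | population: %s\n",
              x$total_live_pups, x$total_production,
              format(x$total_population, big.mark = ",")))
  if (!is.null(x$total_change)) {
    cat(sprintf("Change vs previous census: %s%%\n", x$total_change$label))
  }
  invisible(x)
}

#' Write a census table to CSV
#'
#' @param census a `census_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  utils::write.csv(census$rows, path, row.names = FALSE, na = "Na")
  invisible(path)
}
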