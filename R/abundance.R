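# Colony-level live-pup abundance estimation.
#
# CMR sub-areas use Chapman's bias-corrected two-sample estimator
#   N-hat = (M+1)(n+1)/(m+1) - 1
# with the Seber/Chapman variance
#   var   = (M+1)(n+1)(M-m)(n-m) / [(m+1)^2 (m+2)].
# Colony totals sum sub-area means and variances (independent sub-areas,
# closed population, equal sightability of marked and clear pups).

#' Remove dead marked pups from the marked total
#'
#' Marked pups found dead at resight are removed from the number of marked
#' pups available, so the estimator sees only marks at risk of resighting.
#'
#' @param M_raw marked pups originally placed (count, vectorised).
#' @param dead_marked marked pups recorded dead at resight.
#' @return adjusted marked count `M_raw - dead_marked`.
#' @export
adjust_marked_for_deaths <- function(M_raw, dead_marked) {
  if (any(dead_marked > M_raw)) {
    pc_stop("pc_tally_error",
            "dead_marked exceeds the number of marked pups")
  }
  if (any(M_raw < 0) || any(dead_marked < 0)) {
    pc_stop("pc_tally_error", "negative tallies")
  }
  M_raw - dead_marked
}

#' Chapman (modified Petersen) sub-area estimate
#'
#' @param M marked pups available for resighting (dead marks already
#'   removed, see [adjust_marked_for_deaths()]).
#' @param n total pups counted at resight.
#' @param m marked pups among those resighted.
#' @param warn_low_recapture emit a warning when `m < 5` (the estimator is
#'   defined at `m = 0` but unstable at very low recaptures).
#' @return a `data.frame` with columns `mean` and `variance`, one row per
#'   sub-area.
#' @examples
#' chapman_estimate(100, 150, 50) # mean ~ 298.04
#' @export
chapman_estimate <- function(M, n, m, warn_low_recapture = TRUE) {
  if (any(m > pmin(M, n)) || any(c(M, n, m) < 0)) {
    pc_stop("pc_tally_error",
            "tally invariant violated: need 0 <= m <= min(M, n)")
  }
  if (warn_low_recapture && any(m < 5)) {
    pc_warn("pc_low_recapture_warning",
            sprintf("%d sub-area(s) with fewer than 5 recaptures; estimates are unstable",
                    sum(m < 5)))
  }
  mean <- (M + 1) * (n + 1) / (m + 1) - 1
  variance <- (M + 1) * (n + 1) * (M - m) * (n - m) / ((m + 1)^2 * (m + 2))
  data.frame(mean = mean, variance = variance)
}

new_abundance_estimate <- function(colony_id, season_year, mean, variance,
                                   method, n_replicates = NA_integer_) {
  se <- sqrt(variance)
  structure(
    list(colony_id = colony_id, season_year = season_year,
         mean = mean, variance = variance, se = se,
         ci95 = c(max(0, mean - 1.96 * se), mean + 1.96 * se),
         method = method, n_replicates = n_replicates),
    class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("<abundance_estimate> %s season %s: %s pups (se %.1f, 95%% CI %.0f-%.0f) [%s]\n",
              x$colony_id %||% "?", x$season_year %||% "?",
              format(round_half_away(x$mean)), x$se,
              x$ci95[1], x$ci95[2], x$method))
  invisible(x)
}

#' Aggregate sub-area estimates into a colony estimate
#'
#' The colony total is the sum of sub-area means; the colony variance is the
#' sum of sub-area variances. The 95% CI is the normal approximation
#' mean +/- 1.96 se, floored at 0.
#'
#' @param subareas a `data.frame` with columns `mean` and `variance`
#'   (from [chapman_estimate()]).
#' @param colony_id,season_year identifiers carried onto the estimate.
#' @return an `abundance_estimate` with method `"CMR"`.
#' @export
aggregate_subareas <- function(subareas, colony_id = NA_character_,
                               season_year = NA_integer_) {
  if (is.null(subareas) || nrow(subareas) == 0L) {
    pc_stop("pc_usage_error", "no sub-area estimates to aggregate")
  }
  new_abundance_estimate(colony_id, season_year,
                         mean = sum(subareas$mean),
                         variance = sum(subareas$variance),
                         method = "CMR",
                         n_replicates = nrow(subareas))
}

#' Estimate colony abundance from one CMR survey
#'
#' Applies the dead-mark adjustment, per-sub-area Chapman estimates and
#' sub-area aggregation to a CMR `survey_record`.
#'
#' @param survey a CMR `survey_record` (see [load_surveys()]).
#' @return an `abundance_estimate`.
#' @export
estimate_cmr_survey <- function(survey) {
  stopifnot(inherits(survey, "survey_record"), survey$method == "CMR")
  p <- survey$payload
  M <- adjust_marked_for_deaths(p$marked_available, p$dead_marked)
  sub <- chapman_estimate(M, p$total_resighted, p$marked_resighted)
  aggregate_subareas(sub, survey$colony_id, survey$season_year)
}

#' Estimate colony abundance from replicate direct counts
#'
#' The estimate is the arithmetic mean of the observers' totals; its standard
#' error is the sample SD over sqrt(k). A single replicate yields an estimate
#' with undefined (NA) standard error and a warning.
#'
#' @param counts numeric vector of per-observer totals (>= 0).
#' @param colony_id,season_year identifiers carried onto the estimate.
#' @param method `"direct_count"` or `"aerial"` (same arithmetic).
#' @return an `abundance_estimate`.
#' @examples
#' direct_count_estimate(c(100, 110, 120)) # 110, se 5.77
#' @export
direct_count_estimate <- function(counts, colony_id = NA_character_,
                                  season_year = NA_integer_,
                                  method = c("direct_count", "aerial")) {
  method <- match.arg(method)
  if (any(counts < 0)) pc_stop("pc_validation_error", "negative counts")
  k <- length(counts)
  if (k == 1L) {
    pc_warn("pc_single_replicate_warning",
            "single replicate count: standard error undefined")
    return(new_abundance_estimate(colony_id, season_year, counts, NA_real_,
                                  method, n_replicates = 1L))
  }
  new_abundance_estimate(colony_id, season_year,
                         mean = mean(counts),
                         variance = stats::var(counts) / k,
                         method = method, n_replicates = k)
}

#' Estimate abundance from any survey record
#'
#' Dispatches on the survey method: CMR surveys go through
#' [estimate_cmr_survey()], direct/aerial through [direct_count_estimate()],
#' incidental observations become zero-variance estimates.
#'
#' @param survey a `survey_record`.
#' @return an `abundance_estimate`.
#' @export
estimate_survey <- function(survey) {
  stopifnot(inherits(survey, "survey_record"))
  switch(survey$method,
         CMR = estimate_cmr_survey(survey),
         direct_count = direct_count_estimate(survey$payload, survey$colony_id,
                                              survey$season_year, "direct_count"),
         aerial = direct_count_estimate(survey$payload, survey$colony_id,
                                        survey$season_year, "aerial"),
         incidental = new_abundance_estimate(survey$colony_id,
                                             survey$season_year,
                                             survey$payload, 0,
                                             "incidental", 1L),
         pc_stop("pc_usage_error",
                 paste("unknown survey method:", survey$method)))
}

#' Convert a direct-count estimate to the CMR scale
#'
#' Direct counts under-record pups relative to capture-mark-resight. Where a
#' site-specific, repeatable conversion factor has been calibrated from years
#' with paired methods (e.g. 1.71 at Kanowna Island), it rescales the count
#' to an approximate CMR-equivalent estimate. Mean and SE scale by the
#' factor; the reported mean is rounded half-away-from-zero.
#'
#' @param estimate an `abundance_estimate` with method `direct_count` or
#'   `aerial`.
#' @param factor positive multiplier.
#' @return an `abundance_estimate` with method `"converted_count"`.
#' @examples
#' e <- direct_count_estimate(c(1894, 1894))
#' apply_count_conversion(e, 1.71)$mean  # 3239
#' @export
apply_count_conversion <- function(estimate, factor) {
  stopifnot(inherits(estimate, "abundance_estimate"))
  if (!estimate$method %in% c("direct_count", "aerial")) {
    pc_stop("pc_usage_error",
            "count conversion applies to direct_count/aerial estimates only")
  }
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    pc_stop("pc_config_error", "conversion factor must be a positive number")
  }
  out <- new_abundance_estimate(estimate$colony_id, estimate$season_year,
                                mean = round_half_away(estimate$mean * factor),
                                variance = estimate$variance * factor^2,
                                method = "converted_count",
                                n_replicates = estimate$n_replicates)
  out$mean_raw <- estimate$mean * factor
  out
}

#' Ratio of a direct count to a paired CMR estimate
#'
#' For seasons surveyed by both methods at one colony, the ratio
#' direct / CMR measures the visibility bias of counting; averaging the
#' ratios over paired seasons gives the count-to-CMR conversion factor.
#'
#' @param direct,cmr paired `abundance_estimate`s for the same colony and
#'   season.
#' @return the ratio `direct$mean / cmr$mean`.
#' @seealso [mean_conversion_ratio()]
#' @export
count_to_cmr_ratio <- function(direct, cmr) {
  stopifnot(inherits(direct, "abundance_estimate"),
            inherits(cmr, "abundance_estimate"))
  if (!identical(direct$colony_id, cmr$colony_id) ||
      !identical(direct$season_year, cmr$season_year)) {
    pc_stop("pc_usage_error", "estimates are not a colony/season pair")
  }
  if (cmr$mean <= 0) {
    pc_stop("pc_undefined_ratio_error", "CMR mean is zero: ratio undefined")
  }
  direct$mean / cmr$mean
}

#' Average count-to-CMR ratio over paired seasons
#'
#' @param ratios numeric vector of per-season ratios.
#' @return their arithmetic mean.
#' @examples
#' mean_conversion_ratio(c(0.70, 0.71, 0.66)) # 0.69
#' @export
mean_conversion_ratio <- function(ratios) mean(ratios)

#' Tabulate abundance estimates
#'
#' @param estimates list of `abundance_estimate` objects.
#' @return a `data.frame` with columns colony_id, season_year, method, mean,
#'   se, ci_low, ci_high (the `estimates.csv` schema).
#' @export
estimates_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(colony_id = e$colony_id, season_year = e$season_year,
               method = e$method, mean = e$mean, se = e$se,
               ci_low = e$ci95[1], ci_high = e$ci95[2],
               stringsAsFactors = FALSE)
  }))
}
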