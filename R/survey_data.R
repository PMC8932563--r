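# Colony registry and survey I/O.
#
# Canonical interchange is long-format CSV:
#   colonies.csv      colony_id,name,state,region,latitude,longitude,area_ha,height_m
#   cmr_surveys.csv   colony_id,date,subarea_id,marked_available,total_resighted,
#                     marked_resighted,dead_marked,dead_clear
#   count_surveys.csv colony_id,date,observer_id,count,method
# One row per sub-area tally (CMR) or per observer total (counts).

#' Oceanographic regions recognised by the pipeline
#'
#' Closed vocabulary of the regional oceanographic influences used to group
#' Australian fur seal breeding colonies (currents and upwelling zones of
#' south-eastern Australia).
#' @export
pup_regions <- c(
  "Central Bass Strait",
  "Bonney Upwelling",
  "Kangaroo Island upwelling",
  "Eyre Peninsula Upwelling",
  "Western Tasmanian Shelf Upwelling",
  "Sub-Antarctic surface waters",
  "East Australian Current"
)

#' Survey methods recognised by the pipeline
#' @export
pup_methods <- c("CMR", "direct_count", "aerial", "incidental")

#' Load a colony registry
#'
#' Reads a colony registry CSV (one row per breeding colony) and validates it:
#' unique ids, region drawn from [pup_regions], coordinates within range.
#'
#' @param path path to a `colonies.csv` file with columns `colony_id`, `name`,
#'   `state`, `region`, `latitude`, `longitude`, `area_ha`, `height_m`.
#' @return a `data.frame` with one row per colony and class `colony_registry`.
#' @seealso [afs_colony_registry()] for the bundled Australian fur seal
#'   registry.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) pc_stop("pc_io_error", paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("colony_id", "name", "region", "latitude", "longitude"),
                "colony registry")
  validate_registry(df)
}

validate_registry <- function(df) {
  dup <- unique(df$colony_id[duplicated(df$colony_id)])
  if (length(dup) > 0L) {
    pc_stop("pc_validation_error",
            paste("duplicate colony_id in registry:", paste(dup, collapse = ", ")))
  }
  bad_region <- setdiff(unique(df$region), pup_regions)
  if (length(bad_region) > 0L) {
    pc_stop("pc_validation_error",
            sprintf("unknown region(s): %s; allowed regions are: %s",
                    paste(bad_region, collapse = ", "),
                    paste(pup_regions, collapse = "; ")))
  }
  if (nrow(df) > 0L &&
      (any(abs(df$latitude) > 90, na.rm = TRUE) ||
       any(abs(df$longitude) > 180, na.rm = TRUE))) {
    pc_stop("pc_validation_error", "coordinates outside valid range")
  }
  class(df) <- c("colony_registry", "data.frame")
  df
}

#' Assign a breeding-season year to a survey date
#'
#' Pups are born in November--December; surveys run from December through
#' February. A survey is attributed to the year of pup birth, so surveys in
#' January or February belong to the previous calendar year's cohort. The
#' boundary is the calendar year change.
#'
#' @param date a `Date` (or string coercible to one).
#' @return integer season year (year of pup birth).
#' @examples
#' season_year_from_date(as.Date("2018-01-10")) # 2017
#' season_year_from_date(as.Date("2017-12-16")) # 2017
#' @export
season_year_from_date <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  ifelse(m <= 2L, y - 1L, y)
}

#' Load mark-resight and count surveys
#'
#' Reads the two survey CSV schemas from a directory (or explicit paths) and
#' returns a list of survey records. Each CMR survey groups the sub-area rows
#' for one colony and date; each count survey groups the observer rows.
#' Season years are assigned by [season_year_from_date()]. Multi-day surveys
#' are keyed by their first (recorded) date.
#'
#' @param dir directory containing `cmr_surveys.csv` and/or
#'   `count_surveys.csv` (either may be absent).
#' @param registry a registry from [load_registry()]; every `colony_id` in the
#'   survey files must appear in it.
#' @return a list of `survey_record` objects, each with fields `colony_id`,
#'   `season_year`, `date`, `method` and `payload` (a tally `data.frame` for
#'   CMR, replicate counts for direct/aerial, a single count for incidental).
#' @export
load_surveys <- function(dir, registry) {
  out <- list()
  cmr_path <- file.path(dir, "cmr_surveys.csv")
  cnt_path <- file.path(dir, "count_surveys.csv")
  if (file.exists(cmr_path)) {
    df <- utils::read.csv(cmr_path, stringsAsFactors = FALSE)
    check_columns(df, c("colony_id", "date", "subarea_id", "marked_available",
                        "total_resighted", "marked_resighted",
                        "dead_marked", "dead_clear"),
                  "cmr_surveys.csv")
    check_known_colonies(df$colony_id, registry)
    validate_cmr_rows(df)
    for (key in unique(paste(df$colony_id, df$date, sep = "\r"))) {
      part <- strsplit(key, "\r", fixed = TRUE)[[1]]
      rows <- df[df$colony_id == part[1] & df$date == part[2], , drop = FALSE]
      out[[length(out) + 1L]] <- new_survey_record(
        colony_id = part[1], date = as.Date(part[2]), method = "CMR",
        payload = rows[, c("subarea_id", "marked_available", "total_resighted",
                           "marked_resighted", "dead_marked", "dead_clear")])
    }
  }
  if (file.exists(cnt_path)) {
    df <- utils::read.csv(cnt_path, stringsAsFactors = FALSE)
    check_columns(df, c("colony_id", "date", "observer_id", "count", "method"),
                  "count_surveys.csv")
    check_known_colonies(df$colony_id, registry)
    if (any(df$count < 0)) {
      pc_stop("pc_validation_error", "negative counts in count_surveys.csv")
    }
    bad <- setdiff(unique(df$method), pup_methods)
    if (length(bad) > 0L) {
      pc_stop("pc_validation_error",
              paste("unknown survey method(s):", paste(bad, collapse = ", ")))
    }
    for (key in unique(paste(df$colony_id, df$date, df$method, sep = "\r"))) {
      part <- strsplit(key, "\r", fixed = TRUE)[[1]]
      rows <- df[df$colony_id == part[1] & df$date == part[2] &
                   df$method == part[3], , drop = FALSE]
      payload <- if (part[3] == "incidental") rows$count[1] else rows$count
      out[[length(out) + 1L]] <- new_survey_record(
        colony_id = part[1], date = as.Date(part[2]), method = part[3],
        payload = payload)
    }
  }
  out
}

check_known_colonies <- function(ids, registry) {
  unknown <- setdiff(unique(ids), registry$colony_id)
  if (length(unknown) > 0L) {
    pc_stop("pc_referential_error",
            paste("survey references unknown colony_id:",
                  paste(unknown, collapse = ", ")))
  }
}

validate_cmr_rows <- function(df) {
  num <- c("marked_available", "total_resighted", "marked_resighted",
           "dead_marked", "dead_clear")
  if (any(as.matrix(df[num]) < 0)) {
    pc_stop("pc_validation_error", "negative tallies in cmr_surveys.csv")
  }
  m_avail <- df$marked_available - df$dead_marked
  if (any(df$dead_marked > df$marked_available)) {
    pc_stop("pc_validation_error",
            "dead_marked exceeds marked_available in a sub-area")
  }
  bad <- df$marked_resighted > pmin(m_avail, df$total_resighted)
  if (any(bad)) {
    pc_stop("pc_validation_error",
            sprintf("marked_resighted exceeds min(marked available, total resighted) in sub-area(s): %s",
                    paste(df$subarea_id[bad], collapse = ", ")))
  }
  invisible(df)
}

new_survey_record <- function(colony_id, date, method, payload) {
  structure(
    list(colony_id = colony_id, date = date,
         season_year = season_year_from_date(date),
         method = method, payload = payload),
    class = "survey_record")
}

#' @export
print.survey_record <- function(x, ...) {
  cat(sprintf("<survey_record> %s %s season %d (%s)\n",
              x$colony_id, x$method, x$season_year, format(x$date)))
  invisible(x)
}

#' Write surveys back to the CSV schemas
#'
#' Inverse of [load_surveys()]: writes `cmr_surveys.csv` and
#' `count_surveys.csv` into `dir` so that a round trip reproduces the input
#' field-for-field (column order normalised).
#'
#' @param surveys list of `survey_record` objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_surveys <- function(surveys, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cmr <- Filter(function(s) s$method == "CMR", surveys)
  cnt <- Filter(function(s) s$method != "CMR", surveys)
  if (length(cmr) > 0L) {
    rows <- do.call(rbind, lapply(cmr, function(s) {
      cbind(data.frame(colony_id = s$colony_id, date = format(s$date),
                       stringsAsFactors = FALSE),
            s$payload)
    }))
    utils::write.csv(rows, file.path(dir, "cmr_surveys.csv"), row.names = FALSE)
  }
  if (length(cnt) > 0L) {
    rows <- do.call(rbind, lapply(cnt, function(s) {
      data.frame(colony_id = s$colony_id, date = format(s$date),
                 observer_id = seq_along(s$payload), count = s$payload,
                 method = s$method, stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, file.path(dir, "count_surveys.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Check marking fractions against the field protocol
#'
#' The marking protocol targets a marked fraction above 25% and below 50% of
#' pups present in each sub-area. The fraction is assessed against the
#' sub-area Chapman estimate M / N-hat. Deviations are advisory warnings, not
#' errors: surveys outside the band are still usable.
#'
#' @param survey a CMR `survey_record`.
#' @return (invisibly) a character vector of warning messages, one per
#'   offending sub-area; each is also raised as a condition of class
#'   `pc_protocol_warning`.
#' @export
validate_marking_fraction <- function(survey) {
  stopifnot(inherits(survey, "survey_record"))
  if (survey$method != "CMR") {
    pc_stop("pc_usage_error", "marking fraction applies to CMR surveys only")
  }
  p <- survey$payload
  M <- adjust_marked_for_deaths(p$marked_available, p$dead_marked)
  est <- chapman_estimate(M, p$total_resighted, p$marked_resighted,
                          warn_low_recapture = FALSE)
  frac <- ifelse(est$mean > 0, M / est$mean, NA_real_)
  msgs <- character(0)
  for (i in seq_along(frac)) {
    if (is.na(frac[i])) next
    if (frac[i] <= 0.25) {
      msgs <- c(msgs, sprintf(
        "sub-area %s: marked fraction %.2f below protocol band (0.25, 0.50)",
        p$subarea_id[i], frac[i]))
    } else if (frac[i] >= 0.50) {
      msgs <- c(msgs, sprintf(
        "sub-area %s: marked fraction %.2f above protocol band (0.25, 0.50)",
        p$subarea_id[i], frac[i]))
    }
  }
  for (m in msgs) pc_warn("pc_protocol_warning", m)
  invisible(msgs)
}
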