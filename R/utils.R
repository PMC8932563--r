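# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding used for table display: ties go away from zero
#' (0.5 -> 1, -0.5 -> -1), unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half-away-from-zero.
#' @examples
#' round_half_away(c(0.5, -5.55, 73.9))
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Classed error so callers/tests can discriminate failure modes.
pc_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pupcensus_error"),
                      call = call))
}

pc_warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "pupcensus_warning")))
}

# require named columns in a data.frame read from disk
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    pc_stop("pc_schema_error",
            sprintf("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
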