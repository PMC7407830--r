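#' Express mediator release as percent of the stimulated control
#'
#' Rescales a raw mediator concentration-response series so that the
#' stimulated-control mean equals 100%. Only the upper anchor is used; the
#' uninflamed baseline is not forced to 0%.
#'
#' @param series A raw-scale `cr_series` for a mediator endpoint (see
#'   [extract_series()]).
#' @return The series with `response` mapped to `100 * response / s_mean`
#'   and `scale = "percent_of_stimulated"`; anchors kept on the raw scale.
#' @export
percent_of_stimulated <- function(series) {
  stopifnot(inherits(series, "cr_series"))
  if (series$scale != "raw") {
    stop("series is already on scale ", series$scale, call. = FALSE)
  }
  if (series$endpoint == "TEER") {
    stop("percent_of_stimulated applies to mediator endpoints; use ",
         "normalize_teer for TEER", call. = FALSE)
  }
  if (!is.finite(series$s_mean) || series$s_mean <= 0) {
    stop("degenerate control: stimulated mean must be positive",
         call. = FALSE)
  }
  series$response <- 100 * series$response / series$s_mean
  series$scale <- "percent_of_stimulated"
  series
}

#' Paired TEER difference
#'
#' The barrier statistic is the change in transepithelial resistance over
#' the 48-h treatment window. The difference is stored as
#' `value_after - value_before`, so barrier decline is negative; the
#' normalisation anchors absorb the sign convention, and reports quote the
#' magnitude of decline.
#'
#' @param value_before,value_after Resistances (Ohm), both positive.
#' @return `value_after - value_before` (Ohm).
#' @export
teer_difference <- function(value_before, value_after) {
  if (any(!is.finite(value_before) | value_before <= 0) ||
      any(!is.finite(value_after) | value_after <= 0)) {
    stop("validation error: TEER readings must be positive", call. = FALSE)
  }
  value_after - value_before
}

#' Normalize TEER differences between the control anchors
#'
#' Maps TEER differences onto a percent scale anchored at the stimulated
#' control (0%, fully declined barrier) and the unstimulated control
#' (100%, intact barrier).
#'
#' @param diff TEER difference(s) (Ohm), any sign.
#' @param s_diff_mean Mean difference of the stimulated control wells.
#' @param us_diff_mean Mean difference of the unstimulated control wells.
#' @return `100 * (diff - s_diff_mean) / (us_diff_mean - s_diff_mean)`.
#' @export
normalize_teer <- function(diff, s_diff_mean, us_diff_mean) {
  if (!is.finite(s_diff_mean) || !is.finite(us_diff_mean) ||
      s_diff_mean == us_diff_mean) {
    stop("degenerate control: stimulated and unstimulated TEER anchors ",
         "must differ", call. = FALSE)
  }
  100 * (diff - s_diff_mean) / (us_diff_mean - s_diff_mean)
}

#' Fold induction of a mediator under LPS stimulation
#'
#' @param level_stimulated Mean stimulated-control level (pg/mL).
#' @param level_reference Mean reference level (inactivated `ua` for
#'   macrophage mediators, unstimulated `us` for epithelial mediators).
#' @return Dimensionless ratio of means.
#' @export
fold_induction <- function(level_stimulated, level_reference) {
  if (!is.finite(level_reference) || level_reference <= 0) {
    stop("degenerate control: reference level must be positive",
         call. = FALSE)
  }
  level_stimulated / level_reference
}

#' Put a series on its analysis scale
#'
#' Mediator series go to percent-of-stimulated; TEER series to the
#' normalized 0-100% difference scale, with anchors replaced by their
#' normalized values (0 and 100).
#'
#' @param series A raw `cr_series`.
#' @return The normalized series.
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "cr_series"))
  if (series$endpoint == "TEER") {
    series$response <- normalize_teer(series$response, series$s_mean,
                                      series$ref_mean)
    series$scale <- "normalized_teer"
    series
  } else {
    percent_of_stimulated(series)
  }
}
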