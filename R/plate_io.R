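#' Read a long-format assay table
#'
#' Reads and validates the plate-level long table: one row per
#' well-measurement, annotated with endpoint, compartment, treatment,
#' control class, concentration (ug/mL), time point (h) and replicate.
#' Mediator rows carry the measured concentration in `value` (pg/mL);
#' TEER rows carry the paired resistance readings in `value_before` and
#' `value_after` (Ohm) and leave `value` empty.
#'
#' @param path Path to a UTF-8 CSV file with "." as decimal separator.
#' @param format Input dialect; only `"long_csv"` is supported.
#' @return An object of class `assay_dataset`: a list with elements
#'   `measurements` (the validated data frame) and `metadata` (named list;
#'   units, generator seed if synthetic).
#' @seealso [write_assay_csv()], [extract_series()], [generate_assay()]
#' @export
read_assay_csv <- function(path, format = "long_csv") {
  format <- match.arg(format, "long_csv")
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop("empty input: no measurement rows in ", path, call. = FALSE)
  }
  as_assay_dataset(df, metadata = list(source = path))
}

#' Construct a validated assay dataset from a data frame
#'
#' @param measurements Data frame in the long layout (see [read_assay_csv()]
#'   for the column contract).
#' @param metadata Named list of free-form annotations.
#' @return An `assay_dataset` object.
#' @export
as_assay_dataset <- function(measurements, metadata = list()) {
  df <- as.data.frame(measurements)
  missing_cols <- setdiff(assay_columns(), names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reg <- endpoint_registry()
  bad_ep <- setdiff(unique(df$endpoint), reg$endpoint)
  if (length(bad_ep)) {
    stop("unknown endpoint label(s): ", paste(bad_ep, collapse = ", "),
         call. = FALSE)
  }
  bad_cc <- setdiff(unique(df$control_class), control_classes())
  if (length(bad_cc)) {
    stop("unknown control_class label(s): ", paste(bad_cc, collapse = ", "),
         call. = FALSE)
  }
  # compartment must agree with the endpoint registry
  expected <- reg$compartment[match(df$endpoint, reg$endpoint)]
  mism <- which(df$compartment != expected)
  if (length(mism)) {
    stop("validation error: compartment does not match endpoint at row(s) ",
         paste(utils::head(mism, 5L), collapse = ", "), call. = FALSE)
  }
  is_teer <- df$endpoint == "TEER"
  bad_med <- which(!is_teer & (!is.finite(df$value) | df$value < 0))
  if (length(bad_med)) {
    stop("validation error: negative or missing mediator value at row(s) ",
         paste(utils::head(bad_med, 5L), collapse = ", "), call. = FALSE)
  }
  bad_teer <- which(is_teer & (!is.finite(df$value_before) |
                                 !is.finite(df$value_after) |
                                 df$value_before <= 0 | df$value_after <= 0))
  if (length(bad_teer)) {
    stop("validation error: non-positive TEER reading at row(s) ",
         paste(utils::head(bad_teer, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(df$concentration_ug_ml < 0)) {
    stop("validation error: negative concentration", call. = FALSE)
  }
  structure(list(measurements = df, metadata = metadata),
            class = "assay_dataset")
}

#' @export
print.assay_dataset <- function(x, ...) {
  df <- x$measurements
  cat("Assay dataset:", nrow(df), "well-measurements\n")
  cat("  endpoints: ", paste(unique(df$endpoint), collapse = ", "), "\n")
  cat("  treatments:",
      paste(unique(df$treatment[df$control_class == "treated"]),
            collapse = ", "), "\n")
  cat("  time points (h):",
      paste(sort(unique(df$time_h)), collapse = ", "), "\n")
  if (!is.null(x$metadata$seed)) {
    cat("  synthetic (seed ", x$metadata$seed, ")\n", sep = "")
  }
  invisible(x)
}

#' Write an assay dataset back to long CSV
#'
#' Numeric fields are written with 15 significant digits so that a
#' write/read round trip preserves values to at least 12 significant digits.
#'
#' @param ds An `assay_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(ds, path) {
  stopifnot(inherits(ds, "assay_dataset"))
  df <- ds$measurements
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Extract one concentration-response series
#'
#' Pulls the well-level (concentration, response) pairs for one endpoint x
#' treatment x time cell together with its control anchors: the stimulated
#' control mean and the matched reference control mean (inactivated `ua` for
#' macrophage endpoints, unstimulated `us` for epithelial endpoints and
#' TEER) at the same time point. For TEER the response is the paired
#' difference `value_after - value_before` (Ohm); barrier decline is
#' negative under this convention and the downstream normalisation anchors
#' absorb the sign.
#'
#' @param ds An `assay_dataset`.
#' @param endpoint Endpoint identifier or reporting label (see
#'   [endpoint_registry()]).
#' @param treatment_label Treatment to extract, e.g. `"myrrh"`.
#' @param time_h Time point in hours.
#' @return An object of class `cr_series`: list with `endpoint`, `label`,
#'   `direction`, `treatment_label`, `time_h`, `concentration` (sorted
#'   ascending), `response` (raw scale), `s_mean`, `ref_mean`,
#'   `ref_class`, and `scale = "raw"`.
#' @export
extract_series <- function(ds, endpoint, treatment_label, time_h = 48) {
  stopifnot(inherits(ds, "assay_dataset"))
  info <- endpoint_info(endpoint)
  df <- ds$measurements
  rows <- df$endpoint == info$endpoint & df$time_h == time_h
  if (!any(rows)) {
    stop("lookup error: no rows for endpoint ", info$endpoint,
         " at ", time_h, " h", call. = FALSE)
  }
  sub <- df[rows, , drop = FALSE]
  resp <- function(d) {
    if (info$endpoint == "TEER") d$value_after - d$value_before else d$value
  }
  tr <- sub[sub$control_class == "treated" &
              sub$treatment == treatment_label, , drop = FALSE]
  if (nrow(tr) == 0L) {
    stop("lookup error: no treated rows for ", treatment_label, " x ",
         info$endpoint, " at ", time_h, " h", call. = FALSE)
  }
  s_rows <- sub[sub$control_class == "s", , drop = FALSE]
  ref_rows <- sub[sub$control_class == info$reference, , drop = FALSE]
  if (nrow(s_rows) == 0L || nrow(ref_rows) == 0L) {
    stop("lookup error: missing control anchors (s and ", info$reference,
         ") for ", info$endpoint, call. = FALSE)
  }
  ord <- order(tr$concentration_ug_ml)
  structure(list(
    endpoint = info$endpoint,
    label = info$label,
    direction = info$direction,
    treatment_label = treatment_label,
    time_h = time_h,
    concentration = tr$concentration_ug_ml[ord],
    response = resp(tr)[ord],
    s_mean = mean(resp(s_rows)),
    ref_mean = mean(resp(ref_rows)),
    ref_class = info$reference,
    scale = "raw"
  ), class = "cr_series")
}

#' @export
print.cr_series <- function(x, ...) {
  cat("Concentration-response series ", x$label, " / ", x$treatment_label,
      " (", x$time_h, " h, ", x$scale, " scale)\n", sep = "")
  cat("  ", length(x$concentration), " wells, ",
      length(unique(x$concentration)), " concentrations spanning ",
      format(min(x$concentration)), "-", format(max(x$concentration)),
      " ug/mL\n", sep = "")
  cat("  anchors: s = ", format(x$s_mean, digits = 4), ", ", x$ref_class,
      " = ", format(x$ref_mean, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write a Table-1 style results CSV
#'
#' One row per endpoint; per-treatment columns hold the half-maximal
#' concentration rounded to an integer with the 95% confidence bounds to one
#' decimal, a `"-"` marking treatments with no significant effect (term
#' extracted from the combination index), and the final column holds the
#' combination index to two decimals with its category symbol.
#'
#' @param results An `assay_analysis` object from [run_assay_analysis()], or
#'   a list of per-endpoint lists each holding `fits` (named list of
#'   `pl4_fit` or `NULL`), `active` (named logical) and `ci` (a
#'   `comb_index` or `NULL`).
#' @param path Output CSV path.
#' @return The results table (data frame), invisibly; written to `path`.
#' @export
write_results_table <- function(results, path) {
  if (inherits(results, "assay_analysis")) results <- results$endpoints
  if (length(results) == 0L) {
    stop("empty results: nothing to write", call. = FALSE)
  }
  fmt_fit <- function(fit, active) {
    if (is.null(fit) || !isTRUE(active) || !isTRUE(fit$converged)) return("-")
    sprintf("%d (%.1f-%.1f)", round(fit$half_max),
            fit$ci95[1], fit$ci95[2])
  }
  rows <- lapply(results, function(r) {
    trt <- names(r$fits)
    cells <- vapply(trt, function(tl) fmt_fit(r$fits[[tl]], r$active[[tl]]),
                    character(1))
    ci_cell <- if (is.null(r$ci)) "-" else
      sprintf("%.2f (%s)", r$ci$ci_value, r$ci$symbol)
    c(endpoint = r$label, cells, combination_index = ci_cell)
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
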