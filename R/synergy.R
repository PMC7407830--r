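#' Ternary Chou-style combination index with equal-parts dosing
#'
#' For a combination of equal parts of three extracts, the combination index
#' is `CI = IC50_comb/IC50_A + IC50_comb/IC50_B + IC50_comb/IC50_C`, where
#' `IC50_A..C` are the half-maximal concentrations of the individual
#' extracts and `IC50_comb` is one third of the IC50 estimated for the
#' combination (each component contributes one third of the total mixture
#' concentration). A component with no significant effect on the endpoint is
#' passed as `NA` and its term is extracted from the sum. CI < 0.9 indicates
#' synergism, 0.9-1.10 nearly additive interaction, > 1.10 antagonism; see
#' [categorize_ci()] for the full band scheme. The same formula applies to
#' TEER with EC50 in place of IC50.
#'
#' @param ic50_a,ic50_b,ic50_c Half-maximal concentrations (ug/mL) of the
#'   individual components, or `NA` for an inactive component.
#' @param ic50_combination_total IC50/EC50 of the combination, expressed as
#'   the total mixture concentration (ug/mL).
#' @param labels Component names (length 3), used in the term names.
#' @param endpoint Optional endpoint tag.
#' @return An object of class `comb_index`: `ci_value`, `ic50_comb`
#'   (one third of the total), `terms` (named ratios for included
#'   components), `included` (component names), `category`, `symbol`,
#'   `out_of_scale` flag, `endpoint`.
#' @examples
#' combination_index(14, 152, NA, 5)    # two active components, CI 0.13
#' combination_index(2, 2, 2, 2)        # equal potency: exactly additive
#' @export
combination_index <- function(ic50_a, ic50_b, ic50_c,
                              ic50_combination_total,
                              labels = c("A", "B", "C"),
                              endpoint = NA_character_) {
  ic <- c(ic50_a, ic50_b, ic50_c)
  names(ic) <- labels
  if (!is.finite(ic50_combination_total) || ic50_combination_total <= 0) {
    stop("validation error: combination IC50 must be positive",
         call. = FALSE)
  }
  present <- !is.na(ic)
  if (!any(present)) {
    stop("no active component: all three individual IC50s are absent",
         call. = FALSE)
  }
  if (any(ic[present] <= 0)) {
    stop("validation error: individual IC50s must be positive",
         call. = FALSE)
  }
  ic50_comb <- ic50_combination_total / 3
  terms <- ic50_comb / ic[present]
  ci_value <- sum(terms)
  cat_res <- categorize_ci(ci_value)
  structure(list(endpoint = endpoint, ci_value = ci_value,
                 ic50_comb = ic50_comb,
                 ic50_combination_total = ic50_combination_total,
                 ic50_components = ic, terms = terms,
                 included = names(terms),
                 category = cat_res$category, symbol = cat_res$symbol,
                 out_of_scale = cat_res$out_of_scale),
            class = "comb_index")
}

#' Categorise a combination index on the Chou scale
#'
#' Band scheme: strong synergism `[0.1, 0.3)` (++++), synergism `[0.3, 0.7)`
#' (+++), moderate synergism `[0.7, 0.85)` (++), slight synergism
#' `[0.85, 0.9)` (+), nearly additive `[0.9, 1.10]` (0), slight antagonism
#' `(1.10, 1.20]` (-), moderate antagonism `(1.20, 1.45]` (--), antagonism
#' `(1.45, 3.3]` (---), strong antagonism `(3.3, 10]` (----). Bands are
#' half-open with a fixed edge convention (synergism bands closed at the
#' lower edge, antagonism bands closed at the upper edge) so that every
#' value maps to exactly one category. Values below 0.1 or above 10 fall
#' outside the quoted scale and are reported as the nearest extreme category
#' with `out_of_scale = TRUE`.
#'
#' @param ci_value Positive combination index.
#' @return List with `category`, `symbol`, `out_of_scale`.
#' @examples
#' categorize_ci(0.13)  # strong synergism "++++"
#' categorize_ci(1.00)  # nearly additive "0"
#' categorize_ci(1.11)  # slight antagonism "-"
#' @export
categorize_ci <- function(ci_value) {
  if (!is.finite(ci_value) || ci_value <= 0) {
    stop("validation error: combination index must be positive",
         call. = FALSE)
  }
  category <- c("strong_synergism", "synergism", "moderate_synergism",
                "slight_synergism", "nearly_additive", "slight_antagonism",
                "moderate_antagonism", "antagonism", "strong_antagonism")
  symbol <- c("++++", "+++", "++", "+", "0", "-", "--", "---", "----")
  if (ci_value < 0.1) {
    return(list(category = "strong_synergism", symbol = "++++",
                out_of_scale = TRUE))
  }
  if (ci_value > 10) {
    return(list(category = "strong_antagonism", symbol = "----",
                out_of_scale = TRUE))
  }
  i <- if (ci_value <= 1.10) {
    # synergism bands closed at the lower edge; additive closed at 1.10
    findInterval(ci_value, c(0.1, 0.3, 0.7, 0.85, 0.9))
  } else {
    # antagonism bands closed at the upper edge
    5L + which(ci_value <= c(1.20, 1.45, 3.3, 10))[1]
  }
  list(category = category[i], symbol = symbol[i], out_of_scale = FALSE)
}

#' @export
print.comb_index <- function(x, ...) {
  cat("Combination index",
      if (!is.na(x$endpoint)) paste0(" (", x$endpoint, ")"), ": ",
      sprintf("%.2f", x$ci_value), " (", x$symbol, ") ",
      gsub("_", " ", x$category),
      if (isTRUE(x$out_of_scale)) " [outside the quoted scale]", "\n",
      sep = "")
  cat("  IC50_comb = ", format(x$ic50_comb, digits = 4),
      " ug/mL (one third of combination total ",
      format(x$ic50_combination_total, digits = 4), ")\n", sep = "")
  cat("  included components:", paste(x$included, collapse = ", "), "\n")
  cat("  terms:", paste(sprintf("%s = %.4f", names(x$terms), x$terms),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Parametric-bootstrap interval for a combination index
#'
#' Propagates the asymptotic uncertainty of the individual and combination
#' half-max fits into the combination index: log10 IC50s are resampled from
#' normal distributions centred at each fit's estimate with its asymptotic
#' standard error, the index is recomputed for each draw, and a percentile
#' interval is returned. This uncertainty propagation is an extension beyond
#' the point index the source analysis reports, and is flagged as such in
#' the run report.
#'
#' @param fit_a,fit_b,fit_c `pl4_fit` objects for the components, or `NULL`
#'   for an inactive (extracted) component.
#' @param fit_comb `pl4_fit` for the combination.
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @param level Interval level.
#' @return List with `point` (the plug-in `comb_index`), `lower`, `upper`,
#'   `n_boot`, `level`.
#' @export
combination_interval <- function(fit_a, fit_b, fit_c, fit_comb,
                                 n_boot = 1000, seed = 1L, level = 0.95) {
  fits <- list(fit_a, fit_b, fit_c)
  for (f in c(fits[!vapply(fits, is.null, logical(1))], list(fit_comb))) {
    if (!isTRUE(f$converged) || !is.finite(f$se_log10)) {
      stop("propagation unavailable: a required fit is unconverged or has ",
           "no finite standard error", call. = FALSE)
    }
  }
  point <- combination_index(
    if (is.null(fit_a)) NA_real_ else fit_a$half_max,
    if (is.null(fit_b)) NA_real_ else fit_b$half_max,
    if (is.null(fit_c)) NA_real_ else fit_c$half_max,
    fit_comb$half_max
  )
  set.seed(seed)
  draw <- function(f) {
    if (is.null(f)) return(rep(NA_real_, n_boot))
    10^stats::rnorm(n_boot, f$log10_half_max, f$se_log10)
  }
  a <- draw(fit_a); b <- draw(fit_b); c3 <- draw(fit_c)
  comb <- draw(fit_comb) / 3
  ci_draws <- rowSums(cbind(comb / a, comb / b, comb / c3), na.rm = TRUE)
  q <- stats::quantile(ci_draws, c((1 - level) / 2, (1 + level) / 2),
                       names = FALSE)
  list(point = point, lower = q[1], upper = q[2], n_boot = n_boot,
       level = level)
}
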