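#' Four-parameter logistic concentration-response value
#'
#' Evaluates `bottom + (top - bottom) / (1 + 10^(hill * (log10(x) - e)))`
#' for a falling (inhibition) curve, or the rising mirror
#' `bottom + (top - bottom) / (1 + 10^(hill * (e - log10(x))))` for an
#' enhancement curve. `e` is the log10 of the half-maximal concentration:
#' the response at `x = 10^e` is exactly the midpoint of `top` and `bottom`.
#'
#' @param x Concentrations (> 0).
#' @param top,bottom Plateaus on the response scale.
#' @param e log10 half-maximal concentration.
#' @param hill Hill slope (> 0).
#' @param rising Logical; `TRUE` for enhancement orientation.
#' @return Response values.
#' @export
pl4 <- function(x, top, bottom, e, hill, rising = FALSE) {
  lx <- log10(x)
  z <- if (rising) hill * (e - lx) else hill * (lx - e)
  bottom + (top - bottom) / (1 + 10^z)
}

#' Fit a constrained four-parameter logistic curve
#'
#' Least-squares 4PL fit on log10 concentration, the common model for
#' plate-based concentration-response data. For inhibition series (mediator
#' release, percent-of-stimulated scale) the upper plateau is fixed at the
#' stimulated-control anchor (100%), the lower plateau is constrained to
#' `[0, 100]` and the hill slope to `(0, 10]`; the half-maximal
#' concentration is the curve's own midpoint between the constrained top and
#' the fitted bottom (relative IC50). For enhancement series both plateaus
#' are the scale's defined anchors — 0% (stimulated, fully declined barrier)
#' and 100% (unstimulated, intact barrier) — and are fixed, so the EC50 is
#' the concentration at half-maximal normalized recovery; fixing the upper
#' plateau mirrors the stimulated-control upper constraint of the
#' inhibition fits and keeps the EC50 identified when the sampled grid does
#' not reach the recovery plateau.
#'
#' Well-level residuals (not per-concentration means) enter the loss, and
#' the residual degrees of freedom follow. The optimisation is
#' Levenberg-Marquardt with box bounds, restarted from 5 candidate midpoints
#' log-spaced over the data range (hill start 1), keeping the best sum of
#' squares; convergence tolerance 1e-13 on the relative reduction of the sum
#' of squares, at most 1024 iterations. The 95% confidence interval is the
#' symmetric asymptotic interval on log10 half-max (t quantile at the
#' residual degrees of freedom) back-transformed to ug/mL — appropriate
#' because IC50 uncertainty is strongly right-skewed on the raw scale.
#'
#' Two guards separate real curves from noise. A series whose responses all
#' lie within one standard deviation of the fixed plateau (100% for
#' inhibition, 0% for enhancement), or whose 4PL fit is not significantly
#' better than the constant-at-plateau "no effect" model by the
#' extra-sum-of-squares F test (p >= 0.05), receives the flat-curve verdict:
#' no half-max is estimated and the treatment is considered inactive for the
#' endpoint. A converged fit whose half-max falls more than a factor of 10
#' outside the tested concentration range is flagged `"out_of_range"`: the
#' estimate is reported but the activity layer treats the cell as not
#' quantifiable, mirroring the reporting convention of printing "-" for
#' such cells.
#'
#' @param series A normalized `cr_series` (see [normalize_series()]).
#' @param level Confidence level for the half-max interval.
#' @return An object of class `pl4_fit` with components `top`, `bottom`,
#'   `hill`, `log10_half_max`, `half_max` (ug/mL), `se_log10`, `df`,
#'   `ci95`, `residual_sd`, `n_points`, `converged`, and `verdict`
#'   (`"ok"`, `"flat"`, `"nonconverged"`, `"out_of_range"`, or
#'   `"unbounded_ci"`).
#'   Methods: [print()], [summary()], [coef()], [predict()], [confint()],
#'   [residuals()], [plot()].
#' @examples
#' sim <- generate_assay(generator_config(noise_cv = 0, seed = 1))
#' ser <- normalize_series(extract_series(sim$dataset, "IL6", "myrrh", 48))
#' fit <- fit_4pl(ser)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
fit_4pl <- function(series, level = 0.95) {
  stopifnot(inherits(series, "cr_series"))
  if (series$scale == "raw") {
    stop("series must be normalized first (see normalize_series)",
         call. = FALSE)
  }
  x <- series$concentration
  r <- series$response
  if (!all(is.finite(r))) stop("non-finite responses", call. = FALSE)
  if (length(unique(x)) < 4) {
    stop("insufficient data: need at least 4 distinct concentrations",
         call. = FALSE)
  }
  rising <- series$direction == "enhancement"
  anchor <- if (rising) 0 else 100
  out <- list(endpoint = series$endpoint, label = series$label,
              treatment_label = series$treatment_label,
              direction = series$direction, scale = series$scale,
              level = level, n_points = length(r),
              concentration = x, response = r)

  # flat-curve verdict: no concentration dependence away from the plateau
  s0 <- stats::sd(r)
  if (max(abs(r - anchor)) <= s0 || (s0 == 0 && all(r == anchor))) {
    out <- c(out, list(top = 100,
                       bottom = if (rising) 0 else NA_real_,
                       hill = NA_real_, log10_half_max = NA_real_,
                       half_max = NA_real_, se_log10 = NA_real_,
                       df = NA_integer_, ci95 = c(NA_real_, NA_real_),
                       residual_sd = s0, converged = FALSE,
                       verdict = "flat"))
    class(out) <- "pl4_fit"
    return(out)
  }

  lx <- log10(x)
  dat <- data.frame(lx = lx, r = r)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1024, ftol = 1e-13,
                                     ptol = 1e-13)
  e_lo <- min(lx) - 3
  e_hi <- max(lx) + 3
  best <- NULL
  for (e0 in seq(min(lx), max(lx), length.out = 5)) {
    st <- if (rising) {
      list(e = e0, hill = 1)
    } else {
      list(bottom = min(max(min(r), 0), 100), e = e0, hill = 1)
    }
    f <- tryCatch(suppressWarnings(
      if (rising) {
        minpack.lm::nlsLM(r ~ 100 / (1 + 10^(hill * (e - lx))), data = dat,
                          start = st,
                          lower = c(e = e_lo, hill = 1e-3),
                          upper = c(e = e_hi, hill = 10),
                          control = ctrl)
      } else {
        minpack.lm::nlsLM(
          r ~ bottom + (100 - bottom) / (1 + 10^(hill * (lx - e))),
          data = dat, start = st,
          lower = c(bottom = 0, e = e_lo, hill = 1e-3),
          upper = c(bottom = 100, e = e_hi, hill = 10), control = ctrl)
      }), error = function(err) NULL)
    if (!is.null(f) &&
        (is.null(best) || stats::deviance(f) < stats::deviance(best))) {
      best <- f
    }
  }
  if (is.null(best)) {
    # nothing fit: flat when the data are consistent with the plateau
    # (one-sample t of the mean response against the anchor), otherwise
    # genuinely nonconverged
    n <- length(r)
    tstat <- (mean(r) - anchor) / (s0 / sqrt(n))
    p_anchor <- 2 * stats::pt(-abs(tstat), n - 1)
    out <- c(out, list(top = 100,
                       bottom = if (rising) 0 else NA_real_,
                       hill = NA_real_, log10_half_max = NA_real_,
                       half_max = NA_real_, se_log10 = NA_real_,
                       df = NA_integer_, ci95 = c(NA_real_, NA_real_),
                       residual_sd = s0, converged = FALSE,
                       verdict = if (is.finite(p_anchor) &&
                                       p_anchor >= 0.05) "flat"
                                 else "nonconverged"))
    class(out) <- "pl4_fit"
    return(out)
  }
  co <- stats::coef(best)
  n <- length(r)
  p_free <- if (rising) 2L else 3L
  dfres <- n - p_free
  rss <- stats::deviance(best)
  residual_sd <- sqrt(rss / dfres)
  e_hat <- co[["e"]]
  half_max <- 10^e_hat

  # extra-sum-of-squares F test against the constant-at-plateau model:
  # when the 4PL does not fit significantly better than "no effect", the
  # series is flat and no half-max is quantifiable
  rss0 <- sum((r - anchor)^2)
  f_flat <- ((rss0 - rss) / p_free) / (rss / dfres)
  p_flat <- if (rss == 0) 0 else
    stats::pf(f_flat, p_free, dfres, lower.tail = FALSE)
  if (!is.finite(p_flat) || p_flat >= 0.05) {
    out <- c(out, list(top = 100, bottom = if (rising) 0 else NA_real_,
                       hill = NA_real_, log10_half_max = NA_real_,
                       half_max = NA_real_, se_log10 = NA_real_,
                       df = dfres, ci95 = c(NA_real_, NA_real_),
                       residual_sd = residual_sd, converged = FALSE,
                       verdict = "flat"))
    class(out) <- "pl4_fit"
    return(out)
  }
  # asymptotic se on the log10 half-max; singular covariance is reported
  se_e <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(best))[["e"]])),
                   error = function(err) NA_real_)
  scale_r <- max(abs(r - anchor), 1)
  verdict <- "ok"
  if (residual_sd < 1e-7 * scale_r) {
    # zero-residual limit: the interval collapses onto the point estimate
    ci <- c(half_max, half_max)
    se_e <- 0
  } else if (!is.finite(se_e)) {
    verdict <- "unbounded_ci"
    ci <- c(0, Inf)
  } else {
    tq <- stats::qt((1 + level) / 2, dfres)
    ci <- 10^(e_hat + c(-1, 1) * tq * se_e)
  }
  conv <- isTRUE(best$convInfo$isConv)
  # a half-max far outside the tested grid is not quantifiable from these
  # data; flag it so the activity layer treats the cell as unreported
  if (verdict == "ok" &&
      (half_max > 10 * max(x) || half_max < min(x) / 10)) {
    verdict <- "out_of_range"
  }
  out <- c(out, list(top = 100,
                     bottom = if (rising) 0 else co[["bottom"]],
                     hill = co[["hill"]], log10_half_max = e_hat,
                     half_max = half_max, se_log10 = se_e, df = dfres,
                     ci95 = ci, residual_sd = residual_sd,
                     converged = conv, verdict = verdict, fit = best))
  class(out) <- "pl4_fit"
  out
}

#' Fit an inhibition curve (IC50) on the percent-of-stimulated scale
#'
#' @param series A `cr_series`; raw mediator series are normalized to
#'   percent-of-stimulated automatically.
#' @param level Confidence level.
#' @return A `pl4_fit`; `half_max` is the IC50 in ug/mL.
#' @export
fit_inhibition <- function(series, level = 0.95) {
  stopifnot(inherits(series, "cr_series"))
  if (series$direction != "inhibition") {
    stop("fit_inhibition expects a mediator (inhibition) endpoint",
         call. = FALSE)
  }
  if (series$scale == "raw") series <- percent_of_stimulated(series)
  fit_4pl(series, level = level)
}

#' Fit an enhancement curve (EC50) on the normalized TEER scale
#'
#' @param series A TEER `cr_series`; raw series are normalized to the
#'   0-100% difference scale automatically.
#' @param level Confidence level.
#' @return A `pl4_fit`; `half_max` is the EC50 in ug/mL.
#' @export
fit_enhancement <- function(series, level = 0.95) {
  stopifnot(inherits(series, "cr_series"))
  if (series$direction != "enhancement") {
    stop("fit_enhancement expects the TEER (enhancement) endpoint",
         call. = FALSE)
  }
  if (series$scale == "raw") series <- normalize_series(series)
  fit_4pl(series, level = level)
}

#' @export
print.pl4_fit <- function(x, digits = 4, ...) {
  what <- if (x$direction == "enhancement") "EC50" else "IC50"
  cat("4PL ", x$direction, " fit: ", x$label, " / ", x$treatment_label,
      "\n", sep = "")
  if (x$verdict == "flat") {
    cat("  flat curve: no concentration dependence; no ", what,
        " (treatment inactive)\n", sep = "")
    return(invisible(x))
  }
  if (x$verdict == "nonconverged") {
    cat("  fit did not converge; no ", what, "\n", sep = "")
    return(invisible(x))
  }
  cat("  ", what, " = ", format(x$half_max, digits = digits),
      " ug/mL (95% CI ", format(x$ci95[1], digits = digits), "-",
      format(x$ci95[2], digits = digits), ")\n", sep = "")
  cat("  hill = ", format(x$hill, digits = digits),
      ", top = ", format(x$top, digits = digits), " (fixed)",
      ", bottom = ", format(x$bottom, digits = digits),
      if (x$direction == "enhancement") " (fixed)" else "", "\n", sep = "")
  cat("  n = ", x$n_points, " wells, residual sd = ",
      format(x$residual_sd, digits = 3), "%\n", sep = "")
  if (x$verdict == "out_of_range") {
    cat("  note: ", what, " lies far outside the tested range; ",
        "not quantifiable from these data\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.pl4_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom,
    log10_half_max = object$log10_half_max, hill = object$hill)
}

#' @export
summary.pl4_fit <- function(object, ...) {
  print(object)
  if (object$verdict %in% c("ok", "unbounded_ci")) {
    cat("  log10 half-max = ", format(object$log10_half_max, digits = 6),
        " (se ", format(object$se_log10, digits = 3), ", df ", object$df,
        ")\n  converged: ", object$converged, ", verdict: ", object$verdict,
        "\n", sep = "")
  }
  invisible(object)
}

#' @export
predict.pl4_fit <- function(object, newdata = NULL, ...) {
  if (object$verdict %in% c("flat", "nonconverged")) {
    stop("no fitted curve available (verdict ", object$verdict, ")",
         call. = FALSE)
  }
  x <- if (is.null(newdata)) object$concentration
  else if (is.list(newdata)) newdata$concentration else newdata
  pl4(x, object$top, object$bottom, object$log10_half_max, object$hill,
      rising = object$direction == "enhancement")
}

#' @export
residuals.pl4_fit <- function(object, ...) {
  object$response - predict(object, object$concentration)
}

#' Confidence interval for the half-maximal concentration
#'
#' Symmetric asymptotic interval on the log10 half-max (estimated standard
#' error and t quantile at the residual degrees of freedom), back-transformed
#' to ug/mL.
#'
#' @param object A converged `pl4_fit`.
#' @param parm Ignored; the interval is on the half-max.
#' @param level Confidence level.
#' @param ... Ignored.
#' @return Numeric `c(lower, upper)` in ug/mL; degenerate (equal bounds) in
#'   the zero-residual limit; `c(0, Inf)` when the parameter covariance is
#'   singular (unbounded-CI verdict).
#' @export
confint.pl4_fit <- function(object, parm = "half_max", level = 0.95, ...) {
  if (!isTRUE(object$converged)) {
    stop("fit did not converge: no confidence interval", call. = FALSE)
  }
  if (object$verdict == "unbounded_ci") return(c(0, Inf))
  if (object$se_log10 == 0) return(c(object$half_max, object$half_max))
  tq <- stats::qt((1 + level) / 2, object$df)
  10^(object$log10_half_max + c(-1, 1) * tq * object$se_log10)
}

#' @export
plot.pl4_fit <- function(x, n_curve = 100, ...) {
  graphics::plot(x$concentration, x$response, log = "x",
                 xlab = "concentration (ug/mL)",
                 ylab = paste0("response (", x$scale, ")"),
                 main = paste(x$label, "/", x$treatment_label), ...)
  if (x$verdict %in% c("ok", "unbounded_ci")) {
    xx <- 10^seq(log10(min(x$concentration)), log10(max(x$concentration)),
                 length.out = n_curve)
    graphics::lines(xx, predict(x, xx))
    graphics::abline(v = x$half_max, lty = 2)
  }
  invisible(x)
}
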