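#' Printed half-maximal concentrations of the study's summary table
#'
#' Point estimates (ug/mL) of the half-maximal inhibitory concentration
#' (mediator endpoints) or effective concentration (TEER) for the three
#' individual extracts and the equal-parts combination, as printed in the
#' study's summary table. `NA` marks a treatment with no significant effect
#' on that endpoint (reported as "-"), whose term is extracted from the
#' combination-index sum. These values drive both the Table-replication mode
#' ([replicate_table1()]) and the default ground truth of the synthetic
#' generator.
#'
#' @return Data frame with columns `endpoint`, `label`, `myrrh`,
#'   `coffee charcoal`, `chamomile flower`, `combination`, `printed_ci`,
#'   `printed_symbol`.
#' @export
table1_reference <- function() {
  df <- data.frame(
    endpoint = c("IL6", "TNF", "PGE2_M", "IL8", "MCP1", "PGE2_IEC", "TEER"),
    label = c("M-IL-6", "M-TNF", "M-PGE2", "IEC-IL-8", "IEC-MCP-1",
              "IEC-PGE2", "TEER"),
    myrrh = c(14, 15, 6, 42, 35, 13, 48),
    coffee = c(152, NA, 251, 106, 293, 136, 98),
    chamomile = c(NA, 98, 39, 268, NA, 51, NA),
    combination = c(5, 26, 17, 59, 54, 17, 80),
    printed_ci = c(0.13, 0.67, 1.11, 0.73, 0.58, 0.59, 0.83),
    printed_symbol = c("++++", "+++", "-", "++", "+++", "+++", "++"),
    stringsAsFactors = FALSE
  )
  names(df)[names(df) == "coffee"] <- "coffee charcoal"
  names(df)[names(df) == "chamomile"] <- "chamomile flower"
  df
}

#' Generator configuration for synthetic assay data
#'
#' Defines the statistical structure the analysis assumes: LPS
#' fold-inductions over the uninflamed baseline, monotone 4PL
#' inhibition/enhancement curves with known IC50/EC50, multiplicative
#' log-normal noise on mediator concentrations, and paired TEER readings
#' whose difference embeds a normalized recovery curve. Defaults reproduce
#' the study design: concentration grids myrrh 0.1-100, coffee charcoal
#' 1-500, chamomile flower 0.1-200 and combination 0.25-150 ug/mL; LPS
#' fold-inductions IL-6 8.5, TNF 3.3, macrophage PGE2 6.4, IL-8 12.1,
#' MCP-1 1.6, epithelial PGE2 34; true half-maximal concentrations equal to
#' the printed summary-table values ([table1_reference()]), with `NA` cells
#' generated flat at the stimulated level (inactive).
#'
#' @param true_ic50 Numeric matrix `[4 treatments x 7 endpoints]` of true
#'   IC50/EC50 in ug/mL; `NA` = inactive. Rows `myrrh`, `coffee charcoal`,
#'   `chamomile flower`, `combination`; columns as in [endpoint_registry()].
#' @param true_hill Hill slope, recycled to the shape of `true_ic50`.
#' @param true_floor Lower plateau of the inhibition curves as a fraction of
#'   the stimulated span, in `[0, 1)`.
#' @param baseline Named per-endpoint uninflamed release level (pg/mL),
#'   i.e. the mean of the matched `ua`/`us` control.
#' @param fold_induction Named per-endpoint LPS fold-induction
#'   (stimulated / uninflamed).
#' @param grids Named list of concentration grids (ug/mL) per treatment.
#' @param replicates Wells per condition.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise (mediators) and of the additive TEER-difference noise
#'   relative to the anchor span.
#' @param teer_baseline Pre-treatment TEER (Ohm).
#' @param teer_drop_fraction Fractional TEER decline of the stimulated
#'   control over 48 h, in `(0, 1)`.
#' @param teer_rise_fraction Fractional TEER rise of the unstimulated
#'   control over 48 h.
#' @param times Measurement times (h) for cytokine/chemokine endpoints;
#'   PGE2 and TEER are measured at 48 h only.
#' @param induction_fraction Named fraction of the full 48-h induction
#'   reached at each measurement time.
#' @param seed Integer RNG seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(true_ic50 = NULL,
                             true_hill = 1,
                             true_floor = 0.05,
                             baseline = c(IL6 = 100, TNF = 150, PGE2_M = 200,
                                          IL8 = 120, MCP1 = 800,
                                          PGE2_IEC = 50),
                             fold_induction = c(IL6 = 8.5, TNF = 3.3,
                                                PGE2_M = 6.4, IL8 = 12.1,
                                                MCP1 = 1.6, PGE2_IEC = 34),
                             grids = NULL,
                             replicates = 3,
                             noise_cv = 0.15,
                             teer_baseline = 500,
                             teer_drop_fraction = 0.3,
                             teer_rise_fraction = 0.1,
                             times = c(4, 24, 48),
                             induction_fraction = c(`4` = 0.3, `24` = 0.7,
                                                    `48` = 1),
                             seed = 1L) {
  treatments <- c("myrrh", "coffee charcoal", "chamomile flower",
                  "combination")
  eps <- endpoint_registry()$endpoint
  if (is.null(grids)) {
    logspace <- function(lo, hi, n = 7) 10^seq(log10(lo), log10(hi),
                                               length.out = n)
    grids <- list(
      "myrrh" = logspace(0.1, 100),
      "coffee charcoal" = logspace(1, 500),
      "chamomile flower" = logspace(0.1, 200),
      "combination" = logspace(0.25, 150)
    )
  }
  if (is.null(true_ic50)) {
    tab <- table1_reference()
    true_ic50 <- t(as.matrix(tab[, treatments]))
    colnames(true_ic50) <- tab$endpoint
  }
  stopifnot(identical(rownames(true_ic50), treatments),
            identical(colnames(true_ic50), eps))
  if (any(!is.na(true_ic50) & true_ic50 <= 0)) {
    stop("config error: true_ic50 must be positive where present",
         call. = FALSE)
  }
  hill <- true_ic50; hill[] <- true_hill
  if (any(!is.na(hill) & hill <= 0)) {
    stop("config error: true_hill must be positive", call. = FALSE)
  }
  if (noise_cv < 0) stop("config error: noise_cv must be >= 0",
                         call. = FALSE)
  if (true_floor < 0 || true_floor >= 1) {
    stop("config error: true_floor must be in [0, 1)", call. = FALSE)
  }
  structure(list(
    treatments = treatments, true_ic50 = true_ic50, true_hill = hill,
    true_floor = true_floor, baseline = baseline,
    fold_induction = fold_induction, grids = grids,
    replicates = as.integer(replicates), noise_cv = noise_cv,
    teer_baseline = teer_baseline, teer_drop_fraction = teer_drop_fraction,
    teer_rise_fraction = teer_rise_fraction, times = times,
    induction_fraction = induction_fraction, seed = as.integer(seed)
  ), class = "generator_config")
}

# mean-preserving log-normal factors with the requested CV
ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

# 4PL inhibition mean on the raw scale
inhibition_mean <- function(x, ref, s_level, ic50, hill, floor) {
  if (is.na(ic50)) return(rep(s_level, length(x)))
  g <- floor + (1 - floor) / (1 + (x / ic50)^hill)
  ref + (s_level - ref) * g
}

#' Generate a synthetic assay dataset with known truth
#'
#' Simulates the full plate design of the co-culture experiment: stimulated
#' (`s`), inactivated (`ua`) and unstimulated (`us`) controls, a budesonide
#' positive control (`bud`), and treated wells over each treatment's
#' concentration grid. Treated mediator wells follow
#' `ref + (s - ref) * (floor + (1 - floor) / (1 + (x/ic50)^hill))` with
#' multiplicative log-normal noise; inactive cells are flat at the
#' stimulated level. TEER wells are paired before/after resistances whose
#' difference interpolates between the stimulated (fully declined) and
#' unstimulated (recovered) anchors along `x^hill / (x^hill + ec50^hill)`.
#' Cytokine/chemokine endpoints are generated at 4, 24 and 48 h with a
#' rising induction fraction; PGE2 and TEER at 48 h only.
#'
#' @param config A [generator_config()].
#' @return A list with `dataset` (an `assay_dataset`; identical seed gives
#'   an identical dataset) and `truth` (class `synthetic_truth`): the
#'   realised configuration plus the implied true combination index per
#'   endpoint, recomputed from the true IC50s via [combination_index()].
#' @examples
#' sim <- generate_assay(generator_config(noise_cv = 0, seed = 7))
#' sim$dataset
#' sim$truth$implied_ci$IL6
#' @export
generate_assay <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  reg <- endpoint_registry()
  reps <- config$replicates
  cv <- config$noise_cv
  rows <- list()
  add <- function(endpoint, compartment, treatment, control_class, conc,
                  time_h, value = NA_real_, before = NA_real_,
                  after = NA_real_) {
    n <- max(length(value), length(before))
    rows[[length(rows) + 1L]] <<- data.frame(
      endpoint = endpoint, compartment = compartment, treatment = treatment,
      control_class = control_class, concentration_ug_ml = conc,
      time_h = time_h, replicate = seq_len(n), value = value,
      value_before = before, value_after = after, stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(reg))) {
    ep <- reg$endpoint[i]
    comp <- reg$compartment[i]
    if (ep == "TEER") {
      base <- config$teer_baseline
      s_diff <- -config$teer_drop_fraction * base
      us_diff <- config$teer_rise_fraction * base
      span <- us_diff - s_diff
      teer_wells <- function(diff_mean, n) {
        before <- base * ln_noise(n, cv)
        after <- before + diff_mean + stats::rnorm(n, 0, cv * span)
        list(before = before, after = pmax(after, 1e-6))
      }
      w <- teer_wells(s_diff, reps)
      add(ep, comp, "control", "s", 0, 48, before = w$before,
          after = w$after)
      w <- teer_wells(us_diff, reps)
      add(ep, comp, "control", "us", 0, 48, before = w$before,
          after = w$after)
      w <- teer_wells(s_diff + 0.8 * span, reps)
      add(ep, comp, "budesonide", "bud", 0, 48, before = w$before,
          after = w$after)
      for (tl in config$treatments) {
        ec50 <- config$true_ic50[tl, ep]
        hill <- config$true_hill[tl, ep]
        for (x in config$grids[[tl]]) {
          rec <- if (is.na(ec50)) 0 else x^hill / (x^hill + ec50^hill)
          w <- teer_wells(s_diff + rec * span, reps)
          add(ep, comp, tl, "treated", x, 48, before = w$before,
              after = w$after)
        }
      }
    } else {
      ref <- config$baseline[[ep]]
      s48 <- ref * config$fold_induction[[ep]]
      tms <- if (ep %in% c("IL6", "TNF", "IL8", "MCP1")) config$times else 48
      ref_class <- reg$reference[i]
      for (t in tms) {
        f <- config$induction_fraction[[as.character(t)]]
        s_level <- ref + (s48 - ref) * f
        add(ep, comp, "control", "s", 0, t, value = s_level *
              ln_noise(reps, cv))
        add(ep, comp, "control", ref_class, 0, t,
            value = ref * ln_noise(reps, cv))
        add(ep, comp, "budesonide", "bud", 0, t,
            value = (ref + (s_level - ref) * 0.3) * ln_noise(reps, cv))
        for (tl in config$treatments) {
          ic50 <- config$true_ic50[tl, ep]
          hill <- config$true_hill[tl, ep]
          for (x in config$grids[[tl]]) {
            m <- inhibition_mean(x, ref, s_level, ic50, hill,
                                 config$true_floor)
            add(ep, comp, tl, "treated", x, t, value = m * ln_noise(reps, cv))
          }
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  ds <- as_assay_dataset(df, metadata = list(
    synthetic = TRUE, seed = config$seed, noise_cv = cv,
    budesonide_uM = 0.1, units = list(mediator = "pg/mL", TEER = "Ohm",
                                      concentration = "ug/mL")
  ))
  implied <- lapply(stats::setNames(reg$endpoint, reg$endpoint), function(ep) {
    ic <- config$true_ic50[, ep]
    if (is.na(ic[["combination"]]) || all(is.na(ic[1:3]))) return(NULL)
    combination_index(ic[["myrrh"]], ic[["coffee charcoal"]],
                      ic[["chamomile flower"]], ic[["combination"]],
                      endpoint = ep)
  })
  truth <- structure(list(config = config, true_ic50 = config$true_ic50,
                          true_hill = config$true_hill,
                          true_floor = config$true_floor,
                          implied_ci = implied),
                     class = "synthetic_truth")
  list(dataset = ds, truth = truth)
}

#' Low-noise fixture reproducing the study's summary table
#'
#' A generator preset whose true IC50/EC50 values equal the printed summary
#' table point estimates, with low noise (CV 0.05), so the full pipeline
#' recovers the table approximately and its combination-index column
#' near-exactly.
#'
#' @param seed Integer RNG seed.
#' @param noise_cv Noise level; default 0.05.
#' @param replicates Wells per condition; default 3.
#' @return As [generate_assay()]: list with `dataset` and `truth`.
#' @export
make_table1_fixture <- function(seed = 1L, noise_cv = 0.05, replicates = 3) {
  generate_assay(generator_config(noise_cv = noise_cv,
                                  replicates = replicates, seed = seed))
}
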