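test_that("identical constant groups give adjusted p of 1", {
  v <- rep(5, 9)
  g <- rep(c("s", "a", "b"), each = 3)
  d <- one_way_anova_dunnett(v, g)
  expect_equal(d$comparisons$adjusted_p, c(1, 1))
})

test_that("a single comparison reduces to the pooled two-sample t-test", {
  set.seed(12)
  for (i in 1:5) {
    v <- rnorm(8, sd = runif(1, 0.5, 3))
    g <- rep(c("s", "trt"), each = 4)
    d <- one_way_anova_dunnett(v, g)
    tt <- stats::t.test(v[g == "trt"], v[g == "s"], var.equal = TRUE)
    expect_equal(d$comparisons$adjusted_p, tt$p.value, tolerance = 1e-6)
  }
})

test_that("adjusted p-values match the multivariate-t reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(13)
  # balanced and unbalanced layouts
  layouts <- list(rep(c("s", "a", "b", "c"), each = 4),
                  c(rep("s", 5), rep("a", 3), rep("b", 4)))
  for (g in layouts) {
    v <- stats::rnorm(length(g), mean = (g == "a") * 1.5)
    d <- one_way_anova_dunnett(v, g)
    fg <- factor(g, levels = c("s", setdiff(unique(g), "s")))
    m <- multcomp::glht(stats::aov(v ~ fg),
                        linfct = multcomp::mcp(fg = "Dunnett"))
    ref <- summary(m)$test$pvalues
    ours <- d$comparisons$adjusted_p[
      match(setdiff(levels(fg), "s"), d$comparisons$label)]
    expect_equal(ours, as.numeric(ref), tolerance = 2e-3)
  }
})

test_that("the joint probability is monotone and properly normalised", {
  lam <- rep(1 / sqrt(2), 3)
  ps <- vapply(c(0.5, 1, 2, 4, 8), dunnett_prob, numeric(1),
               lambda = lam, df = 8)
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_equal(dunnett_prob(50, lam, 8), 1, tolerance = 1e-8)
  expect_error(dunnett_prob(2, c(0.5, 1.2), 8), "lambda")
})

test_that("two-way layout: time-constant data has zero time sums of squares", {
  g <- rep(rep(c("s", "a", "b"), each = 3), times = 3)
  tm <- rep(c(4, 24, 48), each = 9)
  base <- rep(rep(c(10, 8, 5), each = 3), times = 3)
  set.seed(14)
  noise <- rnorm(9)           # identical wells replicated across times
  v <- base + rep(noise, times = 3)
  res <- two_way_anova_dunnett(v, g, tm)
  atab <- res$anova
  expect_equal(atab["tim", "Sum Sq"], 0, tolerance = 1e-20)
  expect_equal(atab["trt:tim", "Sum Sq"], 0, tolerance = 1e-20)
})

test_that("a single time point reduces the two-way layout to the one-way test", {
  set.seed(15)
  g <- rep(c("s", "a", "b"), each = 4)
  v <- rnorm(12, mean = (g == "b") * 2)
  one <- one_way_anova_dunnett(v, g)
  two <- two_way_anova_dunnett(v, g, rep(48, 12))
  expect_equal(two$by_time[["48"]]$comparisons$adjusted_p,
               one$comparisons$adjusted_p, tolerance = 1e-12)
})

test_that("design problems are reported with context", {
  expect_error(one_way_anova_dunnett(rnorm(4), c("s", "s", "s", "a")),
               "replication")
  expect_error(one_way_anova_dunnett(rnorm(4), rep("a", 4)), "control")
  g <- rep(c("s", "a"), each = 2)
  expect_error(
    two_way_anova_dunnett(c(rnorm(4), rnorm(4)),
                          c(g, rep("a", 4)),
                          rep(c(4, 24), each = 4)),
    "design error.*24")
})

test_that("the activity verdict combines significance with curve shape", {
  d_ns <- list(comparisons = data.frame(adjusted_p = c(0.3, 0.8)))
  class(d_ns) <- "dunnett_result"
  d_sig <- list(comparisons = data.frame(adjusted_p = c(0.004, 0.8)))
  class(d_sig) <- "dunnett_result"
  expect_false(is_active(d_ns, flat_curve_verdict = TRUE))
  expect_false(is_active(d_ns, flat_curve_verdict = FALSE))
  expect_false(is_active(d_sig, flat_curve_verdict = TRUE))
  expect_true(is_active(d_sig, flat_curve_verdict = FALSE))
})

test_that("a strong inhibitor is detected at its top concentration", {
  hits <- 0L
  for (s in 1:20) {
    sim <- generate_assay(generator_config(noise_cv = 0.15, seed = 100 + s))
    df <- sim$dataset$measurements
    sel <- df$endpoint == "IL6" &
      (df$control_class == "s" |
         (df$control_class == "treated" & df$treatment == "myrrh"))
    sub <- df[sel & df$time_h == 48, ]
    grp <- ifelse(sub$control_class == "s", "s",
                  as.character(sub$concentration_ug_ml))
    d <- one_way_anova_dunnett(sub$value, grp)
    top <- d$comparisons[which.max(as.numeric(d$comparisons$label)), ]
    hits <- hits + (top$adjusted_p < 0.05)
  }
  expect_gte(hits, 18L)
})
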