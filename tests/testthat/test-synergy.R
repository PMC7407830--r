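test_that("all printed summary-table rows reproduce against the brute-force oracle", {
  tab <- table1_reference()
  for (i in seq_len(nrow(tab))) {
    ics <- c(tab$myrrh[i], tab[["coffee charcoal"]][i],
             tab[["chamomile flower"]][i])
    res <- combination_index(ics[1], ics[2], ics[3], tab$combination[i])
    expect_equal(res$ci_value, oracle_ci(ics, tab$combination[i]),
                 tolerance = 1e-12)
    expect_equal(round(res$ci_value, 2), tab$printed_ci[i])
    expect_identical(res$symbol, tab$printed_symbol[i])
    expect_equal(sum(res$terms), res$ci_value, tolerance = 1e-12)
    expect_equal(res$ic50_comb * 3, tab$combination[i])
    expect_equal(length(res$included), sum(!is.na(ics)))
  }
})

test_that("equal potency across components and combination is exactly additive", {
  for (x in c(0.2, 1, 14, 500)) {
    res <- combination_index(x, x, x, x)
    expect_identical(res$ci_value, 1)
    expect_identical(res$category, "nearly_additive")
    expect_identical(res$symbol, "0")
  }
})

test_that("term extraction and input validation behave as specified", {
  res <- combination_index(14, 152, NA, 5, labels = c("m", "c", "ch"))
  expect_identical(res$included, c("m", "c"))
  expect_equal(length(res$terms), 2L)
  expect_error(combination_index(NA, NA, NA, 5), "no active component")
  expect_error(combination_index(-1, 152, NA, 5), "positive")
  expect_error(combination_index(14, 152, NA, 0), "positive")
})

test_that("the index is unit-invariant and monotone in its inputs", {
  set.seed(16)
  for (i in 1:20) {
    ic <- runif(3, 1, 300)
    comb <- runif(1, 1, 200)
    base <- combination_index(ic[1], ic[2], ic[3], comb)$ci_value
    c0 <- runif(1, 0.01, 100)
    scaled <- combination_index(c0 * ic[1], c0 * ic[2], c0 * ic[3],
                                c0 * comb)$ci_value
    expect_equal(scaled, base, tolerance = 1e-12)
    # strictly increasing in the combination, decreasing in each component
    expect_gt(combination_index(ic[1], ic[2], ic[3], comb * 1.3)$ci_value,
              base)
    expect_lt(combination_index(ic[1] * 1.3, ic[2], ic[3], comb)$ci_value,
              base)
  }
})

test_that("category bands follow the Chou scheme with a fixed edge convention", {
  cases <- list(
    list(0.13, "strong_synergism", "++++"),
    list(0.3, "synergism", "+++"),
    list(0.58, "synergism", "+++"),
    list(0.7, "moderate_synergism", "++"),
    list(0.83, "moderate_synergism", "++"),
    list(0.85, "slight_synergism", "+"),
    list(0.9, "nearly_additive", "0"),
    list(1.0, "nearly_additive", "0"),
    list(1.10, "nearly_additive", "0"),
    list(1.11, "slight_antagonism", "-"),
    list(1.20, "slight_antagonism", "-"),
    list(1.45, "moderate_antagonism", "--"),
    list(2.0, "antagonism", "---"),
    list(5.0, "strong_antagonism", "----")
  )
  for (cs in cases) {
    res <- categorize_ci(cs[[1]])
    expect_identical(res$category, cs[[2]])
    expect_identical(res$symbol, cs[[3]])
    expect_false(res$out_of_scale)
  }
  low <- categorize_ci(0.05)
  expect_identical(low$category, "strong_synergism")
  expect_true(low$out_of_scale)
  high <- categorize_ci(12)
  expect_identical(high$category, "strong_antagonism")
  expect_true(high$out_of_scale)
  expect_error(categorize_ci(0), "positive")
  expect_error(categorize_ci(-1), "positive")
})

test_that("bootstrap interval collapses to the point value at zero uncertainty", {
  sim <- noise_free_sim()
  fits <- lapply(c("myrrh", "coffee charcoal", "chamomile flower",
                   "combination"), function(tl) {
    f <- fit_inhibition(extract_series(sim$dataset, "PGE2_M", tl, 48))
    f
  })
  res <- combination_interval(fits[[1]], fits[[2]], fits[[3]], fits[[4]],
                              n_boot = 200, seed = 9)
  expect_equal(res$lower, res$point$ci_value, tolerance = 1e-9)
  expect_equal(res$upper, res$point$ci_value, tolerance = 1e-9)
})

test_that("bootstrap interval brackets the point index under noise", {
  sim <- generate_assay(generator_config(noise_cv = 0.15, seed = 61))
  fits <- lapply(c("myrrh", "coffee charcoal", "chamomile flower",
                   "combination"), function(tl) {
    fit_inhibition(extract_series(sim$dataset, "PGE2_M", tl, 48))
  })
  res <- combination_interval(fits[[1]], fits[[2]], fits[[3]], fits[[4]],
                              n_boot = 500, seed = 9)
  expect_true(res$lower < res$point$ci_value &&
                res$point$ci_value < res$upper)
  res2 <- combination_interval(fits[[1]], fits[[2]], fits[[3]], fits[[4]],
                               n_boot = 500, seed = 9)
  expect_identical(c(res$lower, res$upper), c(res2$lower, res2$upper))

  flat <- fits[[1]]; flat$converged <- FALSE
  expect_error(combination_interval(flat, fits[[2]], fits[[3]], fits[[4]]),
               "propagation unavailable")
})
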