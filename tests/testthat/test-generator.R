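test_that("identical config and seed give an identical dataset", {
  a <- generate_assay(generator_config(seed = 5))
  b <- generate_assay(generator_config(seed = 5))
  expect_identical(a$dataset$measurements, b$dataset$measurements)
  c <- generate_assay(generator_config(seed = 6))
  expect_false(identical(a$dataset$measurements, c$dataset$measurements))
})

test_that("invalid configurations are rejected", {
  ic <- generator_config()$true_ic50
  ic["myrrh", "IL6"] <- -3
  expect_error(generator_config(true_ic50 = ic), "positive")
  expect_error(generator_config(true_hill = 0), "hill")
  expect_error(generator_config(noise_cv = -0.1), "noise_cv")
  expect_error(generator_config(true_floor = 1.2), "floor")
})

test_that("noise-free wells sit exactly on the Hill curve (midpoint identity)", {
  ic <- generator_config()$true_ic50
  ic[] <- NA
  ic["myrrh", "IL6"] <- 10      # grid contains x = 10 exactly
  cfg <- generator_config(true_ic50 = ic, true_floor = 0, noise_cv = 0,
                          seed = 2)
  sim <- generate_assay(cfg)
  ser <- extract_series(sim$dataset, "IL6", "myrrh", 48)
  mid <- ser$response[ser$concentration == 10]
  expect_equal(mid, rep((ser$s_mean + ser$ref_mean) / 2, length(mid)),
               tolerance = 1e-12)
})

test_that("control fold-inductions reproduce the configured LPS response", {
  sim <- noise_free_sim()
  df <- sim$dataset$measurements
  lev <- function(ep, cc) {
    mean(df$value[df$endpoint == ep & df$control_class == cc &
                    df$time_h == 48])
  }
  expect_equal(fold_induction(lev("IL6", "s"), lev("IL6", "ua")), 8.5)
  expect_equal(fold_induction(lev("TNF", "s"), lev("TNF", "ua")), 3.3)
  expect_equal(fold_induction(lev("PGE2_M", "s"), lev("PGE2_M", "ua")), 6.4)
  expect_equal(fold_induction(lev("IL8", "s"), lev("IL8", "us")), 12.1)
  expect_equal(fold_induction(lev("MCP1", "s"), lev("MCP1", "us")), 1.6)
  expect_equal(fold_induction(lev("PGE2_IEC", "s"), lev("PGE2_IEC", "us")),
               34)
})

test_that("noisy fold-inductions match the configuration within 3 SE", {
  cfg <- generator_config(noise_cv = 0.15, replicates = 8, seed = 11)
  df <- generate_assay(cfg)$dataset$measurements
  for (ep in c("IL6", "IL8")) {
    ref_cc <- endpoint_registry()$reference[
      endpoint_registry()$endpoint == ep]
    s <- df$value[df$endpoint == ep & df$control_class == "s" &
                    df$time_h == 48]
    u <- df$value[df$endpoint == ep & df$control_class == ref_cc &
                    df$time_h == 48]
    fold_hat <- mean(s) / mean(u)
    # delta-method SE of the ratio of means
    se <- fold_hat * sqrt(stats::var(s) / (length(s) * mean(s)^2) +
                            stats::var(u) / (length(u) * mean(u)^2))
    expect_lt(abs(fold_hat - cfg$fold_induction[[ep]]), 3 * se)
  }
})

test_that("implied true combination indices are recomputable from the truth", {
  sim <- noise_free_sim()
  truth <- sim$truth
  # epithelial PGE2: hand-frozen value of (17/3) * (1/13 + 1/136 + 1/51)
  expect_equal(truth$implied_ci$PGE2_IEC$ci_value, 0.5886752,
               tolerance = 1e-6)
  for (ep in names(truth$implied_ci)) {
    ic <- truth$true_ic50[, ep]
    expect_equal(truth$implied_ci[[ep]]$ci_value,
                 oracle_ci(ic[1:3], ic[["combination"]]),
                 tolerance = 1e-12)
  }
})

test_that("table fixture truth carries the printed point estimates", {
  fx <- make_table1_fixture(seed = 3)
  expect_equal(unname(fx$truth$true_ic50[, "IL6"]), c(14, 152, NA, 5))
  expect_equal(unname(fx$truth$true_ic50[, "TEER"]), c(48, 98, NA, 80))
  expect_equal(fx$truth$config$noise_cv, 0.05)
})

test_that("TEER wells are positive paired readings embedding the recovery curve", {
  sim <- noise_free_sim()
  df <- sim$dataset$measurements
  te <- df[df$endpoint == "TEER", ]
  expect_true(all(te$value_before > 0 & te$value_after > 0))
  ser <- extract_series(sim$dataset, "TEER", "myrrh", 48)
  norm <- normalize_teer(ser$response, ser$s_mean, ser$ref_mean)
  # at x = ec50 = 48 the normalized recovery would be exactly 50; the grid
  # brackets it, so normalized values must cross 50 monotonically
  expect_true(all(diff(tapply(norm, ser$concentration, mean)) > 0))
  expect_lt(min(norm), 50)
  expect_gt(max(norm), 50)
})
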