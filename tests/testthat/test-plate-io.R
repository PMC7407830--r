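test_that("a minimal well-formed long CSV reads into a validated dataset", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(minimal_long_df(), path, row.names = FALSE)
  ds <- read_assay_csv(path)
  expect_s3_class(ds, "assay_dataset")
  expect_equal(nrow(ds$measurements), 3L)
  expect_output(print(ds), "3 well-measurements")
})

test_that("schema and validation errors name the offending column or row", {
  df <- minimal_long_df()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, setdiff(names(df), "control_class")], path,
                   row.names = FALSE)
  expect_error(read_assay_csv(path), "control_class")

  bad <- df; bad$value[2] <- -5
  expect_error(as_assay_dataset(bad), "row.*2")

  bad <- df; bad$endpoint <- "IL99"
  expect_error(as_assay_dataset(bad), "IL99")

  bad <- df; bad$control_class[1] <- "mystery"
  expect_error(as_assay_dataset(bad), "mystery")

  bad <- df; bad$compartment[1] <- "epithelial_apical"
  expect_error(as_assay_dataset(bad), "compartment")

  empty <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[0, ], empty, row.names = FALSE)
  expect_error(read_assay_csv(empty), "empty")
})

test_that("write/read round trip preserves text exactly and reals to 12 sig digits", {
  sim <- noise_free_sim()
  ds <- generate_assay(generator_config(noise_cv = 0.2, seed = 99))$dataset
  path <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(ds, path)
  back <- read_assay_csv(path)
  a <- ds$measurements
  b <- back$measurements
  expect_identical(dim(a), dim(b))
  for (col in names(a)) {
    if (is.numeric(a[[col]])) {
      expect_equal(b[[col]], a[[col]], tolerance = 1e-12, ignore_attr = TRUE)
    } else {
      expect_identical(as.character(b[[col]]), as.character(a[[col]]))
    }
  }
})

test_that("extract_series returns sorted pairs with anchors over the design grids", {
  sim <- noise_free_sim()
  ser <- extract_series(sim$dataset, "IL6", "myrrh", 48)
  expect_equal(range(ser$concentration), c(0.1, 100))
  expect_false(is.unsorted(ser$concentration))
  expect_gt(ser$s_mean, ser$ref_mean)  # LPS induction

  te <- extract_series(sim$dataset, "TEER", "combination", 48)
  expect_equal(range(te$concentration), c(0.25, 150))
  expect_lt(te$s_mean, te$ref_mean)  # stimulated barrier declines most

  # reporting labels resolve too
  ser2 <- extract_series(sim$dataset, "M-IL-6", "myrrh", 48)
  expect_identical(ser2$response, ser$response)

  expect_error(extract_series(sim$dataset, "IL6", "nonexistent", 48),
               "lookup")
  trunc <- as_assay_dataset(
    sim$dataset$measurements[sim$dataset$measurements$endpoint != "TNF", ])
  expect_error(extract_series(trunc, "TNF", "myrrh", 48), "lookup")
})

test_that("series extraction partitions the dataset: cells plus controls cover every row", {
  sim <- noise_free_sim()
  df <- sim$dataset$measurements
  n_controls <- sum(df$control_class != "treated")
  cells <- unique(df[df$control_class == "treated",
                     c("endpoint", "treatment", "time_h")])
  n_series <- sum(vapply(seq_len(nrow(cells)), function(i) {
    length(extract_series(sim$dataset, cells$endpoint[i],
                          cells$treatment[i],
                          cells$time_h[i])$concentration)
  }, numeric(1)))
  expect_equal(n_series + n_controls, nrow(df))
})

test_that("results table mirrors the summary-table layout", {
  res <- run_assay_analysis(noise_free_sim()$dataset)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_results_table(res, path)
  expect_equal(nrow(tab), 7L)
  expect_true(file.exists(path))
  row1 <- tab[tab$endpoint == "M-IL-6", ]
  expect_match(row1$myrrh, "^14 ")
  expect_identical(row1[["chamomile flower"]], "-")
  expect_match(row1$combination_index, "^0\\.13 \\(\\+\\+\\+\\+\\)$")
  expect_error(write_results_table(list(), path), "empty")
})
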