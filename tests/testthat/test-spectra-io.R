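test_that("spectrum files parse, sort and average duplicate shifts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1350,10.0", "1580,25.0"), f)
  sp <- read_spectrum(f)
  expect_s3_class(sp, "raman_spectrum")
  expect_equal(sp$shifts, c(1350, 1580))
  expect_equal(sp$intensities, c(10, 25))

  # out-of-order rows are sorted
  writeLines(c("1580,25.0", "1350,10.0"), f)
  expect_equal(read_spectrum(f)$shifts, c(1350, 1580))

  # duplicate shifts collapse to the mean intensity
  writeLines(c("1350,10", "1350,30"), f)
  sp <- read_spectrum(f)
  expect_equal(sp$shifts, 1350)
  expect_equal(sp$intensities, 20)
})

test_that("spectrum parsing handles headers, delimiters and bad input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("shift;intensity", "1350;10", "1580;25"), f)
  expect_equal(read_spectrum(f)$intensities, c(10, 25))

  writeLines(c("1350\t10", "1580\t25"), f)
  expect_equal(read_spectrum(f, delimiter = "\t")$shifts, c(1350, 1580))

  writeLines(c("1350,10", "1580,abc"), f)
  expect_error(read_spectrum(f), "line 2.*abc")

  writeLines(character(0), f)
  expect_error(read_spectrum(f), "empty")

  writeLines(c("1350,-5", "1580,25"), f)
  expect_warning(sp <- read_spectrum(f), "clipped")
  expect_equal(sp$intensities, c(0, 25))
})

test_that("reading is order-insensitive up to the sort contract", {
  f <- withr::local_tempfile(fileext = ".csv")
  set.seed(42)
  shifts <- sample(seq(100, 1700, by = 50))
  rows <- sprintf("%g,%g", shifts, sqrt(shifts))
  writeLines(rows, f)
  a <- read_spectrum(f, label = "x")
  writeLines(rev(rows), f)
  b <- read_spectrum(f, label = "x")
  expect_identical(a, b)
})

test_that("case tables validate vocabularies and report counts", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- toy_records()[1:3, ]
  out <- stats::setNames(df, unname(default_case_columns()[names(df)]))
  write.csv(out, f, row.names = FALSE)
  expect_message(cases <- read_case_table(f), "3 case")
  expect_equal(nrow(cases), 3L)
  expect_equal(cases$cnt_type, rep("MWCNT", 3))

  out$Solvent[2] <- "ethanol"
  write.csv(out, f, row.names = FALSE)
  expect_error(suppressMessages(read_case_table(f)), "row 2.*ethanol.*solvent")

  out$Solvent <- NULL
  write.csv(out, f, row.names = FALSE)
  expect_error(read_case_table(f), "missing column.*Solvent")
})

test_that("feature tables round-trip through CSV to 12 significant digits", {
  tab <- data.frame(a = c(pi, exp(1), 1/3) * 1e3, b = c(1e-4, 123456.789, 2/7))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_equal(back$a, tab$a, tolerance = 1e-12)
  expect_equal(back$b, tab$b, tolerance = 1e-12)
})
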